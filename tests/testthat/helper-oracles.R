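# Fixture builders and independent brute-force oracles shared across tests.

# build a kafr_tracks object from coordinate matrices (frames x channels)
make_tracks <- function(x, y = NULL, present = NULL, fps = 6) {
  x <- as.matrix(x)
  y <- if (is.null(y)) matrix(0, nrow(x), ncol(x)) else as.matrix(y)
  channels <- paste0("ch", seq_len(ncol(x)))
  tr <- kafr::new_tracks(channels, nrow(x), fps)
  tr$x[] <- x; tr$y[] <- y
  tr$present[] <- if (is.null(present)) !is.na(x) else as.matrix(present)
  tr$x[!tr$present] <- NA_real_; tr$y[!tr$present] <- NA_real_
  tr
}

# constant-motion track: +speed px/frame along x
linear_track <- function(n, speed = 1, fps = 6) {
  make_tracks(matrix((seq_len(n) - 1) * speed, ncol = 1), fps = fps)
}

# smooth continuously-present tracks: random sinusoid mixtures with drift
# (the regime for which the retained-count monotonicity in z* holds; see
# the methods vignette on why jagged motion or dropout can break it)
smooth_tracks <- function(n_frames, n_channels = 2, seed = 1, fps = 6) {
  set.seed(seed)
  t <- seq_len(n_frames) / fps
  coord <- function() sapply(seq_len(n_channels), function(i)
    runif(1, 0, 100) + runif(1, 2, 15) * sin(2 * pi * t / runif(1, 2, 6) + runif(1, 0, 6)) +
      cumsum(rnorm(n_frames, 0, 0.1)))
  make_tracks(coord(), coord(), fps = fps)
}

# rough random tracks: per-channel random walk with varying step scale
random_tracks <- function(n_frames, n_channels = 2, seed = 1,
                          dropout = 0, fps = 6) {
  set.seed(seed)
  x <- sapply(seq_len(n_channels), function(i)
    cumsum(rnorm(n_frames, 0, runif(1, 0.2, 3))) + runif(1, 0, 100))
  y <- sapply(seq_len(n_channels), function(i)
    cumsum(rnorm(n_frames, 0, runif(1, 0.2, 3))) + runif(1, 0, 100))
  present <- matrix(runif(n_frames * n_channels) >= dropout, n_frames)
  make_tracks(x, y, present, fps = fps)
}

# scalar double-loop anchor-relative displacement sum (0-based i, j)
oracle_disp_sum <- function(tracks, i, j) {
  z <- 0
  for (ch in seq_along(tracks$channels)) {
    if (!tracks$present[i + 1, ch]) next
    for (k in (i + 1):j) {
      if (!tracks$present[k + 1, ch]) next
      z <- z + sqrt((tracks$x[i + 1, ch] - tracks$x[k + 1, ch])^2 +
                    (tracks$y[i + 1, ch] - tracks$y[k + 1, ch])^2)
    }
  }
  unname(z)
}

# scalar backward-difference velocity, independent of compute_velocity
oracle_velocity <- function(tracks, max_gap = 3) {
  n <- nrow(tracks$x); nc <- ncol(tracks$x)
  vx <- matrix(NA_real_, n, nc); vy <- matrix(NA_real_, n, nc)
  for (ch in seq_len(nc)) {
    prev <- NA
    for (k in seq_len(n)) {
      if (!tracks$present[k, ch]) next
      if (!is.na(prev) && (k - prev) <= max_gap) {
        vx[k, ch] <- (tracks$x[k, ch] - tracks$x[prev, ch]) * tracks$fps / (k - prev)
        vy[k, ch] <- (tracks$y[k, ch] - tracks$y[prev, ch]) * tracks$fps / (k - prev)
      }
      prev <- k
    }
  }
  list(vx = vx, vy = vy, defined = !is.na(vx))
}

oracle_vel_sum <- function(vel, i, j) {
  z <- 0
  for (ch in seq_len(ncol(vel$vx))) {
    if (!vel$defined[i + 1, ch]) next
    for (k in (i + 1):j) {
      if (!vel$defined[k + 1, ch]) next
      z <- z + sqrt((vel$vx[i + 1, ch] - vel$vx[k + 1, ch])^2 +
                    (vel$vy[i + 1, ch] - vel$vy[k + 1, ch])^2)
    }
  }
  unname(z)
}

# exhaustive greedy reference: recomputes every anchor sum from scratch by
# double loop; returns 0-based retained indices. Mirrors the stated scan
# rules, including silent re-anchoring away from dead anchors (no usable
# channel) with pair-closing taking precedence.
oracle_select <- function(tracks, mode, zstar, max_gap = 3) {
  n <- nrow(tracks$x)
  vel <- if (mode == "adaptive2") oracle_velocity(tracks, max_gap) else NULL
  usable <- if (mode == "adaptive1") tracks$present else vel$defined
  sum_fun <- function(i, j) {
    if (mode == "adaptive1") oracle_disp_sum(tracks, i, j) else oracle_vel_sum(vel, i, j)
  }
  retained <- 0L
  a <- 0L
  repeat {
    closed <- FALSE
    if (a < n - 1L) {
      for (j in (a + 1L):(n - 1L)) {
        if (sum_fun(a, j) >= zstar) {
          retained <- c(retained, a, j)
          a <- j
          closed <- TRUE
          break
        }
        if (!any(usable[a + 1L, ]) && any(usable[j + 1L, ])) {
          a <- j                       # silent re-anchor, not retained
          closed <- TRUE
          break
        }
      }
    }
    if (!closed) break
  }
  sort(unique(c(retained, n - 1L)))
}

# even-odd point-in-polygon (for the Monte-Carlo centroid oracle)
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- (yi > py) != (yj > py) &
      px < (xj - xi) * (py - yi) / (yj - yi) + xi
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

mc_polygon_centroid <- function(poly, n = 2e5, seed = 42) {
  set.seed(seed)
  px <- runif(n, min(poly[, 1]), max(poly[, 1]))
  py <- runif(n, min(poly[, 2]), max(poly[, 2]))
  hit <- point_in_polygon(px, py, poly)
  c(mean(px[hit]), mean(py[hit]))
}

# pixel-rasterization IOU oracle for axis-aligned boxes
raster_iou <- function(a, b, res = 400) {
  xs <- seq(min(a[1], b[1]), max(a[3], b[3]), length.out = res)
  ys <- seq(min(a[2], b[2]), max(a[4], b[4]), length.out = res)
  g <- expand.grid(x = xs, y = ys)
  in_a <- g$x >= a[1] & g$x <= a[3] & g$y >= a[2] & g$y <= a[4]
  in_b <- g$x >= b[1] & g$x <= b[3] & g$y >= b[2] & g$y <= b[4]
  sum(in_a & in_b) / sum(in_a | in_b)
}
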