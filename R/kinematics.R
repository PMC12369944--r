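#' Per-channel centroid velocity
#'
#' Backward difference to the previous present frame, scaled by true elapsed
#' time: at a present frame `k` whose previous present frame is `p`,
#' `v = (pos_k - pos_p) * fps / (k - p)` in px/s. Velocity is undefined at
#' the first present frame of a channel and after presence gaps longer than
#' `max_gap` frames (occlusion runs would otherwise produce teleport spikes).
#'
#' @param tracks A `kafr_tracks` object.
#' @param max_gap Longest bridgeable presence gap in frames (default 3,
#'   i.e. 0.5 s at 6 fps).
#' @return A `kafr_velocity` object: matrices `vx`, `vy` (px/s, NA where
#'   undefined), logical `defined`, plus `channels`, `frames`, `fps`.
#' @export
compute_velocity <- function(tracks, max_gap = 3L) {
  stopifnot(inherits(tracks, "kafr_tracks"), tracks$fps > 0, max_gap >= 1)
  n <- length(tracks$frames); nc <- length(tracks$channels)
  vx <- matrix(NA_real_, n, nc, dimnames = list(NULL, tracks$channels))
  vy <- vx
  defined <- matrix(FALSE, n, nc, dimnames = list(NULL, tracks$channels))
  for (ch in seq_len(nc)) {
    pres <- which(tracks$present[, ch])
    if (length(pres) < 2) next
    gap <- diff(pres)
    ok <- gap <= max_gap
    k <- pres[-1][ok]; p <- pres[-length(pres)][ok]
    vx[k, ch] <- (tracks$x[k, ch] - tracks$x[p, ch]) * tracks$fps / (k - p)
    vy[k, ch] <- (tracks$y[k, ch] - tracks$y[p, ch]) * tracks$fps / (k - p)
    defined[k, ch] <- TRUE
  }
  structure(list(channels = tracks$channels, frames = tracks$frames,
                 vx = vx, vy = vy, defined = defined, fps = tracks$fps),
            class = "kafr_velocity")
}

#' Anchor-relative displacement sum
#'
#' The accumulation statistic behind the Adaptive 1 selector: for anchor
#' frame `i` and current frame `j`,
#' `z_d = sum over channels s, sum over k = i+1..j of ||s(x_i) - s(x_k)||`
#' (Euclidean distance between the channel's centroid at the anchor and at
#' frame k). Terms where either endpoint is absent contribute 0, so a tool
#' that vanishes never triggers key pairs by itself.
#'
#' @param tracks A `kafr_tracks` object.
#' @param i,j 0-based frame indices with `i < j`.
#' @return Non-negative scalar `z_d`.
#' @export
anchor_displacement_sum <- function(tracks, i, j) {
  .check_anchor_pair(tracks$frames, i, j)
  ai <- i + 1L
  rows <- (i + 2L):(j + 1L)
  dx <- tracks$x[rows, , drop = FALSE] - rep(tracks$x[ai, ], each = length(rows))
  dy <- tracks$y[rows, , drop = FALSE] - rep(tracks$y[ai, ], each = length(rows))
  d <- sqrt(dx^2 + dy^2)
  ok <- tracks$present[rows, , drop = FALSE] &
    rep(tracks$present[ai, ], each = length(rows))
  sum(d[ok])
}

#' Anchor-relative velocity-variation sum
#'
#' The accumulation statistic behind the Adaptive 2 selector: for anchor
#' `i` and current frame `j`,
#' `z_v = sum over channels s, sum over k = i+1..j of ||V_s(x_i) - V_s(x_k)||`.
#' Terms with undefined velocity at either endpoint contribute 0.
#'
#' @param vel A `kafr_velocity` object.
#' @param i,j 0-based frame indices with `i < j`.
#' @return Non-negative scalar `z_v`.
#' @export
anchor_velocity_variation_sum <- function(vel, i, j) {
  .check_anchor_pair(vel$frames, i, j)
  ai <- i + 1L
  rows <- (i + 2L):(j + 1L)
  dvx <- vel$vx[rows, , drop = FALSE] - rep(vel$vx[ai, ], each = length(rows))
  dvy <- vel$vy[rows, , drop = FALSE] - rep(vel$vy[ai, ], each = length(rows))
  d <- sqrt(dvx^2 + dvy^2)
  ok <- vel$defined[rows, , drop = FALSE] &
    rep(vel$defined[ai, ], each = length(rows))
  sum(d[ok])
}

.check_anchor_pair <- function(frames, i, j) {
  if (!(i < j)) kafr_stop("anchor i must precede j", "kafr_argument_error")
  if (i < 0 || j > max(frames)) kafr_stop("frame index out of range", "kafr_argument_error")
  invisible(TRUE)
}

#' Write a velocity table
#'
#' CSV with columns `video`, `channel`, `frame`, `vx`, `vy`, `defined`.
#'
#' @param vel A `kafr_velocity` object.
#' @param path Output CSV path.
#' @param video Video identifier.
#' @export
write_velocity <- function(vel, path, video = "video0") {
  n <- length(vel$frames)
  df <- data.frame(
    video = video,
    channel = rep(vel$channels, each = n),
    frame = rep(vel$frames, times = length(vel$channels)),
    vx = as.vector(vel$vx), vy = as.vector(vel$vy),
    defined = as.vector(vel$defined)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
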