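#' Decreasing similarity transform
#'
#' Maps an accumulated kinematic sum `z` to the similarity scale on which a
#' frame pair is declared "key" when the value drops to or below a threshold
#' `d`: `f(z) = 1 / (z + epsilon)^beta`, strictly decreasing in `z`. The
#' exponent `beta` and guard `epsilon` only matter when a user supplies a
#' threshold on this scale; selection itself runs on the equivalent raw-sum
#' scale (`z >= z*` with `z* = d^(-1/beta) - epsilon`).
#'
#' @param z Non-negative accumulation sum (vectorized).
#' @param beta Positive exponent (default 1).
#' @param epsilon Small positive guard against division by zero
#'   (default 1e-8).
#' @return `1 / (z + epsilon)^beta`.
#' @export
#' @examples
#' f_transform(9, beta = 1, epsilon = 1)  # 0.1
f_transform <- function(z, beta = 1, epsilon = 1e-8) {
  stopifnot(beta > 0, epsilon > 0, all(z >= 0))
  1 / (z + epsilon)^beta
}

#' Selection configuration
#'
#' Exactly one of `threshold_z` (raw-sum scale), `threshold_d`
#' (f-transform scale) or `target_retention` must drive selection.
#'
#' @param mode `"adaptive1"` (anchor-relative displacement) or
#'   `"adaptive2"` (anchor-relative velocity variation).
#' @param threshold_z Threshold on the raw accumulation-sum scale (>= 0).
#' @param threshold_d Threshold on the f-transform scale (> 0); converted
#'   via `z* = d^(-1/beta) - epsilon`.
#' @param target_retention Fraction of frames to retain, in (0, 1]; resolved
#'   to a threshold by [calibrate_threshold()].
#' @param beta,epsilon Parameters of [f_transform()].
#' @param max_gap Passed to [compute_velocity()] for `adaptive2`.
#' @param tol Calibration tolerance on the retained fraction.
#' @return A `selection_config` object.
#' @export
selection_config <- function(mode = c("adaptive1", "adaptive2"),
                             threshold_z = NULL, threshold_d = NULL,
                             target_retention = NULL,
                             beta = 1, epsilon = 1e-8,
                             max_gap = 3L, tol = 0.005) {
  mode <- match.arg(mode)
  n_drivers <- sum(!is.null(threshold_z), !is.null(threshold_d), !is.null(target_retention))
  if (n_drivers != 1)
    kafr_stop("exactly one of threshold_z / threshold_d / target_retention must be set",
              "kafr_config_error")
  stopifnot(beta > 0, epsilon > 0)
  if (!is.null(threshold_z) && threshold_z < 0)
    kafr_stop("threshold_z must be >= 0", "kafr_config_error")
  if (!is.null(threshold_d) && threshold_d <= 0)
    kafr_stop("threshold_d must be > 0", "kafr_config_error")
  if (!is.null(target_retention) &&
      (target_retention <= 0 || target_retention > 1))
    kafr_stop("target_retention must be in (0, 1]", "kafr_config_error")
  structure(list(mode = mode, threshold_z = threshold_z, threshold_d = threshold_d,
                 target_retention = target_retention, beta = beta, epsilon = epsilon,
                 max_gap = as.integer(max_gap), tol = tol),
            class = "selection_config")
}

# channel position/velocity matrices for the scan: rows = frames
.scan_inputs <- function(series_set, mode, max_gap = 3L) {
  if (mode == "adaptive1") {
    stopifnot(inherits(series_set, "kafr_tracks"))
    list(px = series_set$x, py = series_set$y, ok = series_set$present)
  } else {
    vel <- if (inherits(series_set, "kafr_velocity")) series_set
           else compute_velocity(series_set, max_gap = max_gap)
    list(px = vel$vx, py = vel$vy, ok = vel$defined)
  }
}

# greedy key-pair scan on 1-based rows; z accumulates anchor-relative
# channel distances and a pair closes at the first j with z >= zstar.
# A dead anchor (no usable channel: all absent, or velocity undefined at
# the anchor -- always the case at the very first frame in adaptive2) can
# never accumulate, so it is silently re-anchored at the next frame with
# usable data; closing takes precedence so zstar = 0 still retains all.
.scan_adaptive <- function(px, py, ok, zstar) {
  n <- nrow(px)
  pi <- integer(n); pj <- integer(n); np <- 0L
  a <- 1L; z <- 0
  ax <- px[1L, ]; ay <- py[1L, ]; aok <- ok[1L, ]
  a_alive <- any(aok)
  for (j in seq_len(n)[-1L]) {
    jok <- ok[j, ]
    m <- aok & jok
    if (any(m))
      z <- z + sum(sqrt((px[j, m] - ax[m])^2 + (py[j, m] - ay[m])^2))
    if (z >= zstar) {
      np <- np + 1L; pi[np] <- a; pj[np] <- j
    } else if (a_alive || !any(jok)) {
      next
    }
    a <- j; ax <- px[j, ]; ay <- py[j, ]; aok <- jok
    a_alive <- any(aok)
    z <- 0
  }
  list(i = pi[seq_len(np)], j = pj[seq_len(np)], n = n)
}

.keyframes_from_scan <- function(scan, zstar, mode) {
  retained <- sort(unique(c(1L, scan$i, scan$j, scan$n))) - 1L
  pairs <- cbind(i = scan$i - 1L, j = scan$j - 1L)
  structure(list(retained = retained, pairs = pairs,
                 threshold_z_effective = zstar, mode = mode,
                 n_frames = scan$n),
            class = "kafr_keyframes")
}

#' @export
print.kafr_keyframes <- function(x, ...) {
  cat(sprintf("<kafr_keyframes> mode %s: %d / %d frames retained (%.2f%%), z* = %.6g\n",
              x$mode, length(x$retained), x$n_frames,
              100 * length(x$retained) / x$n_frames, x$threshold_z_effective))
  invisible(x)
}

#' Select key frames by adaptive kinematic accumulation
#'
#' Greedy key-pair scan: the first frame is the initial anchor; the scan
#' advances frame by frame accumulating the anchor-relative displacement sum
#' (`adaptive1`, see [anchor_displacement_sum()]) or velocity-variation sum
#' (`adaptive2`, see [anchor_velocity_variation_sum()]). The first frame `j`
#' whose accumulated sum reaches the threshold (`f(z) <= d`, equivalently
#' `z >= z*`) closes the key pair `(i, j)`; frames strictly between are
#' discarded as similar, and `j` becomes the next anchor. Both members of
#' every pair are retained; the first and final frames are always retained,
#' so any sequence yields at least 2 frames.
#'
#' An anchor with no usable channel — every channel absent, or (always the
#' case at the very first frame under `adaptive2`) velocity undefined at
#' the anchor — contributes nothing to any accumulation sum and would stall
#' the scan forever; such a dead anchor is silently re-anchored at the next
#' frame with usable data (pair closing takes precedence, so a zero
#' threshold still retains every frame).
#'
#' @param series_set A `kafr_tracks` object (for `adaptive2` a
#'   `kafr_velocity` is also accepted).
#' @param cfg A [selection_config()].
#' @return A `kafr_keyframes` object with `retained` (0-based indices),
#'   `pairs` (the key-pair chain), `threshold_z_effective`, `mode`,
#'   `n_frames`.
#' @export
select_keyframes <- function(series_set, cfg) {
  stopifnot(inherits(cfg, "selection_config"))
  inp <- .scan_inputs(series_set, cfg$mode, cfg$max_gap)
  if (nrow(inp$px) < 2)
    kafr_stop("need at least 2 frames to select key frames", "kafr_argument_error")
  zstar <- .resolve_zstar(series_set, cfg)
  .keyframes_from_scan(.scan_adaptive(inp$px, inp$py, inp$ok, zstar), zstar, cfg$mode)
}

.resolve_zstar <- function(series_set, cfg) {
  if (!is.null(cfg$threshold_z)) return(cfg$threshold_z)
  if (!is.null(cfg$threshold_d)) return(max(cfg$threshold_d^(-1 / cfg$beta) - cfg$epsilon, 0))
  calibrate_threshold(series_set, cfg$mode, cfg$target_retention,
                      tol = cfg$tol, max_gap = cfg$max_gap)
}

#' Calibrate the selection threshold to a target retention fraction
#'
#' The retained fraction is a non-increasing step function of the raw
#' threshold `z*` (larger `z*` closes fewer pairs). Rather than choosing a
#' threshold on the similarity scale directly, the threshold is adjusted so
#' that a desired percentage of the training frames is kept: bisection over
#' `z*` until the achieved fraction is within `tol` of `target_retention`.
#' When the step function jumps over the target, the threshold whose
#' fraction is closest from above is returned with a warning. Calibration
#' is global over the supplied pool: `series_set` may be a list of track
#' objects (one per video) and a single `z*` is returned for all of them.
#'
#' @param series_set A `kafr_tracks`/`kafr_velocity` object or a list of
#'   them (the training pool).
#' @param mode `"adaptive1"` or `"adaptive2"`.
#' @param target_retention Desired retained fraction in (0, 1].
#' @param tol Tolerance on the achieved fraction (default 0.005).
#' @param max_gap Velocity gap rule for `adaptive2`.
#' @return The calibrated `z*` (numeric scalar) with attribute
#'   `achieved_retention`.
#' @export
calibrate_threshold <- function(series_set, mode = c("adaptive1", "adaptive2"),
                                target_retention, tol = 0.005, max_gap = 3L) {
  mode <- match.arg(mode)
  if (!(target_retention > 0 && target_retention <= 1))
    kafr_stop("target_retention must be in (0, 1]", "kafr_argument_error")
  pool <- if (inherits(series_set, c("kafr_tracks", "kafr_velocity")))
    list(series_set) else series_set
  inputs <- lapply(pool, .scan_inputs, mode = mode, max_gap = max_gap)
  n_frames <- vapply(inputs, function(s) nrow(s$px), integer(1))
  if (any(n_frames < 2))
    kafr_stop("every series needs at least 2 frames", "kafr_argument_error")
  n_total <- sum(n_frames)
  frac_at <- function(zstar) {
    kept <- vapply(inputs, function(s) {
      sc <- .scan_adaptive(s$px, s$py, s$ok, zstar)
      length(unique(c(1L, sc$i, sc$j, sc$n)))
    }, integer(1))
    sum(kept) / n_total
  }
  # achievable range: z* = 0 keeps everything; z* -> Inf keeps {first, last}
  min_frac <- sum(pmin(n_frames, 2L)) / n_total
  if (target_retention < min_frac - tol)
    kafr_stop(sprintf(
      "target retention %.4g unreachable: achievable range is [%.4g, 1]",
      target_retention, min_frac), "kafr_calibration_error")
  lo <- 0; f_lo <- 1                      # frac(lo) >= target always
  if (abs(f_lo - target_retention) <= tol) {
    out <- lo; attr(out, "achieved_retention") <- f_lo
    return(out)
  }
  hi <- 1
  f_hi <- frac_at(hi)
  it <- 0L
  while (f_hi > max(target_retention, min_frac) && it < 80L) {
    lo <- hi; f_lo <- f_hi
    hi <- hi * 4; f_hi <- frac_at(hi)
    it <- it + 1L
  }
  best_z <- lo; best_f <- f_lo            # closest achievable from above
  for (it in seq_len(60L)) {
    mid <- (lo + hi) / 2
    f_mid <- frac_at(mid)
    if (f_mid >= target_retention) {
      lo <- mid; f_lo <- f_mid
      if (f_mid < best_f) { best_z <- mid; best_f <- f_mid }
    } else {
      hi <- mid; f_hi <- f_mid
    }
    if (abs(f_mid - target_retention) <= tol) {
      out <- mid; attr(out, "achieved_retention") <- f_mid
      return(out)
    }
  }
  # step function jumped over the target: report the closest from above,
  # unless the nearest step from below is within tol
  if (target_retention - f_hi <= tol) {
    out <- hi; attr(out, "achieved_retention") <- f_hi
    return(out)
  }
  warning(sprintf(
    "calibration cannot reach %.4g within tol %.4g; returning fraction %.4g (closest from above)",
    target_retention, tol, best_f))
  out <- best_z
  attr(out, "achieved_retention") <- best_f
  out
}

#' Retained fraction of a key-frame set
#'
#' @param kfs A `kafr_keyframes` object.
#' @param n_total Total frame count (>= number retained).
#' @return `length(retained) / n_total`, in (0, 1].
#' @export
retention <- function(kfs, n_total = kfs$n_frames) {
  if (n_total <= 0) kafr_stop("n_total must be positive", "kafr_argument_error")
  if (n_total < length(kfs$retained))
    kafr_stop("n_total smaller than the retained count", "kafr_argument_error")
  length(kfs$retained) / n_total
}

#' Write a key-frame selection table
#'
#' CSV with columns `video`, `frame`, `is_anchor` (anchors are the first
#' members of key pairs, plus the initial frame).
#'
#' @param kfs A `kafr_keyframes` object.
#' @param path Output CSV path.
#' @param video Video identifier.
#' @export
write_keyframes <- function(kfs, path, video = "video0") {
  anchors <- unique(c(0L, kfs$pairs[, "i"], kfs$pairs[, "j"]))
  df <- data.frame(video = video, frame = kfs$retained,
                   is_anchor = kfs$retained %in% anchors)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
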