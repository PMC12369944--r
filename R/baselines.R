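#' Uniform frame sampling
#'
#' The content-blind baseline: keep every k-th frame, with the stride chosen
#' from the requested retention fraction (`k = round(1/fraction)`).
#'
#' @param n_frames Total frame count (>= 1).
#' @param fraction Retained fraction in (0, 1].
#' @return 0-based frame indices at regular intervals, starting at 0.
#' @export
#' @examples
#' uniform_sample(10, 0.5)  # 0 2 4 6 8
uniform_sample <- function(n_frames, fraction) {
  if (!(fraction > 0 && fraction <= 1))
    kafr_stop("fraction must be in (0, 1]", "kafr_argument_error")
  stopifnot(n_frames >= 1)
  stride <- max(1L, as.integer(round(1 / fraction)))
  seq.int(0L, n_frames - 1L, by = stride)
}

#' Mean squared error between two frames
#'
#' Mean over all pixels (and channels) of the squared intensity difference,
#' in real arithmetic. Frames are numeric matrices (grayscale) or
#' height x width x 3 arrays (RGB) of 8-bit intensities.
#'
#' @param a,b Frames of identical shape.
#' @return Non-negative scalar; 0 iff the frames are identical.
#' @export
frame_mse <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    kafr_stop("frame shapes differ", "kafr_argument_error")
  mean((as.numeric(a) - as.numeric(b))^2)
}

# RGB -> luminance; grayscale passes through
.to_gray <- function(frame) {
  d <- dim(frame)
  if (length(d) == 3 && d[3] == 3)
    0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
  else frame
}

#' Select key frames by pixel-MSE dissimilarity
#'
#' The holistic pixel-based baseline, run through the same greedy
#' anchor scan as the kinematic selector so that the two methods differ
#' only in the dissimilarity functional: the anchor is retained, subsequent
#' frames are discarded while `frame_mse(anchor, frame) < threshold` (too
#' similar), and the first frame at or above the threshold becomes the next
#' anchor. The last frame is always retained. Because every pixel
#' contributes, background perturbations move the selection even when the
#' tools are static — the vulnerability the kinematic selector avoids.
#'
#' RGB frames are converted to luminance (0.299/0.587/0.114) before
#' comparison.
#'
#' @param frames List of frames (matrices or RGB arrays, one shape).
#' @param threshold MSE threshold (>= 0), or NULL to calibrate.
#' @param target_retention Retained fraction in (0, 1] to calibrate the
#'   threshold to (bisection, as in [calibrate_threshold()]).
#' @param tol Calibration tolerance.
#' @return A `kafr_keyframes` object (mode `"mse"`).
#' @export
select_keyframes_mse <- function(frames, threshold = NULL,
                                 target_retention = NULL, tol = 0.005) {
  n <- length(frames)
  if (n < 2) kafr_stop("need at least 2 frames", "kafr_argument_error")
  if (is.null(threshold) == is.null(target_retention))
    kafr_stop("supply exactly one of threshold / target_retention", "kafr_config_error")
  gray <- lapply(frames, .to_gray)
  shapes <- vapply(gray, function(f) paste(dim(f), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1)
    kafr_stop("all frames must share one shape", "kafr_argument_error")
  if (is.null(threshold)) {
    if (!(target_retention > 0 && target_retention <= 1))
      kafr_stop("target_retention must be in (0, 1]", "kafr_argument_error")
    min_frac <- min(2L, n) / n
    if (target_retention < min_frac - tol)
      kafr_stop(sprintf(
        "target retention %.4g unreachable: achievable range is [%.4g, 1]",
        target_retention, min_frac), "kafr_calibration_error")
    count_at <- function(thr) length(.scan_mse(gray, thr)$retained_rows)
    threshold <- .bisect_threshold(count_at, n, target_retention, tol)
  }
  if (threshold < 0) kafr_stop("threshold must be >= 0", "kafr_argument_error")
  sc <- .scan_mse(gray, threshold)
  retained <- sc$retained_rows - 1L
  structure(list(retained = retained,
                 pairs = cbind(i = sc$i - 1L, j = sc$j - 1L),
                 threshold_z_effective = threshold, mode = "mse",
                 n_frames = n),
            class = "kafr_keyframes")
}

# anchor-to-current scan: z is the direct dissimilarity, not cumulative
.scan_mse <- function(gray, threshold) {
  n <- length(gray)
  pi <- integer(n); pj <- integer(n); np <- 0L
  a <- 1L
  anchor <- as.numeric(gray[[1L]])
  for (j in seq_len(n)[-1L]) {
    z <- mean((as.numeric(gray[[j]]) - anchor)^2)
    if (z >= threshold) {
      np <- np + 1L; pi[np] <- a; pj[np] <- j
      a <- j; anchor <- as.numeric(gray[[j]])
    }
  }
  list(i = pi[seq_len(np)], j = pj[seq_len(np)],
       retained_rows = sort(unique(c(1L, pi[seq_len(np)], pj[seq_len(np)], n))))
}

# shared bisection on a non-increasing retained-count step function
.bisect_threshold <- function(count_at, n_total, target, tol) {
  frac_at <- function(thr) count_at(thr) / n_total
  lo <- 0; f_lo <- frac_at(0)
  if (abs(f_lo - target) <= tol) return(lo)
  hi <- 1; f_hi <- frac_at(hi); it <- 0L
  while (f_hi > target && it < 80L) {
    lo <- hi; f_lo <- f_hi
    hi <- hi * 4; f_hi <- frac_at(hi); it <- it + 1L
  }
  best_t <- lo; best_f <- f_lo
  for (it in seq_len(60L)) {
    mid <- (lo + hi) / 2
    f_mid <- frac_at(mid)
    if (f_mid >= target) {
      lo <- mid
      if (f_mid < best_f) { best_t <- mid; best_f <- f_mid }
    } else hi <- mid
    if (abs(f_mid - target) <= tol) return(mid)
  }
  f_hi <- frac_at(hi)
  if (target - f_hi <= tol) return(hi)
  warning(sprintf(
    "calibration cannot reach %.4g within tol %.4g; returning fraction %.4g (closest from above)",
    target, tol, best_f))
  best_t
}
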