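#' Phase annotation intervals
#'
#' Labeled frame intervals for one video: six procedural phases plus idle
#' (class 0, "absence of clinically relevant motions"). Intervals are
#' half-open (`end_frame` exclusive) and must not overlap.
#'
#' @param video_id Video identifier.
#' @param phase_label Integer labels in 0..6 (0 = idle).
#' @param start_frame,end_frame 0-based interval bounds, `start < end`,
#'   end exclusive.
#' @return A `phase_annotation` data frame.
#' @export
phase_annotation <- function(video_id, phase_label, start_frame, end_frame) {
  df <- data.frame(video_id = video_id, phase_label = as.integer(phase_label),
                   start_frame = as.integer(start_frame),
                   end_frame = as.integer(end_frame))
  if (any(df$start_frame >= df$end_frame))
    kafr_stop("annotation intervals need start < end", "kafr_argument_error")
  for (v in unique(df$video_id)) {
    sub <- df[df$video_id == v, ]
    sub <- sub[order(sub$start_frame), ]
    if (nrow(sub) > 1 && any(sub$start_frame[-1] < sub$end_frame[-nrow(sub)]))
      kafr_stop(sprintf("overlapping annotation intervals in video '%s'", v),
                "kafr_argument_error")
  }
  class(df) <- c("phase_annotation", "data.frame")
  df
}

#' @rdname phase_annotation
#' @param path CSV with columns `video_id`, `phase_label`, `start_frame`,
#'   `end_frame`.
#' @export
read_phase_annotation <- function(path) {
  if (!file.exists(path))
    kafr_stop(sprintf("no annotation file at '%s'", path), "kafr_io_error")
  df <- read.csv(path)
  phase_annotation(df$video_id, df$phase_label, df$start_frame, df$end_frame)
}

#' @rdname phase_annotation
#' @param ann A `phase_annotation`.
#' @export
write_phase_annotation <- function(ann, path) {
  write.csv(as.data.frame(ann), path, row.names = FALSE)
  invisible(path)
}

# per-frame label lookup; NA outside any interval
.frame_labels <- function(ann, video, frames) {
  sub <- ann[ann$video_id == video, ]
  lab <- rep(NA_integer_, length(frames))
  for (r in seq_len(nrow(sub))) {
    hit <- frames >= sub$start_frame[r] & frames < sub$end_frame[r]
    lab[hit] <- sub$phase_label[r]
  }
  lab
}

#' Group frames by phase
#'
#' @param ann A [phase_annotation()].
#' @param video Which video (default: the first).
#' @param frames Optional frame subset (e.g. the retained key frames);
#'   default all annotated frames.
#' @return Named list mapping phase label to its ordered frame indices.
#' @export
frames_by_phase <- function(ann, video = ann$video_id[1], frames = NULL) {
  sub <- ann[ann$video_id == video, ]
  if (is.null(frames))
    frames <- unlist(lapply(seq_len(nrow(sub)),
                            function(r) seq.int(sub$start_frame[r], sub$end_frame[r] - 1L)))
  frames <- sort(unique(as.integer(frames)))
  lab <- .frame_labels(ann, video, frames)
  keep <- !is.na(lab)
  split(frames[keep], lab[keep])
}

#' Rebalance frames across phases
#'
#' Long phases dominate a frame-balanced classifier unless each phase
#' contributes the same number of training frames: phases longer than
#' `target_n` are evenly subsampled, shorter ones are oversampled by cyclic
#' duplication at evenly spaced insertion points. The total number of
#' duplicated frames introduced (`dup`) is reported.
#'
#' @param frames_by_phase Named list: phase label -> ordered frame indices.
#' @param target_n Desired frames per phase (default 250).
#' @return List with `frames` (the rebalanced mapping) and `dup`
#'   (`sum over phases of max(0, target_n - n_phase)`).
#' @export
balance_phase_frames <- function(frames_by_phase, target_n = 250L) {
  stopifnot(target_n >= 1)
  out <- lapply(names(frames_by_phase), function(ph) {
    fr <- frames_by_phase[[ph]]
    n <- length(fr)
    if (n == 0) {
      warning(sprintf("phase '%s' has no frames; kept empty", ph))
      return(integer(0))
    }
    # floor(k*n/target)+1 subsamples at even stride for n > target and
    # duplicates cyclically at even spacing for n < target
    fr[floor(seq.int(0L, target_n - 1L) * n / target_n) + 1L]
  })
  names(out) <- names(frames_by_phase)
  dup <- sum(vapply(frames_by_phase, function(fr) max(0, target_n - length(fr)), numeric(1)))
  list(frames = out, dup = as.integer(dup))
}

#' Sinusoidal positional encoding of a frame index
#'
#' Standard transformer-style encoding embedding temporal context:
#' component `2k` is `sin(p / 10000^(2k/dim))`, component `2k+1` is
#' `cos(p / 10000^(2k/dim))`.
#'
#' @param position 0-based frame position (`0 <= position < n_total`).
#' @param n_total Sequence length (bound check only).
#' @param dim Even embedding dimension.
#' @return Numeric vector of length `dim`, components in `[-1, 1]`.
#' @export
positional_encoding <- function(position, n_total, dim) {
  if (dim %% 2 != 0) kafr_stop("dim must be even", "kafr_argument_error")
  if (position < 0 || position >= n_total)
    kafr_stop("position out of range", "kafr_argument_error")
  k <- seq_len(dim / 2) - 1
  angle <- position / 10000^(2 * k / dim)
  as.vector(rbind(sin(angle), cos(angle)))
}

.check_probs <- function(probs) {
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-6)
    kafr_stop("probs must be a distribution (non-negative, sums to 1)",
              "kafr_argument_error")
  invisible(probs)
}

#' Earth Mover's Distance to a one-hot target over ordered classes
#'
#' With unit ground metric on the ordered class axis the 1-D EMD reduces to
#' the L1 distance between cumulative distributions:
#' `sum over c of |CDF_pred(c) - CDF_target(c)|`. Phases are ordinal, so
#' mass placed on a phase far from the true one costs proportionally more —
#' the property that encourages a classifier to confuse only temporally
#' adjacent phases.
#'
#' @param probs Predicted distribution over the C ordered classes.
#' @param target 0-based true class index.
#' @return Non-negative scalar; 0 iff `probs` is one-hot at `target`.
#' @export
#' @examples
#' emd_loss(c(0.5, 0.5), 1)  # 0.5
emd_loss <- function(probs, target) {
  .check_probs(probs)
  C <- length(probs)
  if (target < 0 || target >= C) kafr_stop("target class out of range", "kafr_argument_error")
  onehot <- numeric(C); onehot[target + 1] <- 1
  sum(abs(cumsum(probs) - cumsum(onehot)))
}

#' Combined cross-entropy + EMD loss
#'
#' `-log(probs[target] + 1e-12) + lambda_emd * emd_loss(probs, target)`.
#' Cross-entropy drives correctness; the EMD term reflects the sequential
#' nature of the phases.
#'
#' @inheritParams emd_loss
#' @param lambda_emd Non-negative EMD weight (default 1).
#' @return Non-negative scalar.
#' @export
combined_loss <- function(probs, target, lambda_emd = 1) {
  stopifnot(lambda_emd >= 0)
  .check_probs(probs)
  -log(probs[target + 1] + 1e-12) + lambda_emd * emd_loss(probs, target)
}

#' Temporal label smoothing by sliding-window majority vote
#'
#' Each position is replaced by the most frequent label within a centered
#' window (truncated at the sequence boundaries), suppressing short-term
#' misclassifications. Ties keep the original label at that position.
#'
#' @param labels Integer label sequence.
#' @param window Odd window length in frames (default 31).
#' @return Smoothed label sequence of the same length.
#' @export
temporal_smooth <- function(labels, window = 31L) {
  window <- as.integer(window)
  if (window < 1 || window %% 2 == 0)
    kafr_stop("window must be odd and >= 1", "kafr_argument_error")
  n <- length(labels)
  if (n == 0 || window == 1) return(labels)
  half <- window %/% 2
  out <- labels
  for (t in seq_len(n)) {
    w <- labels[max(1, t - half):min(n, t + half)]
    counts <- table(w)
    top <- counts[counts == max(counts)]
    if (length(top) == 1) out[t] <- as.integer(names(top))
    # ties keep the original label
  }
  out
}

#' Per-frame class-probability series
#'
#' @param video_id Video identifier (recycled).
#' @param frames Ordered 0-based frame indices.
#' @param probs Matrix (`length(frames)` x C) of class probabilities; each
#'   row must sum to 1 within 1e-6.
#' @return A `prediction_series` data frame with columns `video_id`,
#'   `frame`, `p0..p<C-1>`, `label` (0-based argmax, ties to the lower
#'   class).
#' @export
prediction_series <- function(video_id, frames, probs) {
  probs <- as.matrix(probs)
  stopifnot(length(frames) == nrow(probs))
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-6))
    kafr_stop("each probability row must be non-negative and sum to 1",
              "kafr_argument_error")
  df <- data.frame(video_id = video_id, frame = as.integer(frames))
  colnames(probs) <- paste0("p", seq_len(ncol(probs)) - 1)
  df <- cbind(df, as.data.frame(probs))
  df$label <- max.col(probs, ties.method = "first") - 1L
  class(df) <- c("prediction_series", "data.frame")
  df
}

.prob_cols <- function(pred) grep("^p[0-9]+$", names(pred), value = TRUE)

#' @rdname prediction_series
#' @param path CSV with columns `video_id`, `frame`, `p0..p6`.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path))
    kafr_stop(sprintf("no predictions file at '%s'", path), "kafr_io_error")
  df <- read.csv(path)
  pc <- grep("^p[0-9]+$", names(df), value = TRUE)
  prediction_series(df$video_id, df$frame, as.matrix(df[, pc]))
}

#' @rdname prediction_series
#' @param pred A `prediction_series`.
#' @export
write_predictions <- function(pred, path) {
  write.csv(as.data.frame(pred), path, row.names = FALSE)
  invisible(path)
}

#' Ensemble two probability streams
#'
#' Per-frame mean of the two class-probability vectors (renormalized), the
#' fusion step of a two-stream (RGB + optical-flow) configuration. The
#' label is the argmax, ties resolved to the lower class index.
#'
#' @param a,b `prediction_series` objects over the same videos and frames.
#' @return A `prediction_series` with the fused probabilities.
#' @export
ensemble_predictions <- function(a, b) {
  key_a <- paste(a$video_id, a$frame); key_b <- paste(b$video_id, b$frame)
  if (!identical(sort(key_a), sort(key_b))) {
    missing_frames <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))
    kafr_stop(paste0("prediction series are misaligned; unmatched frames: ",
                     paste(head(missing_frames, 10), collapse = ", ")),
              "kafr_alignment_error")
  }
  b <- b[match(key_a, key_b), ]
  pc <- .prob_cols(a)
  probs <- (as.matrix(a[, pc]) + as.matrix(b[, pc])) / 2
  probs <- probs / rowSums(probs)
  prediction_series(a$video_id, a$frame, probs)
}

#' Evaluate phase predictions against annotations
#'
#' Accuracy is the fraction of correct predictions over all predictions.
#' F1 is computed per class (`2 * precision * recall / (precision +
#' recall)`, 0 when undefined or when the class is absent from both truth
#' and prediction) and averaged over the 7 classes — macro by default,
#' optionally weighted by class support.
#'
#' @param pred A [prediction_series()].
#' @param truth A [phase_annotation()] covering every predicted frame.
#' @param n_classes Number of phase classes (default 7: six phases + idle).
#' @param average `"macro"` or `"weighted"` F1 averaging.
#' @return A `metric_report` list: `accuracy`, `f1`, `per_class_f1`,
#'   `n_frames`.
#' @export
evaluate_phases <- function(pred, truth, n_classes = 7L,
                            average = c("macro", "weighted")) {
  average <- match.arg(average)
  truth_lab <- rep(NA_integer_, nrow(pred))
  for (v in unique(pred$video_id)) {
    sel <- pred$video_id == v
    truth_lab[sel] <- .frame_labels(truth, v, pred$frame[sel])
  }
  if (anyNA(truth_lab)) {
    bad <- pred$frame[is.na(truth_lab)]
    kafr_stop(paste0("predicted frames lack ground-truth labels: ",
                     paste(head(bad, 10), collapse = ", "),
                     if (length(bad) > 10) " ..."),
              "kafr_argument_error")
  }
  lab <- pred$label
  accuracy <- mean(lab == truth_lab)
  per_class <- numeric(n_classes)
  support <- numeric(n_classes)
  for (c0 in seq_len(n_classes) - 1L) {
    tp <- sum(lab == c0 & truth_lab == c0)
    fp <- sum(lab == c0 & truth_lab != c0)
    fn <- sum(lab != c0 & truth_lab == c0)
    per_class[c0 + 1] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    support[c0 + 1] <- tp + fn
  }
  f1 <- if (average == "macro") mean(per_class)
        else sum(per_class * support) / sum(support)
  structure(list(accuracy = accuracy, f1 = f1, per_class_f1 = per_class,
                 n_frames = nrow(pred)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> accuracy %.4f, F1 %.4f over %d frames\n",
              x$accuracy, x$f1, x$n_frames))
  cat("per-class F1:", paste(sprintf("%.3f", x$per_class_f1), collapse = " "), "\n")
  invisible(x)
}

#' Relative change in percent
#'
#' `(new - original) / original * 100`, the convention used for reporting
#' accuracy and F1 improvements.
#'
#' @param original Baseline value (> 0).
#' @param new New value.
#' @return Percent relative change.
#' @export
#' @examples
#' relative_change(0.749, 0.7814)  # ~4.33
relative_change <- function(original, new) {
  if (any(original <= 0))
    kafr_stop("original must be > 0", "kafr_argument_error")
  (new - original) / original * 100
}
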