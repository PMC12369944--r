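#' Per-frame kinematic features for the reference classifier
#'
#' Per-channel speed magnitude (px/s) from [compute_velocity()], optionally
#' smoothed by an NA-aware running mean. Frames where a channel's velocity
#' is undefined contribute NA before smoothing and 0 after imputation, so a
#' vanished tool looks idle — the same convention the selector uses.
#'
#' @param tracks A `kafr_tracks` object.
#' @param max_gap Velocity gap rule (frames).
#' @param smooth_window Odd running-mean window (default 11; 1 disables).
#' @return Numeric matrix, frames x channels, of smoothed speeds.
#' @export
kinematic_features <- function(tracks, max_gap = 3L, smooth_window = 11L) {
  vel <- compute_velocity(tracks, max_gap = max_gap)
  speed <- sqrt(vel$vx^2 + vel$vy^2)
  if (smooth_window > 1) {
    half <- smooth_window %/% 2
    n <- nrow(speed)
    sm <- speed
    for (ci in seq_len(ncol(speed))) {
      s <- speed[, ci]
      sm[, ci] <- vapply(seq_len(n), function(t) {
        w <- s[max(1, t - half):min(n, t + half)]
        if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
      }, numeric(1))
    }
    speed <- sm
  }
  speed[is.na(speed)] <- 0
  speed
}

#' Nearest-centroid phase classifier
#'
#' A deliberately trivial reference classifier over kinematic features,
#' shipped only so the full pipeline (selection, balancing, smoothing,
#' ensembling, evaluation) can be exercised end to end without an external
#' network: class centroids are the mean feature vectors of the training
#' frames; probabilities are a softmax of negative squared distances.
#'
#' @param features Feature matrix (frames x d).
#' @param rows 1-based training row indices.
#' @param labels Integer class labels (0-based) for `rows`.
#' @param n_classes Number of classes (default 7).
#' @return A `kafr_nearest_centroid` model.
#' @export
fit_nearest_centroid <- function(features, rows, labels, n_classes = 7L) {
  stopifnot(length(rows) == length(labels))
  centroids <- matrix(NA_real_, n_classes, ncol(features))
  for (c0 in seq_len(n_classes) - 1L) {
    sel <- rows[labels == c0]
    if (length(sel) > 0)
      centroids[c0 + 1, ] <- colMeans(features[sel, , drop = FALSE])
  }
  d <- sqrt(rowSums((features[rows, , drop = FALSE] -
                       centroids[labels + 1, , drop = FALSE])^2))
  structure(list(centroids = centroids, scale = max(stats::median(d, na.rm = TRUE), 1e-6)),
            class = "kafr_nearest_centroid")
}

#' @rdname fit_nearest_centroid
#' @param model A fitted `kafr_nearest_centroid`.
#' @param video_id Video identifier for the output series.
#' @param frames 0-based frame indices matching `features` rows.
#' @export
predict_nearest_centroid <- function(model, features, video_id = "sim",
                                     frames = seq_len(nrow(features)) - 1L) {
  n_classes <- nrow(model$centroids)
  d2 <- vapply(seq_len(n_classes), function(ci) {
    cen <- model$centroids[ci, ]
    if (anyNA(cen)) rep(Inf, nrow(features))
    else rowSums((features - rep(cen, each = nrow(features)))^2)
  }, numeric(nrow(features)))
  logit <- -d2 / (2 * model$scale^2)
  logit[is.infinite(logit)] <- -1e9
  probs <- exp(logit - apply(logit, 1, max))
  probs <- probs / rowSums(probs)
  prediction_series(video_id, frames, probs)
}

#' Pipeline run configuration
#'
#' @param out_dir Run directory (created if needed).
#' @param sim A [sim_config()] for the synthetic source (ignored when
#'   external `detections`/`annotations` paths are given).
#' @param detections,annotations Optional external inputs: a JSON-lines
#'   detection file and a phase-annotation CSV.
#' @param parts Tracked-part mode for [part_spec()].
#' @param modes Selection modes to run (default both adaptive selectors).
#' @param target_retention Retention fraction the thresholds are calibrated
#'   to (default 0.10, i.e. a tenfold reduction).
#' @param min_conf Detection confidence floor.
#' @param target_n Frames per phase after rebalancing (default 250).
#' @param window Temporal smoothing window (default 31).
#' @param lambda_emd EMD weight of the combined loss (recorded in the
#'   manifest; the reference classifier is not trained by gradient descent).
#' @param classifier_cmd Optional external classifier command as a character
#'   vector (executable, then any fixed arguments); it is invoked as
#'   `cmd ... <balanced_frames_csv> <tracks_csv> <out_predictions_csv>` once
#'   per selection mode and must write a predictions CSV
#'   (`video_id, frame, p0..p6`). Default NULL uses the built-in
#'   nearest-centroid reference classifier. GPU training thus stays outside
#'   the package without blocking end-to-end runs.
#' @param seed Run seed; all randomness flows from it.
#' @return A `run_config` object.
#' @export
run_config <- function(out_dir,
                       sim = NULL,
                       detections = NULL, annotations = NULL,
                       parts = "two",
                       modes = c("adaptive1", "adaptive2"),
                       target_retention = 0.10,
                       min_conf = 0.5,
                       target_n = 250L,
                       window = 31L,
                       lambda_emd = 1,
                       classifier_cmd = NULL,
                       seed = 1L) {
  sim <- sim %||% sim_config(seed = seed)
  stopifnot(all(modes %in% c("adaptive1", "adaptive2")))
  structure(list(out_dir = out_dir, sim = sim, detections = detections,
                 annotations = annotations, parts = parts, modes = modes,
                 target_retention = target_retention, min_conf = min_conf,
                 target_n = as.integer(target_n), window = as.integer(window),
                 lambda_emd = lambda_emd, classifier_cmd = classifier_cmd,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full key-frame pipeline
#'
#' Executes ingest -> tracks -> calibrated selection (one pass per mode) ->
#' per-phase rebalancing -> classifier -> temporal smoothing -> two-stream
#' ensembling -> evaluation, writing every intermediate artifact, a metrics
#' JSON and a manifest into `cfg$out_dir`. With the default synthetic
#' source the procedure, detections and annotations are generated from
#' `cfg$seed`, so a rerun with the same config reproduces every artifact
#' byte for byte.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the run directory, metrics and per-mode
#'   selections.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (p in c(cfg$detections, cfg$annotations))
    if (!is.null(p) && !file.exists(p))
      kafr_stop(sprintf("input file missing: '%s'", p), "kafr_io_error")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)

  sim <- cfg$sim; sim$seed <- cfg$seed
  fg <- frame_geometry(sim$frame_size[1], sim$frame_size[2], sim$fps)
  if (is.null(cfg$detections)) {
    proc <- simulate_procedure(sim)
    write_tracks(proc$tracks, out("tracks_true.csv"), video = "sim")
    write_phase_annotation(proc$annotation, out("annotation.csv"))
    write_detections_jsonl(emit_detections(proc), out("detections.jsonl"))
    det_path <- out("detections.jsonl"); ann_path <- out("annotation.csv")
  } else {
    det_path <- cfg$detections; ann_path <- cfg$annotations
  }

  ann <- read_phase_annotation(ann_path)
  dets <- read_detections(det_path, "jsonl")
  dets <- merge_class_ids(filter_confidence(dets, cfg$min_conf))
  tracks <- build_tracks(dets, fg, part_spec(cfg$parts),
                         n_frames = max(ann$end_frame))
  write_tracks(tracks, out("tracks.csv"), video = ann$video_id[1])
  write_velocity(compute_velocity(tracks), out("velocity.csv"), video = ann$video_id[1])

  selections <- list(); balanced <- list(); streams <- list()
  features <- kinematic_features(tracks)
  video <- ann$video_id[1]
  for (mode in cfg$modes) {
    kfs <- select_keyframes(tracks, selection_config(
      mode, target_retention = cfg$target_retention))
    selections[[mode]] <- kfs
    write_keyframes(kfs, out(sprintf("keyframes_%s.csv", mode)), video = video)
    bal <- balance_phase_frames(
      frames_by_phase(ann, video = video, frames = kfs$retained),
      target_n = cfg$target_n)
    balanced[[mode]] <- bal
    train_frames <- unlist(bal$frames, use.names = FALSE)
    train_labels <- rep(as.integer(names(bal$frames)),
                        vapply(bal$frames, length, integer(1)))
    bal_df <- data.frame(video = video, frame = train_frames, phase = train_labels)
    write.csv(bal_df, out(sprintf("balanced_%s.csv", mode)), row.names = FALSE)
    pred_path <- out(sprintf("predictions_%s.csv", mode))
    if (!is.null(cfg$classifier_cmd)) {
      cmd <- cfg$classifier_cmd
      status <- system2(cmd[1], c(cmd[-1], out(sprintf("balanced_%s.csv", mode)),
                                  out("tracks.csv"), pred_path))
      if (status != 0 || !file.exists(pred_path))
        kafr_stop(sprintf("stage classifier (%s) failed for mode %s", cmd[1], mode),
                  "kafr_stage_error")
      streams[[mode]] <- read_predictions(pred_path)
    } else {
      model <- fit_nearest_centroid(features, train_frames + 1L, train_labels)
      streams[[mode]] <- predict_nearest_centroid(model, features, video_id = video)
      write_predictions(streams[[mode]], pred_path)
    }
  }

  fused <- if (length(streams) > 1)
    Reduce(ensemble_predictions, streams) else streams[[1]]
  smoothed_labels <- temporal_smooth(fused$label, cfg$window)
  onehot <- matrix(0, nrow(fused), 7)
  onehot[cbind(seq_len(nrow(fused)), smoothed_labels + 1L)] <- 1
  smoothed <- prediction_series(fused$video_id, fused$frame, onehot)
  write_predictions(smoothed, out("predictions_final.csv"))

  metrics <- list(
    ensemble = unclass(evaluate_phases(fused, ann))[c("accuracy", "f1", "per_class_f1")],
    smoothed = unclass(evaluate_phases(smoothed, ann))[c("accuracy", "f1", "per_class_f1")],
    per_stream_accuracy = lapply(streams, function(s) evaluate_phases(s, ann)$accuracy),
    retention = lapply(selections, retention),
    duplicated_frames = lapply(balanced, function(b) b$dup)
  )
  jsonlite::write_json(metrics, out("metrics.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("kafr")),
    config = cfg[setdiff(names(cfg), "sim")],
    sim = unclass(sim),
    artifacts = sort(list.files(cfg$out_dir))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(out_dir = cfg$out_dir, metrics = metrics, selections = selections))
}
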