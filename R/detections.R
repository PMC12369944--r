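#' Read per-frame tool detections
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{`jsonl`}{one JSON object per line with keys `frame`, `class`,
#'     `conf`, and either `box` (`[x_min, y_min, x_max, y_max]`, pixels) or
#'     `poly` (`[[x, y], ...]`); optional `track`.}
#'   \item{`yolo_txt`}{a directory with one file `<frame_index>.txt` per
#'     frame; each line is `class cx cy w h conf` with center/size
#'     coordinates normalized to `[0, 1]` (frame geometry `fg` required to
#'     convert to pixels).}
#' }
#' Frame indices are 0-based. Malformed records raise a parse error naming
#' the offending line.
#'
#' @param path File (jsonl) or directory (yolo_txt).
#' @param dialect `"jsonl"` or `"yolo_txt"`.
#' @param fg A [frame_geometry()]; required for `yolo_txt`.
#' @return A `kafr_detections` data frame with columns `frame`, `class_id`,
#'   `conf`, `x_min`, `y_min`, `x_max`, `y_max`, `track_id`, and a `poly`
#'   list-column (NULL where the record was a box).
#' @export
read_detections <- function(path, dialect = c("jsonl", "yolo_txt"), fg = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "jsonl") .read_detections_jsonl(path) else .read_detections_yolo(path, fg)
}

.empty_detections <- function() {
  df <- data.frame(frame = integer(), class_id = integer(), conf = numeric(),
                   x_min = numeric(), y_min = numeric(),
                   x_max = numeric(), y_max = numeric(),
                   track_id = integer())
  df$poly <- list()
  class(df) <- c("kafr_detections", "data.frame")
  df
}

.new_detections <- function(frame, class_id, conf, box, poly = NULL, track_id = NA_integer_) {
  n <- length(frame)
  df <- data.frame(frame = as.integer(frame), class_id = as.integer(class_id),
                   conf = as.numeric(conf),
                   x_min = box[, 1], y_min = box[, 2],
                   x_max = box[, 3], y_max = box[, 4],
                   track_id = as.integer(track_id))
  df$poly <- poly %||% rep(list(NULL), n)
  class(df) <- c("kafr_detections", "data.frame")
  .validate_detections(df)
}

.validate_detections <- function(df) {
  if (nrow(df) == 0) return(df)
  if (any(df$frame < 0)) kafr_stop("frame indices must be >= 0", "kafr_parse_error")
  if (any(df$conf < 0 | df$conf > 1)) kafr_stop("confidence must be in [0, 1]", "kafr_parse_error")
  is_box <- vapply(df$poly, is.null, logical(1))
  bad <- is_box & (!is.finite(df$x_min) | !is.finite(df$y_min) |
                   df$x_min >= df$x_max | df$y_min >= df$y_max)
  if (any(bad))
    kafr_stop(sprintf("invalid box geometry in %d record(s)", sum(bad)), "kafr_parse_error")
  df
}

.read_detections_jsonl <- function(path) {
  if (!file.exists(path) || dir.exists(path))
    kafr_stop(sprintf("cannot read detections file '%s'", path), "kafr_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(.empty_detections())
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$frame) || is.null(rec$class) || is.null(rec$conf) ||
        (is.null(rec$box) && is.null(rec$poly)))
      kafr_stop(sprintf("malformed detection record at line %d", i), "kafr_parse_error")
    recs[[i]] <- rec
  }
  frame <- vapply(recs, function(r) as.integer(r$frame), integer(1))
  class_id <- vapply(recs, function(r) as.integer(r$class), integer(1))
  conf <- vapply(recs, function(r) as.numeric(r$conf), numeric(1))
  track <- vapply(recs, function(r) as.integer(r$track %||% NA_integer_), integer(1))
  poly <- lapply(recs, function(r) {
    if (is.null(r$poly)) NULL else matrix(as.numeric(t(r$poly)), ncol = 2, byrow = TRUE)
  })
  box <- t(vapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (!is.null(r$box)) {
      b <- as.numeric(r$box)
      if (length(b) != 4)
        kafr_stop(sprintf("box must have 4 numbers at line %d", i), "kafr_parse_error")
      b
    } else {
      p <- poly[[i]]
      if (nrow(p) < 3)
        kafr_stop(sprintf("polygon needs >= 3 vertices at line %d", i), "kafr_parse_error")
      c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))  # bounding box
    }
  }, numeric(4)))
  .new_detections(frame, class_id, conf, box, poly, track)
}

.read_detections_yolo <- function(path, fg) {
  if (is.null(fg)) kafr_stop("yolo_txt dialect requires frame geometry fg", "kafr_config_error")
  stopifnot(inherits(fg, "frame_geometry"))
  if (!dir.exists(path))
    kafr_stop(sprintf("'%s' is not a directory of yolo txt files", path), "kafr_io_error")
  files <- list.files(path, pattern = "^[0-9]+\\.txt$", full.names = TRUE)
  if (length(files) == 0) return(.empty_detections())
  out <- list()
  for (f in files) {
    frame <- as.integer(sub("\\.txt$", "", basename(f)))
    lines <- readLines(f, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (i in seq_along(lines)) {
      fields <- suppressWarnings(as.numeric(strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]))
      if (length(fields) != 6 || anyNA(fields))
        kafr_stop(sprintf("malformed yolo record at %s line %d", basename(f), i),
                  "kafr_parse_error")
      cx <- fields[2] * fg$width; cy <- fields[3] * fg$height
      w <- fields[4] * fg$width;  h <- fields[5] * fg$height
      out[[length(out) + 1]] <- c(frame, fields[1], fields[6],
                                  cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
    }
  }
  m <- do.call(rbind, out)
  .new_detections(m[, 1], m[, 2], m[, 3], m[, 4:7, drop = FALSE])
}

#' Keep detections above a confidence floor
#'
#' Only detections with confidence strictly greater than `min_conf` are
#' retained (the convention used when harvesting detector output for
#' tracking). Order is preserved.
#'
#' @param dets A `kafr_detections` data frame.
#' @param min_conf Confidence floor in `[0, 1]`, default 0.5.
#' @return Filtered detections.
#' @export
filter_confidence <- function(dets, min_conf = 0.5) {
  stopifnot(min_conf >= 0, min_conf <= 1)
  dets[dets$conf > min_conf, , drop = FALSE]
}

#' Merge raw detector class ids
#'
#' Identical instruments detected under distinct raw ids are merged, e.g.
#' two needle drivers whose three parts carry ids 3, 4, 5 and 2, 1, 0: the
#' default map sends 3 to 2, 4 to 1, and 5 to 0. Ids absent from the map
#' pass through unchanged.
#'
#' @param dets A `kafr_detections` data frame.
#' @param merge_map Named integer vector: names are raw ids, values the
#'   merged ids. Default `c("3" = 2, "4" = 1, "5" = 0)`.
#' @return Detections with `class_id` rewritten.
#' @export
merge_class_ids <- function(dets, merge_map = c("3" = 2L, "4" = 1L, "5" = 0L)) {
  if (length(merge_map) == 0 || nrow(dets) == 0) return(dets)
  key <- as.character(dets$class_id)
  hit <- key %in% names(merge_map)
  dets$class_id[hit] <- as.integer(merge_map[key[hit]])
  dets
}

#' Tracked-part specification
#'
#' Which (hand, part) channels to track. The needle-driver parts are
#' part 1 (jaws), part 2 (wrist) and part 3 (shaft); after class merging the
#' default class map is jaw = 0, wrist = 1, shaft = 2. Modes follow the
#' object-count naming convention:
#' \describe{
#'   \item{one}{right-hand jaws only (1 channel)}
#'   \item{two}{jaws of both hands (2 channels)}
#'   \item{four}{jaws + wrists of both hands (4 channels)}
#'   \item{six}{jaws + wrists + shafts of both hands (6 channels)}
#' }
#'
#' @param mode `"one"`, `"two"`, `"four"` or `"six"`.
#' @param class_map Named integer vector mapping part name to merged class
#'   id, default `c(jaw = 0, wrist = 1, shaft = 2)`.
#' @return A `part_spec` object with a `channels` field of
#'   `"<hand>_<part>"` labels.
#' @export
part_spec <- function(mode = c("two", "one", "four", "six"),
                      class_map = c(jaw = 0L, wrist = 1L, shaft = 2L)) {
  mode <- match.arg(mode)
  parts <- switch(mode, one = "jaw", two = "jaw",
                  four = c("jaw", "wrist"), six = c("jaw", "wrist", "shaft"))
  missing_parts <- setdiff(parts, names(class_map))
  if (length(missing_parts) > 0)
    kafr_stop(sprintf("class_map lacks part(s): %s", paste(missing_parts, collapse = ", ")),
              "kafr_config_error")
  channels <- if (mode == "one") "right_jaw" else
    as.vector(t(outer(c("left", "right"), parts, paste, sep = "_")))
  structure(list(mode = mode, class_map = class_map, channels = channels),
            class = "part_spec")
}

#' Build centroid tracks from detections
#'
#' Converts filtered, class-merged detections into one centroid time series
#' per requested (hand, part) channel. Hands are assigned from the centroid's
#' screen half (see [assign_hand()]); when several detections compete for one
#' channel in one frame the highest confidence wins, ties broken by larger
#' geometry area. Channels are keyed by (hand, part) per frame, never by raw
#' tracker ids, which churn after occlusion. Frames with no detection are
#' marked absent.
#'
#' @param dets A `kafr_detections` data frame (filtered and merged).
#' @param fg A [frame_geometry()].
#' @param spec A [part_spec()].
#' @param n_frames Total frame count; default `max(frame) + 1`.
#' @return A `kafr_tracks` object: matrices `x`, `y` (n_frames x n_channels,
#'   NA where absent), logical `present`, `channels`, `frames` (0-based),
#'   `fps`.
#' @export
build_tracks <- function(dets, fg, spec, n_frames = NULL) {
  stopifnot(inherits(fg, "frame_geometry"), inherits(spec, "part_spec"))
  n <- n_frames %||% if (nrow(dets) > 0) max(dets$frame) + 1L else 0L
  tr <- new_tracks(spec$channels, n_frames = n, fps = fg$fps)
  if (nrow(dets) == 0) return(tr)
  part_of <- setNames(names(spec$class_map), as.character(spec$class_map))
  best_conf <- matrix(-Inf, n, length(spec$channels))
  best_area <- matrix(-Inf, n, length(spec$channels))
  for (r in seq_len(nrow(dets))) {
    part <- part_of[as.character(dets$class_id[r])]
    if (is.na(part)) next
    geom <- dets$poly[[r]] %||% c(dets$x_min[r], dets$y_min[r], dets$x_max[r], dets$y_max[r])
    cen <- centroid(geom)
    hand <- suppressWarnings(assign_hand(cen, fg))
    ch <- match(paste(hand, part, sep = "_"), tr$channels)
    if (is.na(ch)) next
    f <- dets$frame[r] + 1L
    if (f > n) next
    area <- (dets$x_max[r] - dets$x_min[r]) * (dets$y_max[r] - dets$y_min[r])
    if (dets$conf[r] > best_conf[f, ch] ||
        (dets$conf[r] == best_conf[f, ch] && area > best_area[f, ch])) {
      best_conf[f, ch] <- dets$conf[r]
      best_area[f, ch] <- area
      tr$x[f, ch] <- cen[1]; tr$y[f, ch] <- cen[2]; tr$present[f, ch] <- TRUE
    }
  }
  tr
}

#' @rdname build_tracks
#' @param channels Character vector of channel labels.
#' @param fps Frames per second.
#' @export
new_tracks <- function(channels, n_frames, fps) {
  m <- matrix(NA_real_, n_frames, length(channels),
              dimnames = list(NULL, channels))
  structure(list(channels = channels, frames = seq_len(n_frames) - 1L,
                 x = m, y = m,
                 present = matrix(FALSE, n_frames, length(channels),
                                  dimnames = list(NULL, channels)),
                 fps = fps),
            class = "kafr_tracks")
}

#' @export
print.kafr_tracks <- function(x, ...) {
  cat(sprintf("<kafr_tracks> %d frames, %d channel(s) [%s], %.3g fps, %.1f%% present\n",
              length(x$frames), length(x$channels),
              paste(x$channels, collapse = ", "), x$fps,
              100 * mean(x$present)))
  invisible(x)
}

#' Write / read a normalized track table
#'
#' CSV with columns `video`, `channel`, `frame`, `x`, `y`, `present`.
#'
#' @param tracks A `kafr_tracks` object.
#' @param path Output CSV path.
#' @param video Video identifier written into the table.
#' @export
write_tracks <- function(tracks, path, video = "video0") {
  n <- length(tracks$frames)
  df <- data.frame(
    video = video,
    channel = rep(tracks$channels, each = n),
    frame = rep(tracks$frames, times = length(tracks$channels)),
    x = as.vector(tracks$x), y = as.vector(tracks$y),
    present = as.vector(tracks$present)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @param fps Frames per second to attach on read (the CSV does not carry it).
#' @export
read_tracks <- function(path, fps = 6) {
  if (!file.exists(path)) kafr_stop(sprintf("no track table at '%s'", path), "kafr_io_error")
  df <- read.csv(path)
  channels <- unique(df$channel)
  n <- max(df$frame) + 1L
  tr <- new_tracks(channels, n, fps)
  for (ch in seq_along(channels)) {
    sub <- df[df$channel == channels[ch], ]
    idx <- sub$frame + 1L
    tr$x[idx, ch] <- sub$x; tr$y[idx, ch] <- sub$y
    tr$present[idx, ch] <- as.logical(sub$present)
  }
  tr$x[!tr$present] <- NA_real_; tr$y[!tr$present] <- NA_real_
  tr
}
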