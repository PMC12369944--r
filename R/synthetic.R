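#' Synthetic procedure configuration
#'
#' States the world the simulator emulates: a stationary endoscope viewing
#' two hand-held instruments (left/right needle drivers, three tracked parts
#' each) through a sequence of annotated phases. Each phase imposes a motion
#' regime: cyclic suturing-like oscillation (constant tangential speed on a
#' circular path) around a hand-specific home position, plus a small
#' mean-reverting (Ornstein-Uhlenbeck) drift of the oscillation center.
#' Idle (phase 0) has near-zero speed. Channels drop out i.i.d. per frame
#' (or in geometric bursts) to emulate occlusion; observed positions carry
#' Gaussian measurement noise.
#'
#' @param n_phases Number of phases including idle (default 7, labels 0..6).
#' @param frames_per_phase Integer range `c(min, max)` of frames per phase
#'   (default 120..360, i.e. 20-60 s at 6 fps).
#' @param fps Frames per second (default 6).
#' @param frame_size `c(width, height)` pixels (default 300 x 300).
#' @param speed_means Mean tool speed per phase label in px/s; default
#'   1 px/s for idle and 18-42 px/s for the six task phases.
#' @param osc_period Oscillation period in seconds (default 3).
#' @param drift_sigma Per-frame OU drift step SD in px (default 0.3).
#' @param drift_tau OU mean-reversion time constant in seconds (default 2).
#' @param dropout_prob Per-frame probability a channel is absent
#'   (default 0.05).
#' @param dropout_burst If TRUE, dropout occurs in geometric-length runs.
#' @param burst_mean Mean occlusion run length in frames (burst mode).
#' @param noise_sigma Positional measurement noise SD in px (default 1).
#' @param background Background intensity for rendering (default 128).
#' @param background_noise_sigma Additive background noise SD in intensity
#'   units for rendering (default 0).
#' @param tool_intensity,tool_radius Rendered blob intensity and radius.
#' @param seed Integer seed fixing the full output.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_phases = 7L,
                       frames_per_phase = c(120L, 360L),
                       fps = 6,
                       frame_size = c(300L, 300L),
                       speed_means = c(1, 25, 35, 18, 42, 30, 22),
                       osc_period = 3,
                       drift_sigma = 0.3,
                       drift_tau = 2,
                       dropout_prob = 0.05,
                       dropout_burst = FALSE,
                       burst_mean = 4,
                       noise_sigma = 1,
                       background = 128,
                       background_noise_sigma = 0,
                       tool_intensity = 210,
                       tool_radius = 6,
                       seed = 1L) {
  stopifnot(n_phases >= 1, length(frames_per_phase) == 2,
            frames_per_phase[1] >= 2, frames_per_phase[2] >= frames_per_phase[1],
            fps > 0, all(frame_size > 0),
            dropout_prob >= 0, dropout_prob <= 1,
            noise_sigma >= 0, background_noise_sigma >= 0, osc_period > 0)
  speed_means <- rep_len(speed_means, n_phases)
  structure(as.list(environment()), class = "sim_config")
}

.sim_channels <- function() {
  parts <- c(jaw = 1.0, wrist = 0.75, shaft = 0.5)  # radius scale per part
  data.frame(
    channel = as.vector(t(outer(c("left", "right"), names(parts), paste, sep = "_"))),
    hand = rep(c("left", "right"), each = 3),
    part = rep(names(parts), 2),
    scale = rep(unname(parts), 2),
    phase_offset = rep(c(0, pi / 3, 2 * pi / 3), 2)
  )
}

#' Simulate a phase-annotated surgical procedure
#'
#' Generates ground-truth and observed centroid tracks for the six (hand,
#' part) channels through the configured phase sequence (labels 0..6 in
#' order), plus the matching phase annotation. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `kafr_procedure` list: `tracks` (observed `kafr_tracks`: noisy,
#'   dropout-masked), `truth` (noiseless, fully present `kafr_tracks`),
#'   `annotation` (a [phase_annotation()]), `truth_speed` (data frame of
#'   realized mean speed per phase and channel, px/s), `cfg`.
#' @export
simulate_procedure <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chans <- .sim_channels()
  w <- cfg$frame_size[1]; h <- cfg$frame_size[2]
  phase_len <- if (cfg$frames_per_phase[1] == cfg$frames_per_phase[2])
    rep(cfg$frames_per_phase[1], cfg$n_phases)
  else sample(seq.int(cfg$frames_per_phase[1], cfg$frames_per_phase[2]), cfg$n_phases,
              replace = TRUE)
  n <- sum(phase_len)
  phase_of <- rep(seq_len(cfg$n_phases) - 1L, phase_len)
  starts <- cumsum(c(0L, phase_len[-cfg$n_phases]))
  ann <- phase_annotation("sim", seq_len(cfg$n_phases) - 1L, starts, starts + phase_len)

  omega <- 2 * pi / cfg$osc_period                 # rad/s
  dt <- 1 / cfg$fps
  home_x <- ifelse(chans$hand == "left", 0.25 * w, 0.75 * w)
  home_y <- rep(0.5 * h, nrow(chans))
  truth <- new_tracks(chans$channel, n, cfg$fps)
  decay <- exp(-dt / cfg$drift_tau)
  for (ci in seq_len(nrow(chans))) {
    theta <- runif(1, 0, 2 * pi) + chans$phase_offset[ci] + omega * dt * (seq_len(n) - 1)
    radius <- cfg$speed_means[phase_of + 1L] / omega * chans$scale[ci]
    dx <- dy <- numeric(n)
    if (cfg$drift_sigma > 0) {
      ex <- rnorm(n, 0, cfg$drift_sigma); ey <- rnorm(n, 0, cfg$drift_sigma)
      for (t in seq_len(n)[-1L]) {
        dx[t] <- dx[t - 1] * decay + ex[t]
        dy[t] <- dy[t - 1] * decay + ey[t]
      }
    }
    x <- home_x[ci] + dx + radius * cos(theta)
    y <- home_y[ci] + dy + radius * sin(theta)
    # keep hands on their screen halves (clamping is rare at defaults)
    x <- if (chans$hand[ci] == "left") pmin(pmax(x, 1), w / 2 - 1)
         else pmin(pmax(x, w / 2), w - 1)
    y <- pmin(pmax(y, 1), h - 1)
    truth$x[, ci] <- x; truth$y[, ci] <- y
  }
  truth$present[] <- TRUE

  present <- matrix(TRUE, n, nrow(chans), dimnames = list(NULL, chans$channel))
  if (cfg$dropout_prob > 0) {
    if (!cfg$dropout_burst) {
      present[] <- runif(n * nrow(chans)) >= cfg$dropout_prob
    } else {
      # alternating visible/occluded runs with geometric lengths chosen so
      # the long-run absent fraction matches dropout_prob
      vis_mean <- cfg$burst_mean * (1 - cfg$dropout_prob) / cfg$dropout_prob
      for (ci in seq_len(nrow(chans))) {
        t <- 1L; vis <- TRUE
        while (t <= n) {
          len <- 1L + stats::rgeom(1, 1 / max(if (vis) vis_mean else cfg$burst_mean, 1))
          present[t:min(n, t + len - 1L), ci] <- vis
          t <- t + len; vis <- !vis
        }
      }
    }
  }
  obs <- truth
  if (cfg$noise_sigma > 0) {
    obs$x <- obs$x + matrix(rnorm(n * nrow(chans), 0, cfg$noise_sigma), n)
    obs$y <- obs$y + matrix(rnorm(n * nrow(chans), 0, cfg$noise_sigma), n)
  }
  obs$present <- present
  obs$x[!present] <- NA_real_; obs$y[!present] <- NA_real_

  truth_speed <- do.call(rbind, lapply(seq_len(cfg$n_phases) - 1L, function(ph) {
    rows <- which(phase_of == ph)
    sp <- vapply(seq_len(nrow(chans)), function(ci) {
      ix <- rows[-1]
      mean(sqrt(diff(truth$x[rows, ci])^2 + diff(truth$y[rows, ci])^2)) * cfg$fps
    }, numeric(1))
    data.frame(phase = ph, channel = chans$channel, mean_speed = sp)
  }))

  structure(list(tracks = obs, truth = truth, annotation = ann,
                 truth_speed = truth_speed, cfg = cfg),
            class = "kafr_procedure")
}

#' @export
print.kafr_procedure <- function(x, ...) {
  cat(sprintf("<kafr_procedure> %d frames, %d phases, %d channels, seed %d\n",
              length(x$tracks$frames), x$cfg$n_phases,
              length(x$tracks$channels), x$cfg$seed))
  invisible(x)
}

#' Render synthetic grayscale frames
#'
#' Each frame is a `height x width` matrix: flat background plus additive
#' Gaussian background noise, with a filled disk at every present channel
#' centroid (true positions), intensities clipped to `[0, 255]`. With
#' static tools and `background_noise_sigma > 0` this is the
#' noise-robustness fixture: every pixel fluctuates while the kinematic
#' accumulation sums stay exactly zero.
#'
#' @param proc A `kafr_procedure`.
#' @param cfg Simulation config (default `proc$cfg`).
#' @param frames Which 0-based frames to render (default all).
#' @param seed Seed for the background noise (default `cfg$seed + 1`).
#' @return List of matrices, one per requested frame.
#' @export
render_frames <- function(proc, cfg = proc$cfg, frames = proc$tracks$frames,
                          seed = cfg$seed + 1L) {
  set.seed(seed)
  w <- cfg$frame_size[1]; h <- cfg$frame_size[2]
  r <- cfg$tool_radius
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]
  lapply(frames, function(f) {
    row <- f + 1L
    img <- matrix(cfg$background, h, w)
    if (cfg$background_noise_sigma > 0)
      img <- img + matrix(rnorm(h * w, 0, cfg$background_noise_sigma), h, w)
    for (ci in seq_along(proc$tracks$channels)) {
      if (!proc$tracks$present[row, ci]) next
      cx <- round(proc$truth$x[row, ci]); cy <- round(proc$truth$y[row, ci])
      px <- off$dx + cx; py <- off$dy + cy
      ok <- px >= 1 & px <= w & py >= 1 & py <= h
      img[cbind(py[ok], px[ok])] <- cfg$tool_intensity
    }
    pmin(pmax(img, 0), 255)
  })
}

#' Emit detections from a simulated procedure
#'
#' Converts every present channel centroid of the observed tracks into a
#' small box detection with uniform-random confidence and optional
#' positional jitter — the inverse of [build_tracks()] up to jitter. Parts
#' map to merged class ids jaw = 0, wrist = 1, shaft = 2 for both hands
#' (hands are recovered downstream from the screen half).
#'
#' @param proc A `kafr_procedure`.
#' @param jitter Uniform box-center jitter in px (default 0).
#' @param conf_range Confidence range `c(lo, hi)` (default `c(0.6, 1)`).
#' @param box_size Box side length in px (default 12).
#' @param seed Seed for jitter and confidence (default `cfg$seed + 2`).
#' @return A `kafr_detections` data frame.
#' @export
emit_detections <- function(proc, jitter = 0, conf_range = c(0.6, 1),
                            box_size = 12, seed = proc$cfg$seed + 2L) {
  set.seed(seed)
  chans <- .sim_channels()
  class_of <- c(jaw = 0L, wrist = 1L, shaft = 2L)
  idx <- which(proc$tracks$present, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  nd <- nrow(idx)
  if (nd == 0) return(.empty_detections())
  cx <- proc$tracks$x[idx] + runif(nd, -jitter, jitter)
  cy <- proc$tracks$y[idx] + runif(nd, -jitter, jitter)
  conf <- runif(nd, conf_range[1], conf_range[2])
  half <- box_size / 2
  .new_detections(frame = idx[, 1] - 1L,
                  class_id = class_of[chans$part[idx[, 2]]],
                  conf = conf,
                  box = cbind(cx - half, cy - half, cx + half, cy + half))
}

#' Write detections as JSON-lines
#'
#' One object per line with keys `frame`, `class`, `conf`, `box`
#' (pixel corners), readable by [read_detections()].
#'
#' @param dets A `kafr_detections` data frame.
#' @param path Output path.
#' @export
write_detections_jsonl <- function(dets, path) {
  lines <- vapply(seq_len(nrow(dets)), function(r) {
    jsonlite::toJSON(list(frame = dets$frame[r], class = dets$class_id[r],
                          conf = round(dets$conf[r], 6),
                          box = round(c(dets$x_min[r], dets$y_min[r],
                                        dets$x_max[r], dets$y_max[r]), 4)),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
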