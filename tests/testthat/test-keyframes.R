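test_that("f_transform evaluates the closed form and decreases in z", {
  expect_equal(f_transform(0, beta = 1, epsilon = 1), 1)
  expect_equal(f_transform(9, beta = 1, epsilon = 1), 0.1)
  expect_equal(f_transform(3, beta = 2, epsilon = 1), 0.0625)
  z <- seq(0, 50, by = 0.5)
  expect_true(all(diff(f_transform(z, beta = 1.7, epsilon = 1e-8)) < 0))
})

test_that("selection_config demands exactly one driver", {
  expect_error(selection_config("adaptive1"), class = "kafr_config_error")
  expect_error(selection_config("adaptive1", threshold_z = 1, target_retention = 0.1),
               class = "kafr_config_error")
  expect_s3_class(selection_config("adaptive2", threshold_z = 0), "selection_config")
})

test_that("greedy scan closes pairs exactly at the accumulated threshold", {
  tr <- linear_track(10, 1)
  kfs <- select_keyframes(tr, selection_config("adaptive1", threshold_z = 6))
  expect_equal(kfs$retained, c(0L, 3L, 6L, 9L))
  expect_equal(unname(kfs$pairs), cbind(c(0L, 3L, 6L), c(3L, 6L, 9L)),
               ignore_attr = TRUE)
  # pair chain: each i equals the previous j
  expect_equal(kfs$pairs[-1, "i"], kfs$pairs[-nrow(kfs$pairs), "j"],
               ignore_attr = TRUE)
  # stationary: nothing accumulates, first and last only
  st <- make_tracks(matrix(3, nrow = 20, ncol = 1))
  expect_equal(select_keyframes(st, selection_config("adaptive1", threshold_z = 0.5))$retained,
               c(0L, 19L))
  # z* = 0: every consecutive pair closes
  expect_equal(select_keyframes(st, selection_config("adaptive1", threshold_z = 0))$retained,
               0:19)
  expect_error(select_keyframes(make_tracks(matrix(1, 1, 1)),
                                selection_config("adaptive1", threshold_z = 1)),
               class = "kafr_argument_error")
})

test_that("selection matches the brute-force oracle on random tracks (both modes)", {
  for (seed in 1:25) {
    set.seed(seed + 1000)
    n <- sample(5:50, 1)
    rt <- random_tracks(n, sample(1:3, 1), seed = seed, dropout = runif(1, 0, 0.3))
    for (mode in c("adaptive1", "adaptive2")) {
      for (q in c(0.3, 0.8)) {
        zmax <- if (mode == "adaptive1") anchor_displacement_sum(rt, 0, n - 1)
                else anchor_velocity_variation_sum(compute_velocity(rt), 0, n - 1)
        zs <- max(q * zmax, 1e-6)
        got <- select_keyframes(rt, selection_config(mode, threshold_z = zs))$retained
        expect_identical(as.integer(got), as.integer(oracle_select(rt, mode, zs)),
                         label = sprintf("seed %d mode %s q %.1f", seed, mode, q))
      }
    }
  }
})

test_that("threshold duality: d-scale selection equals z* = d^(-1/beta) - eps", {
  rt <- random_tracks(60, 2, seed = 77)
  for (beta in c(0.5, 1, 2)) {
    for (zs in c(2, 20, 200)) {
      eps <- 1e-8
      d <- 1 / (zs + eps)^beta
      a <- select_keyframes(rt, selection_config("adaptive1", threshold_z = zs, beta = beta))
      b <- select_keyframes(rt, selection_config("adaptive1", threshold_d = d, beta = beta))
      expect_equal(a$retained, b$retained)
    }
  }
})

test_that("retained count is non-increasing in z* on continuous motion", {
  for (seed in 1:5) {
    rt <- smooth_tracks(120, 2, seed = seed)
    grid <- seq(0, 2 * anchor_displacement_sum(rt, 0, 119) / 119, length.out = 30)
    counts <- vapply(grid, function(zs)
      length(select_keyframes(rt, selection_config("adaptive1", threshold_z = zs))$retained),
      numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("calibration reaches the sweep-grid retention targets within tol", {
  rt <- random_tracks(1200, 2, seed = 5)
  for (target in c(0.01, 0.05, 0.10, 0.15, 0.20, 0.30, 0.50)) {
    z <- calibrate_threshold(rt, "adaptive1", target, tol = 0.005)
    kfs <- select_keyframes(rt, selection_config("adaptive1", threshold_z = as.numeric(z)))
    expect_lte(abs(retention(kfs) - target), 0.005,
               label = sprintf("adaptive1 target %.2f", target))
  }
  # adaptive2 at the pipeline's default target
  z2 <- calibrate_threshold(rt, "adaptive2", 0.10, tol = 0.005)
  expect_lte(abs(attr(z2, "achieved_retention") - 0.10), 0.005)
})

test_that("calibration agrees with an exhaustive threshold-sweep oracle", {
  rt <- linear_track(1000, 1)   # constant speed: z(i, i+k) = k(k+1)/2
  z <- calibrate_threshold(rt, "adaptive1", 0.10, tol = 0.005)
  achieved <- attr(z, "achieved_retention")
  # sweep candidate thresholds densely and find the closest achievable
  sweep_frac <- vapply(seq(1, 200, by = 1), function(zs)
    retention(select_keyframes(rt, selection_config("adaptive1", threshold_z = zs))),
    numeric(1))
  best <- min(abs(sweep_frac - 0.10))
  expect_lte(abs(achieved - 0.10), max(best, 0.005) + 1e-12)
})

test_that("calibration boundary and degenerate cases behave as declared", {
  rt <- random_tracks(200, 1, seed = 2)
  z <- calibrate_threshold(rt, "adaptive1", 1.0)
  expect_equal(as.numeric(z), 0)
  expect_equal(attr(z, "achieved_retention"), 1)
  # two frames: only retention 1 is achievable, smaller targets error
  two <- linear_track(2, 1)
  expect_error(calibrate_threshold(two, "adaptive1", 0.5),
               class = "kafr_calibration_error")
  expect_error(calibrate_threshold(rt, "adaptive1", 0),
               class = "kafr_argument_error")
})

test_that("global calibration pools several videos into one threshold", {
  pool <- list(random_tracks(300, 2, seed = 1), random_tracks(500, 2, seed = 2),
               linear_track(200, 2))
  z <- calibrate_threshold(pool, "adaptive1", 0.15)
  fracs <- vapply(pool, function(tr)
    length(select_keyframes(tr, selection_config("adaptive1",
                                                 threshold_z = as.numeric(z)))$retained),
    numeric(1))
  expect_lte(abs(sum(fracs) / 1000 - 0.15), 0.005)
})

test_that("faster motion yields denser key frames at a fixed threshold", {
  # with anchor-relative accumulation z(i, i+k) ~ v * k(k+1)/2, so the
  # inter-key gap scales as 1/sqrt(speed): doubling speed shrinks the
  # median gap by about sqrt(2) (and never enlarges it)
  slow <- linear_track(600, 1)
  fast <- linear_track(600, 2)
  zs <- 40
  g1 <- median(diff(select_keyframes(slow, selection_config("adaptive1", threshold_z = zs))$retained))
  g2 <- median(diff(select_keyframes(fast, selection_config("adaptive1", threshold_z = zs))$retained))
  expect_lt(g2, g1)
  expect_lte(g2, g1 / sqrt(2) + 1)
})

test_that("retention reports the retained fraction with argument checks", {
  tr <- linear_track(1000, 1)
  kfs <- select_keyframes(tr, selection_config("adaptive1", target_retention = 0.10))
  expect_equal(retention(kfs, 1000), length(kfs$retained) / 1000)
  expect_equal(retention(select_keyframes(make_tracks(matrix(1, 5, 1)),
                                          selection_config("adaptive1", threshold_z = 0))),
               1)
  expect_error(retention(kfs, 0), class = "kafr_argument_error")
  expect_error(retention(kfs, 3), class = "kafr_argument_error")
})
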