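test_that("jsonl detections parse with direct field mapping", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"frame":0,"class":0,"box":[10,10,20,20],"conf":0.9}',
    '{"frame":1,"class":2,"poly":[[0,0],[4,0],[4,4],[0,4]],"conf":0.8,"track":5}'
  ), path)
  dets <- read_detections(path, "jsonl")
  expect_equal(nrow(dets), 2)
  expect_equal(dets$frame, c(0L, 1L))
  expect_equal(dets$class_id, c(0L, 2L))
  expect_equal(dets$conf, c(0.9, 0.8))
  expect_equal(unlist(dets[1, c("x_min", "y_min", "x_max", "y_max")],
                      use.names = FALSE), c(10, 10, 20, 20))
  expect_null(dets$poly[[1]])
  expect_equal(dets$poly[[2]], rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)))
  expect_equal(dets$track_id, c(NA_integer_, 5L))
})

test_that("jsonl parse errors name the offending line; empty file is empty", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"frame":0,"class":0,"box":[1,1,2,2],"conf":0.9}',
               '{"frame":1,"conf":0.5}'), path)
  expect_error(read_detections(path, "jsonl"), "line 2", class = "kafr_parse_error")
  writeLines(character(0), path)
  expect_equal(nrow(read_detections(path, "jsonl")), 0)
  expect_error(read_detections(file.path(tempdir(), "nope.jsonl"), "jsonl"),
               class = "kafr_io_error")
})

test_that("yolo txt normalized boxes convert to pixel corners", {
  dir <- withr::local_tempdir()
  writeLines("0 0.5 0.5 0.1 0.1 0.9", file.path(dir, "0.txt"))
  writeLines(c("1 0.25 0.5 0.2 0.4 0.7", "bad line here"), file.path(dir, "3.txt"))
  fg <- frame_geometry(100, 100)
  expect_error(read_detections(dir, "yolo_txt", fg), "3.txt line 2",
               class = "kafr_parse_error")
  writeLines("1 0.25 0.5 0.2 0.4 0.7", file.path(dir, "3.txt"))
  dets <- read_detections(dir, "yolo_txt", fg)
  d0 <- dets[dets$frame == 0, ]
  expect_equal(unlist(d0[, c("x_min", "y_min", "x_max", "y_max")],
                      use.names = FALSE), c(45, 45, 55, 55))
  d3 <- dets[dets$frame == 3, ]
  expect_equal(unlist(d3[, c("x_min", "y_min", "x_max", "y_max")],
                      use.names = FALSE), c(15, 30, 35, 70))
  expect_error(read_detections(dir, "yolo_txt"), class = "kafr_config_error")
})

test_that("confidence filter is strictly greater-than", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(sprintf('{"frame":%d,"class":0,"box":[1,1,2,2],"conf":%s}',
                     0:2, c("0.4", "0.5", "0.51")), path)
  dets <- read_detections(path, "jsonl")
  expect_equal(nrow(filter_confidence(dets, 0.5)), 1)
  expect_equal(filter_confidence(dets, 0.5)$conf, 0.51)
  expect_equal(nrow(filter_confidence(dets, 0)), 3)
  expect_equal(nrow(filter_confidence(dets[0, ], 0.5)), 0)
})

test_that("class-id merging applies the map and passes unknown ids through", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(sprintf('{"frame":0,"class":%d,"box":[1,1,2,2],"conf":0.9}', c(3, 4, 5, 7, 0)),
             path)
  dets <- read_detections(path, "jsonl")
  merged <- merge_class_ids(dets)
  expect_equal(merged$class_id, c(2L, 1L, 0L, 7L, 0L))
  expect_equal(merge_class_ids(dets, integer(0))$class_id, dets$class_id)
})

test_that("filter and merge commute", {
  set.seed(11)
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(sprintf('{"frame":%d,"class":%d,"box":[1,1,2,2],"conf":%.3f}',
                     0:29, sample(0:7, 30, TRUE), runif(30)), path)
  dets <- read_detections(path, "jsonl")
  a <- merge_class_ids(filter_confidence(dets, 0.5))
  b <- filter_confidence(merge_class_ids(dets), 0.5)
  expect_equal(a, b)
})

test_that("centroid: box center, polygon shoelace, degenerate and invalid cases", {
  expect_equal(centroid(c(45, 45, 55, 55)), c(x = 50, y = 50))
  square <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_equal(centroid(square), c(x = 1, y = 1))
  tri <- rbind(c(0, 0), c(3, 0), c(0, 3))
  expect_equal(centroid(tri), c(x = 1, y = 1))
  # degenerate zero-area polygon falls back to the vertex mean
  flat <- rbind(c(0, 1), c(2, 1), c(4, 1))
  expect_equal(centroid(flat), c(x = 2, y = 1))
  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(centroid(bowtie), class = "kafr_geometry_error")
  expect_error(centroid(c(2, 0, 1, 5)), class = "kafr_geometry_error")
})

test_that("polygon centroid agrees with a Monte-Carlo area-sampling oracle", {
  poly <- rbind(c(1, 1), c(7, 2), c(9, 6), c(4, 9), c(0, 5))  # convex-ish pentagon
  mc <- mc_polygon_centroid(poly, n = 3e5, seed = 99)
  expect_equal(unname(centroid(poly)), mc, tolerance = 0.02)
})

test_that("centroid is translation-equivariant on random polygons", {
  set.seed(21)
  for (rep in 1:20) {
    # star-shaped polygon around a random center: simple by construction
    # (angular gaps kept below pi so every edge stays inside its wedge)
    k <- sample(4:9, 1)
    gaps <- runif(k, 0.5, 1)
    ang <- 2 * pi * cumsum(gaps) / sum(gaps)
    r <- runif(k, 1, 5)
    cx <- runif(1, 10, 50); cy <- runif(1, 10, 50)
    poly <- cbind(cx + r * cos(ang), cy + r * sin(ang))
    shift <- runif(2, 0, 20)
    shifted <- sweep(poly, 2, shift, "+")
    expect_equal(unname(centroid(shifted)), unname(centroid(poly)) + shift,
                 tolerance = 1e-10)
  }
})

test_that("bbox_iou matches hand-computed and rasterized values and is symmetric", {
  expect_equal(bbox_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(bbox_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(bbox_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_equal(raster_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7, tolerance = 0.01)
  set.seed(31)
  for (rep in 1:20) {
    a <- c(sort(runif(2, 0, 10)), sort(runif(2, 0, 10)))[c(1, 3, 2, 4)]
    b <- c(sort(runif(2, 0, 10)), sort(runif(2, 0, 10)))[c(1, 3, 2, 4)]
    expect_equal(bbox_iou(a, b), bbox_iou(b, a))
    expect_gte(bbox_iou(a, b), 0); expect_lte(bbox_iou(a, b), 1)
  }
})

test_that("hand assignment splits at the vertical midline, ties to the right", {
  fg <- frame_geometry(100, 100)
  expect_equal(assign_hand(c(10, 50), fg), "left")
  expect_equal(assign_hand(c(90, 50), fg), "right")
  expect_equal(assign_hand(c(50, 50), fg), "right")
  expect_warning(assign_hand(c(150, 50), fg), "clamping")
})

test_that("build_tracks keys channels by hand and part with confidence tie-break", {
  fg <- frame_geometry(100, 100)
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"frame":0,"class":0,"box":[5,45,15,55],"conf":0.9}',
    '{"frame":0,"class":0,"box":[85,45,95,55],"conf":0.9}',
    '{"frame":1,"class":0,"box":[80,40,90,50],"conf":0.8}',
    '{"frame":1,"class":0,"box":[70,40,80,50],"conf":0.6}'
  ), path)
  dets <- read_detections(path, "jsonl")
  tr <- build_tracks(dets, fg, part_spec("two"), n_frames = 4)
  expect_equal(tr$channels, c("left_jaw", "right_jaw"))
  expect_true(all(tr$present[1, ]))
  expect_equal(unname(tr$x[1, "left_jaw"]), 10)
  expect_equal(unname(tr$x[1, "right_jaw"]), 90)
  # frame 1: two right-side candidates, highest confidence wins
  expect_false(tr$present[2, "left_jaw"])
  expect_equal(unname(tr$x[2, "right_jaw"]), 85)
  # frames 2..3 have no detections
  expect_false(any(tr$present[3:4, ]))
})

test_that("build_tracks channel count follows the part mode", {
  fg <- frame_geometry(100, 100)
  dets <- emit_detections(simulate_procedure(
    sim_config(frames_per_phase = c(5, 5), frame_size = c(100, 100), seed = 2)))
  for (mode in c("one", "two", "four", "six")) {
    nc <- c(one = 1, two = 2, four = 4, six = 6)[[mode]]
    expect_length(build_tracks(dets, fg, part_spec(mode))$channels, nc)
  }
  expect_error(part_spec("two", class_map = c(wrist = 1L)), class = "kafr_config_error")
})

test_that("track tables round-trip through CSV", {
  tr <- random_tracks(25, 2, seed = 8, dropout = 0.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, path, video = "v1")
  rt <- read_tracks(path, fps = 6)
  expect_equal(rt$present, tr$present, ignore_attr = TRUE)
  expect_equal(rt$x, tr$x, ignore_attr = TRUE)
  expect_equal(rt$y, tr$y, ignore_attr = TRUE)
})
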