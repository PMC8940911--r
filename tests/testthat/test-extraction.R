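test_that("percentile segmentation matches the worked example and oracle", {
  # 100 pixels valued 0..99: band [79.2, 94.05] -> {80..94}, mean 87
  f <- matrix(0:99, 10, 10)
  s <- segment_box(f, bbox(0, 0, 10, 10))
  expect_equal(sum(s$mask), 15)
  expect_equal(s$soma_mean, 87)
  expect_equal(sort(f[s$mask]), 80:94)

  # constant box: degenerate distribution selects everything
  cf <- matrix(5, 8, 8)
  sc <- segment_box(cf, bbox(1, 1, 6, 6))
  expect_true(all(sc$mask))
  expect_equal(sc$soma_mean, 5)

  # empty box after clipping errors
  expect_error(segment_box(f, bbox(-10, -10, -1, -1)), "empty")

  # random-box equivalence with the sort-based oracle
  set.seed(9)
  for (k in 1:200) {
    fr <- matrix(rnorm(400), 20, 20)
    b <- random_boxes(1, fov = c(20, 20), max_side = 12)
    got <- segment_box(fr, b)
    want <- segment_oracle(fr[got$rows, got$cols])
    expect_equal(got$soma_mean, want$mean, tolerance = 1e-12)
    expect_equal(sum(got$mask), want$n_sel)
  }
})

test_that("global background averages exactly the non-box pixels", {
  u <- matrix(3.5, 6, 6)
  expect_equal(global_background(u, bbox(0, 0, 3, 3)), 3.5)

  z <- matrix(0, 4, 4)
  z[2:3, 2:3] <- 10
  expect_equal(global_background(z, bbox(1, 1, 3, 3)), 0)

  expect_error(global_background(z, bbox(0, 0, 4, 4)), "entire field")

  set.seed(10)
  for (k in 1:50) {
    fr <- matrix(rnorm(14 * 14), 14, 14)
    b <- random_boxes(3, fov = c(14, 14), max_side = 6)
    expect_equal(global_background(fr, b), bg_oracle(fr, b),
                 tolerance = 1e-12)
  }
})

test_that("local background uses the doubled concentric box minus neighbours", {
  u <- matrix(2, 20, 20)
  b <- bbox(8, 8, 12, 12)
  expect_equal(local_background(u, b), 2)

  # a neighbour fully inside the annulus is excluded even if extreme
  fr <- matrix(1, 20, 20)
  nb <- bbox(13, 9, 15, 11)
  pr <- somatrace:::box_pixel_range(nb, c(20, 20))
  fr[pr$rows, pr$cols] <- 1000
  expect_equal(local_background(fr, b, all_boxes = rbind(b, nb)), 1)

  # doubled box clipped at the FOV border still computes
  edge <- bbox(0, 0, 4, 4)
  expect_equal(local_background(u, edge), 2)

  # fully covered annulus yields NA with a warning
  cover <- bbox(0, 0, 20, 20)
  expect_warning(v <- local_background(fr, b, all_boxes = rbind(b, cover)),
                 "no eligible")
  expect_true(is.na(v))
})

test_that("frame extraction subtracts the common background", {
  reg <- identity_registry()
  reg <- update_tracks(reg, detection_set(bbox(2, 2, 8, 8, score = 1)),
                       frame = 0L)
  traces <- trace_set(matrix(NA_real_, 0, 0), bg = numeric(0),
                      ids = integer(0), frame_rate = 30)
  u <- matrix(7, 16, 16)
  traces <- extract_frame(u, reg, traces)
  expect_equal(traces$traces[1, 1], 0)  # uniform frame -> 0 after subtraction
  expect_equal(traces$bg[1], 7)

  # adding a constant to the frame leaves bg-subtracted traces unchanged
  set.seed(11)
  fr <- matrix(rnorm(256), 16, 16)
  t1 <- extract_frame(fr, reg, trace_set(matrix(NA_real_, 0, 0),
                                         bg = numeric(0), ids = integer(0)))
  t2 <- extract_frame(fr + 42, reg, trace_set(matrix(NA_real_, 0, 0),
                                              bg = numeric(0), ids = integer(0)))
  expect_equal(t1$traces[1, 1], t2$traces[1, 1], tolerance = 1e-9)
})

test_that("extracted traces track the ground-truth transients", {
  r <- small_render(n_cells = 4, fov = 64, n_frames = 60, seed = 43,
                    spike_rate = 1)
  mock <- gt_detector(r$gt_boxes)
  cfg <- pipeline_config(mode = "step", n_frames = 1, detector = "custom",
                         custom_detector = mock)
  res <- run_online(r$stack, cfg)
  expect_equal(ncol(res$traces$traces), 4)
  final <- registry_boxes(res$registry)
  for (i in seq_len(4)) {
    # map identity back to the GT cell at the same position
    gi <- which.max(somatrace:::overlap_matrix(final[i, , drop = FALSE],
                                               r$gt_boxes, "sum"))
    cc <- cor(res$traces$traces[, match(final$identity[i], res$traces$ids)],
              r$gt_traces$traces[, gi])
    expect_gt(cc, 0.99)
  }
})

test_that("online runs are scheduler-invariant and causally masked", {
  r <- small_render(n_cells = 3, fov = 48, n_frames = 21, seed = 3)
  cfg <- pipeline_config(mode = "step", n_frames = 7, score_threshold = 0.1)
  seq_run <- run_online(r$stack, cfg, scheduler = "sequential")
  par_run <- run_online(r$stack, cfg, scheduler = "interleaved",
                        chunk_size = 5)
  expect_identical(seq_run$traces$traces, par_run$traces$traces)
  expect_identical(seq_run$traces$bg, par_run$traces$bg)

  # no trace before the first detection emission (frame 6, 0-based)
  fv <- first_valid_frame(seq_run$traces)
  expect_true(all(fv >= 6))
  expect_true(all(is.na(seq_run$traces$traces[1:6, ])))
  # background defined for every processed frame
  expect_equal(length(seq_run$traces$bg), 21)
  expect_false(anyNA(seq_run$traces$bg))
})

test_that("offline runs use one static box set projected to all frames", {
  # static noiseless movie: no spikes -> constant per-frame soma means
  cfg0 <- scene_config(fov_shape = c(48, 48), n_cells = 3, n_frames = 12,
                       spike_rate = 0, noise_sigma = 0)
  r <- render_movie(generate_scene(cfg0, seed = 19))
  off <- run_offline(r$stack, pipeline_config(score_threshold = 0.1))
  expect_equal(nrow(off$boxes), 3)
  for (j in seq_len(ncol(off$traces$raw))) {
    expect_equal(diff(range(off$traces$raw[, j])), 0, tolerance = 1e-9)
  }

  # online with step n = T matches offline on the commonly defined frames
  on <- run_online(r$stack, pipeline_config(mode = "step", n_frames = 12,
                                            score_threshold = 0.1))
  expect_equal(length(on$emissions), 1)
  ord_on <- order(registry_boxes(on$registry)$y_min)
  ord_off <- order(off$boxes$y_min)
  expect_equal(registry_boxes(on$registry)[ord_on, 1:4],
               off$boxes[ord_off, 1:4], ignore_attr = TRUE)
  on_cols <- match(registry_boxes(on$registry)$identity[ord_on], on$traces$ids)
  expect_identical(unname(on$traces$traces[12, on_cols]),
                   unname(off$traces$traces[12, ord_off]))
  expect_identical(on$traces$bg[12], off$traces$bg[12])
})
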