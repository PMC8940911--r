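test_that("overlap ratios match hand geometry", {
  a <- bbox(0, 0, 2, 2); b <- bbox(1, 1, 3, 3)
  expect_equal(sum_area_overlap(a, a), 0.5)        # I / (A + A)
  expect_equal(standard_iou(a, a), 1)
  expect_equal(sum_area_overlap(a, b), 1 / 8)      # I = 1, A + B = 8
  expect_equal(standard_iou(a, b), 1 / 7)
  far <- bbox(10, 10, 12, 12)
  expect_equal(sum_area_overlap(a, far), 0)
  expect_equal(standard_iou(a, far), 0)
})

test_that("overlap is symmetric and standard IoU dominates the sum ratio", {
  set.seed(6)
  b <- random_boxes(40)
  for (k in 1:60) {
    i <- sample(40, 1); j <- sample(40, 1)
    bi <- b[i, , drop = FALSE]; bj <- b[j, , drop = FALSE]
    expect_equal(sum_area_overlap(bi, bj), sum_area_overlap(bj, bi))
    pov <- sum_area_overlap(bi, bj); iou <- standard_iou(bi, bj)
    expect_gte(iou, pov)
    if (pov > 0) expect_gt(iou, pov) else expect_equal(iou, 0)
  }
})

test_that("duplicate suppression keeps the highest score and matches the oracle", {
  two <- bbox(c(0, 0), c(0, 0), c(4, 4), c(4, 4), score = c(0.9, 0.8))
  kept <- suppress_duplicates(two)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.9)

  # all pairwise overlaps below threshold -> unchanged (up to ordering)
  apart <- bbox(c(0, 20, 40), c(0, 20, 40), c(4, 24, 44), c(4, 24, 44),
                score = c(0.5, 0.9, 0.7))
  kept2 <- suppress_duplicates(apart)
  expect_equal(nrow(kept2), 3)

  # brute-force equivalence on 200 random boxes
  set.seed(7)
  b <- random_boxes(200, fov = c(60, 60), max_side = 14)
  got <- suppress_duplicates(b, 0.2)
  want <- nms_oracle(b, 0.2)
  expect_equal(got, want)
  # no surviving pair above the threshold
  ov <- somatrace:::overlap_matrix(got, got, "sum")
  diag(ov) <- 0
  expect_lte(max(ov), 0.2)
})

test_that("reference detector finds synthetic somata", {
  det <- reference_blob_detector()

  blank <- prepare_detector_input(matrix(0, 64, 64))
  expect_equal(nrow(det$detect(blank)), 0)

  # single disk: one box centred within 1 px of the disk centre
  rows <- 1:64
  prof <- somatrace:::soma_profile(rows, rows, c(30.2, 24.7), 6)
  img <- 10 + 80 * prof
  b <- det$detect(prepare_detector_input(img))
  b <- suppress_duplicates(b)
  expect_equal(nrow(b), 1)
  expect_lt(abs((b$x_min + b$x_max) / 2 - 24.7), 1)
  expect_lt(abs((b$y_min + b$y_max) / 2 - 30.2), 1)

  # 10 well-separated somata: full recall at threshold 0
  r <- small_render(n_cells = 10, fov = 128, n_frames = 3, seed = 13)
  ds <- detect_image(mean_projection(r$stack), det)
  m <- match_detections(ds$boxes, r$gt_boxes)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
})

test_that("the cnn adapter fails loudly and detectors are substitutable", {
  expect_error(cnn_adapter(file.path(tempdir(), "nope.h5")), "not found")
  f <- withr::local_tempfile(fileext = ".h5")
  writeLines("x", f)
  expect_error(cnn_adapter(f), "reference")

  # a custom detector plugged through the same interface drives the
  # pipeline exactly like the built-in one
  r <- small_render(n_cells = 3, fov = 48, n_frames = 12, seed = 2)
  mock <- gt_detector(r$gt_boxes)
  cfg <- pipeline_config(mode = "step", n_frames = 4, detector = "custom",
                         custom_detector = mock)
  res <- run_online(r$stack, cfg)
  expect_equal(length(res$registry$identities), 3)
  ds <- detect_image(mean_projection(r$stack), mock)
  expect_true(all(ds$boxes$score >= 0 & ds$boxes$score <= 1))
})

test_that("tiling plans cover the field of view with anchored final tiles", {
  p1 <- plan_tiles(c(128, 128), 128, 28)
  expect_equal(nrow(p1$offsets), 1)
  expect_equal(unname(unlist(p1$offsets[1, ])), c(0, 0))

  p2 <- plan_tiles(c(228, 228), 128, 28)
  expect_equal(p2$row_offsets, c(0L, 100L))  # exact cover

  p3 <- plan_tiles(c(256, 256), 128, 28)
  expect_equal(p3$row_offsets, c(0L, 100L, 128L))  # anchored final tile

  # coverage property on odd sizes
  for (len in c(130, 200, 301, 515)) {
    p <- plan_tiles(c(len, len), 128, 28)
    covered <- rep(FALSE, len)
    for (o in p$row_offsets) covered[(o + 1):(o + 128)] <- TRUE
    expect_true(all(covered))
  }

  expect_error(plan_tiles(c(100, 100), 128, 28), "exceeds")
})

test_that("tiled detection equals plain detection and dedupes seam cells", {
  det <- reference_blob_detector()
  r <- small_render(n_cells = 5, fov = 128, n_frames = 3, seed = 17)
  img <- mean_projection(r$stack)

  # single tile covering the FOV equals plain detection
  p1 <- plan_tiles(c(128, 128), 128, 28)
  tiled <- detect_tiled(img, det, p1)
  plain <- detect_image(img, det)
  expect_equal(tiled$boxes[order(tiled$boxes$y_min), ],
               plain$boxes[order(plain$boxes$y_min), ],
               ignore_attr = TRUE)

  # a cell straddling the seam inside the overlap keeps exactly one box
  rows <- 1:228
  seam_img <- 10 + 80 * somatrace:::soma_profile(rows, rows, c(114, 114), 6)
  p <- plan_tiles(c(228, 228), 128, 28)
  out <- detect_tiled(seam_img, det, p)
  expect_equal(nrow(out$boxes), 1)

  # empty image -> empty set
  empty <- detect_tiled(matrix(0, 228, 228), det, p)
  expect_equal(nrow(empty$boxes), 0)

  # results independent of batching
  out1 <- detect_tiled(seam_img, det, plan_tiles(c(228, 228), 128, 28, batch_size = 1))
  expect_equal(out$boxes, out1$boxes)
})

test_that("offline grid search has the documented cardinality and argmax", {
  r <- small_render(n_cells = 3, fov = 48, n_frames = 4, seed = 23)
  mock <- gt_detector(r$gt_boxes)

  # default grids: 15 x 19 = 285 evaluations
  gs <- grid_search_offline(r$stack, r$gt_boxes, mock)
  expect_equal(nrow(gs$surface), 285)
  expect_true(all(gs$surface$f1 >= 0 & gs$surface$f1 <= 1))
  expect_equal(gs$best_f1, max(gs$surface$f1))

  # self-consistency: a movie rendered at the reference detector's native
  # scale scores its maximal F-1 at upscale 1
  det <- reference_blob_detector()
  r2 <- small_render(n_cells = 5, fov = 96, n_frames = 3, seed = 29)
  gs2 <- grid_search_offline(r2$stack, r2$gt_boxes, det,
                             upscale_grid = c(0.6, 1, 1.8),
                             threshold_grid = c(0.05, 0.5))
  at_one <- max(gs2$surface$f1[gs2$surface$upscale == 1])
  expect_equal(at_one, gs2$best_f1)
})

test_that("online grid search reduces to per-frame detection at n = 1", {
  r <- small_render(n_cells = 4, fov = 64, n_frames = 10, seed = 31,
                    noise_sigma = 0)
  det <- reference_blob_detector()
  gs <- grid_search_online(r$stack, r$gt_boxes, det, n_grid = c(1, 5),
                           threshold_grid = c(0.1, 0.5))
  expect_equal(nrow(gs$surface), 4)  # |n_grid| x |threshold_grid|
  expect_true(all(gs$surface$f1 >= 0 & gs$surface$f1 <= 1))

  # n = 1: final tracked set equals running per-frame detection + tracking
  reg <- identity_registry()
  for (t in 1:10) {
    ds <- detect_image(r$stack$frames[, , t], det, score_threshold = 0.1)
    reg <- update_tracks(reg, ds, fov_shape = c(48, 48))
  }
  m <- match_detections(registry_boxes(reg), r$gt_boxes)
  expect_equal(gs$surface$f1[gs$surface$n == 1 & gs$surface$threshold == 0.1],
               m$f1)
})

test_that("averaging helps detection on noisy movies", {
  r <- small_render(n_cells = 6, fov = 64, n_frames = 40, seed = 37,
                    noise_sigma = 60)
  det <- reference_blob_detector()
  gs <- grid_search_online(r$stack, r$gt_boxes, det, n_grid = c(1, 20),
                           threshold_grid = c(0.2))
  f1_n1 <- gs$surface$f1[gs$surface$n == 1]
  f1_n20 <- gs$surface$f1[gs$surface$n == 20]
  expect_gte(f1_n20, f1_n1)
})
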