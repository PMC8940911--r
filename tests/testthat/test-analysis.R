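test_that("detection matching follows the counting conventions", {
  b <- bbox(c(0, 20), c(0, 20), c(10, 30), c(10, 30), score = c(0.9, 0.8))
  m <- match_detections(b, b)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$mean_iou, 1)

  # empty predictions against 5 GT boxes
  gt5 <- random_boxes(5)
  m0 <- match_detections(empty_boxes(), gt5)
  expect_equal(m0$tp, 0); expect_equal(m0$fn, 5)
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 0)  # degenerate-count convention

  # no ground truth to find -> recall 1 by convention
  m1 <- match_detections(gt5, empty_boxes())
  expect_equal(m1$recall, 1)
  expect_equal(m1$precision, 0)
})

test_that("matching is count-symmetric and equals the brute-force oracle", {
  set.seed(12)
  pred <- random_boxes(25, fov = c(60, 60), max_side = 15)
  gt <- random_boxes(25, fov = c(60, 60), max_side = 15)
  m <- match_detections(pred, gt)
  want <- match_oracle(pred, gt)
  expect_equal(m$tp, want$tp)
  expect_equal(m$fp, want$fp)
  expect_equal(m$fn, want$fn)
  # swapping pred and gt swaps FP and FN, TP unchanged
  ms <- match_detections(gt, pred)
  expect_equal(ms$tp, m$tp)
  expect_equal(ms$fp, m$fn)
  expect_equal(ms$fn, m$fp)
})

test_that("the F-1 harmonic mean reproduces the worked mesoscale numbers", {
  expect_equal(round(f1_from_counts(0.77, 0.42), 2), 0.54)
  expect_equal(f1_from_counts(1, 1), 1)
  expect_equal(f1_from_counts(1, 0), 0)
  expect_equal(f1_from_counts(0, 0), 0)
  # algebraic identity on a dense grid
  for (p in seq(0.05, 1, 0.05)) for (r in seq(0.05, 1, 0.05)) {
    expect_equal(f1_from_counts(p, r), 2 * p * r / (p + r), tolerance = 1e-12)
  }
})

test_that("consensus merge separates shared and disputed annotations", {
  g1 <- bbox(c(0, 20), c(0, 20), c(10, 30), c(10, 30))
  same <- consensus_merge(g1, g1)
  expect_equal(nrow(same$consensus), 2)
  expect_equal(nrow(same$disputed), 0)

  g2 <- bbox(c(50, 70), c(50, 70), c(60, 80), c(60, 80))
  disj <- consensus_merge(g1, g2)
  expect_equal(nrow(disj$consensus), 0)
  expect_equal(nrow(disj$disputed), 4)

  # one shared box plus one unique per grader -> 1 consensus, 2 disputed
  a <- bbox(c(0, 40), c(0, 40), c(10, 50), c(10, 50))
  b <- bbox(c(1, 70), c(1, 70), c(11, 80), c(11, 80))
  mix <- consensus_merge(a, b)
  expect_equal(nrow(mix$consensus), 1)
  expect_equal(mix$consensus$x_min, 0)  # grader 1's box by convention
  expect_equal(nrow(mix$disputed), 2)
})

test_that("calcium events obey the prominence and height thresholds", {
  expect_equal(nrow(detect_events(rep(0, 60))), 0)

  # amplitude-20 transient over zero baseline -> exactly one event at peak
  tr <- 20 * somatrace:::geci_kernel(((0:99) - 30) / 10, 0.1, 1)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$frame - (30 + 3)), 8)  # near the kernel peak

  # amplitude 2 < min_height 3 -> no events
  expect_equal(nrow(detect_events(2 * somatrace:::geci_kernel(
    ((0:99) - 30) / 10, 0.1, 1))), 0)

  expect_error(detect_events(rep(0, 5)), "shorter")

  # leading missing values are skipped and offset back
  tr2 <- c(rep(NA, 10), tr)
  ev2 <- detect_events(tr2)
  expect_equal(ev2$frame, ev$frame + 10)
})

test_that("SNR is mean over population standard deviation", {
  expect_equal(snr(c(1, 3)), 2)
  set.seed(13)
  v <- rnorm(500, mean = 10, sd = 2)
  expect_equal(snr(5 * v), snr(v), tolerance = 1e-12)  # scale invariance
  # two-pass oracle
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / length(v))
  expect_equal(snr(v), m / s, tolerance = 1e-12)
  expect_error(snr(rep(1, 5)), "zero standard deviation")
  expect_error(snr(1), "at least 2")
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(14)
  x <- rnorm(200)
  m <- cbind(x, -x, rnorm(200))
  cc <- correlation_matrix(m)
  expect_equal(diag(cc), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cc[1, 2], -1)
  expect_equal(cc, t(cc))

  # independent noise decorrelates at length 1e4
  big <- cbind(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(correlation_matrix(big)[1, 2]), 0.1)

  # constant trace -> missing row/column with a warning
  expect_warning(cc2 <- correlation_matrix(cbind(x, rep(1, 200))), "constant")
  expect_true(all(is.na(cc2[2, ])))
})

test_that("dendrogram sorting keeps correlated blocks contiguous", {
  expect_setequal(dendrogram_order(diag(2)), 1:2)

  # two blocks of 5 at r = 0.9 within, 0 across
  blk <- matrix(0, 10, 10)
  blk[1:5, 1:5] <- 0.9; blk[6:10, 6:10] <- 0.9
  diag(blk) <- 1
  ord <- dendrogram_order(blk)
  pos <- match(1:10, ord)
  expect_lt(max(abs(diff(sort(pos[1:5])))), 2)  # block 1 contiguous
  expect_lt(max(abs(diff(sort(pos[6:10])))), 2) # block 2 contiguous

  # permuting rows permutes the clustering consistently
  set.seed(15)
  p <- sample(10)
  ord_p <- dendrogram_order(blk[p, p])
  groups <- function(o, labels) {
    first_five <- labels[o[1:5]]
    sort(first_five)
  }
  expect_true(identical(groups(ord_p, p), 1:5) ||
                identical(groups(ord_p, p), 6:10))
})

test_that("gaussian smoothing preserves mass and matches direct convolution", {
  expect_equal(gaussian_smooth(rep(4, 30)), rep(4, 30), tolerance = 1e-12)

  imp <- c(rep(0, 20), 1, rep(0, 20))
  sm <- gaussian_smooth(imp, 1)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  k <- dnorm(-4:4); k <- k / sum(k)
  expect_equal(sm[17:25], k, tolerance = 1e-12)

  # direct-convolution oracle in the interior
  set.seed(16)
  x <- rnorm(50)
  smx <- gaussian_smooth(x, 1)
  for (i in 10:40) {
    expect_equal(smx[i], sum(x[(i - 4):(i + 4)] * k), tolerance = 1e-12)
  }
})

test_that("online F-1 curves are defined per emission in [0, 1]", {
  r <- small_render(n_cells = 4, fov = 64, n_frames = 20, seed = 45)
  mock <- gt_detector(r$gt_boxes)
  cfg <- pipeline_config(mode = "step", n_frames = 5, detector = "custom",
                         custom_detector = mock)
  res <- run_online(r$stack, cfg)
  curve <- evaluate_online_run(res$emissions, r$gt_boxes, total_frames = 20)
  expect_equal(nrow(curve), 4)
  expect_true(all(curve$f1 >= 0 & curve$f1 <= 1))
  # perfect detector on a static movie: constantly 1 after first emission
  expect_true(all(curve$f1 == 1))
  expect_true(all(curve$fraction <= 1))
})

test_that("conventional average precision is 1 for a perfect ranking", {
  gt <- random_boxes(6, fov = c(50, 50))
  pred <- gt; pred$score <- seq(0.9, 0.4, length.out = 6)
  expect_equal(detection_ap(pred, gt), 1)
  expect_equal(detection_ap(empty_boxes(), gt), 0)
})
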