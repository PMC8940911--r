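# Shared fixtures and independent brute-force oracles.

# A small rendered scene used across modules.
small_render <- function(n_cells = 4, fov = 64, n_frames = 30, seed = 3,
                         noise_sigma = 0, neuropil = 0, spike_rate = 0.2,
                         ...) {
  sc <- generate_scene(scene_config(fov_shape = c(fov, fov),
                                    n_cells = n_cells, n_frames = n_frames,
                                    noise_sigma = noise_sigma,
                                    neuropil_amplitude = neuropil,
                                    spike_rate = spike_rate, ...),
                       seed = seed)
  c(render_movie(sc), list(scene = sc))
}

# Random valid boxes inside a fov.
random_boxes <- function(n, fov = c(100, 100), max_side = 20) {
  x0 <- runif(n, 0, fov[2] - 2)
  y0 <- runif(n, 0, fov[1] - 2)
  w <- runif(n, 1, pmin(max_side, fov[2] - x0))
  h <- runif(n, 1, pmin(max_side, fov[1] - y0))
  bbox(x0, y0, x0 + w, y0 + h, score = runif(n))
}

# Exhaustive O(n^2) non-maximum suppression oracle.
nms_oracle <- function(boxes, threshold = 0.2) {
  ord <- order(-boxes$score, boxes$y_min, boxes$x_min)
  b <- boxes[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(b))
  for (i in seq_len(nrow(b))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(b))) {
      if (j != i && keep[j] && j > i) {
        ov <- sum_area_overlap(b[i, , drop = FALSE], b[j, , drop = FALSE])
        if (ov > threshold) keep[j] <- FALSE
      }
    }
  }
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force greedy matching oracle: repeatedly take the best remaining
# (pred, gt) pair above the cutoff.
match_oracle <- function(pred, gt, cutoff = 0.5) {
  used_p <- logical(nrow(pred)); used_g <- logical(nrow(gt))
  tp <- 0L
  repeat {
    best <- 0; bi <- 0; bj <- 0
    for (i in which(!used_p)) {
      for (j in which(!used_g)) {
        ov <- pair_min_overlap(pred[i, , drop = FALSE], gt[j, , drop = FALSE])
        if (ov > cutoff && ov > best) { best <- ov; bi <- i; bj <- j }
      }
    }
    if (bi == 0) break
    used_p[bi] <- TRUE; used_g[bj] <- TRUE; tp <- tp + 1L
  }
  list(tp = tp, fp = nrow(pred) - tp, fn = nrow(gt) - tp)
}

pair_min_overlap <- function(a, b) {
  w <- max(0, min(a$x_max, b$x_max) - max(a$x_min, b$x_min))
  h <- max(0, min(a$y_max, b$y_max) - max(a$y_min, b$y_min))
  (w * h) / min(box_area(a), box_area(b))
}

# Masked-statistics oracle for percentile segmentation: sort-based, via the
# same interpolation definition written out explicitly.
segment_oracle <- function(vals, p_low = 80, p_high = 95) {
  v <- sort(as.numeric(vals))
  n <- length(v)
  interp_q <- function(p) {
    hpos <- (n - 1) * p / 100 + 1
    lo <- floor(hpos)
    hi <- ceiling(hpos)
    v[lo] + (hpos - lo) * (v[hi] - v[lo])
  }
  q1 <- interp_q(p_low); q2 <- interp_q(p_high)
  sel <- as.numeric(vals)[as.numeric(vals) >= q1 & as.numeric(vals) <= q2]
  list(q = c(q1, q2), mean = mean(sel), n_sel = length(sel))
}

# Mean of pixels outside all boxes, by explicit per-pixel loop.
bg_oracle <- function(frame, boxes) {
  total <- 0; n <- 0
  for (r in seq_len(nrow(frame))) {
    for (cc in seq_len(ncol(frame))) {
      x <- cc - 1; y <- r - 1
      inside <- FALSE
      for (b in seq_len(nrow(boxes))) {
        if (x >= floor(boxes$x_min[b]) && x < ceiling(boxes$x_max[b]) &&
            y >= floor(boxes$y_min[b]) && y < ceiling(boxes$y_max[b])) {
          inside <- TRUE
          break
        }
      }
      if (!inside) { total <- total + frame[r, cc]; n <- n + 1 }
    }
  }
  total / n
}

# A deterministic mock detector that reports a fixed box table regardless of
# the input (used for interface-contract and grid-cardinality tests).
fixed_detector <- function(boxes) {
  force(boxes)
  soma_detector(function(input) boxes, name = "mock-fixed")
}

# A perfect detector that scales the scene's ground truth to the detector
# input frame (for tracking tests decoupled from the blob detector).
gt_detector <- function(gt) {
  force(gt)
  soma_detector(function(input) {
    b <- gt
    u <- input$upscale_factor
    for (col in c("x_min", "y_min", "x_max", "y_max")) b[[col]] <- b[[col]] * u
    b$score <- rep(1, nrow(b))
    b
  }, name = "mock-gt")
}
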