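#' Create a pluggable soma detector
#'
#' A detector is any object exposing `detect(input)` that maps a
#' `detector_input` (see [prepare_detector_input()]) to a scored box table in
#' the input's coordinate frame, with scores in `[0, 1]`. Detectors are
#' interchangeable throughout the pipeline.
#'
#' @param detect function of one `detector_input` argument returning a box
#'   `data.frame`.
#' @param name,version descriptor strings.
#' @return a `soma_detector`.
#' @export
soma_detector <- function(detect, name = "custom", version = "0") {
  stopifnot(is.function(detect))
  structure(list(detect = detect, name = name, version = version),
            class = "soma_detector")
}

#' The reference blob detector
#'
#' A classical multiscale Laplacian-of-Gaussian blob detector serving as the
#' library's built-in detector: the first channel of the 8-bit input is
#' filtered with scale-normalised LoG kernels across `scale_range`, local
#' maxima of the (sign-flipped, so bright blobs score positive) response
#' over space and scale above `response_floor` become detections, each with
#' a box of side `2 * sqrt(2) * sigma` centred on the peak. Scores are the
#' responses normalised to `[0, 1]` by the strongest response in the image.
#'
#' @param scale_range vector of Gaussian scales (sigma, pixels) to probe.
#' @param response_floor minimum scale-normalised response (on intensities
#'   normalised to `[0, 1]`) for a peak to count.
#' @return a [soma_detector()].
#' @export
reference_blob_detector <- function(scale_range = seq(2.5, 8, by = 1.1),
                                    response_floor = 0.02) {
  detect <- function(input) {
    stopifnot(inherits(input, "detector_input"))
    img <- input$image[, , 1] / 255
    h <- nrow(img); w <- ncol(img)
    ns <- length(scale_range)
    resp <- array(0, c(h, w, ns))
    for (k in seq_len(ns)) {
      resp[, , k] <- -log_filter(img, scale_range[k])
    }
    peaks <- local_maxima_3d(resp, floor = response_floor)
    if (nrow(peaks) == 0L) return(empty_boxes())
    top <- max(peaks$value)
    half <- sqrt(2) * scale_range[peaks$scale]
    b <- data.frame(x_min = peaks$col - 0.5 - half,
                    y_min = peaks$row - 0.5 - half,
                    x_max = peaks$col - 0.5 + half,
                    y_max = peaks$row - 0.5 + half,
                    score = pmin(peaks$value / top, 1),
                    identity = NA_integer_)
    clip_boxes(b, c(h, w))
  }
  soma_detector(detect, name = "reference-log", version = "1")
}

# Scale-normalised Laplacian-of-Gaussian response (sigma^2 * LoG * image),
# replicate border handling.
log_filter <- function(img, sigma) {
  half <- max(2L, ceiling(3 * sigma))
  # the kernel cannot exceed the image (small tiles, strong downscaling)
  max_half <- (min(dim(img)) - 1L) %/% 2L
  if (max_half < 2L) return(matrix(0, nrow(img), ncol(img)))
  half <- min(half, max_half)
  ax <- (-half):half
  g2 <- outer(ax^2, ax^2, `+`)
  k <- exp(-g2 / (2 * sigma^2))
  k <- k / sum(k)
  log_k <- k * (g2 - 2 * sigma^2) / sigma^4
  log_k <- log_k - mean(log_k)  # zero response to constant images
  sigma^2 * EBImage::filter2(img, log_k, boundary = "replicate")
}

# Local maxima of a (H, W, S) response volume: strictly greater than the 8
# spatial neighbours at the same scale and >= the same pixel at adjacent
# scales, value >= floor. Border pixels are excluded spatially.
local_maxima_3d <- function(resp, floor) {
  d <- dim(resp)
  out <- list()
  for (k in seq_len(d[3])) {
    r <- resp[, , k]
    h <- d[1]; w <- d[2]
    if (h < 3 || w < 3) next
    c0 <- r[2:(h - 1), 2:(w - 1)]
    is_max <- c0 >= floor &
      c0 > r[1:(h - 2), 2:(w - 1)] & c0 > r[3:h, 2:(w - 1)] &
      c0 > r[2:(h - 1), 1:(w - 2)] & c0 > r[2:(h - 1), 3:w] &
      c0 > r[1:(h - 2), 1:(w - 2)] & c0 > r[1:(h - 2), 3:w] &
      c0 > r[3:h, 1:(w - 2)] & c0 > r[3:h, 3:w]
    if (k > 1) is_max <- is_max & c0 >= resp[2:(h - 1), 2:(w - 1), k - 1]
    if (k < d[3]) is_max <- is_max & c0 >= resp[2:(h - 1), 2:(w - 1), k + 1]
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx)) {
      out[[length(out) + 1L]] <- data.frame(row = idx[, 1] + 1L,
                                            col = idx[, 2] + 1L,
                                            scale = k, value = c0[is_max])
    }
  }
  if (!length(out)) {
    return(data.frame(row = integer(0), col = integer(0), scale = integer(0),
                      value = numeric(0)))
  }
  do.call(rbind, out)
}

#' Adapter for an externally trained box-regression model
#'
#' Loads a single-class detection model through a generic inference runtime
#' and wraps it as a [soma_detector()]. A missing or unreadable model file is
#' a load error; the rest of the library never depends on a model being
#' present — use [reference_blob_detector()] instead.
#'
#' @param model_path path to the trained model file.
#' @return a [soma_detector()] (on successful load).
#' @export
cnn_adapter <- function(model_path) {
  if (!file.exists(model_path)) {
    stop("model file not found: '", model_path,
         "'. Use detector = \"reference\" (the built-in blob detector) if no ",
         "trained model is available.")
  }
  stop("cannot load '", model_path, "': no compatible inference runtime for ",
       "this model format is available. Use detector = \"reference\" or plug ",
       "in a detector via soma_detector().")
}

# Detector plug-in discovery by config name.
get_detector <- function(config) {
  switch(config$detector,
         reference = reference_blob_detector(
           scale_range = config$scale_range,
           response_floor = config$response_floor),
         cnn = cnn_adapter(config$model_path),
         custom = config$custom_detector,
         stop("unknown detector: ", config$detector))
}

#' Suppress duplicate detections (non-maximum suppression)
#'
#' Greedy NMS by descending score using the sum-of-areas overlap
#' ([sum_area_overlap()] by default): the highest-scoring box is retained and
#' every box overlapping it above `overlap_threshold` is discarded. Score
#' ties are broken toward smaller `(y_min, x_min)` so the result is
#' deterministic.
#'
#' @param boxes scored box `data.frame`.
#' @param overlap_threshold boxes overlapping a kept box above this are
#'   duplicates (default 0.2).
#' @param method overlap measure: `"sum"` (default) or `"iou"`.
#' @return the surviving boxes; no surviving pair overlaps above threshold.
#' @export
suppress_duplicates <- function(boxes, overlap_threshold = 0.2,
                                method = c("sum", "iou")) {
  method <- match.arg(method)
  if (nrow(boxes) <= 1L) return(boxes)
  ord <- order(-boxes$score, boxes$y_min, boxes$x_min)
  b <- boxes[ord, , drop = FALSE]
  keep <- logical(nrow(b))
  alive <- rep(TRUE, nrow(b))
  ov <- overlap_matrix(b, b, method = method)
  for (i in seq_len(nrow(b))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    dup <- ov[i, ] > overlap_threshold
    dup[i] <- FALSE
    alive[dup] <- FALSE
  }
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' A set of filtered, duplicate-suppressed detections
#'
#' @param boxes box `data.frame`.
#' @param score_threshold the threshold the boxes were filtered at.
#' @param frame 0-based frame index of the detector input (`NA` for a
#'   projection image).
#' @return a `detection_set`.
#' @export
detection_set <- function(boxes, score_threshold = 0, frame = NA_integer_) {
  structure(list(boxes = boxes, score_threshold = score_threshold,
                 frame = frame),
            class = "detection_set")
}

#' Run a detector on an image and return cleaned native-scale boxes
#'
#' Prepares the detector input at `upscale_factor`, runs the detector, maps
#' boxes back to native pixels (divide by the factor, round half-up), drops
#' boxes below `score_threshold`, and suppresses duplicates at
#' `nms_threshold`.
#'
#' @param image `H x W` matrix.
#' @param detector a [soma_detector()].
#' @param upscale_factor spatial upscaling before detection.
#' @param score_threshold minimum score retained.
#' @param nms_threshold duplicate-suppression overlap threshold.
#' @param frame 0-based frame index recorded in the result.
#' @return a [detection_set()].
#' @export
detect_image <- function(image, detector, upscale_factor = 1,
                         score_threshold = 0, nms_threshold = 0.2,
                         frame = NA_integer_) {
  input <- prepare_detector_input(image, upscale_factor)
  boxes <- detector$detect(input)
  boxes <- boxes_to_native(boxes, upscale_factor, dim(image))
  boxes <- boxes[boxes$score >= score_threshold, , drop = FALSE]
  boxes <- suppress_duplicates(boxes, overlap_threshold = nms_threshold)
  detection_set(boxes, score_threshold = score_threshold, frame = frame)
}

# Map detector-frame boxes back to native pixels: divide by the upscale
# factor and round half-up (the single place scale conversion happens).
boxes_to_native <- function(boxes, upscale_factor, native_shape) {
  if (nrow(boxes) == 0L || upscale_factor == 1) {
    return(clip_boxes(boxes, native_shape))
  }
  for (col in c("x_min", "y_min", "x_max", "y_max")) {
    boxes[[col]] <- round_half_up(boxes[[col]] / upscale_factor)
  }
  boxes <- boxes[boxes$x_max > boxes$x_min & boxes$y_max > boxes$y_min, ,
                 drop = FALSE]
  clip_boxes(boxes, native_shape)
}

#' Plan a tiling of a large field of view
#'
#' Tiles are laid out at stride `tile_size - overlap` from offset 0; when the
#' strided grid leaves uncovered pixels on an axis, a final tile anchored at
#' `dim - tile_size` is appended, so the union of tiles always covers the
#' field of view.
#'
#' @param fov_shape `c(H, W)` in pixels.
#' @param tile_size square tile side (default 128).
#' @param overlap tile overlap in pixels (default 28; must be < `tile_size`).
#' @param batch_size tiles per detector batch (a throughput hint; results
#'   are independent of batching).
#' @return a `tiling_plan` with the per-axis offsets and the full offset
#'   grid.
#' @export
plan_tiles <- function(fov_shape, tile_size = 128, overlap = 28,
                       batch_size = 8) {
  stopifnot(overlap < tile_size, batch_size >= 1)
  if (tile_size > min(fov_shape)) {
    stop("tile_size ", tile_size, " exceeds the field of view ",
         fov_shape[1], "x", fov_shape[2])
  }
  axis_offsets <- function(len) {
    stride <- tile_size - overlap
    offs <- seq(0L, len - tile_size, by = stride)
    if (max(offs) + tile_size < len) offs <- c(offs, len - tile_size)
    as.integer(offs)
  }
  rows <- axis_offsets(fov_shape[1])
  cols <- axis_offsets(fov_shape[2])
  grid <- expand.grid(row = rows, col = cols, KEEP.OUT.ATTRS = FALSE)
  structure(list(tile_size = as.integer(tile_size),
                 overlap = as.integer(overlap),
                 row_offsets = rows, col_offsets = cols,
                 offsets = grid, batch_size = as.integer(batch_size),
                 fov_shape = fov_shape),
            class = "tiling_plan")
}

#' Tiled detection over a large field of view
#'
#' Runs the detector on each tile (in batches of `plan$batch_size`),
#' translates the per-tile boxes back to field-of-view coordinates, then
#' score-filters and suppresses duplicates over the merged set, removing the
#' double detections that arise in tile-overlap regions.
#'
#' @param image full-field `H x W` matrix.
#' @param detector a [soma_detector()].
#' @param plan a [plan_tiles()] result.
#' @param score_threshold minimum score retained.
#' @param upscale_factor per-tile upscaling before detection.
#' @param nms_threshold duplicate-suppression overlap threshold.
#' @return a [detection_set()] over the full field of view.
#' @export
detect_tiled <- function(image, detector, plan, score_threshold = 0,
                         upscale_factor = 1, nms_threshold = 0.2) {
  stopifnot(inherits(plan, "tiling_plan"),
            all(dim(image) == plan$fov_shape))
  n_tiles <- nrow(plan$offsets)
  pieces <- vector("list", n_tiles)
  for (start in seq(1L, n_tiles, by = plan$batch_size)) {
    batch <- start:min(start + plan$batch_size - 1L, n_tiles)
    for (i in batch) {
      ro <- plan$offsets$row[i]; co <- plan$offsets$col[i]
      tile <- image[(ro + 1):(ro + plan$tile_size),
                    (co + 1):(co + plan$tile_size), drop = FALSE]
      input <- prepare_detector_input(tile, upscale_factor)
      b <- boxes_to_native(detector$detect(input), upscale_factor,
                           c(plan$tile_size, plan$tile_size))
      if (nrow(b)) {
        b$x_min <- b$x_min + co; b$x_max <- b$x_max + co
        b$y_min <- b$y_min + ro; b$y_max <- b$y_max + ro
      }
      pieces[[i]] <- b
    }
  }
  merged <- do.call(rbind, c(list(empty_boxes()), pieces))
  merged <- merged[merged$score >= score_threshold, , drop = FALSE]
  merged <- suppress_duplicates(merged, overlap_threshold = nms_threshold)
  detection_set(merged, score_threshold = score_threshold)
}

#' Offline grid search over upscaling factor and score threshold
#'
#' Evaluates the offline detection F-1 against ground truth at every point
#' of the `upscale x threshold` grid (the detector runs once per upscaling
#' factor; thresholding and duplicate suppression are replayed per
#' threshold). Ties are broken toward smaller upscale, then higher
#' threshold.
#'
#' @param stack a [movie_stack()].
#' @param gt ground-truth box table.
#' @param detector a [soma_detector()].
#' @param upscale_grid upscaling factors (default 0.6 to 3.4, step 0.2).
#' @param threshold_grid score thresholds (default 0.05 to 0.95, step 0.05).
#' @param nms_threshold duplicate-suppression threshold.
#' @return list with `best_upscale`, `best_threshold`, `best_f1`, and the
#'   full `surface` data frame (`upscale`, `threshold`, `f1`).
#' @export
grid_search_offline <- function(stack, gt, detector,
                                upscale_grid = seq(0.6, 3.4, by = 0.2),
                                threshold_grid = seq(0.05, 0.95, by = 0.05),
                                nms_threshold = 0.2) {
  med <- median_projection(stack)
  surface <- expand.grid(upscale = upscale_grid, threshold = threshold_grid,
                         KEEP.OUT.ATTRS = FALSE)
  surface$f1 <- NA_real_
  for (u in upscale_grid) {
    input <- prepare_detector_input(med, u)
    raw <- boxes_to_native(detector$detect(input), u, dim(med))
    for (th in threshold_grid) {
      b <- raw[raw$score >= th, , drop = FALSE]
      b <- suppress_duplicates(b, overlap_threshold = nms_threshold)
      m <- match_detections(b, gt)
      surface$f1[surface$upscale == u & surface$threshold == th] <- m$f1
    }
  }
  pick_best(surface, "upscale")
}

#' Online grid search over frame-downsampling and score threshold
#'
#' For each buffer length `n`, the online detection loop (buffer ->
#' detector -> duplicate suppression -> identity tracking) is replayed over
#' the movie; detector outputs are cached per emission so each score
#' threshold reuses them. The F-1 of the final tracked identities against
#' ground truth is recorded at every `(n, threshold)` grid point.
#'
#' @param stack a [movie_stack()].
#' @param gt ground-truth box table.
#' @param detector a [soma_detector()].
#' @param n_grid buffer lengths to evaluate.
#' @param threshold_grid score thresholds to evaluate.
#' @param mode `"sliding"` or `"step"` averaging.
#' @param upscale_factor upscaling applied to each emitted average.
#' @param new_id_threshold tracker new-identity threshold.
#' @param nms_threshold duplicate-suppression threshold.
#' @return as [grid_search_offline()], with `best_n` instead of
#'   `best_upscale`.
#' @export
grid_search_online <- function(stack, gt, detector, n_grid = c(1, 5, 10, 20),
                               threshold_grid = seq(0.05, 0.95, by = 0.05),
                               mode = "sliding", upscale_factor = 1,
                               new_id_threshold = 0.2, nms_threshold = 0.2) {
  tt <- n_frames(stack)
  shape <- fov_shape(stack)
  surface <- expand.grid(n = n_grid, threshold = threshold_grid,
                         KEEP.OUT.ATTRS = FALSE)
  surface$f1 <- NA_real_
  for (n in n_grid) {
    buf <- average_buffer(mode = mode, n = n)
    raw_by_emission <- list()
    for (t in seq_len(tt)) {
      avg <- push_frame(buf, stack$frames[, , t])
      if (!is.null(avg)) {
        input <- prepare_detector_input(avg, upscale_factor)
        raw_by_emission[[length(raw_by_emission) + 1L]] <-
          boxes_to_native(detector$detect(input), upscale_factor, shape)
      }
    }
    for (th in threshold_grid) {
      reg <- identity_registry()
      for (raw in raw_by_emission) {
        b <- raw[raw$score >= th, , drop = FALSE]
        b <- suppress_duplicates(b, overlap_threshold = nms_threshold)
        reg <- update_tracks(reg, detection_set(b, th),
                             new_id_threshold = new_id_threshold,
                             fov_shape = shape)
      }
      final <- registry_boxes(reg)
      m <- match_detections(final, gt)
      surface$f1[surface$n == n & surface$threshold == th] <- m$f1
    }
  }
  pick_best(surface, "n")
}

# Argmax over an F-1 surface; ties toward smaller first parameter, then
# higher threshold.
pick_best <- function(surface, param) {
  ord <- order(-surface$f1, surface[[param]], -surface$threshold)
  best <- surface[ord[1], ]
  out <- list(best_threshold = best$threshold, best_f1 = best$f1,
              surface = surface)
  out[[paste0("best_", param)]] <- best[[param]]
  out
}
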