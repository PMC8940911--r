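#' Construct a trace set
#'
#' Per-identity background-subtracted fluorescence series aligned to a
#' common frame axis, plus the per-frame global background trace. Entries
#' before an identity's first detection are missing (`NA`) by construction.
#'
#' @param traces `T x n` matrix, one column per identity.
#' @param bg length-`T` background series.
#' @param ids integer identity labels (one per column).
#' @param frame_rate frames per second.
#' @param raw optional `T x n` matrix of soma means before background
#'   subtraction (kept for correlation diagnostics).
#' @return a `trace_set`.
#' @export
trace_set <- function(traces, bg, ids = seq_len(ncol(traces)) - 1L,
                      frame_rate = 30, raw = NULL) {
  traces <- as.matrix(traces)
  stopifnot(nrow(traces) == length(bg) || ncol(traces) == 0L,
            ncol(traces) == length(ids))
  structure(list(traces = traces, bg = as.numeric(bg),
                 ids = as.integer(ids), frame_rate = frame_rate, raw = raw),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d identities x %d frames (%.3g Hz)\n",
              ncol(x$traces), length(x$bg), x$frame_rate))
  invisible(x)
}

#' First frame at which each identity has a value
#' @param traces a [trace_set()].
#' @return integer vector of 0-based first-valid frame indices (`NA` for
#'   all-missing columns).
#' @export
first_valid_frame <- function(traces) {
  apply(traces$traces, 2, function(v) {
    i <- which(!is.na(v))
    if (length(i)) i[1] - 1L else NA_integer_
  })
}

#' Dynamic percentile segmentation of one box in one frame
#'
#' Percentiles are computed on the intensity distribution of the pixels
#' inside the box *for this frame* (linear interpolation between order
#' statistics); the mask selects pixels with values in the closed interval
#' `[P_low, P_high]` and the soma mean is the arithmetic mean of the masked
#' values. The mask is intended to be recomputed for every new frame.
#'
#' @param frame `H x W` matrix.
#' @param box single-row box `data.frame` (clipped to the frame internally).
#' @param p_low,p_high percentile band (defaults 80 and 95).
#' @return list with `mask` (logical matrix over the clipped box), `rows`,
#'   `cols` (1-based pixel indices), and `soma_mean`.
#' @export
segment_box <- function(frame, box, p_low = 80, p_high = 95) {
  shape <- dim(frame)
  cb <- clip_boxes(box, shape)
  if (nrow(cb) == 0L) stop("box is empty after clipping to the frame")
  px <- box_pixel_range(cb, shape)
  vals <- frame[px$rows, px$cols, drop = FALSE]
  q <- stats::quantile(vals, c(p_low, p_high) / 100, type = 7, names = FALSE)
  mask <- vals >= q[1] & vals <= q[2]
  if (!any(mask)) {
    # interpolated band can fall strictly between two observed values in
    # tiny boxes; fall back to the value(s) nearest the band midpoint
    mid <- mean(q)
    mask <- abs(vals - mid) == min(abs(vals - mid))
  }
  list(mask = mask, rows = px$rows, cols = px$cols,
       soma_mean = mean(vals[mask]))
}

#' Global background of one frame
#'
#' Arithmetic mean of all pixels outside the union of the current bounding
#' boxes. Because boxes change across frames, the set of background pixels
#' changes in number and identity too; the value must be recomputed per
#' frame.
#'
#' @param frame `H x W` matrix.
#' @param boxes current box table (may be empty: the mean of the whole
#'   frame is returned).
#' @return background fluorescence (a.u.).
#' @export
global_background <- function(frame, boxes) {
  shape <- dim(frame)
  mask <- matrix(TRUE, shape[1], shape[2])
  if (nrow(boxes)) {
    cb <- clip_boxes(boxes, shape)
    for (i in seq_len(nrow(cb))) {
      px <- box_pixel_range(cb[i, , drop = FALSE], shape)
      mask[px$rows, px$cols] <- FALSE
    }
  }
  if (!any(mask)) stop("bounding boxes cover the entire field of view: ",
                       "no background pixels left")
  mean(frame[mask])
}

#' Local background around one box
#'
#' Mean of the pixels inside a concentric box of doubled side lengths,
#' excluding the cell's own box and any pixel inside another bounding box;
#' the doubled box is clipped to the field of view. Retained as an analysis
#' utility — the main extraction path uses [global_background()].
#'
#' @param frame `H x W` matrix.
#' @param box the cell's single-row box.
#' @param all_boxes all current boxes (the cell's own row may be included).
#' @return local background value, or `NA` (with a warning) when no
#'   eligible pixel remains.
#' @export
local_background <- function(frame, box, all_boxes = box) {
  shape <- dim(frame)
  cx <- (box$x_min + box$x_max) / 2; cy <- (box$y_min + box$y_max) / 2
  w <- box$x_max - box$x_min; h <- box$y_max - box$y_min
  big <- bbox(cx - w, cy - h, cx + w, cy + h)
  big <- clip_boxes(big, shape)
  px <- box_pixel_range(big, shape)
  mask <- matrix(TRUE, length(px$rows), length(px$cols))
  exclude <- rbind(box[, names(empty_boxes())],
                   all_boxes[, names(empty_boxes())])
  cbx <- clip_boxes(exclude, shape)
  for (i in seq_len(nrow(cbx))) {
    er <- box_pixel_range(cbx[i, , drop = FALSE], shape)
    mask[px$rows %in% er$rows, px$cols %in% er$cols] <- FALSE
  }
  if (!any(mask)) {
    warning("no eligible pixels for local background of box at (",
            box$x_min, ", ", box$y_min, ")")
    return(NA_real_)
  }
  vals <- frame[px$rows, px$cols, drop = FALSE]
  mean(vals[mask])
}

# Extract one frame for a set of identity boxes. Returns list(bg, raw
# named by identity). Per-identity segmentation errors become NA values
# without aborting the frame.
extract_frame_values <- function(frame, boxes, p_low, p_high) {
  bg <- global_background(frame, boxes)
  raw <- numeric(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    raw[i] <- tryCatch(
      segment_box(frame, boxes[i, , drop = FALSE], p_low, p_high)$soma_mean,
      error = function(e) {
        warning("identity ", boxes$identity[i], ": ", conditionMessage(e))
        NA_real_
      })
  }
  list(bg = bg, raw = raw, ids = boxes$identity)
}

#' Extract traces for the current frame
#'
#' Appends one frame of background-subtracted values to a trace set: for
#' every identity in the registry (active and, by default, inactive ones at
#' their last rigid-shifted box) the value is the percentile-segmented soma
#' mean minus the global background of this frame.
#'
#' @param frame `H x W` matrix.
#' @param registry an [identity_registry()].
#' @param traces a [trace_set()] (may have fewer columns than the registry
#'   has identities; new columns are added, back-filled with `NA`).
#' @param p_low,p_high percentile band.
#' @param extract_inactive also extract identities not actively detected.
#' @return the extended [trace_set()].
#' @export
extract_frame <- function(frame, registry, traces, p_low = 80, p_high = 95,
                          extract_inactive = TRUE) {
  boxes <- registry_boxes(registry, active_only = !extract_inactive)
  append_extraction(traces, frame, boxes,
                    list(p_low = p_low, p_high = p_high))
}

#' Run the online pipeline over a movie
#'
#' Sequentially replays the streaming loop: each frame is pushed into the
#' averaging buffer; whenever the buffer emits, the detector runs on the
#' averaged image, duplicates are suppressed, and identities are updated;
#' every frame — regardless of the detection cadence — is extracted against
#' the identities known at that frame. The output is invariant to how the
#' work is scheduled: `scheduler = "interleaved"` defers extraction to chunk
#' boundaries using per-frame registry snapshots and must produce an
#' identical result to the sequential reference.
#'
#' @param stack a [movie_stack()] (the frame source, replayed in order).
#' @param config a [pipeline_config()].
#' @param scheduler `"sequential"` or `"interleaved"` (a scheduling-
#'   invariance contract, not a performance knob).
#' @param chunk_size frames per chunk for the interleaved scheduler.
#' @return list with `traces` ([trace_set()]), `registry`
#'   ([identity_registry()]), `emissions` (per-emission [detection_set()]s),
#'   and `log` (per-stage event records).
#' @export
run_online <- function(stack, config = pipeline_config(),
                       scheduler = c("sequential", "interleaved"),
                       chunk_size = 16L) {
  stopifnot(inherits(stack, "movie_stack"))
  scheduler <- match.arg(scheduler)
  config <- resolve_config(config, stack)
  detector <- get_detector(config)
  shape <- fov_shape(stack)
  tt <- n_frames(stack)
  buf <- average_buffer(mode = config$mode, n = config$n_frames)
  registry <- identity_registry()
  traces <- trace_set(matrix(NA_real_, 0, 0), bg = numeric(0),
                      ids = integer(0), frame_rate = stack$frame_rate)
  emissions <- list()
  log <- list()
  snapshots <- vector("list", tt)
  t0 <- proc.time()[3]
  for (t in seq_len(tt)) {
    frame <- stack$frames[, , t]
    avg <- push_frame(buf, frame)
    if (!is.null(avg)) {
      det <- detect_image(avg, detector,
                          upscale_factor = config$upscale_factor,
                          score_threshold = config$score_threshold,
                          nms_threshold = config$nms_threshold,
                          frame = t - 1L)
      registry <- update_tracks(registry, det,
                                new_id_threshold = config$new_id_threshold,
                                matching = config$matching,
                                frame = t - 1L, fov_shape = shape)
      emissions[[length(emissions) + 1L]] <- det
      log[[length(log) + 1L]] <- list(stage = "detect", frame = t - 1L,
                                      wall_s = unname(proc.time()[3] - t0),
                                      count = nrow(det$boxes))
    }
    snapshots[[t]] <- registry_boxes(registry,
                                     active_only = !config$extract_inactive)
    if (scheduler == "sequential") {
      traces <- append_extraction(traces, frame, snapshots[[t]], config)
    }
  }
  if (scheduler == "interleaved") {
    for (start in seq(1L, tt, by = chunk_size)) {
      for (t in start:min(start + chunk_size - 1L, tt)) {
        traces <- append_extraction(traces, stack$frames[, , t],
                                    snapshots[[t]], config)
      }
    }
  }
  log[[length(log) + 1L]] <- list(stage = "done", frame = tt - 1L,
                                  wall_s = unname(proc.time()[3] - t0),
                                  count = length(registry$identities))
  list(traces = traces, registry = registry, emissions = emissions,
       log = log, config = config)
}

# Shared per-frame extraction step against a box snapshot. Keeps the trace
# and raw matrices at exactly length(bg) rows, adding NA-backfilled columns
# when identities appear.
append_extraction <- function(traces, frame, boxes, config) {
  vals <- extract_frame_values(frame, boxes, config$p_low, config$p_high)
  t_prev <- length(traces$bg)
  if (is.null(traces$raw)) traces$raw <- matrix(NA_real_, t_prev, ncol(traces$traces))
  if (ncol(traces$traces) == 0L) {
    traces$traces <- matrix(NA_real_, t_prev, 0)
    traces$raw <- matrix(NA_real_, t_prev, 0)
  }
  new_ids <- setdiff(vals$ids, traces$ids)
  if (length(new_ids)) {
    add <- matrix(NA_real_, t_prev, length(new_ids))
    traces$traces <- cbind(traces$traces, add)
    traces$raw <- cbind(traces$raw, add)
    traces$ids <- c(traces$ids, as.integer(new_ids))
  }
  n_col <- ncol(traces$traces)
  traces$traces <- rbind(traces$traces, matrix(NA_real_, 1, n_col))
  traces$raw <- rbind(traces$raw, matrix(NA_real_, 1, n_col))
  col <- match(vals$ids, traces$ids)
  if (length(col)) {
    traces$raw[t_prev + 1L, col] <- vals$raw
    traces$traces[t_prev + 1L, col] <- vals$raw - vals$bg
  }
  traces$bg <- c(traces$bg, vals$bg)
  traces
}

#' Run the offline pipeline over a movie
#'
#' Optionally registers the stack, collapses it onto its temporal median,
#' detects once on the prepared projection, and projects the resulting
#' static box set onto every frame, extracting a background-subtracted
#' trace per box per frame.
#'
#' @param stack a [movie_stack()].
#' @param config a [pipeline_config()].
#' @return list with `traces`, `boxes` (the static box set, identities
#'   assigned 0..k-1), `detections` (the single [detection_set()]), and
#'   `shifts` (registration corrections, when registration ran).
#' @export
run_offline <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(stack, "movie_stack"))
  config <- resolve_config(config, stack)
  detector <- get_detector(config)
  shifts <- NULL
  if (isTRUE(config$register)) {
    reg <- rigid_register(stack, max_shift = config$max_shift)
    stack <- reg$stack
    shifts <- reg$shifts
  }
  med <- median_projection(stack)
  det <- detect_image(med, detector, upscale_factor = config$upscale_factor,
                      score_threshold = config$score_threshold,
                      nms_threshold = config$nms_threshold)
  boxes <- det$boxes
  if (nrow(boxes)) boxes$identity <- seq_len(nrow(boxes)) - 1L
  tt <- n_frames(stack)
  n <- nrow(boxes)
  raw <- matrix(NA_real_, tt, n)
  bg <- numeric(tt)
  for (t in seq_len(tt)) {
    vals <- extract_frame_values(stack$frames[, , t], boxes,
                                 config$p_low, config$p_high)
    bg[t] <- vals$bg
    if (n) raw[t, ] <- vals$raw
  }
  traces <- trace_set(if (n) raw - bg else raw, bg = bg, ids = boxes$identity,
                      frame_rate = stack$frame_rate, raw = raw)
  list(traces = traces, boxes = boxes, detections = det, shifts = shifts)
}
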