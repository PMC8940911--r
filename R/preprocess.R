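#' Temporal median projection of a movie
#'
#' @param stack a [movie_stack()] (or `H x W x T` array).
#' @return `H x W` matrix of per-pixel temporal medians.
#' @export
median_projection <- function(stack) {
  f <- if (inherits(stack, "movie_stack")) stack$frames else stack
  stopifnot(length(dim(f)) == 3L)
  if (dim(f)[3] == 1L) return(f[, , 1])
  d <- dim(f)
  matrix(apply(matrix(aperm(f, c(3, 1, 2)), nrow = d[3]), 2, stats::median),
         d[1], d[2])
}

#' Mean projection of a movie
#' @inheritParams median_projection
#' @return `H x W` matrix of per-pixel temporal means.
#' @export
mean_projection <- function(stack) {
  f <- if (inherits(stack, "movie_stack")) stack$frames else stack
  apply(f, c(1, 2), mean)
}

# Phase correlation: displacement (dx, dy) such that img is ref shifted by
# that amount. Optional sub-pixel refinement by parabolic interpolation of
# the correlation peak, quantised to 0.1 px.
phase_correlation <- function(ref, img, subpixel = TRUE) {
  if (stats::sd(ref) == 0 || stats::sd(img) == 0) return(c(0, 0))
  h <- nrow(ref); w <- ncol(ref)
  cp <- stats::fft(ref) * Conj(stats::fft(img))
  m <- Mod(cp)
  r <- Re(stats::fft(cp / (m + 1e-12), inverse = TRUE))
  pk <- arrayInd(which.max(r), dim(r))
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)
  sub_off <- function(vals) {
    den <- vals[1] - 2 * vals[2] + vals[3]
    if (den == 0) 0 else {
      o <- 0.5 * (vals[1] - vals[3]) / den
      max(min(o, 0.5), -0.5)
    }
  }
  dr <- pk[1] - 1; dc <- pk[2] - 1
  if (subpixel) {
    ri <- c((pk[1] - 2) %% h + 1, pk[1], pk[1] %% h + 1)
    ci <- c((pk[2] - 2) %% w + 1, pk[2], pk[2] %% w + 1)
    dr <- dr + sub_off(r[cbind(ri, pk[2])])
    dc <- dc + sub_off(r[cbind(pk[1], ci)])
  }
  d <- c(wrap(dc, w), wrap(dr, h))  # (dx, dy): img displaced by -d rel to ref
  d <- -d
  if (subpixel) round_half_up(d, 1) else round(d)
}

#' Rigid registration of a movie by phase correlation
#'
#' Each frame is aligned to a reference (by default the raw median
#' projection) through Fourier-domain phase correlation. Correction
#' components are clipped to `max_shift` pixels. Sub-pixel corrections are
#' quantised to 0.1 px; set `subpixel = FALSE` for integer shifts.
#'
#' @param stack a [movie_stack()].
#' @param max_shift maximum correction per axis, in pixels.
#' @param subpixel refine the correlation peak to 0.1 px.
#' @param reference optional `H x W` reference image.
#' @return list with the registered `stack` and `shifts`, a `T x 2` matrix of
#'   the `(dx, dy)` corrections applied to each frame.
#' @export
rigid_register <- function(stack, max_shift = 13, subpixel = TRUE,
                           reference = NULL) {
  stopifnot(inherits(stack, "movie_stack"))
  if (is.null(reference)) reference <- median_projection(stack)
  tt <- n_frames(stack)
  shifts <- matrix(0, tt, 2, dimnames = list(NULL, c("dx", "dy")))
  frames <- stack$frames
  for (t in seq_len(tt)) {
    d <- phase_correlation(reference, stack$frames[, , t], subpixel = subpixel)
    corr <- pmax(pmin(-d, max_shift), -max_shift)
    shifts[t, ] <- corr
    if (any(corr != 0)) {
      frames[, , t] <- shift_image(stack$frames[, , t], corr[1], corr[2],
                                   fill = min(stack$frames[, , t]))
    }
  }
  list(stack = movie_stack(frames, frame_rate = stack$frame_rate,
                           pixel_size = stack$pixel_size,
                           bit_depth = stack$bit_depth),
       shifts = shifts)
}

# Reflect-pad a matrix by one pixel on every side.
reflect_pad1 <- function(x) {
  x <- rbind(x[2, ], x, x[nrow(x) - 1, ])
  cbind(x[, 2], x, x[, ncol(x) - 1])
}

#' Enhance a projection image for annotation
#'
#' Builds the high-contrast enhanced projection used for manual labelling:
#' the image is converted to 8-bit, sharpened with the 3x3 kernel
#' `[[-1,-1,-1],[-1,12,-1],[-1,-1,-1]]` (reflect padding), gamma-corrected
#' with exponent 0.3 on `[0, 1]`-normalised intensities, and linearly
#' rescaled to span the full 8-bit range.
#'
#' @param image single-channel matrix.
#' @return 8-bit matrix (integers 0..255). A constant input returns mid-gray
#'   with a warning (degenerate range).
#' @export
enhance_projection <- function(image) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("constant image: returning mid-gray enhanced projection")
    return(matrix(127, nrow(image), ncol(image)))
  }
  img8 <- round((image - rng[1]) / (rng[2] - rng[1]) * 255)
  p <- reflect_pad1(img8)
  h <- nrow(img8); w <- ncol(img8)
  ctr <- p[2:(h + 1), 2:(w + 1)]
  sharp <- 12 * ctr -
    p[1:h, 1:w] - p[1:h, 2:(w + 1)] - p[1:h, 3:(w + 2)] -
    p[2:(h + 1), 1:w] - p[2:(h + 1), 3:(w + 2)] -
    p[3:(h + 2), 1:w] - p[3:(h + 2), 2:(w + 1)] - p[3:(h + 2), 3:(w + 2)]
  sharp <- pmin(pmax(sharp, 0), 255)
  g <- (sharp / 255)^0.3
  rg <- range(g)
  if (rg[1] == rg[2]) {
    warning("degenerate range after sharpening: returning mid-gray")
    return(matrix(127, h, w))
  }
  round((g - rg[1]) / (rg[2] - rg[1]) * 255)
}

#' Create a frame-averaging buffer
#'
#' The buffer implements the two frame-downsampling strategies that feed the
#' detector: `sliding` emits the arithmetic mean of the last `n` frames at
#' every frame once warmed up; `step` emits the mean of each disjoint
#' `n`-frame block, once per block, emptying the buffer after each emission.
#'
#' @param mode `"sliding"` or `"step"`.
#' @param n window/block length in frames (>= 1).
#' @return an `average_buffer` object (mutable; see [push_frame()]).
#' @export
average_buffer <- function(mode = c("sliding", "step"), n = 1) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, n == round(n))
  buf <- new.env(parent = emptyenv())
  buf$mode <- mode
  buf$n <- as.integer(n)
  buf$queue <- list()
  buf$sum <- NULL
  buf$frames_seen <- 0L
  class(buf) <- "average_buffer"
  buf
}

#' Push a frame into an averaging buffer
#'
#' @param buffer an [average_buffer()] (modified in place).
#' @param frame `H x W` matrix; all frames must share one shape.
#' @return the averaged image when the buffer emits, otherwise `NULL`.
#' @export
push_frame <- function(buffer, frame) {
  stopifnot(inherits(buffer, "average_buffer"), is.matrix(frame))
  if (is.null(buffer$sum)) {
    buffer$sum <- matrix(0, nrow(frame), ncol(frame))
  } else if (!all(dim(frame) == dim(buffer$sum))) {
    stop("frame shape changed mid-stream: got ", nrow(frame), "x", ncol(frame))
  }
  buffer$frames_seen <- buffer$frames_seen + 1L
  # running sum with add/subtract update; equals the brute-force window mean
  buffer$sum <- buffer$sum + frame
  buffer$queue[[length(buffer$queue) + 1L]] <- frame
  if (buffer$mode == "sliding") {
    if (length(buffer$queue) > buffer$n) {
      buffer$sum <- buffer$sum - buffer$queue[[1]]
      buffer$queue[[1]] <- NULL
    }
    if (buffer$frames_seen >= buffer$n) return(buffer$sum / buffer$n)
    return(invisible(NULL))
  }
  if (length(buffer$queue) == buffer$n) {
    out <- buffer$sum / buffer$n
    buffer$queue <- list()
    buffer$sum <- buffer$sum * 0
    return(out)
  }
  invisible(NULL)
}

#' Initial detection lag of an averaging buffer
#'
#' The first detector input is available only after `n` frames have been
#' acquired, i.e. after `n / frame_rate` seconds.
#'
#' @param n frames in the first window/block.
#' @param frame_rate acquisition rate in Hz.
#' @return lag in seconds.
#' @export
buffer_lag <- function(n, frame_rate) {
  stopifnot(n >= 1, frame_rate > 0)
  n / frame_rate
}

#' Prepare an image for the detector
#'
#' Linearly rescales intensities to 8-bit using the image's own range,
#' upscales spatially by `upscale_factor` with bilinear interpolation
#' (preserving aspect ratio), and replicates the result into three identical
#' channels.
#'
#' @param image `H x W` matrix.
#' @param upscale_factor spatial scale ratio (> 0).
#' @return a `detector_input`: list with `image` (`H' x W' x 3` 8-bit array),
#'   `upscale_factor`, and `original_shape`.
#' @export
prepare_detector_input <- function(image, upscale_factor = 1) {
  stopifnot(is.matrix(image), upscale_factor > 0)
  rng <- range(image)
  img8 <- if (rng[1] == rng[2]) {
    matrix(0, nrow(image), ncol(image))
  } else {
    round((image - rng[1]) / (rng[2] - rng[1]) * 255)
  }
  if (upscale_factor != 1) {
    nh <- max(1L, round(nrow(img8) * upscale_factor))
    nw <- max(1L, round(ncol(img8) * upscale_factor))
    img8 <- round(pmin(pmax(EBImage::resize(img8, w = nh, h = nw,
                                            filter = "bilinear"), 0), 255))
  }
  structure(list(image = array(img8, c(dim(img8), 3L)),
                 upscale_factor = upscale_factor,
                 original_shape = dim(image)),
            class = "detector_input")
}

#' Upscaling-factor heuristic from field-of-view and feature size
#'
#' The optimal upscaling factor is linear in the square root of the ratio
#' between the field-of-view area and the mean bounding-box area. The
#' calibration `(slope, intercept)` can be fitted from grid-search optima
#' with [calibrate_upscale()].
#'
#' @param fov_area field-of-view area in px^2.
#' @param mean_box_area mean bounding-box area in px^2.
#' @param calibration `c(slope, intercept)` of the linear relation.
#' @param floor_at minimum returned factor.
#' @return the upscaling factor; non-positive predictions are an error.
#' @export
upscale_factor_heuristic <- function(fov_area, mean_box_area,
                                     calibration = c(1, 0), floor_at = 0.6) {
  stopifnot(fov_area > 0, mean_box_area > 0)
  f <- calibration[1] * sqrt(fov_area / mean_box_area) + calibration[2]
  if (f <= 0) stop("upscale heuristic produced a non-positive factor: ", f)
  max(f, floor_at)
}

#' Fit the upscaling calibration line
#'
#' Least-squares fit of optimal upscaling factors against
#' `sqrt(fov_area / mean_box_area)`.
#'
#' @param fov_areas,box_areas,factors numeric vectors (one entry per
#'   dataset): field-of-view areas, mean box areas, and grid-search-optimal
#'   upscaling factors.
#' @return `c(slope, intercept)`.
#' @export
calibrate_upscale <- function(fov_areas, box_areas, factors) {
  x <- sqrt(fov_areas / box_areas)
  fit <- stats::lm(factors ~ x)
  c(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]))
}
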