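#' Construct a table of bounding boxes
#'
#' Boxes use a single internal convention throughout the package: 0-based,
#' half-open pixel coordinates `[x_min, x_max) x [y_min, y_max)` where `x`
#' indexes columns and `y` indexes rows. Under this convention the box area is
#' `(x_max - x_min) * (y_max - y_min)` pixels. The 1-based inclusive
#' convention of Pascal-VOC files is converted at the I/O boundary only
#' (see [read_voc_boxes()]).
#'
#' @param x_min,y_min,x_max,y_max numeric vectors of box edges (pixels).
#' @param score detector confidence in `[0, 1]` (`NA` when not applicable).
#' @param identity optional integer identity label.
#' @return a `data.frame` with columns `x_min`, `y_min`, `x_max`, `y_max`,
#'   `score`, `identity`, one row per box.
#' @export
bbox <- function(x_min, y_min, x_max, y_max, score = NA_real_,
                 identity = NA_integer_) {
  b <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                  x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                  score = as.numeric(score), identity = as.integer(identity))
  validate_boxes(b)
  b
}

#' An empty box table with the standard columns
#' @return zero-row box `data.frame`.
#' @export
empty_boxes <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
             y_max = numeric(0), score = numeric(0), identity = integer(0))
}

#' Validate a box table
#'
#' @param boxes box `data.frame`.
#' @param fov_shape optional `c(H, W)`; when given, boxes must lie inside the
#'   field of view.
#' @return `boxes`, invisibly; signals an error listing offending rows.
#' @export
validate_boxes <- function(boxes, fov_shape = NULL) {
  stopifnot(is.data.frame(boxes))
  need <- c("x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(boxes))) {
    stop("box table must have columns x_min, y_min, x_max, y_max")
  }
  bad <- which(!(boxes$x_max > boxes$x_min & boxes$y_max > boxes$y_min))
  if (length(bad)) {
    stop("degenerate boxes (x_max <= x_min or y_max <= y_min) at rows: ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(fov_shape)) {
    out <- which(boxes$x_min < 0 | boxes$y_min < 0 |
                   boxes$x_max > fov_shape[2] | boxes$y_max > fov_shape[1])
    if (length(out)) {
      stop("boxes outside the ", fov_shape[1], "x", fov_shape[2],
           " field of view at rows: ", paste(out, collapse = ", "))
    }
  }
  invisible(boxes)
}

#' Box areas in pixels
#' @param boxes box `data.frame`.
#' @return numeric vector of areas under the half-open convention.
#' @export
box_area <- function(boxes) {
  (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
}

#' Clip boxes to a field of view
#'
#' @param boxes box `data.frame`.
#' @param fov_shape `c(H, W)` in pixels.
#' @return the clipped table; rows that vanish entirely are dropped.
#' @export
clip_boxes <- function(boxes, fov_shape) {
  boxes$x_min <- pmax(boxes$x_min, 0)
  boxes$y_min <- pmax(boxes$y_min, 0)
  boxes$x_max <- pmin(boxes$x_max, fov_shape[2])
  boxes$y_max <- pmin(boxes$y_max, fov_shape[1])
  boxes[boxes$x_max > boxes$x_min & boxes$y_max > boxes$y_min, , drop = FALSE]
}

pair_intersection <- function(a, b) {
  w <- pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min)
  h <- pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min)
  pmax(w, 0) * pmax(h, 0)
}

#' Sum-of-areas overlap ratio between two boxes
#'
#' Overlap defined as the intersection area divided by the *sum* of the two
#' box areas. This is the overlap measure thresholded at 20%/25% throughout
#' the pipeline; it is symmetric, zero iff the boxes are disjoint, and at
#' most 0.5 (attained for identical boxes). It is deliberately distinct from
#' [standard_iou()].
#'
#' @param a,b single-row box `data.frame`s (or equal-length tables, matched
#'   row-wise).
#' @return overlap ratio(s) in `[0, 0.5]`.
#' @export
sum_area_overlap <- function(a, b) {
  pair_intersection(a, b) / (box_area(a) + box_area(b))
}

#' Standard intersection-over-union between two boxes
#'
#' Provided for interoperability with conventional detection tooling; the
#' pipeline's own overlap thresholds use [sum_area_overlap()].
#'
#' @inheritParams sum_area_overlap
#' @return IoU value(s) in `[0, 1]`.
#' @export
standard_iou <- function(a, b) {
  i <- pair_intersection(a, b)
  i / (box_area(a) + box_area(b) - i)
}

# All-pairs overlap matrix (rows of a x rows of b).
overlap_matrix <- function(a, b, method = c("sum", "iou", "iomin")) {
  method <- match.arg(method)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(matrix(0, nrow(a), nrow(b)))
  }
  w <- outer(a$x_max, b$x_max, pmin) - outer(a$x_min, b$x_min, pmax)
  h <- outer(a$y_max, b$y_max, pmin) - outer(a$y_min, b$y_min, pmax)
  inter <- pmax(w, 0) * pmax(h, 0)
  aa <- box_area(a); ab <- box_area(b)
  switch(method,
         sum = inter / outer(aa, ab, `+`),
         iou = inter / (outer(aa, ab, `+`) - inter),
         iomin = inter / outer(aa, ab, pmin))
}

# round() uses banker's rounding; detector scale conversion needs half-up.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# 1-based row/col index ranges of the pixels covered by a (possibly
# fractional) box, after clipping to the frame.
box_pixel_range <- function(box, fov_shape) {
  rows <- (floor(max(box$y_min, 0)) + 1L):ceiling(min(box$y_max, fov_shape[1]))
  cols <- (floor(max(box$x_min, 0)) + 1L):ceiling(min(box$x_max, fov_shape[2]))
  list(rows = rows, cols = cols)
}
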