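#' Construct a movie stack
#'
#' A movie stack is the in-memory form of a t-series: an `H x W x T` array of
#' grayscale intensities plus acquisition metadata. Frames are stored with
#' rows as image rows (`y`) and columns as image columns (`x`).
#'
#' @param frames `H x W x T` numeric array (a single matrix is promoted to
#'   `T = 1`).
#' @param frame_rate acquisition rate in Hz.
#' @param pixel_size lateral pixel size in micrometres per pixel.
#' @param bit_depth nominal bit depth (8, 16, or 32 for float data).
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(frames, frame_rate = 30, pixel_size = 1,
                        bit_depth = 16) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L, frame_rate > 0, pixel_size > 0)
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_size = pixel_size, bit_depth = bit_depth),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie_stack: %d x %d px, %d frames, %.3g Hz, %.3g um/px, %d-bit\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_size, x$bit_depth))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]
fov_shape <- function(stack) dim(stack$frames)[1:2]

#' Read a multi-page TIFF movie
#'
#' Integer stacks (8/16-bit) are read bit-exactly; 32-bit float stacks are
#' read as stored. Mixed frame shapes are a format error.
#'
#' @param path TIFF file path.
#' @param frame_rate,pixel_size acquisition metadata (TIFF does not carry
#'   them; supply the values from the acquisition or a config file).
#' @return a [movie_stack()].
#' @export
read_movie <- function(path, frame_rate = 30, pixel_size = 1) {
  if (!file.exists(path)) stop("movie file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("not a readable TIFF ('", path,
                                             "'): ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("mixed frame shapes in TIFF: ", path)
  }
  if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1)))) {
    stop("only single-channel grayscale TIFFs are supported: ", path)
  }
  is_int <- all(vapply(pages, function(p) all(p == round(p)), logical(1)))
  depth <- if (!is_int) 32L else if (max(vapply(pages, max, numeric(1))) > 255) 16L else 8L
  frames <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  movie_stack(frames, frame_rate = frame_rate, pixel_size = pixel_size,
              bit_depth = depth)
}

#' Write a movie stack as a multi-page TIFF
#'
#' Integer stacks round-trip losslessly through [read_movie()]. Float stacks
#' (`bit_depth = 32`) must hold values in `[0, 1]`.
#'
#' @param stack a [movie_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"))
  f <- stack$frames
  if (stack$bit_depth %in% c(8L, 16L)) {
    mx <- 2^stack$bit_depth - 1
    if (any(f < 0) || any(f > mx) || any(f != round(f))) {
      stop("integer movie values must be whole numbers in [0, ", mx, "]")
    }
    pages <- lapply(seq_len(dim(f)[3]), function(t) f[, , t] / mx)
    tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  } else if (stack$bit_depth == 32L) {
    if (any(f < 0) || any(f > 1)) stop("float movies must lie in [0, 1]")
    pages <- lapply(seq_len(dim(f)[3]), function(t) f[, , t])
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
  } else {
    stop("unsupported bit depth: ", stack$bit_depth)
  }
  invisible(path)
}

#' Read bounding boxes from a Pascal-VOC XML annotation
#'
#' VOC stores 1-based inclusive corner coordinates; they are converted to the
#' package's 0-based half-open convention here, at the I/O boundary.
#'
#' @param path XML file path.
#' @return a box `data.frame` (see [bbox()]); empty annotations give an empty
#'   table.
#' @export
read_voc_boxes <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- xml2::read_xml(path)
  objs <- xml2::xml_find_all(doc, ".//object")
  if (length(objs) == 0L) return(empty_boxes())
  num <- function(node, tag) {
    as.numeric(xml2::xml_text(xml2::xml_find_first(node, paste0(".//", tag))))
  }
  b <- data.frame(
    x_min = vapply(objs, num, numeric(1), "xmin") - 1,
    y_min = vapply(objs, num, numeric(1), "ymin") - 1,
    x_max = vapply(objs, num, numeric(1), "xmax"),
    y_max = vapply(objs, num, numeric(1), "ymax"),
    score = vapply(objs, function(o) {
      s <- xml2::xml_find_first(o, ".//score")
      if (inherits(s, "xml_missing")) NA_real_ else as.numeric(xml2::xml_text(s))
    }, numeric(1)),
    identity = NA_integer_)
  validate_boxes(b)
  b
}

#' Write bounding boxes as a Pascal-VOC XML annotation
#'
#' A single object class (`cell`) is written; detector scores are stored in
#' an auxiliary `<score>` element that VOC readers ignore.
#'
#' @param boxes box `data.frame`.
#' @param path output path.
#' @param image_shape `c(H, W)` of the annotated image; boxes outside it are
#'   a validation error.
#' @return `path`, invisibly.
#' @export
write_voc_boxes <- function(boxes, path, image_shape) {
  validate_boxes(boxes, fov_shape = image_shape)
  doc <- xml2::xml_new_root("annotation")
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(image_shape[2]))
  xml2::xml_add_child(size, "height", as.character(image_shape[1]))
  xml2::xml_add_child(size, "depth", "1")
  fmt <- function(x) sprintf("%.17g", x)
  for (i in seq_len(nrow(boxes))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", "cell")
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", fmt(boxes$x_min[i] + 1))
    xml2::xml_add_child(bb, "ymin", fmt(boxes$y_min[i] + 1))
    xml2::xml_add_child(bb, "xmax", fmt(boxes$x_max[i]))
    xml2::xml_add_child(bb, "ymax", fmt(boxes$y_max[i]))
    if (!is.na(boxes$score[i])) {
      xml2::xml_add_child(obj, "score", fmt(boxes$score[i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a trace set as CSV
#'
#' One column per identity plus the per-frame background trace and
#' timestamps. Frames before an identity's first detection are missing by
#' construction and are written as empty fields (`NA`), never as 0.
#'
#' @param traces a [trace_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  t_idx <- seq_len(length(traces$bg)) - 1L
  df <- data.frame(frame = t_idx, time_s = t_idx / traces$frame_rate,
                   bg = traces$bg, check.names = FALSE)
  if (ncol(traces$traces) > 0) {
    m <- traces$traces
    colnames(m) <- paste0("cell_", traces$ids)
    df <- cbind(df, m)
  }
  # full float precision: format numerics as %.17g so the round-trip is exact
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(df[[j]]), NA, sprintf("%.17g", df[[j]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a trace-set CSV written by [write_traces()]
#'
#' @param path CSV path.
#' @param frame_rate frames per second used for the time column.
#' @return a [trace_set()].
#' @export
read_traces <- function(path, frame_rate = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(frame_rate)) {
    frame_rate <- if (nrow(df) > 1) 1 / (df$time_s[2] - df$time_s[1]) else 1
  }
  cell_cols <- grep("^cell_", names(df), value = TRUE)
  m <- as.matrix(df[, cell_cols, drop = FALSE])
  ids <- as.integer(sub("^cell_", "", cell_cols))
  trace_set(traces = unname(m), bg = df$bg, ids = ids, frame_rate = frame_rate)
}
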