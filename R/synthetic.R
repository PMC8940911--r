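#' Configuration for a synthetic imaging scene
#'
#' Describes a raster-scanned two-photon-like acquisition: bright somata on a
#' dim background, indicator-like transient kinetics, an optional shared
#' neuropil signal, and per-pixel Gaussian noise. Defaults describe a
#' 256 x 256 px, 300-frame field of view with 20 non-overlapping cells.
#'
#' @param fov_shape `c(H, W)` in pixels.
#' @param pixel_size micrometres per pixel.
#' @param frame_rate frames per second.
#' @param n_frames number of frames (>= 1).
#' @param n_cells number of somata to place.
#' @param radius_range `c(min, max)` soma radius in pixels.
#' @param min_spacing minimum pairwise centre distance, in units of the
#'   maximum soma radius.
#' @param baseline background fluorescence offset (a.u.).
#' @param brightness_range per-cell resting brightness above baseline (a.u.).
#' @param spike_rate mean calcium-event rate per cell (Hz).
#' @param rise_tau,decay_tau transient kinetics (s); `decay_tau > rise_tau`.
#' @param amplitude_range per-cell transient peak amplitude (a.u.).
#' @param neuropil_amplitude amplitude of the shared slow neuropil signal
#'   (a.u.; 0 disables it).
#' @param noise_sigma per-pixel Gaussian noise standard deviation (a.u.).
#' @return a `scene_config` list.
#' @export
scene_config <- function(fov_shape = c(256, 256), pixel_size = 1,
                         frame_rate = 30, n_frames = 300, n_cells = 20,
                         radius_range = c(5, 7), min_spacing = 3,
                         baseline = 100, brightness_range = c(40, 80),
                         spike_rate = 0.2, rise_tau = 0.1, decay_tau = 1,
                         amplitude_range = c(40, 80),
                         neuropil_amplitude = 0, noise_sigma = 0) {
  stopifnot(n_frames >= 1, n_cells >= 0, noise_sigma >= 0,
            decay_tau > rise_tau, rise_tau > 0, all(radius_range > 0),
            frame_rate > 0, pixel_size > 0)
  structure(as.list(environment()), class = "scene_config")
}

#' Generate a synthetic scene with ground truth
#'
#' Cells are placed by rejection sampling so that all pairwise centre
#' distances are at least `min_spacing` times the maximum radius; per-cell
#' spike trains are homogeneous Poisson. The returned scene carries the
#' tightest ground-truth box around each soma disk. Deterministic given
#' `seed`.
#'
#' @param config a [scene_config()].
#' @param seed integer random seed.
#' @return a `synthetic_scene` with fields `cells` (list of per-cell specs),
#'   `gt_boxes`, and the acquisition metadata from `config`.
#' @export
generate_scene <- function(config, seed = 1) {
  stopifnot(inherits(config, "scene_config"))
  rng <- local_rng(seed)
  on.exit(rng())
  h <- config$fov_shape[1]; w <- config$fov_shape[2]
  spacing_px <- config$min_spacing * max(config$radius_range)
  centers <- matrix(numeric(0), 0, 2)
  cells <- list()
  for (i in seq_len(config$n_cells)) {
    r <- stats::runif(1, config$radius_range[1], config$radius_range[2])
    placed <- FALSE
    for (try in seq_len(5000)) {
      cy <- stats::runif(1, r + 1, h - r - 1)
      cx <- stats::runif(1, r + 1, w - r - 1)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >= spacing_px)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("cell placement failure: cannot fit ", config$n_cells,
           " cells at minimum spacing ", spacing_px, " px in a ", h, "x", w,
           " field of view")
    }
    centers <- rbind(centers, c(cy, cx))
    n_sp <- stats::rpois(1, config$spike_rate * config$n_frames / config$frame_rate)
    spikes <- sort(stats::runif(n_sp, 0, config$n_frames - 1))
    cells[[i]] <- list(
      center = c(cy, cx), radius = r,
      baseline_brightness = stats::runif(1, config$brightness_range[1],
                                         config$brightness_range[2]),
      spike_times = spikes,
      rise_tau = config$rise_tau, decay_tau = config$decay_tau,
      transient_amplitude = stats::runif(1, config$amplitude_range[1],
                                         config$amplitude_range[2]))
  }
  gt <- if (length(cells)) {
    do.call(rbind, lapply(seq_along(cells), function(i) {
      c <- cells[[i]]
      bbox(floor(c$center[2] - c$radius), floor(c$center[1] - c$radius),
           ceiling(c$center[2] + c$radius), ceiling(c$center[1] + c$radius),
           score = 1, identity = i - 1L)
    }))
  } else empty_boxes()
  structure(c(config[setdiff(names(config), c("n_cells", "radius_range",
                                              "min_spacing", "brightness_range",
                                              "spike_rate", "amplitude_range"))],
              list(cells = cells, gt_boxes = gt, seed = as.integer(seed))),
            class = "synthetic_scene")
}

# Double-exponential indicator kernel, peak-normalised to 1. t in seconds.
geci_kernel <- function(t, rise_tau, decay_tau) {
  tp <- rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
  peak <- exp(-tp / decay_tau) - exp(-tp / rise_tau)
  ifelse(t >= 0, (exp(-t / decay_tau) - exp(-t / rise_tau)) / peak, 0)
}

# Smooth soma profile: unit disk with a 1-pixel Gaussian edge.
soma_profile <- function(rows, cols, center, radius) {
  d <- sqrt(outer((rows - 0.5 - center[1])^2, (cols - 0.5 - center[2])^2, `+`))
  stats::pnorm(radius - d)
}

# Per-cell activity time course at the frame times (a.u., above baseline).
cell_activity <- function(cell, n_frames, frame_rate) {
  t_frames <- seq_len(n_frames) - 1
  a <- rep(cell$baseline_brightness, n_frames)
  for (sp in cell$spike_times) {
    a <- a + cell$transient_amplitude *
      geci_kernel((t_frames - sp) / frame_rate, cell$rise_tau, cell$decay_tau)
  }
  a
}

#' Render a scene into a movie with ground truth
#'
#' Each frame is `baseline + sum(soma profile x activity) + neuropil + noise`,
#' where the neuropil term is a low-pass-filtered Gaussian signal shared by
#' every pixel and the noise is i.i.d. Gaussian per pixel. Ground-truth
#' traces are the noiseless soma-mean signal of each cell (its own activity
#' averaged over the ground-truth disk; neuropil and noise excluded).
#' Bitwise deterministic given the scene seed.
#'
#' @param scene a [generate_scene()] result.
#' @return list with `stack` ([movie_stack()]), `gt_boxes`, and `gt_traces`
#'   (a [trace_set()]).
#' @export
render_movie <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  rng <- local_rng(scene$seed + 1000L)
  on.exit(rng())
  h <- scene$fov_shape[1]; w <- scene$fov_shape[2]; tt <- scene$n_frames
  frames <- array(scene$baseline, c(h, w, tt))
  n_cells <- length(scene$cells)
  gt_traces <- matrix(NA_real_, tt, n_cells)
  for (i in seq_len(n_cells)) {
    cell <- scene$cells[[i]]
    rows <- max(1, floor(cell$center[1] - cell$radius - 3)):
      min(h, ceiling(cell$center[1] + cell$radius + 3))
    cols <- max(1, floor(cell$center[2] - cell$radius - 3)):
      min(w, ceiling(cell$center[2] + cell$radius + 3))
    prof <- soma_profile(rows, cols, cell$center, cell$radius)
    act <- cell_activity(cell, tt, scene$frame_rate)
    for (t in seq_len(tt)) {
      frames[rows, cols, t] <- frames[rows, cols, t] + prof * act[t]
    }
    # soma-mean over the GT disk (profile >= 0.5 <=> inside the disk)
    mask_mean <- mean(prof[prof >= 0.5])
    gt_traces[, i] <- scene$baseline + mask_mean * act
  }
  if (scene$neuropil_amplitude > 0) {
    s <- lowpass_noise(tt, scene$frame_rate)
    for (t in seq_len(tt)) {
      frames[, , t] <- frames[, , t] + scene$neuropil_amplitude * s[t]
    }
  }
  if (scene$noise_sigma > 0) {
    frames <- frames + array(stats::rnorm(h * w * tt, sd = scene$noise_sigma),
                             c(h, w, tt))
  }
  list(stack = movie_stack(frames, frame_rate = scene$frame_rate,
                           pixel_size = scene$pixel_size, bit_depth = 32L),
       gt_boxes = scene$gt_boxes,
       gt_traces = trace_set(traces = gt_traces, bg = rep(scene$baseline, tt),
                             ids = seq_len(n_cells) - 1L,
                             frame_rate = scene$frame_rate))
}

# Shared slow neuropil signal: Gaussian noise low-pass filtered with a ~0.5 s
# Gaussian window (zero-padded, edge-renormalised), rescaled to unit
# standard deviation.
lowpass_noise <- function(n, frame_rate) {
  x <- stats::rnorm(n)
  sigma <- max(1, min(0.5 * frame_rate, n / 4))
  half <- ceiling(3 * sigma)
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  sm <- (as.numeric(num) / as.numeric(den))[(half + 1):(half + n)]
  s <- stats::sd(sm)
  if (is.na(s) || s == 0) return(rep(0, n))
  sm / s
}

#' Describe a rigid lateral drift
#'
#' @param total_displacement total drift in micrometres (>= 0).
#' @param duration ramp duration in seconds (> 0).
#' @param onset_frame 0-based frame index at which the ramp starts.
#' @param direction drift direction `c(dx, dy)`; normalised internally.
#' @return a `motion_profile` list.
#' @export
motion_profile <- function(total_displacement, duration, onset_frame = 0,
                           direction = c(1, 0)) {
  stopifnot(total_displacement >= 0, duration > 0, onset_frame >= 0)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) direction <- c(1, 0) else direction <- direction / nrm
  structure(list(total_displacement = total_displacement, duration = duration,
                 onset_frame = onset_frame, direction = direction),
            class = "motion_profile")
}

#' Inject rigid lateral drift into a movie
#'
#' The cumulative displacement ramps linearly from 0 to
#' `total_displacement / pixel_size` pixels over `duration`, starting at
#' `onset_frame`, and stays at its final value afterwards. Frames are warped
#' by sub-pixel bilinear interpolation; pixels shifted in from outside the
#' field of view are filled with `fill_value` (or the field is cropped by the
#' maximum displacement on every side with `fill = "crop"`). Ground-truth
#' boxes are translated frame-by-frame by the same shift.
#'
#' @param stack a [movie_stack()].
#' @param profile a [motion_profile()].
#' @param gt_boxes ground-truth box table to translate along with the frames.
#' @param fill `"baseline"` (fill revealed pixels with `fill_value`) or
#'   `"crop"`.
#' @param fill_value fill intensity; defaults to the stack's per-pixel
#'   minimum.
#' @return list with the shifted `stack`, `shifted_gt` (per-frame list of box
#'   tables), and `shift_log` (`T x 2` matrix of cumulative `(dx, dy)` in
#'   pixels).
#' @export
inject_motion <- function(stack, profile, gt_boxes = empty_boxes(),
                          fill = c("baseline", "crop"), fill_value = NULL) {
  stopifnot(inherits(stack, "movie_stack"), inherits(profile, "motion_profile"))
  fill <- match.arg(fill)
  tt <- n_frames(stack); shape <- fov_shape(stack)
  if (profile$onset_frame >= tt) stop("onset_frame beyond the last frame")
  total_px <- profile$total_displacement / stack$pixel_size
  if (total_px >= min(shape)) {
    stop("displacement of ", total_px, " px exceeds the field of view")
  }
  if (is.null(fill_value)) fill_value <- min(stack$frames)
  ramp <- max(1, round(profile$duration * stack$frame_rate))
  frac <- pmin(pmax((seq_len(tt) - 1 - profile$onset_frame) / ramp, 0), 1)
  shift_log <- cbind(dx = frac * total_px * profile$direction[1],
                     dy = frac * total_px * profile$direction[2])
  frames <- stack$frames
  shifted_gt <- vector("list", tt)
  for (t in seq_len(tt)) {
    frames[, , t] <- shift_image(stack$frames[, , t], shift_log[t, 1],
                                 shift_log[t, 2], fill = fill_value)
    g <- gt_boxes
    if (nrow(g)) {
      g$x_min <- g$x_min + shift_log[t, 1]; g$x_max <- g$x_max + shift_log[t, 1]
      g$y_min <- g$y_min + shift_log[t, 2]; g$y_max <- g$y_max + shift_log[t, 2]
      g <- clip_boxes(g, shape)
    }
    shifted_gt[[t]] <- g
  }
  out <- movie_stack(frames, frame_rate = stack$frame_rate,
                     pixel_size = stack$pixel_size, bit_depth = stack$bit_depth)
  if (fill == "crop") {
    m <- ceiling(total_px)
    if (m > 0) {
      out$frames <- out$frames[(m + 1):(shape[1] - m),
                               (m + 1):(shape[2] - m), , drop = FALSE]
      shifted_gt <- lapply(shifted_gt, function(g) {
        if (nrow(g)) {
          g$x_min <- g$x_min - m; g$x_max <- g$x_max - m
          g$y_min <- g$y_min - m; g$y_max <- g$y_max - m
          g <- clip_boxes(g, dim(out$frames)[1:2])
        }
        g
      })
    }
  }
  list(stack = out, shifted_gt = shifted_gt, shift_log = shift_log)
}

# Shift an image by (dx, dy) pixels with bilinear interpolation; revealed
# pixels take `fill`. Exact translation for integer shifts.
shift_image <- function(img, dx, dy, fill = 0) {
  if (dx == 0 && dy == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  rs <- matrix(seq_len(h), h, w) - dy
  cs <- matrix(seq_len(w), h, w, byrow = TRUE) - dx
  r0 <- floor(rs); c0 <- floor(cs)
  fr <- rs - r0; fc <- cs - c0
  sample_at <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- matrix(fill, h, w)
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  sample_at(r0, c0) * (1 - fr) * (1 - fc) +
    sample_at(r0 + 1, c0) * fr * (1 - fc) +
    sample_at(r0, c0 + 1) * (1 - fr) * fc +
    sample_at(r0 + 1, c0 + 1) * fr * fc
}

# Scoped RNG: seed now, restore the caller's RNG state on exit.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
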