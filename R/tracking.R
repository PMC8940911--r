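#' Create an empty identity registry
#'
#' The registry holds persistent per-cell identities across detection
#' updates: the current box, an active/inactive flag, frames of first and
#' last active detection, and the full box history. Identity numbers start
#' at 0 and are never reused or deleted.
#'
#' @return an `identity_registry`.
#' @export
identity_registry <- function() {
  structure(list(identities = list(), next_id = 0L, updates = 0L),
            class = "identity_registry")
}

#' Update tracked identities from a new detection set
#'
#' Detections (already score-filtered and duplicate-suppressed) are matched
#' one-to-one to existing identities by descending sum-of-areas overlap.
#' Matched identities take the coordinates of the new detection and are
#' marked active. A detection overlapping *every* existing identity below
#' `new_id_threshold` spawns a new identity. Identities with no match are
#' marked inactive and their boxes are translated by the mean centre shift
#' of the identities matched in this step (left in place when nothing
#' matched), clipped so they never leave the field of view.
#'
#' @param registry an [identity_registry()].
#' @param detections a [detection_set()].
#' @param new_id_threshold overlap below which a detection is a new cell
#'   (default 0.2; 0.25 is the documented alternative preset).
#' @param matching `"greedy"` (default; sort candidate pairs by overlap and
#'   accept one-to-one) or `"optimal"` (maximum-total-overlap assignment).
#' @param frame 0-based frame index of this update.
#' @param fov_shape optional `c(H, W)` used to clip rigid-shifted boxes.
#' @return the updated registry.
#' @export
update_tracks <- function(registry, detections, new_id_threshold = 0.2,
                          matching = c("greedy", "optimal"),
                          frame = NA_integer_, fov_shape = NULL) {
  stopifnot(inherits(registry, "identity_registry"),
            inherits(detections, "detection_set"))
  matching <- match.arg(matching)
  det <- detections$boxes
  ids <- registry$identities
  n_det <- nrow(det); n_id <- length(ids)
  registry$updates <- registry$updates + 1L

  matched_det <- integer(0); matched_id <- integer(0)
  if (n_det > 0 && n_id > 0) {
    cur <- do.call(rbind, lapply(ids, function(x) x$box))
    ov <- overlap_matrix(det, cur, method = "sum")
    if (matching == "greedy") {
      pairs <- which(ov >= new_id_threshold, arr.ind = TRUE)
      if (nrow(pairs)) {
        pairs <- pairs[order(-ov[pairs]), , drop = FALSE]
        used_d <- logical(n_det); used_i <- logical(n_id)
        for (p in seq_len(nrow(pairs))) {
          d <- pairs[p, 1]; i <- pairs[p, 2]
          if (!used_d[d] && !used_i[i]) {
            used_d[d] <- TRUE; used_i[i] <- TRUE
            matched_det <- c(matched_det, d); matched_id <- c(matched_id, i)
          }
        }
      }
    } else {
      asg <- hungarian_max(ov)
      keep <- which(!is.na(asg) & ov[cbind(seq_len(n_det), asg)] >= new_id_threshold)
      matched_det <- keep; matched_id <- asg[keep]
    }
  }

  # (2) matched identities: update coordinates, mark active
  shifts <- matrix(numeric(0), 0, 2)
  for (k in seq_along(matched_det)) {
    d <- matched_det[k]; i <- matched_id[k]
    old <- ids[[i]]$box
    new <- det[d, , drop = FALSE]
    new$identity <- old$identity
    shifts <- rbind(shifts,
                    c((new$x_min + new$x_max - old$x_min - old$x_max) / 2,
                      (new$y_min + new$y_max - old$y_min - old$y_max) / 2))
    ids[[i]]$box <- new
    ids[[i]]$active <- TRUE
    ids[[i]]$last_active <- frame
    ids[[i]]$history[[length(ids[[i]]$history) + 1L]] <- new
  }

  # (4) unmatched identities: inactive, rigid-shifted by the mean matched
  # shift (rounded to 0.1 px), frozen at the border rather than deleted
  mean_shift <- if (nrow(shifts)) round_half_up(colMeans(shifts), 1) else c(0, 0)
  unmatched_ids <- setdiff(seq_len(n_id), matched_id)
  for (i in unmatched_ids) {
    ids[[i]]$active <- FALSE
    if (any(mean_shift != 0)) {
      b <- ids[[i]]$box
      dx <- mean_shift[1]; dy <- mean_shift[2]
      if (!is.null(fov_shape)) {
        dx <- max(min(dx, fov_shape[2] - b$x_max), -b$x_min)
        dy <- max(min(dy, fov_shape[1] - b$y_max), -b$y_min)
      }
      b$x_min <- b$x_min + dx; b$x_max <- b$x_max + dx
      b$y_min <- b$y_min + dy; b$y_max <- b$y_max + dy
      ids[[i]]$box <- b
    }
  }

  # (3) detections below threshold against ALL existing identities: new ids
  if (n_det > 0) {
    for (d in setdiff(seq_len(n_det), matched_det)) {
      max_ov <- if (n_id > 0) max(ov[d, ]) else 0
      if (max_ov < new_id_threshold) {
        b <- det[d, , drop = FALSE]
        b$identity <- registry$next_id
        ids[[length(ids) + 1L]] <- list(box = b, active = TRUE,
                                        first_frame = frame,
                                        last_active = frame,
                                        history = list(b))
        registry$next_id <- registry$next_id + 1L
      }
    }
  }
  registry$identities <- ids
  registry
}

#' Current boxes of all identities in a registry
#'
#' @param registry an [identity_registry()].
#' @param active_only return only actively detected identities.
#' @return box `data.frame` with `identity` set and an `active` column.
#' @export
registry_boxes <- function(registry, active_only = FALSE) {
  ids <- registry$identities
  if (!length(ids)) {
    out <- empty_boxes()
    out$active <- logical(0)
    return(out)
  }
  out <- do.call(rbind, lapply(ids, function(x) x$box))
  out$active <- vapply(ids, function(x) x$active, logical(1))
  rownames(out) <- NULL
  if (active_only) out <- out[out$active, , drop = FALSE]
  out
}

#' Summary statistics of a tracking run
#'
#' @param registry an [identity_registry()].
#' @return list with identity counts, per-identity lifetimes, and the
#'   identity-creation timeline (non-decreasing by construction).
#' @export
track_statistics <- function(registry) {
  ids <- registry$identities
  n <- length(ids)
  if (n == 0L) {
    return(list(total = 0L, active = 0L, inactive = 0L,
                lifetimes = data.frame(identity = integer(0),
                                       first_frame = integer(0),
                                       last_active = integer(0),
                                       n_updates = integer(0)),
                creation_timeline = data.frame(first_frame = integer(0),
                                               cumulative = integer(0))))
  }
  active <- vapply(ids, function(x) x$active, logical(1))
  lifetimes <- data.frame(
    identity = vapply(ids, function(x) x$box$identity, integer(1)),
    first_frame = vapply(ids, function(x) as.integer(x$first_frame), integer(1)),
    last_active = vapply(ids, function(x) as.integer(x$last_active), integer(1)),
    n_updates = vapply(ids, function(x) length(x$history), integer(1)))
  tl <- lifetimes[order(lifetimes$first_frame, lifetimes$identity), ]
  list(total = n, active = sum(active), inactive = sum(!active),
       lifetimes = lifetimes,
       creation_timeline = data.frame(first_frame = tl$first_frame,
                                      cumulative = seq_len(n)))
}

#' Serialize a registry to JSON
#'
#' @param registry an [identity_registry()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
registry_to_json <- function(registry, path = NULL) {
  ids <- lapply(registry$identities, function(x) {
    list(identity = x$box$identity, active = x$active,
         first_frame = x$first_frame, last_active = x$last_active,
         box = as.list(x$box[1, c("x_min", "y_min", "x_max", "y_max", "score")]),
         history = lapply(x$history, function(b) {
           as.list(b[1, c("x_min", "y_min", "x_max", "y_max", "score")])
         }))
  })
  js <- jsonlite::toJSON(list(next_id = registry$next_id,
                              updates = registry$updates,
                              identities = ids),
                         auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore a registry from JSON
#'
#' @param path file path or JSON string produced by [registry_to_json()].
#' @return an [identity_registry()].
#' @export
registry_from_json <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path), collapse = "\n") else path
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  reg <- identity_registry()
  reg$next_id <- as.integer(obj$next_id)
  reg$updates <- as.integer(obj$updates)
  reg$identities <- lapply(obj$identities, function(x) {
    mk <- function(b, id) bbox(b$x_min, b$y_min, b$x_max, b$y_max,
                               score = if (is.null(b$score)) NA else b$score,
                               identity = id)
    list(box = mk(x$box, as.integer(x$identity)),
         active = isTRUE(x$active),
         first_frame = if (is.null(x$first_frame)) NA_integer_ else as.integer(x$first_frame),
         last_active = if (is.null(x$last_active)) NA_integer_ else as.integer(x$last_active),
         history = lapply(x$history, mk, id = as.integer(x$identity)))
  })
  reg
}

# Maximum-weight one-to-one assignment (Hungarian algorithm on the negated,
# zero-padded square matrix; indices are offset by one to host the 0-based
# sentinel row/column of the classic formulation). Returns, for each row,
# the assigned column or NA. Used by the "optimal" matching alternative.
hungarian_max <- function(w) {
  n <- max(dim(w))
  cost <- matrix(0, n, n)
  cost[seq_len(nrow(w)), seq_len(ncol(w))] <- max(w) - w
  u <- numeric(n + 1)    # row potentials, u[i + 1] (i = 0 is the sentinel)
  v <- numeric(n + 1)    # column potentials, v[j + 1]
  p <- integer(n + 1)    # p[j + 1]: row currently assigned to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- logical(n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_col <- rep(NA_integer_, nrow(w))
  for (j in seq_len(n)) {
    r <- p[j + 1]
    if (r >= 1 && r <= nrow(w) && j <= ncol(w)) assign_col[r] <- j
  }
  assign_col
}
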