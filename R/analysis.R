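#' Match predicted boxes to ground truth and score the detection
#'
#' Predictions and ground-truth boxes are matched one-to-one greedily by
#' descending overlap ratio; pairs above `overlap_cutoff` are true
#' positives, unmatched predictions false positives, unmatched ground-truth
#' boxes false negatives. The default overlap measure for the 0.5 cutoff is
#' intersection over the smaller box area (`"iomin"`); standard IoU is
#' available via `overlap`. `mean_iou` is the mean *standard* IoU over the
#' true-positive pairs.
#'
#' Degenerate-count conventions: precision is 0 when there are no
#' predictions; recall is 1 when there is no ground truth to find.
#'
#' @param pred predicted box `data.frame`.
#' @param gt ground-truth box `data.frame`.
#' @param overlap_cutoff minimum overlap for a true positive (default 0.5).
#' @param overlap matching overlap measure: `"iomin"` (default) or `"iou"`.
#' @return a `metrics_report`: list with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `mean_iou`, and `matches` (pred row, gt row, overlap).
#' @export
match_detections <- function(pred, gt, overlap_cutoff = 0.5,
                             overlap = c("iomin", "iou")) {
  overlap <- match.arg(overlap)
  matches <- data.frame(pred = integer(0), gt = integer(0),
                        overlap = numeric(0))
  if (nrow(pred) > 0 && nrow(gt) > 0) {
    ov <- overlap_matrix(pred, gt, method = overlap)
    cand <- which(ov > overlap_cutoff, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(-ov[cand]), , drop = FALSE]
      used_p <- logical(nrow(pred)); used_g <- logical(nrow(gt))
      for (k in seq_len(nrow(cand))) {
        p <- cand[k, 1]; g <- cand[k, 2]
        if (!used_p[p] && !used_g[g]) {
          used_p[p] <- TRUE; used_g[g] <- TRUE
          matches <- rbind(matches,
                           data.frame(pred = p, gt = g, overlap = ov[p, g]))
        }
      }
    }
  }
  tp <- nrow(matches)
  fp <- nrow(pred) - tp
  fn <- nrow(gt) - tp
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  mean_iou <- if (tp == 0) NA_real_ else {
    mean(vapply(seq_len(tp), function(k) {
      standard_iou(pred[matches$pred[k], , drop = FALSE],
                   gt[matches$gt[k], , drop = FALSE])
    }, numeric(1)))
  }
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1_from_counts(precision, recall),
                 mean_iou = mean_iou, matches = matches),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | precision %.3f  recall %.3f  F-1 %.3f",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  if (!is.na(x$mean_iou)) cat(sprintf("  <IoU> %.3f", x$mean_iou))
  cat("\n")
  invisible(x)
}

#' F-1 score from precision and recall
#'
#' Harmonic mean, `2 * P * R / (P + R)`; 0 when both are 0.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return the F-1 score.
#' @export
f1_from_counts <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Conventional detection average precision
#'
#' Area under the precision–recall curve obtained by sweeping the score-
#' ranked predictions (all-point interpolation). Provided alongside — and
#' clearly distinct from — the `mean_iou` reported by [match_detections()],
#' which is the literal mean IoU over matched pairs.
#'
#' @param pred scored predicted boxes.
#' @param gt ground-truth boxes.
#' @param overlap_cutoff minimum overlap for a true positive.
#' @param overlap matching overlap measure (see [match_detections()]).
#' @return average precision in `[0, 1]`.
#' @export
detection_ap <- function(pred, gt, overlap_cutoff = 0.5,
                         overlap = c("iomin", "iou")) {
  overlap <- match.arg(overlap)
  if (nrow(gt) == 0L) return(NA_real_)
  if (nrow(pred) == 0L) return(0)
  ord <- order(-pred$score, pred$y_min, pred$x_min)
  pred <- pred[ord, , drop = FALSE]
  ov <- overlap_matrix(pred, gt, method = overlap)
  taken <- logical(nrow(gt))
  is_tp <- logical(nrow(pred))
  for (p in seq_len(nrow(pred))) {
    free <- which(!taken & ov[p, ] > overlap_cutoff)
    if (length(free)) {
      g <- free[which.max(ov[p, free])]
      taken[g] <- TRUE
      is_tp[p] <- TRUE
    }
  }
  cum_tp <- cumsum(is_tp)
  prec <- cum_tp / seq_along(is_tp)
  # all-point interpolation: each TP contributes its precision x (1 / n_gt)
  sum(prec[is_tp]) / nrow(gt)
}

#' Merge two graders' annotations into a consensus
#'
#' Boxes from the two sets whose overlap (intersection over the smaller box)
#' exceeds `overlap_threshold` enter the consensus directly (one box per
#' pair — grader 1's by convention); every remaining box from either grader
#' goes to the disputed list for joint adjudication. The adjudicated
#' consensus is the accepted overlap plus whichever disputed singletons the
#' graders agree to keep.
#'
#' @param gt1,gt2 the two annotation sets over the same image.
#' @param overlap_threshold acceptance threshold (default 0.5).
#' @return list with `consensus` and `disputed` box tables.
#' @export
consensus_merge <- function(gt1, gt2, overlap_threshold = 0.5) {
  m <- match_detections(gt1, gt2, overlap_cutoff = overlap_threshold,
                        overlap = "iomin")
  consensus <- gt1[m$matches$pred, , drop = FALSE]
  disputed <- rbind(gt1[setdiff(seq_len(nrow(gt1)), m$matches$pred), ,
                        drop = FALSE],
                    gt2[setdiff(seq_len(nrow(gt2)), m$matches$gt), ,
                        drop = FALSE])
  rownames(consensus) <- rownames(disputed) <- NULL
  list(consensus = consensus, disputed = disputed)
}

#' Detect calcium events in a fluorescence trace
#'
#' The trace is smoothed with a second-order Savitzky–Golay filter over
#' `window` frames; local maxima of the smoothed trace with prominence at
#' least `prominence` and height at least `min_height` (positive-going
#' peaks only) are calcium events.
#'
#' @param trace numeric fluorescence series (leading missing values are
#'   skipped; internal ones are an error).
#' @param window Savitzky–Golay window in frames (odd; default 15).
#' @param prominence minimum peak prominence (default 7).
#' @param min_height minimum peak height (default 3).
#' @return data frame with 0-based `frame` and smoothed `amplitude` per
#'   event; indices strictly increasing.
#' @export
detect_events <- function(trace, window = 15, prominence = 7, min_height = 3) {
  offset <- 0L
  if (anyNA(trace)) {
    valid <- which(!is.na(trace))
    if (!length(valid)) return(data.frame(frame = integer(0),
                                          amplitude = numeric(0)))
    offset <- valid[1] - 1L
    trace <- trace[valid[1]:length(trace)]
    if (anyNA(trace)) stop("trace has internal missing values")
  }
  if (length(trace) < window) {
    stop("trace shorter than the smoothing window (", window, " frames)")
  }
  sm <- signal::sgolayfilt(trace, p = 2, n = window)
  pk <- find_peaks(sm)
  keep <- pk$height >= min_height & pk$prominence >= prominence
  data.frame(frame = pk$index[keep] - 1L + offset,
             amplitude = pk$height[keep])
}

# Local maxima with prominences (topographic definition: height above the
# higher of the two lowest points separating the peak from higher terrain).
find_peaks <- function(x) {
  n <- length(x)
  idx <- which(diff(sign(diff(x))) < 0) + 1L
  idx <- idx[x[idx] > x[idx - 1] & x[idx] > x[idx + 1]]
  prom <- vapply(idx, function(i) {
    left <- x[seq_len(i - 1)]
    higher_l <- which(left > x[i])
    base_l <- min(x[(if (length(higher_l)) max(higher_l) else 1):i])
    right <- x[(i + 1):n]
    higher_r <- which(right > x[i])
    stop_r <- if (length(higher_r)) i + min(higher_r) else n
    base_r <- min(x[i:stop_r])
    x[i] - max(base_l, base_r)
  }, numeric(1))
  list(index = idx, height = x[idx], prominence = prom)
}

#' Signal-to-noise ratio of a value set
#'
#' Mean divided by the (population) standard deviation; applicable to a
#' whole t-series, the pixels of one ROI, or a single trace.
#'
#' @param values numeric vector, matrix, or array (>= 2 values).
#' @return mean / sd.
#' @export
snr <- function(values) {
  v <- as.numeric(values)
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 values to compute an SNR")
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) stop("zero standard deviation: SNR undefined")
  mean(v) / s
}

#' Pairwise trace correlation matrix at lag zero
#'
#' Pearson correlation over jointly valid frames for every pair of
#' identities; symmetric with unit diagonal. Constant traces get missing
#' rows/columns (with a warning).
#'
#' @param traces a [trace_set()] or a `T x n` matrix.
#' @param use `"traces"` (background-subtracted, default) or `"raw"` when a
#'   [trace_set()] is given.
#' @return `n x n` correlation matrix.
#' @export
correlation_matrix <- function(traces, use = c("traces", "raw")) {
  use <- match.arg(use)
  m <- if (inherits(traces, "trace_set")) traces[[use]] else as.matrix(traces)
  n <- ncol(m)
  if (n < 2) stop("need at least 2 identities")
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  const <- which(is.na(sds) | sds == 0)
  if (length(const)) {
    warning("constant traces (columns ", paste(const, collapse = ", "),
            "): correlations set to NA")
  }
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(cc) <- 1
  if (length(const)) {
    cc[const, ] <- NA_real_
    cc[, const] <- NA_real_
  }
  cc
}

#' Mean pairwise correlation (off-diagonal average)
#' @param corr square correlation matrix.
#' @return mean of the upper-triangle entries, `NA`s removed.
#' @export
mean_pairwise_correlation <- function(corr) {
  mean(corr[upper.tri(corr)], na.rm = TRUE)
}

#' Dendrogram leaf order for sorting a correlation matrix
#'
#' Agglomerative clustering with Ward linkage on the pairwise Manhattan
#' distances between correlation-matrix rows; the returned leaf order is
#' the one used to sort correlation matrices for display.
#'
#' @param corr_matrix square correlation matrix (no missing values).
#' @return integer leaf order (a permutation of `1:n`).
#' @export
dendrogram_order <- function(corr_matrix) {
  stopifnot(is.matrix(corr_matrix), nrow(corr_matrix) == ncol(corr_matrix))
  if (anyNA(corr_matrix)) stop("correlation matrix has missing values")
  if (nrow(corr_matrix) == 1L) return(1L)
  hc <- stats::hclust(stats::dist(corr_matrix, method = "manhattan"),
                      method = "ward.D2")
  hc$order
}

#' Gaussian smoothing of a trace
#'
#' Convolution with a normalised Gaussian kernel (standard deviation
#' `sigma_frames`); the kernel is renormalised over its valid support at the
#' edges, so the trace mean — and any constant trace — is preserved.
#'
#' @param trace numeric series.
#' @param sigma_frames kernel standard deviation in frames (default 1).
#' @return the smoothed trace.
#' @export
gaussian_smooth <- function(trace, sigma_frames = 1) {
  n <- length(trace)
  if (n == 0L || sigma_frames <= 0) return(trace)
  half <- ceiling(4 * sigma_frames)
  k <- stats::dnorm(-half:half, sd = sigma_frames)
  k <- k / sum(k)
  num <- stats::filter(c(rep(0, half), trace, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  (as.numeric(num) / as.numeric(den))[(half + 1):(half + n)]
}

#' F-1 against ground truth as the run progresses
#'
#' Scores each detection emission of an online run against the ground truth
#' of its frame (per-frame translated ground truth when motion was
#' injected), yielding the F-1 curve over the normalised run fraction.
#'
#' @param emissions list of per-emission [detection_set()]s (as returned in
#'   `run_online()$emissions`).
#' @param gt either a single box table (static scene) or a per-frame list.
#' @param total_frames total frames in the run (for the fraction axis).
#' @param overlap_cutoff matching cutoff (see [match_detections()]).
#' @return data frame with `frame`, `fraction`, `precision`, `recall`, `f1`
#'   — one row per emission; values defined only from the first emission on.
#' @export
evaluate_online_run <- function(emissions, gt, total_frames,
                                overlap_cutoff = 0.5) {
  rows <- lapply(emissions, function(e) {
    g <- if (is.data.frame(gt)) gt else gt[[e$frame + 1L]]
    m <- match_detections(e$boxes, g, overlap_cutoff = overlap_cutoff)
    data.frame(frame = e$frame, fraction = (e$frame + 1) / total_frames,
               precision = m$precision, recall = m$recall, f1 = m$f1)
  })
  do.call(rbind, c(list(data.frame(frame = integer(0), fraction = numeric(0),
                                   precision = numeric(0), recall = numeric(0),
                                   f1 = numeric(0))), rows))
}
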