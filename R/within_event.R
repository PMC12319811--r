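# Within-event / within-movie-clip ISTS: trajectory similarity restricted to
# the TRs of each stable neural event (from the HMM segmentation of DMN
# activity, applied to every ROI) or of each movie clip, then averaged
# across windows to one value per dyad per ROI.

#' Build event windows from a segmentation or a clip table
#'
#' @param x An `event_segmentation` (windows are the maximal runs of constant
#'   state assignment) or a clip table data frame with 0-based half-open
#'   `start_tr` / `end_tr` columns.
#' @param min_length Windows shorter than this many TRs are dropped (a 2-TR
#'   window has a single off-diagonal trajectory entry, so no correlation
#'   can be formed); the number skipped is recorded.
#' @return An `event_windows` object: list of `[start, end)` 0-based
#'   intervals, the source (`"hmm"` or `"clips"`), and the skip count.
#' @export
build_event_windows <- function(x, min_length = 3L) {
  if (inherits(x, "event_segmentation")) {
    a <- x$assignment
    starts <- c(0L, x$boundaries)
    ends <- c(x$boundaries, length(a))
    source <- "hmm"
  } else if (is.data.frame(x)) {
    stopifnot(all(c("start_tr", "end_tr") %in% names(x)))
    x <- x[order(x$start_tr), , drop = FALSE]
    starts <- as.integer(x$start_tr)
    ends <- as.integer(x$end_tr)
    if (any(ends <= starts)) stop("empty clip interval")
    if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)])) {
      stop("clip intervals overlap")
    }
    source <- "clips"
  } else {
    stop("x must be an event_segmentation or a clip table")
  }
  keep <- (ends - starts) >= min_length
  n_skipped <- sum(!keep)
  windows <- Map(function(s, e) c(start = s, end = e), starts[keep], ends[keep])
  if (!length(windows)) stop("no usable windows after filtering short events")
  structure(list(source = source, windows = windows, n_skipped = n_skipped,
                 min_length = as.integer(min_length)),
            class = "event_windows")
}

#' @export
print.event_windows <- function(x, ...) {
  cat(sprintf("<event_windows> %d windows from %s (%d skipped as < %d TRs)\n",
              length(x$windows), x$source, x$n_skipped, x$min_length))
  invisible(x)
}

#' Within-window ISTS for one dyad in one ROI
#'
#' For each window, both subjects' trajectory matrices are rebuilt from that
#' window's TRs only and correlated; the per-window values are then averaged
#' (unweighted) into a single within-event ISTS.
#'
#' @param a_ts,b_ts `roi_timeseries` of the two dyad members (same T).
#' @param windows An `event_windows`.
#' @param weight_by_length Weight the average by window length instead of the
#'   default unweighted mean.
#' @return List with `mean_ists`, `per_window` values, and the number of
#'   windows where ISTS was undefined and skipped.
#' @export
within_window_ists <- function(a_ts, b_ts, windows, weight_by_length = FALSE) {
  stopifnot(inherits(windows, "event_windows"))
  if (ncol(a_ts$data) != ncol(b_ts$data)) stop("subjects differ in T")
  vals <- rep(NA_real_, length(windows$windows))
  lens <- integer(length(vals))
  for (i in seq_along(windows$windows)) {
    w <- windows$windows[[i]]
    trs <- seq.int(w[["start"]], w[["end"]] - 1L) # 0-based
    lens[i] <- length(trs)
    vals[i] <- tryCatch({
      ta <- build_trajectory_matrix(a_ts, tr_mask = trs)
      tb <- build_trajectory_matrix(b_ts, tr_mask = trs)
      suppressWarnings(compute_ists(ta, tb))
    }, error = function(e) NA_real_)
  }
  ok <- !is.na(vals)
  if (!any(ok)) {
    warning("ISTS undefined in every window")
    return(list(mean_ists = NA_real_, per_window = vals, n_skipped = sum(!ok)))
  }
  m <- if (weight_by_length) {
    sum(vals[ok] * lens[ok]) / sum(lens[ok])
  } else {
    mean(vals[ok])
  }
  list(mean_ists = m, per_window = vals, n_skipped = sum(!ok))
}

#' Within-event ISTS table for all dyads and ROIs
#'
#' @param dataset A `dyad_dataset`.
#' @param windows An `event_windows` (typically from the DMN segmentation
#'   fitted on all couples pooled, applied to every ROI).
#' @param dyads Dyad table to evaluate; defaults to the dataset's.
#' @param roi_ids ROIs to include.
#' @param weight_by_length Passed to [within_window_ists()].
#' @return An `ists_table` whose values are within-event means.
#' @export
within_event_ists_table <- function(dataset, windows, dyads = dataset$dyads,
                                    roi_ids = dataset$rois,
                                    weight_by_length = FALSE) {
  values <- matrix(NA_real_, nrow(dyads), length(roi_ids),
                   dimnames = list(dyads$dyad_id, roi_ids))
  for (j in seq_along(roi_ids)) {
    roi <- roi_ids[j]
    for (i in seq_len(nrow(dyads))) {
      a <- get_timeseries(dataset, dyads$male_id[i], roi)
      b <- get_timeseries(dataset, dyads$female_id[i], roi)
      values[i, j] <- within_window_ists(a, b, windows,
                                         weight_by_length = weight_by_length)$mean_ists
    }
  }
  structure(list(values = values, zvalues = NULL, dyads = dyads,
                 roi_ids = roi_ids, windows = windows),
            class = "ists_table")
}
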