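# Pattern-trajectory matrices and inter-subject trajectory similarity (ISTS).
#
# For one subject and ROI, the multi-voxel pattern (MVP) at TR t is the
# V-vector of voxel activities. The pattern trajectory matrix is the T x T
# matrix of Pearson correlations between the MVPs at every pair of TRs; it
# encodes how the spatial response pattern evolves. ISTS for a dyad is the
# Pearson correlation between the two subjects' vectorized trajectory
# matrices (strict upper triangle; the unit diagonal carries no information).

#' Build the TR-by-TR pattern trajectory matrix
#'
#' @param ts A `roi_timeseries`.
#' @param tr_mask Optional TR subset: logical vector of length T or 0-based
#'   integer indices. Masking selects the TRs *before* correlation, so only
#'   within-condition temporal structure is compared.
#' @return A `trajectory_matrix`: symmetric T' x T' correlation matrix with
#'   unit diagonal; TRs whose MVP has zero variance across voxels yield NA
#'   rows/columns (with a warning).
#' @export
build_trajectory_matrix <- function(ts, tr_mask = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"))
  X <- ts$data
  if (!is.null(tr_mask)) {
    if (is.logical(tr_mask)) {
      stopifnot(length(tr_mask) == ncol(X))
      keep <- which(tr_mask)
    } else {
      keep <- as.integer(tr_mask) + 1L # 0-based on disk, 1-based in R
      stopifnot(all(keep >= 1L), all(keep <= ncol(X)))
    }
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) < 3L) stop("fewer than 3 TRs after masking")
  sds <- apply(X, 2L, stats::sd)
  bad <- sds == 0
  m <- matrix(NA_real_, ncol(X), ncol(X))
  if (sum(!bad) < 3L) stop("fewer than 3 TRs with non-degenerate MVPs")
  if (any(bad)) {
    warning(sprintf("%d TR(s) with zero-variance MVP set to missing", sum(bad)))
  }
  m[!bad, !bad] <- stats::cor(X[, !bad, drop = FALSE])
  diag(m)[!bad] <- 1
  structure(m, class = c("trajectory_matrix", "matrix"),
            subject_id = ts$subject_id, roi_id = ts$roi_id)
}

#' Inter-subject trajectory similarity between two trajectory matrices
#'
#' Pearson correlation between the vectorized strict upper triangles,
#' missing entries dropped pairwise-complete.
#'
#' @param a,b `trajectory_matrix` objects of identical dimension.
#' @return ISTS in `[-1, 1]`, or NA (with a warning) if fewer than 3 valid
#'   paired entries remain.
#' @export
compute_ists <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("trajectory matrices differ in shape")
  ut <- upper.tri(a)
  va <- a[ut]; vb <- b[ut]
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 3L) {
    warning("fewer than 3 valid trajectory entries; ISTS undefined")
    return(NA_real_)
  }
  if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) {
    warning("constant trajectory vector; ISTS undefined")
    return(NA_real_)
  }
  stats::cor(va[ok], vb[ok])
}

#' Random (non-couple) male-female pairings
#'
#' Draws a derangement of wives against husbands: each male is paired with
#' exactly one female who is not his own wife, and no female is reused —
#' the null class against which couple ISTS is compared.
#'
#' @param dyads Dyad table whose couple rows define the spouse map.
#' @param seed Integer seed (rejection sampling of permutations).
#' @return A dyad table of class `"random"` rows.
#' @export
make_random_pairs <- function(dyads, seed = 1L) {
  couples <- dyads[dyads$dyad_class != "random", , drop = FALSE]
  n <- nrow(couples)
  if (n < 2L) stop("need at least 2 couples to form a derangement")
  set.seed(seed)
  repeat {
    perm <- sample.int(n)
    if (all(perm != seq_len(n))) break
  }
  data.frame(
    dyad_id = sprintf("R%03d", seq_len(n)),
    male_id = couples$male_id,
    female_id = couples$female_id[perm],
    dyad_class = "random",
    cmqi_score = NA_real_,
    marriage_duration = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Compute the dyad-by-ROI ISTS table for a dataset
#'
#' Builds each subject's trajectory matrix once per ROI, then correlates the
#' two members of every dyad.
#'
#' @param dataset A `dyad_dataset`.
#' @param dyads Dyad table to evaluate; defaults to the dataset's own table.
#' @param tr_mask Optional TR mask passed to [build_trajectory_matrix()], or
#'   a condition label to select from the dataset's condition mask.
#' @param roi_ids ROIs to include; defaults to all.
#' @return An `ists_table`: list with `values` (dyad x ROI matrix), `dyads`,
#'   and empty `zvalues` until [zscore_across_dyads()] is applied.
#' @export
compute_ists_table <- function(dataset, dyads = dataset$dyads, tr_mask = NULL,
                               roi_ids = dataset$rois) {
  if (is.character(tr_mask) && length(tr_mask) == 1L) {
    if (is.null(dataset$condition_mask)) stop("dataset has no condition mask")
    tr_mask <- dataset$condition_mask == tr_mask
  }
  subjects <- unique(c(dyads$male_id, dyads$female_id))
  values <- matrix(NA_real_, nrow(dyads), length(roi_ids),
                   dimnames = list(dyads$dyad_id, roi_ids))
  for (j in seq_along(roi_ids)) {
    roi <- roi_ids[j]
    tm <- lapply(stats::setNames(subjects, subjects), function(s) {
      build_trajectory_matrix(get_timeseries(dataset, s, roi), tr_mask = tr_mask)
    })
    for (i in seq_len(nrow(dyads))) {
      values[i, j] <- compute_ists(tm[[dyads$male_id[i]]], tm[[dyads$female_id[i]]])
    }
  }
  structure(list(values = values, zvalues = NULL, dyads = dyads,
                 roi_ids = roi_ids),
            class = "ists_table")
}

#' @export
print.ists_table <- function(x, ...) {
  cat(sprintf("<ists_table> %d dyads x %d ROIs (z-scored: %s)\n",
              nrow(x$values), ncol(x$values), !is.null(x$zvalues)))
  invisible(x)
}

#' Z-score ISTS across dyads per ROI (ISTS-Z)
#'
#' Normalisation pools the included dyad classes (by default couples of both
#' satisfaction levels together with random pairs), so each ROI's ISTS-Z has
#' mean 0 and SD 1 across those dyads.
#'
#' @param table An `ists_table`.
#' @param classes_included Dyad classes pooled for the normalisation.
#' @return The table with `zvalues` filled; ROIs with zero SD get NA z-values
#'   and a warning.
#' @export
zscore_across_dyads <- function(table,
                                classes_included = c("couple_high", "couple_low", "random")) {
  stopifnot(inherits(table, "ists_table"))
  inc <- table$dyads$dyad_class %in% classes_included
  if (sum(inc) < 3L) stop("need at least 3 dyads in the included classes")
  v <- table$values
  z <- v
  n_degenerate <- 0L
  for (j in seq_len(ncol(v))) {
    mu <- mean(v[inc, j], na.rm = TRUE)
    s <- stats::sd(v[inc, j], na.rm = TRUE)
    if (is.na(s) || s == 0) {
      z[, j] <- NA_real_
      n_degenerate <- n_degenerate + 1L
    } else {
      z[, j] <- (v[, j] - mu) / s
    }
  }
  if (n_degenerate > 0L) {
    warning(sprintf("%d ROI(s) with zero ISTS variance: z-values set to missing",
                    n_degenerate))
  }
  table$zvalues <- z
  table$z_classes <- classes_included
  table
}

#' Whole-brain (or network-restricted) average ISTS per dyad
#'
#' @param table An `ists_table`.
#' @param roi_ids ROIs to average over (e.g. a network's ROIs); default all.
#' @param use_z Average the z-scored values instead of raw ISTS.
#' @return Data frame with dyad_id, mean ISTS, and the number of ROIs that
#'   contributed (missing entries are skipped).
#' @export
whole_brain_average <- function(table, roi_ids = table$roi_ids, use_z = FALSE) {
  stopifnot(inherits(table, "ists_table"))
  m <- if (use_z) table$zvalues else table$values
  if (is.null(m)) stop("z-values requested but not computed")
  sel <- m[, as.character(roi_ids), drop = FALSE]
  data.frame(
    dyad_id = rownames(sel),
    mean_ists = rowMeans(sel, na.rm = TRUE),
    n_rois = rowSums(!is.na(sel)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
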