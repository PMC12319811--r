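#' @importFrom stats cor sd var aov t.test cor.test p.adjust rnorm runif
#' @importFrom utils head tail
NULL

# Seven canonical resting/task networks of the default parcellation.
NETWORKS <- c("VN", "SMN", "DAN", "VAN", "LN", "CEN", "DMN")

#' Construct a per-subject, per-ROI voxel-by-TR time series
#'
#' The raw material of every downstream stage: the BOLD signal of all voxels
#' in one region of interest (ROI) for one subject, one column per TR.
#'
#' @param subject_id Character scalar.
#' @param roi_id Integer ROI index (1-based).
#' @param data Numeric matrix, voxels x TRs. At least 3 voxels and 3 TRs are
#'   required; a multi-voxel pattern (one column) with fewer than 3 voxels
#'   has a degenerate Pearson correlation.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(subject_id, roi_id, data) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time series data must be numeric")
  if (anyNA(data) || any(!is.finite(data))) {
    stop(sprintf("non-finite values in time series of subject %s, ROI %d",
                 subject_id, as.integer(roi_id)))
  }
  if (nrow(data) < 3L || ncol(data) < 3L) {
    stop(sprintf("subject %s, ROI %d: need >= 3 voxels and >= 3 TRs, got %d x %d",
                 subject_id, as.integer(roi_id), nrow(data), ncol(data)))
  }
  zero_var <- which(apply(data, 2L, stats::sd) == 0)
  structure(
    list(subject_id = as.character(subject_id),
         roi_id = as.integer(roi_id),
         data = unname(data),
         zero_variance_trs = zero_var),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> subject %s, ROI %d: %d voxels x %d TRs\n",
              x$subject_id, x$roi_id, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Validate a parcellation table
#'
#' @param df Data frame with columns `roi_id`, `roi_name`, `network`.
#' @return The validated data frame.
#' @export
validate_parcellation <- function(df) {
  stopifnot(all(c("roi_id", "roi_name", "network") %in% names(df)))
  if (anyDuplicated(df$roi_id)) stop("duplicate roi_id in parcellation")
  bad <- setdiff(unique(df$network), NETWORKS)
  if (length(bad)) stop("unknown network label(s): ", paste(bad, collapse = ", "))
  df$roi_id <- as.integer(df$roi_id)
  df[order(df$roi_id), , drop = FALSE]
}

#' Validate a dyad table
#'
#' Checks the class/threshold consistency (CMQI > 60 for highly satisfied
#' couples, < 60 for low satisfaction) and that no random pairing puts a
#' husband with his own wife.
#'
#' @param df Data frame with columns `dyad_id`, `male_id`, `female_id`,
#'   `dyad_class`, `cmqi_score`, `marriage_duration`.
#' @param spouse_of Optional named character vector mapping each male_id of a
#'   real couple to his wife's female_id; used to verify random pairings.
#' @return The validated data frame.
#' @export
validate_dyads <- function(df, spouse_of = NULL) {
  need <- c("dyad_id", "male_id", "female_id", "dyad_class")
  stopifnot(all(need %in% names(df)))
  if (!"cmqi_score" %in% names(df)) df$cmqi_score <- NA_real_
  if (!"marriage_duration" %in% names(df)) df$marriage_duration <- NA_real_
  if (any(df$male_id == df$female_id)) stop("invalid dyad: subject paired with themself")
  ok_class <- df$dyad_class %in% c("couple_high", "couple_low", "random")
  if (!all(ok_class)) stop("unknown dyad_class: ", paste(unique(df$dyad_class[!ok_class]), collapse = ", "))
  couples <- df$dyad_class != "random"
  sc <- df$cmqi_score[couples]
  cl <- df$dyad_class[couples]
  if (any(is.na(sc))) stop("couple dyad missing cmqi_score")
  if (any(cl == "couple_high" & sc <= 60) || any(cl == "couple_low" & sc >= 60)) {
    stop("dyad_class inconsistent with CMQI threshold of 60")
  }
  if (is.null(spouse_of)) {
    spouse_of <- stats::setNames(df$female_id[couples], df$male_id[couples])
  }
  rnd <- df[df$dyad_class == "random", , drop = FALSE]
  if (nrow(rnd)) {
    own <- !is.na(spouse_of[rnd$male_id]) & spouse_of[rnd$male_id] == rnd$female_id
    if (any(own)) stop("invalid dyad: random pair matches a real couple")
    if (anyDuplicated(rnd$female_id) || anyDuplicated(rnd$male_id)) {
      stop("random pairing reuses a subject")
    }
  }
  df
}

#' Assemble a validated dyadic dataset
#'
#' @param timeseries List of `roi_timeseries` objects.
#' @param parcellation Parcellation data frame (`roi_id`, `roi_name`, `network`).
#' @param dyads Dyad table data frame.
#' @param condition_mask Optional per-TR label vector (length T), e.g.
#'   `"marital"` / `"non_marital"` / `"none"`.
#' @param clip_table Optional data frame (`clip_id`, `start_tr`, `end_tr`,
#'   `theme`); TR intervals are 0-based half-open `[start_tr, end_tr)`.
#' @return An object of class `dyad_dataset`.
#' @export
dyad_dataset <- function(timeseries, parcellation, dyads,
                         condition_mask = NULL, clip_table = NULL) {
  stopifnot(length(timeseries) > 0L)
  ok <- vapply(timeseries, inherits, logical(1), "roi_timeseries")
  if (!all(ok)) stop("timeseries must be a list of roi_timeseries objects")
  parcellation <- validate_parcellation(parcellation)
  dyads <- validate_dyads(dyads)

  subjects <- sort(unique(vapply(timeseries, `[[`, character(1), "subject_id")))
  rois <- sort(unique(vapply(timeseries, `[[`, integer(1), "roi_id")))
  t_all <- vapply(timeseries, function(ts) ncol(ts$data), integer(1))
  if (length(unique(t_all)) != 1L) stop("all time series must share the same number of TRs")
  n_tr <- t_all[[1L]]

  unknown_roi <- setdiff(rois, parcellation$roi_id)
  if (length(unknown_roi)) stop("time series reference ROI(s) absent from parcellation: ",
                                paste(unknown_roi, collapse = ", "))
  dyad_subj <- unique(c(dyads$male_id, dyads$female_id))
  missing_subj <- setdiff(dyad_subj, subjects)
  if (length(missing_subj)) stop("dyad table references unknown subject(s): ",
                                 paste(missing_subj, collapse = ", "))

  if (!is.null(condition_mask)) {
    if (length(condition_mask) != n_tr) stop("condition mask length must equal T")
  }
  if (!is.null(clip_table)) {
    stopifnot(all(c("clip_id", "start_tr", "end_tr") %in% names(clip_table)))
    ct <- clip_table[order(clip_table$start_tr), , drop = FALSE]
    if (any(ct$start_tr < 0) || any(ct$end_tr > n_tr) || any(ct$end_tr <= ct$start_tr)) {
      stop("clip intervals must be non-empty and within [0, T)")
    }
    if (nrow(ct) > 1L && any(ct$start_tr[-1L] < ct$end_tr[-nrow(ct)])) {
      stop("clip intervals overlap")
    }
    clip_table <- ct
  }

  # index by subject then ROI for O(1) lookup
  index <- stats::setNames(vector("list", length(subjects)), subjects)
  for (ts in timeseries) index[[ts$subject_id]][[as.character(ts$roi_id)]] <- ts

  structure(
    list(timeseries = index, parcellation = parcellation, dyads = dyads,
         condition_mask = condition_mask, clip_table = clip_table,
         subjects = subjects, rois = rois, n_tr = n_tr),
    class = "dyad_dataset"
  )
}

#' @export
print.dyad_dataset <- function(x, ...) {
  cat(sprintf("<dyad_dataset> %d subjects, %d ROIs, T = %d TRs, %d dyads (%s)\n",
              length(x$subjects), length(x$rois), x$n_tr, nrow(x$dyads),
              paste(sprintf("%s: %d", names(table(x$dyads$dyad_class)),
                            table(x$dyads$dyad_class)), collapse = ", ")))
  invisible(x)
}

#' Fetch one subject's time series in one ROI
#' @param dataset A `dyad_dataset`.
#' @param subject_id,roi_id Which series.
#' @return The `roi_timeseries`.
#' @export
get_timeseries <- function(dataset, subject_id, roi_id) {
  ts <- dataset$timeseries[[subject_id]][[as.character(roi_id)]]
  if (is.null(ts)) stop(sprintf("no time series for subject %s, ROI %d", subject_id, roi_id))
  ts
}

# Full-precision numeric TSV: %.17g round-trips IEEE doubles exactly.
write_matrix_tsv <- function(mat, path) {
  lines <- apply(mat, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
}

read_matrix_tsv <- function(path) {
  as.matrix(data.table::fread(path, header = FALSE, sep = "\t"))
}

#' Write a dataset to the on-disk layout
#'
#' Layout: `data/<subject>/roi_<k>.tsv` (voxel x TR matrix, full precision),
#' `parcellation.tsv`, `dyads.tsv`, optional `clips.tsv` and
#' `condition_mask.tsv`, and a `manifest.json` tying it together. All TR
#' indices on disk are 0-based with half-open intervals.
#'
#' @param dataset A `dyad_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  files <- list()
  for (subj in dataset$subjects) {
    sdir <- file.path(dir, "data", subj)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    for (roi in names(dataset$timeseries[[subj]])) {
      ts <- dataset$timeseries[[subj]][[roi]]
      rel <- file.path("data", subj, sprintf("roi_%s.tsv", roi))
      write_matrix_tsv(ts$data, file.path(dir, rel))
      files[[length(files) + 1L]] <- list(subject_id = subj,
                                          roi_id = as.integer(roi), path = rel)
    }
  }
  data.table::fwrite(dataset$parcellation, file.path(dir, "parcellation.tsv"), sep = "\t")
  data.table::fwrite(dataset$dyads, file.path(dir, "dyads.tsv"), sep = "\t")
  if (!is.null(dataset$clip_table)) {
    data.table::fwrite(dataset$clip_table, file.path(dir, "clips.tsv"), sep = "\t")
  }
  if (!is.null(dataset$condition_mask)) {
    data.table::fwrite(
      data.frame(tr = seq_along(dataset$condition_mask) - 1L,
                 label = dataset$condition_mask),
      file.path(dir, "condition_mask.tsv"), sep = "\t")
  }
  manifest <- list(
    n_tr = dataset$n_tr,
    files = files,
    parcellation = "parcellation.tsv",
    dyads = "dyads.tsv",
    clips = if (!is.null(dataset$clip_table)) "clips.tsv",
    condition_mask = if (!is.null(dataset$condition_mask)) "condition_mask.tsv"
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(mpath)
}

#' Load and validate a dataset from a manifest
#'
#' Every file named by the manifest must exist; dyads must reference known
#' subjects; every matrix must satisfy the `roi_timeseries` invariants.
#'
#' @param manifest_path Path to `manifest.json` written by [write_dataset()].
#' @return A validated `dyad_dataset`.
#' @export
load_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  root <- dirname(manifest_path)
  manifest <- jsonlite::read_json(manifest_path)
  ts_list <- lapply(manifest$files, function(f) {
    p <- file.path(root, f$path)
    if (!file.exists(p)) stop("missing data file: ", p)
    roi_timeseries(f$subject_id, f$roi_id, read_matrix_tsv(p))
  })
  parc <- as.data.frame(data.table::fread(file.path(root, manifest$parcellation)))
  dyads <- as.data.frame(data.table::fread(file.path(root, manifest$dyads)))
  clip_table <- NULL
  if (!is.null(manifest$clips)) {
    clip_table <- as.data.frame(data.table::fread(file.path(root, manifest$clips)))
  }
  condition_mask <- NULL
  if (!is.null(manifest$condition_mask)) {
    cm <- as.data.frame(data.table::fread(file.path(root, manifest$condition_mask)))
    condition_mask <- cm$label[order(cm$tr)]
  }
  dyad_dataset(ts_list, parc, dyads, condition_mask = condition_mask,
               clip_table = clip_table)
}

#' Write result tables and a machine-readable summary
#'
#' Each element of `tables` that is a data frame is written as a TSV with a
#' deterministic column order (as given); scalar summaries are collected into
#' `summary.json`. Re-running with identical inputs yields identical files.
#'
#' @param tables Named list of data frames and/or scalar summaries.
#' @param out_dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("unwritable output directory: ", out_dir)
  stopifnot(!is.null(names(tables)), all(nzchar(names(tables))))
  paths <- character(0)
  summary <- list()
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      data.table::fwrite(x, p, sep = "\t")
      paths <- c(paths, p)
      summary[[nm]] <- list(rows = nrow(x), columns = names(x))
    } else {
      summary[[nm]] <- x
    }
  }
  sp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, sp))
}

#' Long-format export of an ISTS table
#'
#' @param table An `ists_table` (see [compute_ists_table()]).
#' @param scope Character tag recorded in the `scope` column (e.g.
#'   `"full_run"`, `"within_event"`, `"within_clip"`).
#' @return A data frame with columns dyad_id, roi_id, ists, ists_z, scope.
#' @export
ists_long_format <- function(table, scope = "full_run") {
  stopifnot(inherits(table, "ists_table"))
  v <- table$values
  z <- table$zvalues
  data.frame(
    dyad_id = rep(rownames(v), times = ncol(v)),
    roi_id = rep(as.integer(colnames(v)), each = nrow(v)),
    ists = as.vector(v),
    ists_z = if (is.null(z)) NA_real_ else as.vector(z),
    scope = scope,
    stringsAsFactors = FALSE
  )
}
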