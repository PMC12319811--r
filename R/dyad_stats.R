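# Group statistics and PLS-1 inference relating regional ISTS to
# satisfaction: the first partial-least-squares component is the ROI weight
# vector maximising covariance between weighted ISTS and the satisfaction
# score; its significance is assessed by permutation of the scores, regional
# reliability by bootstrap z values with FDR control.

center_cols <- function(X) sweep(X, 2L, colMeans(X))

# squared covariance between the first PLS score and y; for univariate y
# this equals ||Xc' yc||^2 / (n - 1)^2, which the permutation test exploits
pls1_stat <- function(Xc, yc) {
  n <- length(yc)
  sum(crossprod(Xc, yc)^2) / (n - 1)^2
}

#' First partial-least-squares component (PLS-1)
#'
#' Finds the unit ROI-weight vector maximising covariance between the
#' weighted ISTS profile and the satisfaction score (both centred
#' internally). The sign convention makes the score-satisfaction correlation
#' non-negative.
#'
#' @param X Dyad x ROI matrix of ISTS values.
#' @param y Satisfaction score per dyad.
#' @return List of class `pls1_fit`: `weights` (unit norm), `scores`
#'   (`X_c w`), `covariance_explained` (squared covariance of the first
#'   score with y), and `score_cor` (Pearson r of score with y).
#' @export
pls1_fit <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 3L)
  if (stats::sd(y) == 0) stop("satisfaction scores have zero variance")
  Xc <- center_cols(X)
  yc <- y - mean(y)
  # first left singular vector of the cross-covariance Xc' yc
  cc <- crossprod(Xc, yc)
  sv <- svd(cc, nu = 1L, nv = 0L)
  w <- drop(sv$u)
  scores <- drop(Xc %*% w)
  if (stats::cor(scores, y) < 0) {
    w <- -w
    scores <- -scores
  }
  structure(
    list(weights = w, scores = scores,
         covariance_explained = stats::cov(scores, y)^2,
         score_cor = stats::cor(scores, y)),
    class = "pls1_fit"
  )
}

#' Permutation test of the PLS-1 covariance
#'
#' Shuffles the satisfaction scores across dyads and compares the covariance
#' explained by PLS-1 against the null distribution; the add-one formula
#' p = (1 + #{null >= observed}) / (1 + n_perm) avoids p = 0.
#'
#' @param X Dyad x ROI ISTS matrix.
#' @param y Satisfaction scores.
#' @param n_perm Number of permutations (reference analysis: 5000).
#' @param seed Integer seed.
#' @return List with `p_value`, `observed` statistic, and the `null` vector.
#' @export
pls_permutation_test <- function(X, y, n_perm = 5000L, seed = 1L) {
  stopifnot(n_perm >= 100L)
  X <- as.matrix(X)
  Xc <- center_cols(X)
  yc <- y - mean(y)
  observed <- pls1_stat(Xc, yc)
  set.seed(seed)
  n <- length(y)
  perm_mat <- vapply(seq_len(n_perm), function(i) yc[sample.int(n)], numeric(n))
  null <- colSums(crossprod(Xc, perm_mat)^2) / (n - 1)^2
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  list(p_value = p, observed = observed, null = null)
}

#' Bootstrap z values for PLS-1 regional weights
#'
#' Resamples dyads with replacement, refits PLS-1, aligns each replicate's
#' sign to the original weights (PLS components are sign-indeterminate), and
#' forms z = w / SE_boot per ROI with normal-theory confidence intervals.
#'
#' @param X Dyad x ROI ISTS matrix.
#' @param y Satisfaction scores.
#' @param n_boot Bootstrap samples (reference analysis: 500).
#' @param seed Integer seed.
#' @param conf Confidence level for the intervals.
#' @return List with `z`, `se`, `ci` (ROI x 2), two-sided normal `p`,
#'   original `weights`, and the count of redrawn degenerate resamples.
#' @export
pls_bootstrap_z <- function(X, y, n_boot = 500L, seed = 1L, conf = 0.95) {
  stopifnot(n_boot >= 100L)
  X <- as.matrix(X)
  fit0 <- pls1_fit(X, y)
  set.seed(seed)
  n <- length(y)
  W <- matrix(NA_real_, n_boot, ncol(X))
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      ix <- sample.int(n, replace = TRUE)
      if (stats::sd(y[ix]) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    wb <- pls1_fit(X[ix, , drop = FALSE], y[ix])$weights
    if (sum(wb * fit0$weights) < 0) wb <- -wb
    W[b, ] <- wb
  }
  se <- apply(W, 2L, stats::sd)
  z <- fit0$weights / se
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- cbind(lower = fit0$weights - zq * se, upper = fit0$weights + zq * se)
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, se = se, ci = ci, p = p, weights = fit0$weights,
       n_redrawn = n_redrawn)
}

#' Benjamini-Hochberg FDR correction
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @param q FDR level.
#' @return List with the BH-`adjusted` p-values and the rejection `mask`
#'   (adjusted p below q).
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, mask = !is.na(adjusted) & adjusted < q)
}

#' Full PLS-1 inference: fit, permutation p, bootstrap z, FDR mask
#'
#' @param X Dyad x ROI ISTS matrix (columns named by ROI).
#' @param y Satisfaction scores.
#' @param n_perm,n_boot Permutation and bootstrap counts.
#' @param q FDR level for the regional mask.
#' @param seed Integer seed (permutations and bootstrap use derived seeds).
#' @return A `pls_result`: per-ROI table (weight, z, CI, p, significance)
#'   plus the permutation p-value and covariance explained.
#' @export
pls_inference <- function(X, y, n_perm = 5000L, n_boot = 500L, q = 0.05,
                          seed = 1L) {
  fit <- pls1_fit(X, y)
  perm <- pls_permutation_test(X, y, n_perm = n_perm, seed = seed)
  boot <- pls_bootstrap_z(X, y, n_boot = n_boot, seed = seed + 1L)
  fdr <- fdr_correct(boot$p, q = q)
  roi_ids <- colnames(as.matrix(X))
  if (is.null(roi_ids)) roi_ids <- as.character(seq_along(fit$weights))
  table <- data.frame(
    roi_id = roi_ids,
    weight = fit$weights,
    z = boot$z,
    ci_low = boot$ci[, "lower"],
    ci_high = boot$ci[, "upper"],
    p = boot$p,
    p_adjusted = fdr$adjusted,
    fdr_significant = fdr$mask,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(
    list(table = table, weights = fit$weights,
         covariance_explained = fit$covariance_explained,
         score_cor = fit$score_cor,
         p_permutation = perm$p_value, fdr_mask = fdr$mask),
    class = "pls_result"
  )
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> %d ROIs, cov explained = %.4g, permutation p = %.4g, %d FDR-significant\n",
              nrow(x$table), x$covariance_explained, x$p_permutation,
              sum(x$fdr_mask)))
  invisible(x)
}

cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Group comparisons of whole-brain ISTS
#'
#' Two-way ANOVA of dyad-level whole-brain ISTS on fMRI state (movie vs
#' rest) and marital status (high / low satisfaction / random pairs, or
#' couples only when `couples_only = TRUE`), plus pairwise Welch t-tests
#' with Cohen's d, and Pearson / Spearman correlations for the satisfaction
#' and marriage-duration analyses.
#'
#' @param df Long data frame with columns `value`, `status`, and optionally
#'   `state`.
#' @param couples_only Drop random pairs before the ANOVA (the 2 x 2 variant).
#' @return List with `anova` (effects table), `t_tests` (pairwise, per
#'   state when present), each row carrying t, df, p and Cohen's d.
#' @export
group_compare <- function(df, couples_only = FALSE) {
  stopifnot(all(c("value", "status") %in% names(df)))
  if (couples_only) df <- df[df$status != "random", , drop = FALSE]
  df$status <- factor(df$status)
  if (any(table(df$status) < 2L)) stop("need >= 2 observations per group")
  has_state <- "state" %in% names(df) && length(unique(df$state)) > 1L
  if (has_state) {
    df$state <- factor(df$state)
    fit <- stats::aov(value ~ state * status, data = df)
  } else {
    fit <- stats::aov(value ~ status, data = df)
  }
  an <- as.data.frame(summary(fit)[[1L]])
  an$term <- trimws(rownames(an))
  names(an) <- c("df", "sum_sq", "mean_sq", "F", "p", "term")
  rownames(an) <- NULL

  pairwise <- function(sub, state_label) {
    lv <- levels(droplevels(sub$status))
    out <- list()
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
      if (j <= i) next
      x <- sub$value[sub$status == lv[i]]
      y <- sub$value[sub$status == lv[j]]
      tt <- stats::t.test(x, y)
      out[[length(out) + 1L]] <- data.frame(
        state = state_label, group_1 = lv[i], group_2 = lv[j],
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, cohens_d = cohens_d(x, y),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  tt <- if (has_state) {
    do.call(rbind, lapply(levels(df$state), function(s) {
      pairwise(df[df$state == s, , drop = FALSE], s)
    }))
  } else {
    pairwise(df, NA_character_)
  }
  list(anova = an[, c("term", "df", "sum_sq", "mean_sq", "F", "p")],
       t_tests = tt)
}

#' Correlation of whole-brain ISTS with a dyad covariate
#'
#' @param ists Per-dyad whole-brain ISTS.
#' @param covariate Satisfaction score or marriage duration.
#' @param method `"pearson"` (satisfaction) or `"spearman"` (duration).
#' @return List with `r` and `p`.
#' @export
ists_correlation <- function(ists, covariate, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(ists) & !is.na(covariate)
  ct <- stats::cor.test(ists[ok], covariate[ok], method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value)
}
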