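# Ordered-state ("no-return") HMM event segmentation.
#
# Model: T observations (per-TR z-scored D-vectors) arise from K latent
# events visited strictly in order. Emissions are isotropic Gaussian around a
# per-state mean pattern with a single shared variance. From state k the
# chain stays at k or advances to k + 1; the advance probability is fixed at
# K / T (expected K events in T TRs), not learned — the structure, not the
# rate, is the modelling constraint. The chain starts in state 1 and the
# likelihood conditions on it finishing in state K, so every event is
# visited. Fitting is EM with exact forward-backward in log space;
# initialisation tiles the run into K equal contiguous blocks, so fitting is
# deterministic given the data.

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# z-score each TR's pattern across features (population SD, so the
# normalisation is invariant to duplicating features)
zscore_rows <- function(X) {
  mu <- rowMeans(X)
  s <- sqrt(rowSums((X - mu)^2) / ncol(X))
  if (any(s == 0)) stop("TR with zero pattern variance cannot be z-scored")
  (X - mu) / s
}

# T x K matrix of log N(x_t | mu_k, sigma2 I)
emission_logdens <- function(X, means, sigma2) {
  D <- ncol(X)
  d2 <- outer(rowSums(X^2), rowSums(means^2), "+") - 2 * X %*% t(means)
  d2[d2 < 0] <- 0
  -0.5 * D * log(2 * pi * sigma2) - d2 / (2 * sigma2)
}

# forward-backward under the ordered-state transition structure
forward_backward <- function(emit_log, advance_prob) {
  T <- nrow(emit_log); K <- ncol(emit_log)
  if (K == 1L) {
    ll <- sum(emit_log)
    return(list(log_likelihood = ll,
                posterior = matrix(1, T, 1L)))
  }
  log_adv <- log(advance_prob)
  log_stay <- c(rep(log1p(-advance_prob), K - 1L), 0) # final state absorbing

  alpha <- matrix(-Inf, T, K)
  alpha[1L, 1L] <- emit_log[1L, 1L]
  for (t in 2:T) {
    stay <- alpha[t - 1L, ] + log_stay
    adv <- c(-Inf, alpha[t - 1L, -K] + log_adv)
    alpha[t, ] <- emit_log[t, ] + logsumexp2(stay, adv)
  }
  ll <- alpha[T, K]

  beta <- matrix(-Inf, T, K)
  beta[T, K] <- 0
  for (t in (T - 1L):1L) {
    stay <- log_stay + emit_log[t + 1L, ] + beta[t + 1L, ]
    adv <- c(log_adv + emit_log[t + 1L, -1L] + beta[t + 1L, -1L], -Inf)
    beta[t, ] <- logsumexp2(stay, adv)
  }
  gamma <- exp(alpha + beta - ll)
  gamma <- gamma / rowSums(gamma) # renormalise away rounding
  list(log_likelihood = ll, posterior = gamma)
}

make_segmentation <- function(K, means, sigma2, posterior, ll, advance_prob,
                              trace = NULL, n_iter = NA_integer_, converged = NA) {
  assignment <- max.col(posterior, ties.method = "first")
  assignment <- cummax(assignment) # enforce the no-return invariant
  boundaries <- which(diff(assignment) > 0) # 0-based first TR of each new event
  structure(
    list(K = K, state_means = means, emission_var = sigma2,
         posterior = posterior, assignment = assignment,
         boundaries = as.integer(boundaries), log_likelihood = ll,
         advance_prob = advance_prob, loglik_trace = trace,
         n_iter = n_iter, converged = converged),
    class = "event_segmentation"
  )
}

#' @export
print.event_segmentation <- function(x, ...) {
  cat(sprintf("<event_segmentation> K = %d over %d TRs, logL = %.3f, boundaries: %s\n",
              x$K, nrow(x$posterior), x$log_likelihood,
              if (length(x$boundaries)) paste(x$boundaries, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Fit an ordered-state HMM event segmentation
#'
#' @param data T x D numeric matrix: one feature vector per TR (ROI-mean
#'   signals of a network, or voxels).
#' @param K Number of events (states); `K <= T`.
#' @param normalize Z-score each TR's pattern across features first (the
#'   model's reference preprocessing); set FALSE if already normalised.
#' @param tol Relative log-likelihood change declaring EM convergence.
#' @param max_iter EM iteration cap.
#' @param split_merge Optional post-EM refinement for uneven event lengths:
#'   repeatedly propose merging the most similar adjacent states while
#'   splitting the longest event, keeping K fixed; accept when the
#'   log-likelihood improves. Default off.
#' @return An `event_segmentation`: state means (K x D), shared emission
#'   variance, T x K posterior, per-TR assignment (non-decreasing), 0-based
#'   interior boundaries, and the EM log-likelihood trace.
#' @export
fit_event_hmm <- function(data, K, normalize = TRUE, tol = 1e-6,
                          max_iter = 200L, split_merge = FALSE) {
  X <- as.matrix(data)
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite values in feature series")
  T <- nrow(X); D <- ncol(X)
  if (K > T) stop(sprintf("K = %d exceeds T = %d", K, T))
  if (K < 1L) stop("K must be >= 1")
  if (normalize) X <- zscore_rows(X)

  blocks <- split(seq_len(T), pmin(K, ceiling(seq_len(T) * K / T)))
  means <- do.call(rbind, lapply(blocks, function(ix) colMeans(X[ix, , drop = FALSE])))
  fit <- em_run(X, K, means, tol, max_iter)

  if (split_merge && K >= 3L) fit <- split_merge_refine(X, K, fit, tol, max_iter)

  make_segmentation(K, fit$means, fit$sigma2, fit$fb$posterior,
                    fit$fb$log_likelihood, fit$advance_prob,
                    trace = fit$trace, n_iter = fit$n_iter,
                    converged = fit$converged)
}

em_run <- function(X, K, means, tol, max_iter) {
  T <- nrow(X); D <- ncol(X)
  p_adv <- K / T
  sigma2 <- max(mean((X - colMeans(X)[col(X)])^2), 1e-8)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  fb <- NULL
  for (iter in seq_len(max_iter)) {
    emit <- emission_logdens(X, means, sigma2)
    fb <- forward_backward(emit, p_adv)
    trace <- c(trace, fb$log_likelihood)
    if (is.finite(ll_prev) &&
        abs(fb$log_likelihood - ll_prev) < tol * max(1, abs(ll_prev))) {
      converged <- TRUE
      break
    }
    ll_prev <- fb$log_likelihood
    g <- fb$posterior
    nk <- colSums(g)
    means <- (t(g) %*% X) / nk
    d2 <- outer(rowSums(X^2), rowSums(means^2), "+") - 2 * X %*% t(means)
    d2[d2 < 0] <- 0
    sigma2 <- max(sum(g * d2) / (T * D), 1e-8)
  }
  list(means = means, sigma2 = sigma2, fb = fb, advance_prob = p_adv,
       trace = trace, n_iter = length(trace), converged = converged)
}

split_merge_refine <- function(X, K, fit, tol, max_iter, max_rounds = 5L) {
  for (round in seq_len(max_rounds)) {
    assignment <- cummax(max.col(fit$fb$posterior, ties.method = "first"))
    lens <- tabulate(assignment, K)
    # most similar adjacent pair by state-mean correlation
    sim <- vapply(seq_len(K - 1L), function(k) {
      stats::cor(fit$means[k, ], fit$means[k + 1L, ])
    }, numeric(1))
    merge_k <- which.max(sim)
    split_k <- which.max(lens)
    if (split_k %in% c(merge_k, merge_k + 1L) || lens[split_k] < 6L) break
    means <- fit$means
    merged <- colMeans(means[c(merge_k, merge_k + 1L), , drop = FALSE])
    ix <- which(assignment == split_k)
    half1 <- colMeans(X[ix[seq_len(floor(length(ix) / 2))], , drop = FALSE])
    half2 <- colMeans(X[ix[-seq_len(floor(length(ix) / 2))], , drop = FALSE])
    # rebuild the ordered mean list: adjacent pair merged, longest event split
    out <- list()
    for (k in seq_len(K)) {
      if (k == merge_k) { out[[length(out) + 1L]] <- merged; next }
      if (k == merge_k + 1L) next
      if (k == split_k) {
        out[[length(out) + 1L]] <- half1
        out[[length(out) + 1L]] <- half2
      } else {
        out[[length(out) + 1L]] <- means[k, ]
      }
    }
    cand <- em_run(X, K, do.call(rbind, out), tol, max_iter)
    if (cand$fb$log_likelihood > fit$fb$log_likelihood + 1e-9) fit <- cand else break
  }
  fit
}

#' Log-likelihood of held-out data under a fitted segmentation
#'
#' Forward-algorithm likelihood with state means and emission variance
#' frozen; the advance probability is K / T of the evaluated series.
#'
#' @param model An `event_segmentation`.
#' @param data T x D matrix; D must match the model.
#' @param normalize Apply the same per-TR z-scoring used at fit time.
#' @return Log-likelihood (scalar).
#' @export
held_out_loglik <- function(model, data, normalize = TRUE) {
  stopifnot(inherits(model, "event_segmentation"))
  X <- as.matrix(data)
  if (ncol(X) != ncol(model$state_means)) {
    stop(sprintf("feature dimension %d does not match model (%d)",
                 ncol(X), ncol(model$state_means)))
  }
  if (normalize) X <- zscore_rows(X)
  emit <- emission_logdens(X, model$state_means, model$emission_var)
  forward_backward(emit, model$K / nrow(X))$log_likelihood
}

#' Interior event boundaries of a fitted segmentation
#'
#' @param model An `event_segmentation`.
#' @return 0-based TR indices at which the state assignment increments.
#' @export
extract_boundaries <- function(model) {
  stopifnot(inherits(model, "event_segmentation"))
  model$boundaries
}

#' Group-average feature series
#'
#' Averages subjects' series after per-TR pattern z-scoring, the standard
#' group series for event segmentation (idiosyncratic fluctuations average
#' out, the shared stimulus-locked structure remains).
#'
#' @param data_list List of T x D matrices, one per subject.
#' @return T x D matrix.
#' @export
average_subjects <- function(data_list) {
  zs <- lapply(data_list, zscore_rows)
  Reduce(`+`, zs) / length(zs)
}

#' Select the number of events by nested cross-validation
#'
#' Outer loop: each subject in turn is held out as the test subject; the
#' remainder are randomly split into training and validation sets whose
#' (per-TR z-scored) series are each averaged. Inner loop: every K in
#' `k_range` is fitted on the training average and scored on the validation
#' average; K* maximises the mean validation log-likelihood across outer
#' folds (ties to the smaller K). A final model with K* is fitted to the
#' grand average and to each held-out subject.
#'
#' @param data_list List of T x D matrices, one per subject.
#' @param k_range Candidate numbers of events (truncated at T with a warning
#'   if needed).
#' @param n_train,n_valid Inner split sizes; default reproduces the reference
#'   ratio 27:8 of the inner-loop subject count.
#' @param seed Integer seed controlling the fold splits.
#' @param refit_test Also fit a K*-state model per held-out subject.
#' @return List with `k_star`, `fold_loglik` (fold x K validation matrix),
#'   `mean_loglik`, the final `model` on the grand average, and per-subject
#'   test models if requested.
#' @export
select_num_states <- function(data_list, k_range = 1:10, n_train = NULL,
                              n_valid = NULL, seed = 1L, refit_test = FALSE) {
  n <- length(data_list)
  stopifnot(n >= 3L)
  T <- nrow(data_list[[1L]])
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range > T)) {
    warning(sprintf("k_range truncated at T = %d", T))
    k_range <- k_range[k_range <= T]
  }
  inner_n <- n - 1L
  if (is.null(n_train)) n_train <- max(1L, round(inner_n * 27 / 35))
  if (is.null(n_valid)) n_valid <- inner_n - n_train
  if (n_train + n_valid != inner_n || n_valid < 1L) {
    stop("train and validation sizes must partition the inner-loop subjects")
  }

  fold_ll <- matrix(NA_real_, n, length(k_range),
                    dimnames = list(NULL, k_range))
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    set.seed(seed + i)
    perm <- sample(rest)
    train_avg <- average_subjects(data_list[perm[seq_len(n_train)]])
    valid_avg <- average_subjects(data_list[perm[n_train + seq_len(n_valid)]])
    for (j in seq_along(k_range)) {
      m <- fit_event_hmm(train_avg, k_range[j], normalize = TRUE)
      fold_ll[i, j] <- held_out_loglik(m, valid_avg, normalize = TRUE)
    }
  }
  mean_ll <- colMeans(fold_ll)
  k_star <- k_range[which.max(mean_ll)]

  grand <- average_subjects(data_list)
  final <- fit_event_hmm(grand, k_star, normalize = TRUE)
  test_models <- NULL
  if (refit_test) {
    test_models <- lapply(data_list, function(d) fit_event_hmm(d, k_star, normalize = TRUE))
  }
  list(k_star = k_star, fold_loglik = fold_ll, mean_loglik = mean_ll,
       k_range = k_range, model = final, test_models = test_models)
}

#' Compare event segmentations between two groups
#'
#' Runs [select_num_states()] independently per group (e.g. highly vs less
#' satisfied couples) on the same network features and tabulates the selected
#' number of events and boundaries.
#'
#' @param group_a,group_b Lists of T x D matrices (subjects per group).
#' @param k_range,seed,... Passed to [select_num_states()].
#' @return List with the per-group selections and a one-row comparison table.
#' @export
compare_group_segmentations <- function(group_a, group_b, k_range = 1:10,
                                        seed = 1L, ...) {
  sel_a <- select_num_states(group_a, k_range = k_range, seed = seed, ...)
  sel_b <- select_num_states(group_b, k_range = k_range, seed = seed, ...)
  list(
    a = sel_a, b = sel_b,
    table = data.frame(
      k_star_a = sel_a$k_star, k_star_b = sel_b$k_star,
      boundaries_a = paste(sel_a$model$boundaries, collapse = ","),
      boundaries_b = paste(sel_b$model$boundaries, collapse = ","),
      stringsAsFactors = FALSE
    )
  )
}

#' Assemble network-level feature series from a dataset
#'
#' The default feature vector at each TR is the mean BOLD signal of each ROI
#' in the network (TR x n_rois); `level = "voxel"` concatenates the network's
#' voxels instead.
#'
#' @param dataset A `dyad_dataset`.
#' @param subject_id Subject whose series to assemble.
#' @param network Network label (e.g. `"DMN"`); `NULL` uses all ROIs.
#' @param level `"roi_mean"` or `"voxel"`.
#' @return T x D numeric matrix.
#' @export
network_features <- function(dataset, subject_id, network = NULL,
                             level = c("roi_mean", "voxel")) {
  level <- match.arg(level)
  parc <- dataset$parcellation
  rois <- if (is.null(network)) dataset$rois else parc$roi_id[parc$network == network]
  rois <- intersect(rois, dataset$rois)
  if (!length(rois)) stop("no ROIs in network: ", network)
  cols <- lapply(rois, function(r) {
    d <- get_timeseries(dataset, subject_id, r)$data
    if (level == "roi_mean") matrix(colMeans(d), ncol = 1L) else t(d)
  })
  do.call(cbind, cols)
}
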