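test_that("a single-state model spans all TRs with the data's mean pattern", {
  set.seed(21)
  X <- matrix(rnorm(30 * 6), 30, 6)
  m <- fit_event_hmm(X, 1)
  expect_identical(m$boundaries, integer(0))
  expect_true(all(m$assignment == 1))
  expect_equal(drop(m$state_means), colMeans(dyadsync:::zscore_rows(X)),
               tolerance = 1e-8)
  expect_equal(rowSums(m$posterior), rep(1, 30))
})

test_that("a clean two-event switch is recovered within one TR", {
  for (s in 1:5) {
    d <- make_event_data(K = 2, T = 40, D = 8, contrast = 2, noise_sd = 0.3,
                         seed = s, boundaries = 20)
    m <- fit_event_hmm(d$X, 2)
    expect_true(abs(m$boundaries - 20) <= 1)
  }
})

test_that("forward log-likelihood equals exhaustive monotone-path enumeration", {
  set.seed(77)
  for (i in 1:15) {
    T <- sample(3:6, 1)
    K <- sample(1:min(3, T), 1)
    X <- matrix(rnorm(T * 4), T, 4)
    Xz <- dyadsync:::zscore_rows(X)
    means <- matrix(rnorm(K * 4), K, 4)
    sigma2 <- runif(1, 0.5, 2)
    emit <- dyadsync:::emission_logdens(Xz, means, sigma2)
    fb <- dyadsync:::forward_backward(emit, K / T)
    expect_equal(fb$log_likelihood,
                 enumerate_monotone_loglik(emit, K / T), tolerance = 1e-8)
    expect_equal(rowSums(fb$posterior), rep(1, T), tolerance = 1e-8)
  }
})

test_that("EM log-likelihood is non-decreasing on every fit", {
  set.seed(5)
  for (i in 1:5) {
    X <- matrix(rnorm(50 * 6), 50, 6)
    m <- fit_event_hmm(X, sample(2:5, 1))
    expect_true(all(diff(m$loglik_trace) > -1e-9))
  }
  d <- make_event_data(K = 4, T = 80, D = 10, contrast = 3, noise_sd = 0.5, seed = 8)
  m <- fit_event_hmm(d$X, 4)
  expect_true(all(diff(m$loglik_trace) > -1e-9))
  expect_true(m$converged)
})

test_that("held-out likelihood prefers the true model and matches enumeration", {
  d <- make_event_data(K = 3, T = 60, D = 8, contrast = 3, noise_sd = 0.4, seed = 3)
  m <- fit_event_hmm(d$X, 3)
  ll_true <- held_out_loglik(m, d$X)
  # permuting the state means destroys the temporal ordering
  m_perm <- m
  m_perm$state_means <- m$state_means[c(2, 3, 1), ]
  expect_gt(ll_true, held_out_loglik(m_perm, d$X))

  # small-instance agreement with the enumeration oracle
  set.seed(9)
  Xs <- matrix(rnorm(5 * 4), 5, 4)
  ms <- fit_event_hmm(Xs, 2)
  emit <- dyadsync:::emission_logdens(dyadsync:::zscore_rows(Xs),
                                      ms$state_means, ms$emission_var)
  expect_equal(held_out_loglik(ms, Xs),
               enumerate_monotone_loglik(emit, 2 / 5), tolerance = 1e-8)

  expect_error(held_out_loglik(ms, matrix(rnorm(10), 5, 2)), "dimension")
})

test_that("duplicating features exactly doubles the single-state likelihood", {
  # Gaussian emission check: with K = 1 the log-likelihood is a sum of
  # per-feature quadratic terms, so doubling the features doubles it
  set.seed(31)
  X <- matrix(rnorm(20 * 5), 20, 5)
  m1 <- fit_event_hmm(X, 1)
  m2 <- fit_event_hmm(cbind(X, X), 1)
  expect_equal(m2$log_likelihood, 2 * m1$log_likelihood, tolerance = 1e-6)
})

test_that("boundaries come from assignment increments and count K - 1", {
  d <- make_event_data(K = 4, T = 60, D = 10, contrast = 4, noise_sd = 0.4, seed = 12)
  m <- fit_event_hmm(d$X, 4)
  expect_equal(extract_boundaries(m),
               which(diff(m$assignment) > 0))
  expect_length(m$boundaries, length(unique(m$assignment)) - 1)
  expect_true(all(diff(m$assignment) >= 0))
  # low-noise recovery within 1 TR of the generative truth
  expect_true(all(vapply(d$boundaries, function(b) {
    min(abs(m$boundaries - b)) <= 1
  }, logical(1))))
})

test_that("nested CV selection is deterministic and finds the true K", {
  make_group <- function(K, seed, n = 8, T = 60, D = 8) {
    shared <- make_event_data(K, T, D, contrast = 3, noise_sd = 0.01, seed = seed)
    lapply(seq_len(n), function(i) {
      shared$X + matrix(rnorm(T * D, 0, 0.6), T, D)
    })
  }
  set.seed(1)
  g <- make_group(3, seed = 101)
  s1 <- select_num_states(g, k_range = 1:6, seed = 5)
  s2 <- select_num_states(g, k_range = 1:6, seed = 5)
  expect_identical(s1$k_star, s2$k_star)
  expect_identical(s1$fold_loglik, s2$fold_loglik)
  expect_true(abs(s1$k_star - 3) <= 1)
  expect_equal(dim(s1$fold_loglik), c(8, 6))
})

test_that("featureless noise selects a single event in most seeds", {
  hits <- 0L
  for (s in 1:5) {
    set.seed(1000 + s)
    g <- lapply(1:6, function(i) matrix(rnorm(40 * 6), 40, 6))
    sel <- select_num_states(g, k_range = c(1, 2, 3, 5), seed = s)
    if (sel$k_star == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 4L) # >= 80% of seeds
})

test_that("group comparison orders event counts and is symmetric", {
  make_group <- function(K, seed, n = 6, T = 60, D = 8) {
    shared <- make_event_data(K, T, D, contrast = 3, noise_sd = 0.01, seed = seed)
    lapply(seq_len(n), function(i) shared$X + matrix(rnorm(T * D, 0, 0.6), T, D))
  }
  set.seed(2)
  ga <- make_group(6, seed = 7)
  gb <- make_group(3, seed = 8)
  cmp <- compare_group_segmentations(ga, gb, k_range = 1:8, seed = 3)
  expect_gt(cmp$table$k_star_a, cmp$table$k_star_b)

  same <- compare_group_segmentations(ga, ga, k_range = 1:8, seed = 3)
  expect_identical(same$table$k_star_a, same$table$k_star_b)
  expect_identical(same$table$boundaries_a, same$table$boundaries_b)
})

test_that("split-merge refinement never worsens the fit on uneven events", {
  d <- make_event_data(K = 4, T = 80, D = 8, contrast = 3, noise_sd = 0.5,
                       seed = 17, boundaries = c(8, 16, 60))
  base <- fit_event_hmm(d$X, 4)
  refined <- fit_event_hmm(d$X, 4, split_merge = TRUE)
  expect_gte(refined$log_likelihood, base$log_likelihood - 1e-9)
})

test_that("network features assemble ROI-mean series in parcellation order", {
  ds <- make_tiny_dataset(n_couples = 2, n_rois = 4, V = 5, T = 8)
  f <- network_features(ds, "M001", network = NULL)
  expect_equal(dim(f), c(8, 4))
  expect_equal(f[, 2], colMeans(get_timeseries(ds, "M001", 2)$data))
  fv <- network_features(ds, "M001", network = NULL, level = "voxel")
  expect_equal(dim(fv), c(8, 20))
  dmn_rois <- ds$parcellation$roi_id[ds$parcellation$network == "DMN"]
  if (length(dmn_rois)) {
    expect_equal(ncol(network_features(ds, "M001", network = "DMN")),
                 length(dmn_rois))
  }
})
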