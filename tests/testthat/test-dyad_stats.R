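test_that("PLS-1 reduces to simple correlation for a single predictor", {
  set.seed(1)
  x <- matrix(rnorm(15), 15, 1)
  y <- 2 * x[, 1] + rnorm(15, 0, 0.5)
  f <- pls1_fit(x, y)
  expect_equal(abs(f$weights), 1)
  expect_equal(f$score_cor, abs(cor(x[, 1], y)), tolerance = 1e-12)
  expect_error(pls1_fit(x, rep(3, 15)), "zero variance")
})

test_that("PLS-1 weights equal the normalised centred cross-covariance", {
  set.seed(2)
  for (i in 1:8) {
    X <- matrix(rnorm(10 * 6), 10, 6)
    y <- rnorm(10)
    f <- pls1_fit(X, y)
    # closed-form first direction, computed by hand
    Xc <- sweep(X, 2, colMeans(X))
    yc <- y - mean(y)
    w_hand <- drop(t(Xc) %*% yc)
    w_hand <- w_hand / sqrt(sum(w_hand^2))
    if (sum(w_hand * f$weights) < 0) w_hand <- -w_hand
    expect_equal(f$weights, w_hand, tolerance = 1e-10)
    expect_equal(sum(f$weights^2), 1, tolerance = 1e-12)
    expect_gte(f$score_cor, 0) # deterministic sign convention
    expect_equal(f$covariance_explained, cov(f$scores, y)^2, tolerance = 1e-12)
  }
})

test_that("the permutation statistic matches the fitted covariance explained", {
  set.seed(3)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- rnorm(20)
  pt <- pls_permutation_test(X, y, n_perm = 100, seed = 1)
  expect_equal(pt$observed, pls1_fit(X, y)$covariance_explained,
               tolerance = 1e-12)
})

test_that("permutation p-values hit the floor for perfect signal and are
           seed-reproducible", {
  set.seed(4)
  X <- matrix(rnorm(20 * 4), 20, 4)
  w <- c(2, -1, 0.5, 0)
  y <- drop(X %*% w) # y exactly a linear combination, no noise
  pt <- pls_permutation_test(X, y, n_perm = 200, seed = 9)
  expect_equal(pt$p_value, 1 / 201)

  y2 <- rnorm(20)
  p_a <- pls_permutation_test(X, y2, n_perm = 150, seed = 5)$p_value
  p_b <- pls_permutation_test(X, y2, n_perm = 150, seed = 5)$p_value
  expect_identical(p_a, p_b)
})

test_that("bootstrap z flags the signal-carrying ROI and shrinks with
           duplicated data", {
  set.seed(6)
  hits <- 0L
  for (i in 1:5) {
    X <- matrix(rnorm(30 * 5), 30, 5)
    y <- 3 * X[, 2] + rnorm(30, 0, 0.5) # all signal in ROI 2
    bz <- pls_bootstrap_z(X, y, n_boot = 150, seed = i)
    if (which.max(abs(bz$z)) == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 4L)

  X <- matrix(rnorm(20 * 4), 20, 4)
  y <- 2 * X[, 1] + rnorm(20, 0, 1)
  b1 <- pls_bootstrap_z(X, y, n_boot = 200, seed = 3)
  b2 <- pls_bootstrap_z(rbind(X, X), c(y, y), n_boot = 200, seed = 3)
  expect_gt(mean(abs(b2$z)), mean(abs(b1$z))) # doubled n shrinks the SE

  r1 <- pls_bootstrap_z(X, y, n_boot = 120, seed = 8)
  r2 <- pls_bootstrap_z(X, y, n_boot = 120, seed = 8)
  expect_identical(r1$z, r2$z)
})

test_that("Benjamini-Hochberg control matches the hand computation", {
  # sorted p * m / rank: .04, .04, .0533, .20 -> reject the first two at .05
  res <- fdr_correct(c(0.01, 0.02, 0.04, 0.20), q = 0.05)
  expect_identical(res$mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$adjusted, c(0.04, 0.04, 0.04 * 4 / 3, 0.20))

  expect_true(all(fdr_correct(rep(0.001, 8))$mask))
  expect_false(any(fdr_correct(rep(0.9, 8))$mask))

  # rejections are a prefix of the sorted p-values; adjusted p monotone
  set.seed(10)
  for (i in 1:5) {
    p <- runif(12)
    r <- fdr_correct(p, q = 0.2)
    o <- order(p)
    expect_true(all(diff(r$adjusted[o]) > -1e-15))
    rej <- r$mask[o]
    if (any(rej)) expect_true(all(rej[seq_len(max(which(rej)))]))
  }
})

test_that("the full PLS inference table is coherent", {
  set.seed(11)
  X <- matrix(rnorm(25 * 6), 25, 6)
  colnames(X) <- paste0("roi", 1:6)
  y <- 2 * X[, 1] + rnorm(25, 0, 0.8)
  res <- pls_inference(X, y, n_perm = 300, n_boot = 150, seed = 2)
  expect_s3_class(res, "pls_result")
  expect_equal(nrow(res$table), 6)
  expect_true(res$p_permutation > 0 && res$p_permutation <= 1)
  expect_identical(res$table$fdr_significant,
                   unname(fdr_correct(res$table$p)$mask))
  # the FDR invariant: significant implies adjusted p below threshold
  expect_true(all(res$table$p_adjusted[res$table$fdr_significant] < 0.05))
})

test_that("group comparisons agree with hand formulas and handle identity", {
  x <- c(0.2, 0.3, 0.25, 0.28)
  same <- data.frame(value = c(x, x), status = rep(c("a", "b"), each = 4))
  g <- group_compare(same)
  expect_equal(g$t_tests$t, 0)
  expect_equal(g$t_tests$cohens_d, 0)

  set.seed(12)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  df <- data.frame(value = c(a, b), status = rep(c("a", "b"), c(12, 15)))
  g2 <- group_compare(df)
  # Welch statistic from the definitional formula
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 12 + var(b) / 15)
  expect_equal(g2$t_tests$t, t_hand, tolerance = 1e-8)
  d_hand <- (mean(a) - mean(b)) /
    sqrt((11 * var(a) + 14 * var(b)) / 25)
  expect_equal(g2$t_tests$cohens_d, d_hand, tolerance = 1e-12)
  expect_equal(sign(g2$t_tests$cohens_d), sign(mean(a) - mean(b)))

  # two-way layout produces state, status and interaction effects
  df2 <- data.frame(
    value = rnorm(60),
    state = rep(c("movie", "rest"), each = 30),
    status = rep(c("couple_high", "couple_low", "random"), 20)
  )
  g3 <- group_compare(df2)
  expect_setequal(setdiff(g3$anova$term, "Residuals"),
                  c("state", "status", "state:status"))
  expect_equal(nrow(g3$t_tests), 2 * 3) # 3 pairs per state
})

test_that("whole-brain ISTS correlations report r and p for both methods", {
  set.seed(13)
  x <- rnorm(20)
  y <- x + rnorm(20, 0, 0.5)
  pe <- ists_correlation(x, y, "pearson")
  expect_equal(pe$r, cor(x, y), tolerance = 1e-12)
  sp <- ists_correlation(x, y, "spearman")
  expect_equal(sp$r, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_true(pe$p < 0.05)
})
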