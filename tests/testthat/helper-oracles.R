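# Independent oracles: hand formulas, double loops and exhaustive
# enumeration, deliberately sharing no code with the package internals.

# Pearson correlation from the definitional formula
naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# trajectory matrix by double loop over TR pairs
naive_trajectory <- function(X) {
  T <- ncol(X)
  m <- matrix(NA_real_, T, T)
  for (i in seq_len(T)) for (j in seq_len(T)) {
    m[i, j] <- naive_pearson(X[, i], X[, j])
  }
  m
}

# ISTS by explicit upper-triangle vector extraction
naive_ists <- function(a, b) {
  T <- nrow(a)
  va <- vb <- numeric(0)
  for (i in seq_len(T - 1L)) for (j in (i + 1L):T) {
    va <- c(va, a[i, j])
    vb <- c(vb, b[i, j])
  }
  naive_pearson(va, vb)
}

# all derangements of 1..n by brute-force enumeration
all_derangements <- function(n) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  Filter(function(p) all(p != seq_len(n)), perms(seq_len(n)))
}

# log-likelihood of an ordered-state HMM by exhaustive enumeration of every
# monotone path from state 1 to state K; emit_log is T x K, p the advance
# probability. Paths are indexed by their K - 1 boundary positions.
enumerate_monotone_loglik <- function(emit_log, p) {
  T <- nrow(emit_log); K <- ncol(emit_log)
  if (K == 1L) return(sum(emit_log[, 1L]))
  bsets <- utils::combn(T - 1L, K - 1L, simplify = FALSE)
  logps <- vapply(bsets, function(b) {
    states <- findInterval(seq_len(T), c(1L, b + 1L))
    lp <- sum(emit_log[cbind(seq_len(T), states)])
    # transitions: K-1 advances; stays in states < K cost log(1 - p),
    # stays in state K cost 0 (absorbing)
    stays_lt_K <- sum(states[-T] == states[-1L] & states[-T] < K)
    lp <- lp + (K - 1L) * log(p)
    if (stays_lt_K > 0L) lp <- lp + stays_lt_K * log1p(-p)
    lp
  }, numeric(1))
  m <- max(logps)
  m + log(sum(exp(logps - m)))
}

# block-structured event data: K events of given per-event mean patterns
make_event_data <- function(K, T, D, contrast, noise_sd, seed,
                            boundaries = NULL) {
  set.seed(seed)
  if (is.null(boundaries)) {
    lens <- rep(T %/% K, K)
    lens[K] <- T - sum(lens[-K])
    boundaries <- cumsum(lens)[-K]
  }
  states <- findInterval(seq_len(T) - 1L, c(0L, boundaries))
  means <- matrix(rnorm(K * D, 0, contrast), K, D)
  X <- means[states, , drop = FALSE] + matrix(rnorm(T * D, 0, noise_sd), T, D)
  list(X = X, boundaries = boundaries, states = states, means = means)
}

# small valid dyadic fixture: n couples, r ROIs, V voxels, T TRs
make_tiny_dataset <- function(n_couples = 2, n_rois = 2, V = 4, T = 8,
                              seed = 1) {
  cfg <- synthetic_config(n_couples = n_couples, n_rois = n_rois,
                          voxels_per_roi = V, n_trs = T,
                          n_events = 1, coupling = 0.5, seed = seed)
  generate_dyad_timeseries(cfg)$dataset
}
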