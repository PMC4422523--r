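# Independent oracle implementations used to cross-check the package.
# These deliberately use a different algorithmic route than the package code.

# Mutual rank by direct pairwise counting: rank of j in i's list is
# 1 + #{k: rho[i,k] > rho[i,j]} + #{k: tied}/2 (average ranks), self excluded.
oracle_mutual_rank <- function(rho) {
  n <- nrow(rho)
  out <- matrix(NA_real_, n, n, dimnames = dimnames(rho))
  rank_of <- function(i, j) {
    others <- setdiff(seq_len(n), i)
    v <- rho[i, others]
    x <- rho[i, j]
    1 + sum(v > x) + (sum(v == x) - 1) / 2
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    out[i, j] <- sqrt(rank_of(i, j) * rank_of(j, i))
  }
  out
}

# Hypergeometric upper tail by exhaustive enumeration of all draws.
oracle_hyper_p <- function(universe, term, query) {
  draws <- utils::combn(universe, length(query))
  sig <- length(intersect(query, term))
  mean(apply(draws, 2, function(d) length(intersect(d, term)) >= sig))
}

# BH step-up by hand: q_(i) = min_{j >= i} p_(j) * m / j, input order kept.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  res <- numeric(m)
  res[o] <- q
  res
}

pair_key_test <- function(m) {
  paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
}

# Small synthetic config shared by cheap tests.
tiny_config <- function(seed = 1L, ...) {
  cg <- default_clock_genes()
  synthetic_config(n_samples = 60, n_background_genes = 80,
                   clock_genes = cg,
                   planted_edges = default_planted_edges(cg, n_targets = 10),
                   rng_seed = seed, ...)
}

# Random symmetric pseudo-correlation matrix with ties.
random_corr <- function(n, seed) {
  set.seed(seed)
  m <- matrix(round(runif(n * n, -1, 1), 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(paste0("g", 1:n), paste0("g", 1:n))
  m
}
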