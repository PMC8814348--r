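# Shared fixtures, built in code.

# Two planted factors over 8 items, salient loadings `load` in blocks
# {1-4} and {5-8}.
two_block_spec <- function(load = 0.8, noise_sd = 0.5, missing_rate = 0,
                           items = c(paste0("C1", 1:4), paste0("C2", 1:4))) {
  L <- matrix(0, 8, 2, dimnames = list(items, NULL))
  L[1:4, 1] <- load
  L[5:8, 2] <- load
  factor_spec(L, noise_sd = noise_sd, missing_rate = missing_rate)
}

# A random valid expert influence survey on n criteria.
random_survey_spec <- function(n = 8, H = 10, disagreement = 0.1, seed = 1) {
  with_fixed_seed(seed, {
    G <- matrix(sample(0:4, n * n, replace = TRUE), n)
    diag(G) <- 0
    influence_spec(G, H, disagreement)
  })
}

with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Brute-force Pearson correlation via explicit pairwise sums (oracle).
pearson_bruteforce <- function(X) {
  n <- nrow(X); p <- ncol(X)
  R <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    x <- X[, i]; y <- X[, j]
    sx <- sum(x); sy <- sum(y)
    num <- n * sum(x * y) - sx * sy
    den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
    R[i, j] <- num / den
  }
  R
}

# Truncated power-series oracle for the total-influence matrix.
power_series_T <- function(D, Q = 200) {
  acc <- matrix(0, nrow(D), ncol(D))
  P <- diag(nrow(D))
  for (q in seq_len(Q)) {
    P <- P %*% D
    acc <- acc + P
  }
  acc
}

# Power-iteration oracle for the stationary column of a column-stochastic W.
power_iteration_weights <- function(W, iters = 5000) {
  v <- rep(1 / nrow(W), nrow(W))
  for (i in seq_len(iters)) v <- as.vector(W %*% v)
  v / sum(v)
}
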