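# shared fixtures built in code; expensive cohorts are memoised per session

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# random positive-definite covariance with unit-ish diagonal
random_pd_cov <- function(n, seed) {
  set.seed(seed)
  B <- matrix(rnorm(n * n), n)
  S <- crossprod(B) / n + diag(n) * 0.5
  (S + t(S)) / 2
}

# node x time data whose sample covariance (denominator T) equals S exactly
exact_cov_ts <- function(S, T_, seed = 1) {
  n <- nrow(S)
  stopifnot(T_ > n)
  set.seed(seed)
  Z <- matrix(rnorm(T_ * n), T_, n)
  Z <- sweep(Z, 2, colMeans(Z))
  Z <- qr.Q(qr(Z)) * sqrt(T_)         # exact identity sample covariance
  X <- Z %*% chol(S)
  t(X)                                 # nodes x time
}

# OLS-residual oracle for partial correlation: for each pair, regress both
# nodes on all remaining nodes and correlate the residuals
partial_oracle <- function(ts) {
  X <- t(ts)
  n <- ncol(X)
  pc <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rest <- setdiff(seq_len(n), c(i, j))
      if (length(rest) == 0) {
        pc[i, j] <- pc[j, i] <- cor(X[, i], X[, j])
      } else {
        ri <- residuals(lm(X[, i] ~ X[, rest, drop = FALSE]))
        rj <- residuals(lm(X[, j] ~ X[, rest, drop = FALSE]))
        pc[i, j] <- pc[j, i] <- cor(ri, rj)
      }
    }
  }
  pc
}

# small benchmark cohort reused by several test files
small_benchmark <- function() {
  memo("small_benchmark", benchmark_cohort(seed = 11, n_subjects = 6,
                                           n_nodes = 50))
}

# Shrout & Fleiss (1979) worked example: 6 targets rated by 4 judges;
# published ICC(2,1) = 0.29
shrout_fleiss_table <- function() {
  matrix(c(9, 2, 5, 8,
           6, 1, 3, 2,
           8, 4, 6, 8,
           7, 1, 2, 6,
           10, 5, 6, 9,
           6, 2, 4, 7), nrow = 6, byrow = TRUE)
}

# build a binary_connectome from an explicit upper-triangle edge list
adj_from_edges <- function(n, edges) {
  adj <- matrix(FALSE, n, n)
  for (e in edges) adj[e[1], e[2]] <- TRUE
  adj <- adj | t(adj)
  connmix:::.binary_connectome(adj, "manual", NA)
}
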