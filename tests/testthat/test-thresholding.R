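# oracle fit object with known parameters (bypasses EM)
oracle_fit <- function(p0 = 1, null = c(0, 1), signal = c(9, 3)) {
  structure(list(p0 = p0, null_params = null, signal_params = signal,
                 loglik_trace = 0, n_iter = 1, converged = TRUE, n = NA,
                 spec = mixture_spec("gaussian", "gamma"),
                 flags = character(0)),
            class = "mixture_fit")
}

test_that("pseudo-FDR approximates the tail ratio on pure-null data", {
  set.seed(1)
  x <- rnorm(5000)
  curve <- pseudo_fdr_curve(oracle_fit(), x)
  # with p0 = 1 and a perfect null fit the curve sits near 1 until the
  # empirical tail runs out of data
  mid <- curve[curve$x < 1.5, ]
  expect_true(all(abs(mid$fdr - 1) < 0.25))
  # below the sample minimum everything exceeds the cut on both sides
  expect_lt(abs(curve$fdr[1] - 1), 0.05)
})

test_that("pseudo-FDR vanishes below a well-separated signal mass", {
  set.seed(2)
  x <- c(rnorm(900), rnorm(100, mean = 5, sd = 0.05))
  curve <- pseudo_fdr_curve(oracle_fit(p0 = 0.9), x)
  near5 <- curve[curve$x > 4.5 & curve$x < 4.9, ]
  # numerator ~ 0.9 * (1 - Phi(4.7)), denominator ~ 0.1
  expect_true(all(near5$fdr < 1e-4))
  # curve values are not clipped at 1 where the model overestimates
  expect_true(any(curve$fdr > 1) || max(curve$fdr) <= 1)
})

test_that("threshold selection takes the last down-crossing", {
  # monotone curve: unique crossing, identical to the naive rule
  x <- seq(0, 5, by = 0.1)
  fdr <- rev(seq(0.001, 1, length.out = length(x)))
  pick <- connmix:::.pfdr_pick_threshold(x, fdr, 0.05)
  naive <- min(x[fdr <= 0.05])
  expect_lt(pick$threshold, naive)
  expect_true(all(fdr[x > pick$threshold] <= 0.05))
  # three-segment curve: dips below q, rises above, falls again
  x2 <- seq(0, 3, by = 0.01)
  fdr2 <- ifelse(x2 < 1, 0.5 - 0.48 * x2,
                 ifelse(x2 < 2, 0.02 + 0.2 * (x2 - 1), 0.22 - 0.21 * (x2 - 2)))
  pick2 <- connmix:::.pfdr_pick_threshold(x2, fdr2, 0.05)
  first_cross <- min(x2[fdr2 <= 0.05])
  expect_gt(pick2$threshold, first_cross)
  expect_true(all(fdr2[x2 > pick2$threshold] <= 0.05))
})

test_that("pfdr thresholding handles the degenerate regimes", {
  set.seed(3)
  S <- random_pd_cov(6, 31)
  zc <- fisher_standardize(precision_to_partial(
    estimate_covariance(exact_cov_ts(S, 80, 5), "empirical")))
  # impossible cut: null mass everywhere above q -> empty connectome, flagged
  wide <- oracle_fit(p0 = 1, null = c(0, 50))
  bc <- pfdr_threshold(zc, wide, q = 0.01)
  expect_equal(sum(bc$adj), 0)
  expect_true("no_threshold" %in% bc$flags)
})

test_that("pfdr thresholds are nested over q", {
  bm <- small_benchmark()
  zc <- cohort_connectomes(bm$panel, "ledoit_wolf")[[1]]
  fit <- em_fit(zc$z_std, mixture_spec("gaussian", "gamma"))
  prev <- NULL
  for (q in c(0.01, 0.05, 0.1, 0.3)) {
    bc <- pfdr_threshold(zc, fit, q)
    if (!is.null(prev)) expect_true(all(bc$adj[prev$adj]))
    prev <- bc
  }
})

test_that("hard thresholding keeps exactly the entries above the cut", {
  m <- matrix(c(0, 0.2, -0.1, 0.2, 0, 0.3, -0.1, 0.3, 0), 3)
  diag(m) <- 1
  all_pos <- hard_threshold(abs(m) + 0.01, 0)
  expect_equal(sum(all_pos$adj[upper.tri(all_pos$adj)]), 3)
  none <- hard_threshold(m, Inf)
  expect_equal(sum(none$adj), 0)
  mixed <- hard_threshold(m, 0)
  expect_identical(mixed$adj[upper.tri(mixed$adj)],
                   m[upper.tri(m)] > 0)
})

test_that("proportional thresholding is exact and breaks ties lexically", {
  set.seed(4)
  m <- matrix(rnorm(25), 5); m <- (m + t(m)) / 2; diag(m) <- 1
  # 10 pairs, fraction 0.10 -> exactly one edge
  bc <- proportional_threshold(m, 0.10)
  expect_equal(sum(bc$adj[upper.tri(bc$adj)]), 1)
  expect_equal(bc$density, 1 / 10)
  # full graph
  expect_equal(proportional_threshold(m, 1)$density, 1)
  # all-equal values: lexical tie-break keeps the same 5 edges every time
  eq <- matrix(1, 5, 5)
  b1 <- proportional_threshold(eq, 0.5)
  b2 <- proportional_threshold(eq, 0.5)
  expect_identical(b1$adj, b2$adj)
  expect_equal(sum(b1$adj[upper.tri(b1$adj)]), 5)
  ut <- which(upper.tri(eq), arr.ind = TRUE)
  expected_first <- ut[order(ut[, 1], ut[, 2]), ][1:5, ]
  expect_true(all(b1$adj[expected_first]))
  # k = 0: empty with a warning
  expect_warning(b0 <- proportional_threshold(m, 0.01), "zero edges")
  expect_equal(sum(b0$adj), 0)
})

white_noise_panel <- function(n_sub, n, T_, seed) {
  set.seed(seed)
  data <- array(rnorm(n_sub * n * T_), dim = c(n_sub, n, T_),
                dimnames = list(sprintf("s%02d", 1:n_sub),
                                sprintf("node%02d", 1:n), NULL))
  structure(list(data = data, TR_s = 1, subject_ids = sprintf("s%02d", 1:n_sub),
                 lags = NULL, cfg = NULL), class = "bold_panel")
}

test_that("group permutation test is calibrated on independent noise", {
  panel <- white_noise_panel(20, 10, 150, seed = 91)
  pg <- permutation_group(panel, "empirical", n_perm = 400, p = 0.1, seed = 1)
  kept <- mean(vapply(pg$connectomes, function(b)
    mean(b$adj[upper.tri(b$adj)]), numeric(1)))
  # binomial 95% band around p over 20 x 45 edge decisions (correlated across
  # subjects through the shared cuts; allow a generous band)
  expect_gt(kept, 0.05)
  expect_lt(kept, 0.16)
  # determinism
  pg2 <- permutation_group(panel, "empirical", n_perm = 400, p = 0.1, seed = 1)
  expect_identical(pg$cuts, pg2$cuts)
  expect_error(permutation_group(panel, "empirical", n_perm = 50, p = 0.001),
               "resolution")
})

test_that("group permutation test detects a strongly coupled pair", {
  set.seed(17)
  n_sub <- 15; n <- 8; T_ <- 200
  data <- array(rnorm(n_sub * n * T_), dim = c(n_sub, n, T_))
  for (s in 1:n_sub) {
    shared <- rnorm(T_)
    data[s, 1, ] <- shared + rnorm(T_, sd = 0.3)
    data[s, 2, ] <- shared + rnorm(T_, sd = 0.3)
  }
  dimnames(data) <- list(sprintf("s%02d", 1:n_sub), sprintf("n%02d", 1:n), NULL)
  panel <- structure(list(data = data, TR_s = 1,
                          subject_ids = sprintf("s%02d", 1:n_sub),
                          lags = NULL, cfg = NULL), class = "bold_panel")
  pg <- permutation_group(panel, "empirical", n_perm = 300, p = 0.05, seed = 2)
  hit <- mean(vapply(pg$connectomes, function(b) b$adj[1, 2], logical(1)))
  expect_gte(hit, 0.95)
  other <- mean(vapply(pg$connectomes, function(b) {
    a <- b$adj; a[1, 2] <- a[2, 1] <- FALSE; mean(a[upper.tri(a)])
  }, numeric(1)))
  expect_lt(other, 0.15)
})

test_that("subject permutation test is calibrated and uses valid surrogates", {
  set.seed(23)
  ts <- matrix(rnorm(15 * 250), 15, 250)
  bc <- permutation_subject(ts, "empirical", n_perm = 300, p = 0.1, seed = 3)
  kept <- mean(bc$adj[upper.tri(bc$adj)])
  expect_gt(kept, 0.03)
  expect_lt(kept, 0.2)
  expect_identical(bc$adj,
                   permutation_subject(ts, "empirical", n_perm = 300,
                                       p = 0.1, seed = 3)$adj)
  expect_error(permutation_subject(ts, "empirical", n_perm = 50, p = 0.001),
               "resolution")
})

test_that("full shuffling inflates detections on autocorrelated null data", {
  # AR(1) nodes, no coupling: circular shifts preserve autocorrelation and
  # stay calibrated; full shuffling narrows the null and keeps more edges
  set.seed(29)
  n <- 10; T_ <- 300
  ts <- t(sapply(1:n, function(i)
    as.numeric(arima.sim(list(ar = 0.9), T_))))
  circ <- permutation_subject(ts, "empirical", n_perm = 300, p = 0.05,
                              seed = 4, mode = "circular")
  shuf <- permutation_subject(ts, "empirical", n_perm = 300, p = 0.05,
                              seed = 4, mode = "shuffle")
  expect_gte(sum(shuf$adj), sum(circ$adj))
})

test_that("thresholded connectomes are symmetric and self-edge free", {
  bm <- small_benchmark()
  zc <- cohort_connectomes(bm$panel, "ledoit_wolf")[[1]]
  fit <- em_fit(zc$z_std, mixture_spec("gaussian", "gamma"))
  for (bc in list(pfdr_threshold(zc, fit, 0.05),
                  hard_threshold(zc, 0),
                  proportional_threshold(zc, 0.1))) {
    expect_identical(bc$adj, t(bc$adj))
    expect_false(any(diag(bc$adj)))
    expect_gte(bc$density, 0)
    expect_lte(bc$density, 1)
  }
})
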