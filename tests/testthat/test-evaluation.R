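test_that("scoring counts the upper triangle correctly", {
  tr <- build_topology(10, seed = 2)
  perfect <- connmix:::.binary_connectome(tr$truth_undirected, "manual", NA)
  sc <- score_connectome(perfect, tr)
  expect_equal(sc$performance, 1)
  expect_equal(sc$FPR, 0)
  expect_equal(sc$FDR, 0)
  expect_equal(sc$TP + sc$FP + sc$TN + sc$FN, choose(10, 2))
  comp <- connmix:::.binary_connectome(!tr$truth_undirected, "manual", NA)
  expect_equal(score_connectome(comp, tr)$performance, 0)
  small <- connmix:::.binary_connectome(matrix(FALSE, 4, 4), "manual", NA)
  expect_error(score_connectome(small, tr), "comparison error")
})

test_that("random estimates match the closed-form expected performance", {
  tr <- build_topology(50, seed = 9)
  d_true <- tr$density
  set.seed(101)
  for (d in c(0.1, 0.3)) {
    perfs <- replicate(150, {
      adj <- matrix(FALSE, 50, 50)
      adj[upper.tri(adj)] <- runif(1225) < d
      adj <- adj | t(adj)
      score_connectome(connmix:::.binary_connectome(adj, "rand", d),
                       tr)$performance
    })
    # E[perf] = d * d_true + (1 - d) * (1 - d_true)
    expected <- d * d_true + (1 - d) * (1 - d_true)
    se <- sd(perfs) / sqrt(length(perfs))
    expect_lt(abs(mean(perfs) - expected), 4 * se + 1e-3)
  }
})

test_that("mean performance is the arithmetic mean over subjects", {
  tr <- build_topology(6, seed = 3)
  full <- connmix:::.binary_connectome(tr$truth_undirected, "manual", NA)
  none <- connmix:::.binary_connectome(matrix(FALSE, 6, 6), "manual", NA)
  expect_equal(mean_performance(list(full, full), tr), 1)
  p_none <- score_connectome(none, tr)$performance
  expect_equal(mean_performance(list(full, none), tr), (1 + p_none) / 2)
  expect_error(mean_performance(list(), tr), "empty")
})

test_that("AUC handles perfect, random and hand-placed curves", {
  # perfect separation: TPR 1 at FPR 0
  perfect <- roc_auc(c(0, 0.1, 0.2), c(1, 1, 1), clip = c(0, 0.2))
  expect_equal(perfect$auc, 1)
  # hand-computed trapezoid: points (0,0), (0.1, 0.4), (0.2, 0.8)
  hand <- roc_auc(c(0.1, 0.2), c(0.4, 0.8), clip = c(0, 0.2))
  expect_equal(hand$auc, (0.1 * 0.2 + 0.1 * 0.6) / 0.2, tolerance = 1e-12)
  # scores independent of labels: full-range AUC ~ 0.5 (permutation oracle)
  set.seed(55)
  labs <- rbinom(400, 1, 0.3)
  scores <- rnorm(400)
  cuts <- quantile(scores, seq(0.02, 0.98, length.out = 30))
  fpr <- sapply(cuts, function(ct) mean(scores[labs == 0] > ct))
  tpr <- sapply(cuts, function(ct) mean(scores[labs == 1] > ct))
  expect_lt(abs(roc_auc(fpr, tpr, clip = c(0, 1))$auc - 0.5), 0.1)
  expect_error(roc_auc(c(0.1, 0.1), c(0.5, 0.5)), "degenerate")
})

test_that("dominating curves dominate in AUC", {
  fpr <- seq(0, 0.5, length.out = 11)
  tpr_lo <- fpr * 1.5
  tpr_hi <- pmin(tpr_lo + 0.2, 1)
  expect_gte(roc_auc(fpr, tpr_hi, c(0, 0.2))$auc,
             roc_auc(fpr, tpr_lo, c(0, 0.2))$auc)
})

test_that("pseudo-FDR calibration tracks nominal levels under an oracle fit", {
  # Gaussian null plus a well-separated signal mass with the generating
  # parameters known exactly: the realized FDR then matches the nominal level
  # up to Monte-Carlo error
  set.seed(66)
  n <- 40
  n_pairs <- choose(n, 2)
  truth_adj <- matrix(FALSE, n, n)
  true_idx <- sample.int(n_pairs, round(0.1 * n_pairs))
  ut <- which(upper.tri(truth_adj))
  truth_adj[ut[true_idx]] <- TRUE
  truth_adj <- truth_adj | t(truth_adj)
  truth <- structure(list(n_nodes = n, truth_undirected = truth_adj,
                          density = 0.1, n_edges = length(true_idx)),
                     class = "ground_truth_network")
  make_zc <- function(seed) {
    set.seed(seed)
    vals <- rnorm(n_pairs)
    vals[true_idx] <- rnorm(length(true_idx), mean = 5, sd = 0.3)
    z <- matrix(0, n, n)
    z[upper.tri(z)] <- vals
    z <- z + t(z); diag(z) <- 0
    structure(list(partial = tanh(z), z = z, z_std = vals,
                   standardizer = c(mean = 0, sd = 1),
                   cov_method = "oracle", shrinkage = 0, nodes = NULL),
              class = "z_connectome")
  }
  zcs <- lapply(1:10, make_zc)
  fits <- replicate(10, structure(
    list(p0 = 0.9, null_params = c(0, 1), signal_params = c(9, 3),
         loglik_trace = 0, n_iter = 1, converged = TRUE, n = n_pairs,
         spec = mixture_spec("gaussian", "gamma"), flags = character(0)),
    class = "mixture_fit"), simplify = FALSE)
  cal <- fdr_calibration(zcs, fits, truth, q_grid = c(0.05, 0.1, 0.2))
  expect_true(all(abs(cal$realized - cal$nominal) < 0.06))
  # keep-everything limit: at q = 1 the realized FDR equals the false
  # fraction among all positive values
  cal1 <- fdr_calibration(zcs[1], fits[1], truth, q_grid = 1 - 1e-9)
  pos <- zcs[[1]]$z_std > 0
  expect_equal(cal1$realized,
               sum(pos & !truth_adj[upper.tri(truth_adj)]) / sum(pos),
               tolerance = 0.05)
})

test_that("index of overlap reproduces the Dice fixtures", {
  a <- adj_from_edges(6, list(c(1, 2), c(3, 4)))
  b <- adj_from_edges(6, list(c(1, 2), c(5, 6)))
  expect_equal(index_of_overlap(a, a), 100)
  expect_equal(index_of_overlap(a, b), 50)       # |A|=2, |B|=2, |A&B|=1
  disjoint <- adj_from_edges(6, list(c(2, 3)))
  expect_equal(index_of_overlap(a, disjoint), 0)
  empty <- adj_from_edges(6, list())
  expect_equal(index_of_overlap(empty, empty), 100)
  # symmetry
  expect_equal(index_of_overlap(a, b), index_of_overlap(b, a))
  # jaccard variant
  expect_equal(index_of_overlap(a, b, type = "jaccard"), 100 / 3,
               tolerance = 1e-12)
})

test_that("ICC(2,1) matches the published worked example and an aov oracle", {
  Y <- shrout_fleiss_table()           # 6 targets x 4 judges
  stack <- t(Y)                        # subjects (judges) x edges (targets)
  expect_equal(round(icc(stack), 2), 0.29)
  # independent recomputation from the two-way ANOVA mean squares
  df <- data.frame(y = as.vector(Y),
                   target = factor(rep(1:6, 4)),
                   judge = factor(rep(1:4, each = 6)))
  ms <- anova(lm(y ~ target + judge, data = df))[["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  icc_oracle <- (MSR - MSE) / (MSR + (4 - 1) * MSE + 4 * (MSC - MSE) / 6)
  expect_equal(icc(stack), icc_oracle, tolerance = 1e-12)
})

test_that("ICC is 1 for identical subjects and ~0 for independent ones", {
  edge_vals <- rnorm(30)
  same <- rbind(edge_vals, edge_vals, edge_vals)
  expect_equal(icc(same), 1, tolerance = 1e-12)
  set.seed(13)
  indep <- matrix(rnorm(20 * 400), 20, 400)
  expect_lt(abs(icc(indep)), 0.05)
  expect_error(icc(matrix(1, 1, 5)), "at least 2")
})

test_that("group contrast flags a fully separating edge and nothing else", {
  n <- 6
  present <- adj_from_edges(n, list(c(1, 2)))
  absent <- adj_from_edges(n, list())
  coh_a <- replicate(12, present, simplify = FALSE)
  coh_b <- replicate(12, absent, simplify = FALSE)
  gc <- group_contrast(coh_a, coh_b, alpha = 0.01)
  hit <- gc$table$i == 1 & gc$table$j == 2
  expect_true(gc$table$significant[hit])
  expect_false(any(gc$table$significant[!hit]))
  expect_equal(gc$table$diff[hit], 12)
  expect_true(all(abs(gc$table$diff) <= 12))
  expect_equal(gc$pct_nonzero, 100 / choose(n, 2), tolerance = 1e-12)
  # identical cohorts: no differences, nothing significant
  gc0 <- group_contrast(coh_a, coh_a)
  expect_true(all(gc0$table$diff == 0))
  expect_false(any(gc0$table$significant))
  expect_error(group_contrast(list(), coh_b), "empty")
})

test_that("the size sweep at full size equals the plain evaluation", {
  bm <- small_benchmark()
  sw <- size_sweep(bm$panel, bm$truth, sizes = bm$truth$n_nodes,
                   methods = c("lw_hard", "prop10"), seed = 1)
  ev <- evaluate_methods(bm$panel, bm$truth, methods = c("lw_hard", "prop10"),
                         seed = 1)
  expect_equal(sw$performance, ev$performance, tolerance = 1e-12)
  expect_equal(sw$TPR, ev$TPR, tolerance = 1e-12)
})

test_that("proportional 5% on a 5-node subnetwork keeps zero edges", {
  # 10 pairs, fraction 0.05 -> k = floor(0.5) = 0: the all-negative baseline
  bm <- small_benchmark()
  sub <- extract_subnetwork(bm$panel, bm$truth, 5, seed = 4)
  zc <- cohort_connectomes(sub$panel, "ledoit_wolf")[[1]]
  expect_warning(bc <- proportional_threshold(zc, 0.05), "zero edges")
  sc <- score_connectome(bc, sub$truth)
  expect_equal(sc$TP + sc$FP, 0)
  expect_equal(sc$performance, 1 - sub$truth$density)
})
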