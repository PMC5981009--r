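#' Score a binarized connectome against ground truth
#'
#' Counts true/false positives and negatives over the upper triangle only
#' (each node pair counted once). Performance is the fraction of correctly
#' classified pairs `(TP + TN) / n_pairs`; the realized FDR is
#' `FP / max(TP + FP, 1)`.
#'
#' @param est a `binary_connectome` (or logical adjacency matrix).
#' @param truth a `ground_truth_network` (or logical adjacency matrix).
#' @return a named list: `TP`, `FP`, `TN`, `FN`, `performance`, `TPR`, `FPR`,
#'   `FDR`.
#' @export
score_connectome <- function(est, truth) {
  e <- if (inherits(est, "binary_connectome")) est$adj else est
  g <- if (inherits(truth, "ground_truth_network")) truth$truth_undirected else truth
  if (!all(dim(e) == dim(g)))
    stop("comparison error: estimate and truth have different sizes")
  ut <- upper.tri(g)
  ev <- e[ut]; gv <- g[ut]
  TP <- sum(ev & gv); FP <- sum(ev & !gv)
  TN <- sum(!ev & !gv); FN <- sum(!ev & gv)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       performance = (TP + TN) / (TP + TN + FP + FN),
       TPR = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       FPR = if (FP + TN > 0) FP / (FP + TN) else NA_real_,
       FDR = FP / max(TP + FP, 1))
}

#' Cohort-mean performance
#'
#' @param estimates list of `binary_connectome`s (one per subject).
#' @param truth the shared ground truth.
#' @return arithmetic mean of the per-subject performance.
#' @export
mean_performance <- function(estimates, truth) {
  if (length(estimates) == 0) stop("empty cohort")
  mean(vapply(estimates, function(e) score_connectome(e, truth)$performance,
              numeric(1)))
}

# mean TPR/FPR/FDR across subjects
.cohort_rates <- function(estimates, truth) {
  sc <- lapply(estimates, score_connectome, truth = truth)
  c(performance = mean(vapply(sc, `[[`, numeric(1), "performance")),
    TPR = mean(vapply(sc, `[[`, numeric(1), "TPR")),
    FPR = mean(vapply(sc, `[[`, numeric(1), "FPR")),
    FDR = mean(vapply(sc, `[[`, numeric(1), "FDR")))
}

#' Area under a (clipped) ROC curve
#'
#' Sorts the points by FPR, merges ties by averaging TPR, anchors the curve at
#' (0, 0), interpolates TPR at the clip boundary and integrates by the
#' trapezoid rule over the clipped FPR range, normalized by the clip width.
#' If the curve does not reach the upper clip boundary it is extended
#' horizontally at its maximal TPR.
#'
#' @param fpr,tpr coordinates of the ROC points (e.g. cohort means per
#'   threshold parameter).
#' @param clip FPR range to integrate over, e.g. `c(0, 0.2)`.
#' @return list with `auc` and the cleaned `points` data frame.
#' @export
roc_auc <- function(fpr, tpr, clip = c(0, 0.2)) {
  keep <- is.finite(fpr) & is.finite(tpr)
  fpr <- fpr[keep]; tpr <- tpr[keep]
  if (length(unique(fpr)) < 2) stop("degenerate ROC: fewer than 2 distinct points")
  agg <- tapply(tpr, fpr, mean)
  x <- as.numeric(names(agg)); y <- as.numeric(agg)
  o <- order(x); x <- x[o]; y <- y[o]
  if (x[1] > 0) { x <- c(0, x); y <- c(0, y) }
  lo <- clip[1]; hi <- clip[2]
  xe <- c(x, max(hi, max(x) + 1e-12)); ye <- c(y, max(y))
  grid <- sort(unique(c(lo, hi, xe[xe >= lo & xe <= hi])))
  yg <- approx(xe, ye, xout = grid, ties = "ordered", rule = 2)$y
  auc <- sum(diff(grid) * (head(yg, -1) + tail(yg, -1)) / 2) / (hi - lo)
  list(auc = auc, points = data.frame(fpr = x, tpr = y))
}

#' Pseudo-FDR calibration curve
#'
#' For a grid of nominal pseudo-FDR levels, thresholds every subject's fit at
#' that level and records the cohort-mean realized FDR against ground truth.
#' The method is conservative where the realized value stays at or below the
#' nominal one.
#'
#' @param zcs list of standardized `z_connectome`s (one per subject).
#' @param fits matching list of mixture fits.
#' @param truth ground-truth network.
#' @param q_grid nominal levels.
#' @return data frame with columns `nominal` and `realized`.
#' @export
fdr_calibration <- function(zcs, fits, truth,
                            q_grid = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.5)) {
  realized <- vapply(q_grid, function(q) {
    mean(vapply(seq_along(zcs), function(s)
      score_connectome(pfdr_threshold(zcs[[s]], fits[[s]], q), truth)$FDR,
      numeric(1)))
  }, numeric(1))
  data.frame(nominal = q_grid, realized = realized)
}

#' Index of Overlap between two binary connectomes
#'
#' Test-retest agreement of the two edge sets on a 0-100 scale, computed as
#' the Dice coefficient times 100: `100 * 2|A & B| / (|A| + |B|)` over the
#' upper triangle. Defined as 100 when both edge sets are empty. A Jaccard
#' variant (`100 * |A & B| / |A | B|`) is available.
#'
#' @param a,b `binary_connectome`s (or logical adjacency matrices) on the same
#'   node set.
#' @param type `"dice"` (default) or `"jaccard"`.
#' @export
index_of_overlap <- function(a, b, type = c("dice", "jaccard")) {
  type <- match.arg(type)
  A <- if (inherits(a, "binary_connectome")) a$adj else a
  B <- if (inherits(b, "binary_connectome")) b$adj else b
  if (!all(dim(A) == dim(B))) stop("size mismatch between connectomes")
  ut <- upper.tri(A)
  av <- A[ut]; bv <- B[ut]
  na <- sum(av); nb <- sum(bv); ni <- sum(av & bv)
  if (na + nb == 0) return(100)
  if (type == "dice") 100 * 2 * ni / (na + nb)
  else 100 * ni / (na + nb - ni)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures, with edges as
#' targets and subjects as raters: quantifies how consistent edge values are
#' across subjects.
#'
#' @param stack subjects x edges numeric (or logical) matrix.
#' @return the ICC(2,1) value.
#' @export
icc <- function(stack) {
  stack <- as.matrix(stack) * 1.0
  if (nrow(stack) < 2 || ncol(stack) < 2)
    stop("icc needs at least 2 subjects and 2 edges")
  # targets (rows of the ANOVA layout) = edges, raters = subjects
  Y <- t(stack)
  n <- nrow(Y)  # targets
  k <- ncol(Y)  # raters
  mu <- mean(Y)
  row_m <- rowMeans(Y)
  col_m <- colMeans(Y)
  SSR <- k * sum((row_m - mu)^2)           # between targets
  SSC <- n * sum((col_m - mu)^2)           # between raters
  SSE <- sum((Y - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + mu)^2)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

#' Edge-wise group contrast between two cohorts of binary connectomes
#'
#' For every edge, reports the difference in the number of subjects carrying
#' that edge between cohorts (`count_a - count_b`) and a Mann-Whitney U test
#' on the per-subject 0/1 indicators, Bonferroni-corrected over the number of
#' edges.
#'
#' @param cohort_a,cohort_b lists of `binary_connectome`s.
#' @param alpha significance level applied after Bonferroni correction.
#' @return list with the per-edge `table` (data frame: edge indices, counts,
#'   difference, U, p, adjusted p, significance), `pct_nonzero` (percentage of
#'   edges with a non-zero count difference) and `pct_significant`.
#' @export
group_contrast <- function(cohort_a, cohort_b, alpha = 0.01) {
  if (length(cohort_a) == 0 || length(cohort_b) == 0) stop("empty cohorts")
  n <- nrow(cohort_a[[1]]$adj)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  stack_a <- vapply(cohort_a, function(c_) c_$adj[upper.tri(c_$adj)] * 1,
                    numeric(nrow(ut)))
  stack_b <- vapply(cohort_b, function(c_) c_$adj[upper.tri(c_$adj)] * 1,
                    numeric(nrow(ut)))
  count_a <- rowSums(stack_a)
  count_b <- rowSums(stack_b)
  m <- nrow(ut)
  u_stat <- p_val <- numeric(m)
  for (e in seq_len(m)) {
    if (all(stack_a[e, ] == stack_a[e, 1]) &&
        all(stack_b[e, ] == stack_b[e, 1]) &&
        stack_a[e, 1] == stack_b[e, 1]) {
      u_stat[e] <- ncol(stack_a) * ncol(stack_b) / 2
      p_val[e] <- 1
    } else {
      wt <- suppressWarnings(
        wilcox.test(stack_a[e, ], stack_b[e, ], exact = FALSE, correct = TRUE))
      u_stat[e] <- unname(wt$statistic)
      p_val[e] <- wt$p.value
    }
  }
  p_adj <- pmin(1, p_val * m)
  tab <- data.frame(i = ut[, 1], j = ut[, 2],
                    count_a = count_a, count_b = count_b,
                    diff = count_a - count_b,
                    U = u_stat, p = p_val, p_bonf = p_adj,
                    significant = p_adj < alpha)
  list(table = tab,
       pct_nonzero = 100 * mean(tab$diff != 0),
       pct_significant = 100 * mean(tab$significant))
}

#' Network-size sweep of thresholding performance
#'
#' Extracts subnetworks of the requested sizes (see [extract_subnetwork()])
#' and records the cohort-mean performance of each method at its canonical
#' parameter on every size. The full network size runs the plain evaluation
#' without node removal.
#'
#' @param panel a `bold_panel`.
#' @param truth the matching ground truth.
#' @param sizes network sizes to evaluate.
#' @param methods character vector of method names understood by
#'   [evaluate_methods()].
#' @param seed RNG seed for the node-removal paths and permutation nulls.
#' @param n_perm surrogate count for the permutation method.
#' @param params canonical parameters, see [canonical_params()].
#' @return data frame with columns `size`, `method`, `performance`, `TPR`,
#'   `FPR`, `FDR`.
#' @export
size_sweep <- function(panel, truth, sizes, methods = NULL, seed = 1L,
                       n_perm = 200L, params = canonical_params()) {
  out <- list()
  for (sz in sizes) {
    if (sz == truth$n_nodes) {
      sub <- list(panel = panel, truth = truth)
    } else {
      sub <- extract_subnetwork(panel, truth, sz, seed = seed)
    }
    ev <- evaluate_methods(sub$panel, sub$truth, methods = methods,
                           seed = seed, n_perm = n_perm, params = params)
    ev$size <- sz
    out[[length(out) + 1]] <- ev
  }
  do.call(rbind, out)[, c("size", "method", "performance", "TPR", "FPR", "FDR")]
}
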