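# constructor for binarized connectomes with provenance
.binary_connectome <- function(adj, method, parameter, threshold_value = NA,
                               flags = character(0)) {
  diag(adj) <- FALSE
  structure(list(adj = adj, method = method, parameter = parameter,
                 threshold_value = threshold_value, flags = flags,
                 density = sum(adj[upper.tri(adj)]) / choose(nrow(adj), 2)),
            class = "binary_connectome")
}

#' @export
print.binary_connectome <- function(x, ...) {
  cat(sprintf("binary_connectome (%s, parameter %s): %d nodes, density %.4f\n",
              x$method, paste(signif(unlist(x$parameter), 4), collapse = ","),
              nrow(x$adj), x$density))
  invisible(x)
}

#' Pseudo-FDR curve of a mixture fit
#'
#' For each candidate threshold `x` (the observed positive values plus a fine
#' grid over `[0, max]`), computes
#' `FDR(x) = p0 (1 - F0(x)) / (#\{t_i >= x\} / n)`:
#' the model-estimated null exceedance mass over the empirical fraction of
#' values above the threshold. Values may exceed 1 where the fitted mixture
#' overestimates the total density; they are reported unclipped.
#'
#' @param fit a [em_fit()] result.
#' @param z_std the standardized values the fit was computed on.
#' @param grid_n number of grid candidates added to the observed values.
#' @return a data frame with columns `x` and `fdr`.
#' @export
pseudo_fdr_curve <- function(fit, z_std, grid_n = 1000L) {
  stopifnot(inherits(fit, "mixture_fit"))
  x <- as.numeric(z_std)
  n <- length(x)
  pos <- sort(unique(x[x > 0]))
  if (length(pos) == 0)
    return(data.frame(x = numeric(0), fdr = numeric(0)))
  cand <- sort(unique(c(pos, seq(0, max(pos), length.out = grid_n))))
  xs <- sort(x)
  # exceedance count #{t_i >= c} via binary search on the sorted sample
  n_ge <- n - findInterval(cand, xs, left.open = TRUE)
  keep <- n_ge > 0
  cand <- cand[keep]; n_ge <- n_ge[keep]
  surv0 <- 1 - .null_cdf(fit$spec$null_family, fit$null_params, cand)
  data.frame(x = cand, fdr = fit$p0 * surv0 / (n_ge / n))
}

# threshold selection on a pseudo-FDR curve: the last down-crossing, i.e. the
# supremum of the violating set {x : FDR(x) > q}
.pfdr_pick_threshold <- function(x, fdr, q) {
  viol <- x[fdr > q]
  if (length(viol) == 0)
    return(list(threshold = min(x), flag = "all_pass"))
  t_ <- max(viol)
  if (t_ >= max(x))
    return(list(threshold = Inf, flag = "no_threshold"))
  list(threshold = t_, flag = character(0))
}

#' Threshold a connectome at a target pseudo-FDR
#'
#' Selects the highest candidate threshold passing the FDR cutoff: the
#' supremum of `{x : FDR(x) > q}`, so that every candidate above the returned
#' threshold satisfies `FDR <= q`. This choice is robust to the non-monotone
#' (non-bijective) shape the pseudo-FDR curve can take. Edges with
#' standardized values strictly above the threshold are kept. If no candidate
#' attains `FDR <= q` an empty connectome is returned with a `no_threshold`
#' flag.
#'
#' @param zc a standardized `z_connectome` (see [fisher_standardize()]).
#' @param fit the mixture fit computed on `zc$z_std`.
#' @param q target pseudo-FDR level in (0, 1).
#' @param grid_n passed to [pseudo_fdr_curve()].
#' @return a `binary_connectome`; `threshold_value` reports the cut on the
#'   standardized, z and partial-correlation scales.
#' @export
pfdr_threshold <- function(zc, fit, q = 0.05, grid_n = 1000L) {
  stopifnot(inherits(zc, "z_connectome"), !is.null(zc$z_std))
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  curve <- pseudo_fdr_curve(fit, zc$z_std, grid_n = grid_n)
  n <- nrow(zc$partial)
  adj <- matrix(FALSE, n, n, dimnames = dimnames(zc$partial))
  if (nrow(curve) == 0)
    return(.binary_connectome(adj, "pfdr", q, NA, "no_positive_values"))
  pick <- .pfdr_pick_threshold(curve$x, curve$fdr, q)
  if (is.infinite(pick$threshold))
    return(.binary_connectome(adj, "pfdr", q,
                              .threshold_scales(max(curve$x), zc$standardizer),
                              "no_threshold"))
  keep <- zc$z_std > pick$threshold
  ut <- upper.tri(adj)
  adj[ut] <- keep
  adj <- adj | t(adj)
  .binary_connectome(adj, "pfdr", q,
                     .threshold_scales(pick$threshold, zc$standardizer),
                     pick$flag)
}

#' Hard thresholding
#'
#' Keeps every edge whose weight strictly exceeds a fixed cut (0.0 by
#' default, i.e. all positive partial correlations).
#'
#' @param partial square symmetric weight matrix (or a `z_connectome`).
#' @param cut threshold on the weight scale.
#' @export
hard_threshold <- function(partial, cut = 0.0) {
  if (inherits(partial, "z_connectome")) partial <- partial$partial
  stopifnot(is.matrix(partial), nrow(partial) == ncol(partial))
  adj <- partial > cut
  adj <- adj | t(adj)
  .binary_connectome(adj, "hard", cut, cut)
}

#' Proportional thresholding
#'
#' Keeps the top `floor(fraction * n(n-1)/2)` upper-triangle weights. Ties at
#' the boundary are broken by (row, column) lexical order so the result is
#' reproducible; the realized density is exactly `k / (n(n-1)/2)`.
#'
#' @param partial square symmetric weight matrix (or a `z_connectome`).
#' @param fraction proportion of node pairs to keep, in (0, 1].
#' @export
proportional_threshold <- function(partial, fraction) {
  if (inherits(partial, "z_connectome")) partial <- partial$partial
  stopifnot(is.matrix(partial), nrow(partial) == ncol(partial))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- nrow(partial)
  ut <- which(upper.tri(partial), arr.ind = TRUE)
  vals <- partial[upper.tri(partial)]
  k <- floor(fraction * nrow(ut))
  adj <- matrix(FALSE, n, n, dimnames = dimnames(partial))
  flags <- character(0)
  thr <- NA_real_
  if (k == 0) {
    flags <- "empty"
    warning("proportional threshold keeps zero edges (k = 0)")
  } else {
    o <- order(-vals, ut[, 1], ut[, 2])
    sel <- o[seq_len(k)]
    adj[ut[sel, , drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    thr <- min(vals[sel])
  }
  .binary_connectome(adj, "proportional", fraction, thr, flags)
}

# partial correlations of one surrogate dataset, upper triangle
.surrogate_partial <- function(ts, cov_method) {
  zc <- precision_to_partial(estimate_covariance(ts, cov_method))
  zc$partial[upper.tri(zc$partial)]
}

#' Group-level permutation thresholds
#'
#' Builds edge-wise null distributions by reassigning, independently per node,
#' that node's time series from a randomly chosen subject. This breaks the
#' between-node coupling while keeping each node's temporal autocorrelation
#' intact. Partial correlations of the surrogate datasets form a per-edge
#' null; the per-edge cut is the upper one-sided `1 - p` quantile, and each
#' real subject's connectome is binarized edge-wise against these cuts.
#'
#' @param panel a `bold_panel` with at least 2 subjects.
#' @param cov_method covariance estimator for the surrogate and subject
#'   partial correlations.
#' @param n_perm number of surrogate datasets (at least 20).
#' @param p one-sided significance level; requires `p >= 1/n_perm`.
#' @param seed RNG seed for the surrogate assignments.
#' @return an object of class `permutation_null`: per-edge cuts, the matrix of
#'   surrogate partial correlations (`n_perm` x edges, reusable for threshold
#'   sweeps) and one `binary_connectome` per subject.
#' @export
permutation_group <- function(panel, cov_method = c("ledoit_wolf", "empirical"),
                              n_perm = 1000L, p = 0.05, seed = 1L) {
  cov_method <- match.arg(cov_method)
  stopifnot(inherits(panel, "bold_panel"))
  n_sub <- dim(panel$data)[1]
  if (n_sub < 2) stop("permutation_group needs at least 2 subjects")
  if (n_perm < 20) stop("n_perm must be at least 20")
  if (p < 1 / n_perm)
    stop("resolution error: p < 1/n_perm cannot be resolved")
  n <- dim(panel$data)[2]
  set.seed(as.integer(seed))
  null_mat <- matrix(NA_real_, n_perm, choose(n, 2))
  for (b in seq_len(n_perm)) {
    pick <- sample.int(n_sub, n, replace = TRUE)
    ts <- t(vapply(seq_len(n), function(i) panel$data[pick[i], i, ],
                   numeric(dim(panel$data)[3])))
    rownames(ts) <- dimnames(panel$data)[[2]]
    null_mat[b, ] <- .surrogate_partial(ts, cov_method)
  }
  res <- permutation_apply(null_mat, panel, cov_method, p)
  structure(list(cuts = res$cuts, null = null_mat, p = p,
                 cov_method = cov_method,
                 connectomes = res$connectomes, seed = as.integer(seed)),
            class = "permutation_null")
}

#' Re-threshold a panel against an existing permutation null
#'
#' @param null_mat surrogate partial correlations (`n_perm` x edges), e.g.
#'   `permutation_group(...)$null`.
#' @param panel the `bold_panel` to binarize.
#' @param cov_method covariance estimator for the subject connectomes.
#' @param p one-sided significance level.
#' @return list with per-edge `cuts` and per-subject `connectomes`.
#' @export
permutation_apply <- function(null_mat, panel,
                              cov_method = c("ledoit_wolf", "empirical"), p) {
  cov_method <- match.arg(cov_method)
  n <- dim(panel$data)[2]
  cuts <- apply(null_mat, 2, quantile, probs = 1 - p, names = FALSE)
  connectomes <- lapply(seq_len(dim(panel$data)[1]), function(s) {
    pc <- .surrogate_partial(panel_ts(panel, s), cov_method)
    adj <- matrix(FALSE, n, n, dimnames = dimnames(panel$data)[c(2, 2)])
    adj[upper.tri(adj)] <- pc > cuts
    adj <- adj | t(adj)
    .binary_connectome(adj, "perm_group", p)
  })
  list(cuts = cuts, connectomes = connectomes)
}

#' Subject-level permutation thresholds
#'
#' Builds surrogate datasets from one subject's own time series by
#' independently circularly shifting each node's series by a random non-zero
#' offset (preserving the autocorrelation structure), or, in `"shuffle"` mode,
#' by fully permuting the samples of each node (which destroys
#' autocorrelation and inflates false positives on autocorrelated data). The
#' per-edge cut is the upper one-sided `1 - p` quantile of the surrogate
#' partial correlations.
#'
#' @param ts nodes x timepoints matrix of one subject.
#' @param cov_method covariance estimator.
#' @param n_perm number of surrogates (at least 20).
#' @param p one-sided significance level; requires `p >= 1/n_perm`.
#' @param seed RNG seed.
#' @param mode `"circular"` (default) or `"shuffle"`.
#' @return a `binary_connectome` with per-edge cuts in `threshold_value`.
#' @export
permutation_subject <- function(ts, cov_method = c("ledoit_wolf", "empirical"),
                                n_perm = 1000L, p = 0.05, seed = 1L,
                                mode = c("circular", "shuffle")) {
  cov_method <- match.arg(cov_method)
  mode <- match.arg(mode)
  stopifnot(is.matrix(ts))
  if (n_perm < 20) stop("n_perm must be at least 20")
  if (p < 1 / n_perm)
    stop("resolution error: p < 1/n_perm cannot be resolved")
  n <- nrow(ts); Tn <- ncol(ts)
  set.seed(as.integer(seed))
  null_mat <- matrix(NA_real_, n_perm, choose(n, 2))
  for (b in seq_len(n_perm)) {
    surr <- ts
    for (i in seq_len(n)) {
      if (mode == "circular") {
        off <- sample.int(Tn - 1L, 1L)  # zero shift excluded
        surr[i, ] <- ts[i, c((off + 1):Tn, 1:off)]
      } else {
        surr[i, ] <- ts[i, sample.int(Tn)]
      }
    }
    null_mat[b, ] <- .surrogate_partial(surr, cov_method)
  }
  cuts <- apply(null_mat, 2, quantile, probs = 1 - p, names = FALSE)
  pc <- .surrogate_partial(ts, cov_method)
  adj <- matrix(FALSE, n, n, dimnames = list(rownames(ts), rownames(ts)))
  adj[upper.tri(adj)] <- pc > cuts
  adj <- adj | t(adj)
  out <- .binary_connectome(adj, paste0("perm_subject_", mode), p, cuts)
  out$null <- null_mat
  out
}
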