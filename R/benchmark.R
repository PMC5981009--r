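#' Canonical thresholding parameters
#'
#' The parameter set used throughout the benchmark comparisons: hard cut 0.0
#' for the empirical-precision and Ledoit-Wolf methods, p = 0.05 for
#' permutation testing, pseudo-FDR q = 0.05 for mixture modeling, and
#' proportions 5% and 10% for proportional thresholding.
#'
#' @export
canonical_params <- function() {
  list(hard_cut = 0.0, p = 0.05, q = 0.05, proportions = c(0.05, 0.10))
}

#' Standardized connectomes for a whole cohort
#'
#' @param panel a `bold_panel`.
#' @param method covariance estimator.
#' @return list of standardized `z_connectome`s, one per subject.
#' @export
cohort_connectomes <- function(panel, method = c("ledoit_wolf", "empirical")) {
  method <- match.arg(method)
  lapply(seq_len(dim(panel$data)[1]), function(s)
    partial_connectome(panel_ts(panel, s), method))
}

#' Fit the mixture variants across a cohort
#'
#' Fits the requested mixture families to each subject's standardized values
#' for one covariance method.
#'
#' @param zcs list of standardized `z_connectome`s.
#' @param specs list of [mixture_spec()]s (defaults to the four families for
#'   the covariance method of the first connectome).
#' @param tol,max_iter passed to [em_fit()].
#' @return list (per spec) of lists (per subject) of `mixture_fit`s.
#' @export
cohort_fits <- function(zcs, specs = NULL, tol = 0.001, max_iter = 500L) {
  if (is.null(specs)) {
    cm <- zcs[[1]]$cov_method
    specs <- Filter(function(sp) sp$covariance_method == cm, mixture_variants())
  }
  lapply(specs, function(sp)
    lapply(zcs, function(zc) em_fit(zc$z_std, sp, tol = tol,
                                    max_iter = max_iter)))
}

#' Rank the eight mixture variants on a cohort by mean BIC
#'
#' Computes the four mixture-family fits on both covariance methods for every
#' subject and averages the per-subject BIC per variant.
#'
#' @param panel a `bold_panel` (or `zcs_lw`/`zcs_emp` supplied directly).
#' @param zcs_lw,zcs_emp optional precomputed cohort connectomes.
#' @return data frame with columns `variant` and `mean_bic`, ascending.
#' @export
variant_bic_table <- function(panel = NULL, zcs_lw = NULL, zcs_emp = NULL) {
  if (is.null(zcs_lw)) zcs_lw <- cohort_connectomes(panel, "ledoit_wolf")
  if (is.null(zcs_emp)) zcs_emp <- cohort_connectomes(panel, "empirical")
  variants <- mixture_variants()
  mean_bic <- vapply(names(variants), function(nm) {
    sp <- variants[[nm]]
    zcs <- if (sp$covariance_method == "ledoit_wolf") zcs_lw else zcs_emp
    mean(vapply(zcs, function(zc) mixture_bic(em_fit(zc$z_std, sp)),
                numeric(1)))
  }, numeric(1))
  out <- data.frame(variant = names(variants), mean_bic = mean_bic,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$mean_bic), , drop = FALSE]
}

#' Evaluate the six thresholding methods at canonical parameters
#'
#' Runs, against the ground truth: empirical precision and Ledoit-Wolf
#' partial correlations with the hard cut, group-level permutation testing,
#' mixture-model pseudo-FDR thresholding (Gauss-Gamma on Ledoit-Wolf
#' partials), and proportional thresholding at the two canonical proportions.
#'
#' @param panel a `bold_panel`.
#' @param truth the matching ground truth.
#' @param methods subset of `c("ep_hard", "lw_hard", "perm", "mm",
#'   "prop05", "prop10")`; default all six.
#' @param seed RNG seed (permutation surrogates).
#' @param n_perm surrogate count for permutation testing.
#' @param params canonical parameters, see [canonical_params()].
#' @param zcs_lw,zcs_emp optional precomputed cohort connectomes.
#' @param fits_mm optional precomputed Gauss-Gamma fits on `zcs_lw`.
#' @return data frame with one row per method: `performance`, `TPR`, `FPR`,
#'   `FDR`.
#' @export
evaluate_methods <- function(panel, truth, methods = NULL, seed = 1L,
                             n_perm = 1000L, params = canonical_params(),
                             zcs_lw = NULL, zcs_emp = NULL, fits_mm = NULL) {
  all_methods <- c("ep_hard", "lw_hard", "perm", "mm", "prop05", "prop10")
  if (is.null(methods)) methods <- all_methods
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  need_lw <- any(c("lw_hard", "mm", "prop05", "prop10") %in% methods)
  need_emp <- "ep_hard" %in% methods
  if (need_lw && is.null(zcs_lw)) zcs_lw <- cohort_connectomes(panel, "ledoit_wolf")
  if (need_emp && is.null(zcs_emp)) zcs_emp <- cohort_connectomes(panel, "empirical")

  rows <- list()
  add <- function(name, ests)
    rows[[name]] <<- c(method = name, .cohort_rates(ests, truth))
  if ("ep_hard" %in% methods)
    add("ep_hard", lapply(zcs_emp, hard_threshold, cut = params$hard_cut))
  if ("lw_hard" %in% methods)
    add("lw_hard", lapply(zcs_lw, hard_threshold, cut = params$hard_cut))
  if ("perm" %in% methods) {
    pg <- permutation_group(panel, "ledoit_wolf", n_perm = n_perm,
                            p = params$p, seed = seed)
    add("perm", pg$connectomes)
  }
  if ("mm" %in% methods) {
    if (is.null(fits_mm))
      fits_mm <- lapply(zcs_lw, function(zc)
        em_fit(zc$z_std, mixture_spec("gaussian", "gamma", "ledoit_wolf")))
    add("mm", lapply(seq_along(zcs_lw), function(s)
      pfdr_threshold(zcs_lw[[s]], fits_mm[[s]], q = params$q)))
  }
  if ("prop05" %in% methods)
    add("prop05", lapply(zcs_lw, proportional_threshold,
                         fraction = params$proportions[1]))
  if ("prop10" %in% methods)
    add("prop10", lapply(zcs_lw, proportional_threshold,
                         fraction = params$proportions[2]))

  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  out$performance <- as.numeric(out$performance)
  out$TPR <- as.numeric(out$TPR)
  out$FPR <- as.numeric(out$FPR)
  out$FDR <- as.numeric(out$FDR)
  rownames(out) <- NULL
  out
}

#' Cohort-mean ROC points for one method over its sweep parameter
#'
#' Sweeps the method's scalar parameter (pseudo-FDR q, permutation p, hard
#' cut, or kept proportion) and records the cohort-mean (FPR, TPR) per
#' parameter value. Log grids over `[1e-4, 0.5]` are used for q and p, the
#' hard cut sweeps observed-value quantiles, and proportions sweep 1%-50%.
#'
#' @param method one of `"mm"`, `"perm"`, `"ep_hard"`, `"lw_hard"`, `"prop"`.
#' @param panel,truth benchmark cohort and ground truth.
#' @param seed,n_perm permutation settings (method `"perm"`).
#' @param grid_n number of sweep points.
#' @param zcs_lw,zcs_emp,fits_mm optional precomputed inputs.
#' @return data frame with columns `param`, `fpr`, `tpr`.
#' @export
roc_table <- function(method = c("mm", "perm", "ep_hard", "lw_hard", "prop"),
                      panel, truth, seed = 1L, n_perm = 1000L, grid_n = 41L,
                      zcs_lw = NULL, zcs_emp = NULL, fits_mm = NULL) {
  method <- match.arg(method)
  rates_for <- function(ests)
    .cohort_rates(ests, truth)[c("FPR", "TPR")]
  if (method %in% c("mm", "lw_hard", "prop") && is.null(zcs_lw))
    zcs_lw <- cohort_connectomes(panel, "ledoit_wolf")
  if (method == "ep_hard" && is.null(zcs_emp))
    zcs_emp <- cohort_connectomes(panel, "empirical")

  if (method == "mm") {
    if (is.null(fits_mm))
      fits_mm <- lapply(zcs_lw, function(zc)
        em_fit(zc$z_std, mixture_spec("gaussian", "gamma", "ledoit_wolf")))
    # the pseudo-FDR sweep must run close to 1 for the realized FPR of the
    # mean ROC to cover the clipped range
    grid <- exp(seq(log(1e-4), log(0.99), length.out = grid_n))
    pts <- t(vapply(grid, function(q) {
      rates_for(lapply(seq_along(zcs_lw), function(s)
        pfdr_threshold(zcs_lw[[s]], fits_mm[[s]], q = q)))
    }, numeric(2)))
  } else if (method == "perm") {
    pg <- permutation_group(panel, "ledoit_wolf", n_perm = n_perm,
                            p = max(0.5, 1 / n_perm), seed = seed)
    grid <- exp(seq(log(max(1e-4, 1 / n_perm)), log(0.5), length.out = grid_n))
    pts <- t(vapply(grid, function(p) {
      res <- permutation_apply(pg$null, panel, "ledoit_wolf", p)
      rates_for(res$connectomes)
    }, numeric(2)))
  } else if (method %in% c("ep_hard", "lw_hard")) {
    zcs <- if (method == "ep_hard") zcs_emp else zcs_lw
    vals <- unlist(lapply(zcs, function(zc) zc$partial[upper.tri(zc$partial)]))
    grid <- unique(quantile(vals, probs = seq(0.02, 0.995, length.out = grid_n),
                            names = FALSE))
    pts <- t(vapply(grid, function(cut)
      rates_for(lapply(zcs, hard_threshold, cut = cut)), numeric(2)))
  } else {
    grid <- seq(0.01, 0.5, length.out = grid_n)
    pts <- t(vapply(grid, function(fr)
      rates_for(lapply(zcs_lw, proportional_threshold, fraction = fr)),
      numeric(2)))
  }
  data.frame(param = grid, fpr = pts[, 1], tpr = pts[, 2])
}

#' Generate one scaled benchmark replicate
#'
#' Builds the ground-truth network and simulates a cohort under the benchmark
#' study conditions (defaults: 10-minute sessions at TR 3.0 s, 1% thermal
#' noise, 0.5 s haemodynamic-lag SD).
#'
#' @param seed master seed for topology and cohort.
#' @param n_subjects,n_nodes cohort and network size.
#' @param duration_s,TR_s session length and sampling time (seconds).
#' @param ... further arguments to [simulation_config()].
#' @return list with `truth` and `panel`.
#' @export
benchmark_cohort <- function(seed = 1L, n_subjects = 50L, n_nodes = 50L,
                             duration_s = 600, TR_s = 3.0, ...) {
  truth <- build_topology(n_nodes, seed = seed)
  cfg <- simulation_config(n_subjects = n_subjects, n_nodes = n_nodes,
                           duration_s = duration_s, TR_s = TR_s,
                           seed = seed, ...)
  list(truth = truth, panel = generate_cohort(truth, cfg))
}
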