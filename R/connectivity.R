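#' Estimate a covariance matrix from regional time series
#'
#' Computes either the maximum-likelihood sample covariance (denominator `T`,
#' the number of time points) or its Ledoit-Wolf shrinkage version with the
#' constant-correlation target: the target matrix keeps the sample variances
#' and replaces every correlation by the average sample correlation, and the
#' shrinkage intensity is the closed-form asymptotically optimal estimate,
#' clipped to `[0, 1]`. The result is symmetrized and checked for positive
#' definiteness.
#'
#' @param ts nodes x timepoints numeric matrix (one row per node).
#' @param method `"empirical"` or `"ledoit_wolf"`.
#' @return an object of class `covariance_estimate` with fields `S`, `method`,
#'   `shrinkage`, `n_obs` and `nodes`.
#' @export
estimate_covariance <- function(ts, method = c("ledoit_wolf", "empirical")) {
  method <- match.arg(method)
  if (!is.matrix(ts) || nrow(ts) < 2 || ncol(ts) < 2)
    stop("ts must be a nodes x timepoints matrix with >= 2 nodes and >= 2 time points")
  if (!all(is.finite(ts))) stop("ts contains non-finite values")
  X <- t(ts)                             # T x n
  Tn <- nrow(X); n <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / Tn                # ML denominator T
  S <- (S + t(S)) / 2
  shrink <- 0

  if (method == "ledoit_wolf") {
    sv <- diag(S)
    if (any(sv <= 0)) stop("singular-covariance error: a node has zero variance")
    sd_ <- sqrt(sv)
    R <- S / tcrossprod(sd_)
    rbar <- (sum(R) - n) / (n * (n - 1))
    F_ <- rbar * tcrossprod(sd_)
    diag(F_) <- sv

    # closed-form optimal intensity (constant-correlation target)
    Y <- Xc
    pi_mat <- crossprod(Y^2) / Tn - S^2
    pi_hat <- sum(pi_mat)
    gamma_hat <- sum((F_ - S)^2)
    # theta_{ii,ij}: asymptotic covariances between variances and covariances
    term1 <- crossprod(Y^3, Y) / Tn
    theta <- term1 - sv * S                # theta[i, j] = theta_{ii, ij}
    diag(theta) <- 0
    rho_hat <- sum(diag(pi_mat)) +
      rbar * sum(outer(1 / sd_, sd_) * theta)
    kappa_hat <- if (gamma_hat > 0) (pi_hat - rho_hat) / gamma_hat else 0
    shrink <- max(0, min(1, kappa_hat / Tn))
    S <- (1 - shrink) * S + shrink * F_
    S <- (S + t(S)) / 2
  }

  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ok <- ev[length(ev)] > max(ev) * 1e-10
  if (!ok) {
    hint <- if (method == "empirical")
      " (try method = 'ledoit_wolf' or add jitter)" else ""
    stop("singular-covariance error: estimate is not positive-definite", hint)
  }
  structure(list(S = S, method = method, shrinkage = shrink, n_obs = Tn,
                 nodes = rownames(ts)),
            class = "covariance_estimate")
}

#' Partial correlations from a precision matrix
#'
#' Inverts the covariance estimate and normalizes the negated off-diagonal of
#' the precision matrix `P` by its diagonal: `partial_ij = -P_ij /
#' sqrt(P_ii P_jj)`. This equals the correlation between the two nodes after
#' regressing out all other nodes.
#'
#' @param cov a [estimate_covariance()] result.
#' @return an object of class `z_connectome` with the `partial` field filled
#'   (diagonal 1, symmetric, entries in (-1, 1)).
#' @export
precision_to_partial <- function(cov) {
  stopifnot(inherits(cov, "covariance_estimate"))
  P <- tryCatch(chol2inv(chol(cov$S)),
                error = function(e) stop("singular-covariance error: inversion failed"))
  d <- sqrt(diag(P))
  partial <- -P / tcrossprod(d)
  diag(partial) <- 1
  partial <- (partial + t(partial)) / 2
  if (!is.null(cov$nodes)) dimnames(partial) <- list(cov$nodes, cov$nodes)
  structure(list(partial = partial, z = NULL, z_std = NULL,
                 standardizer = NULL, cov_method = cov$method,
                 shrinkage = cov$shrinkage, nodes = cov$nodes),
            class = "z_connectome")
}

#' Fisher-transform and standardize a partial-correlation connectome
#'
#' Applies the Fisher r-to-z transform `z = atanh(partial)` off-diagonal and
#' standardizes the upper-triangle values to mean 0 and SD 1 (self-connections
#' are excluded throughout). The standardizer (mean, SD) is stored so that
#' thresholds selected on the standardized scale can be mapped back to z and
#' partial-correlation units.
#'
#' @param zc a `z_connectome` with the `partial` field filled.
#' @return the same object with `z`, `z_std` and `standardizer` filled.
#' @export
fisher_standardize <- function(zc) {
  stopifnot(inherits(zc, "z_connectome"))
  p <- zc$partial
  off <- p[upper.tri(p) | lower.tri(p)]
  if (any(abs(off) >= 1))
    stop("transform-domain error: |partial| >= 1 off-diagonal")
  z <- atanh(p)
  diag(z) <- 0
  ut <- z[upper.tri(z)]
  m <- mean(ut)
  s <- sd(ut)
  if (!is.finite(s) || s <= .Machine$double.eps)
    stop("transform-domain error: degenerate standardization (SD = 0)")
  zc$z <- z
  zc$z_std <- (ut - m) / s
  zc$standardizer <- c(mean = m, sd = s)
  zc
}

#' @export
print.z_connectome <- function(x, ...) {
  n <- nrow(x$partial)
  cat(sprintf("z_connectome: %d nodes (%s covariance%s)%s\n", n, x$cov_method,
              if (x$cov_method == "ledoit_wolf")
                sprintf(", shrinkage %.3f", x$shrinkage) else "",
              if (is.null(x$z_std)) " [not yet standardized]" else ""))
  invisible(x)
}

#' Partial-correlation connectome pipeline
#'
#' Convenience wrapper: covariance estimation, precision-based partial
#' correlations and Fisher standardization in one call.
#'
#' @inheritParams estimate_covariance
#' @return a fully populated `z_connectome`.
#' @export
partial_connectome <- function(ts, method = c("ledoit_wolf", "empirical")) {
  fisher_standardize(precision_to_partial(estimate_covariance(ts, method)))
}

# map a threshold on the standardized scale back to z and partial units
.threshold_scales <- function(t_std, standardizer) {
  z <- t_std * standardizer[["sd"]] + standardizer[["mean"]]
  c(z_std = t_std, z = z, partial = tanh(z))
}
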