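#' Mixture specification
#'
#' One of the eight admissible estimator-by-mixture variants: the pseudo-null
#' family (Gaussian or Laplace), the signal family for reliable connections
#' (Gamma or Inverse-Gamma, both supported on positive values only) and the
#' covariance estimator feeding the partial correlations (empirical or
#' Ledoit-Wolf).
#'
#' @param null_family `"gaussian"` or `"laplace"`.
#' @param signal_family `"gamma"` or `"inverse_gamma"`.
#' @param covariance_method `"ledoit_wolf"` or `"empirical"`.
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(null_family = c("gaussian", "laplace"),
                         signal_family = c("gamma", "inverse_gamma"),
                         covariance_method = c("ledoit_wolf", "empirical")) {
  structure(list(null_family = match.arg(null_family),
                 signal_family = match.arg(signal_family),
                 covariance_method = match.arg(covariance_method)),
            class = "mixture_spec")
}

#' All eight mixture variants
#'
#' @return a named list of [mixture_spec()] objects; names follow the field
#'   abbreviations (GG, GIG, LG, LIG) suffixed with the covariance method.
#' @export
mixture_variants <- function() {
  out <- list()
  for (cm in c("ledoit_wolf", "empirical"))
    for (nf in c("gaussian", "laplace"))
      for (sf in c("gamma", "inverse_gamma")) {
        ab <- paste0(if (nf == "gaussian") "G" else "L",
                     if (sf == "gamma") "G" else "IG")
        out[[paste0(ab, "_", if (cm == "ledoit_wolf") "lw" else "emp")]] <-
          mixture_spec(nf, sf, cm)
      }
  out
}

# Laplace density/CDF, parameterized by location and scale b
.dlaplace <- function(x, location = 0, scale = 1)
  exp(-abs(x - location) / scale) / (2 * scale)
.plaplace <- function(q, location = 0, scale = 1) {
  z <- (q - location) / scale
  ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
}
# Inverse-Gamma density, shape a and scale b: b^a x^{-a-1} exp(-b/x)/Gamma(a)
.dinvgamma <- function(x, shape, scale) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- exp(shape * log(scale) - lgamma(shape) -
                    (shape + 1) * log(x[pos]) - scale / x[pos])
  out
}

#' Component probability density
#'
#' Densities of the mixture components. The Gaussian and Laplace families are
#' defined on the whole real line; the Gamma (shape/rate) and Inverse-Gamma
#' (shape/scale) families are zero for `x <= 0`.
#'
#' @param family one of `"gaussian"`, `"laplace"`, `"gamma"`,
#'   `"inverse_gamma"`.
#' @param params numeric vector of length 2: (location, scale) for the null
#'   families; (shape, rate) for Gamma; (shape, scale) for Inverse-Gamma.
#' @param x values at which to evaluate the density.
#' @export
component_pdf <- function(family, params, x) {
  family <- match.arg(family, c("gaussian", "laplace", "gamma", "inverse_gamma"))
  if (length(params) != 2 || !all(is.finite(params)))
    stop("parameter error: params must be two finite numbers")
  if (params[2] <= 0)
    stop("parameter error: scale/rate must be positive")
  if (family %in% c("gamma", "inverse_gamma") && params[1] <= 0)
    stop("parameter error: shape must be positive")
  switch(family,
         gaussian = dnorm(x, params[1], params[2]),
         laplace = .dlaplace(x, params[1], params[2]),
         gamma = ifelse(x > 0, dgamma(x, shape = params[1], rate = params[2]), 0),
         inverse_gamma = .dinvgamma(x, params[1], params[2]))
}

# null CDF used by the pseudo-FDR curve
.null_cdf <- function(family, params, x) {
  switch(family,
         gaussian = pnorm(x, params[1], params[2]),
         laplace = .plaplace(x, params[1], params[2]))
}

#' Initial mixture parameters
#'
#' Deterministic initialization on standardized data: the null starts at
#' location 0 with SD 1 (for Laplace the scale is `1/sqrt(2)` so that the
#' distribution SD is 1), the signal component is moment-matched to mean 3 and
#' variance 1 (Gamma shape 9, rate 3; Inverse-Gamma shape 11, scale 30), and
#' the mixing proportions start flat at 0.5/0.5.
#'
#' @param spec a [mixture_spec()].
#' @return a list with `p0`, `null_params`, `signal_params`.
#' @export
initialize_fit <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  null_params <- if (spec$null_family == "gaussian") c(0, 1) else c(0, 1 / sqrt(2))
  signal_params <- if (spec$signal_family == "gamma") c(9, 3) else c(11, 30)
  list(p0 = 0.5, null_params = null_params, signal_params = signal_params)
}

.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

# weighted ML shape for a Gamma sample: solve log(a) - digamma(a) = s by
# Newton iterations, with a moment-matching fallback
.gamma_shape_ml <- function(s, a0, max_newton = 25L) {
  if (!is.finite(s) || s <= 0) return(list(shape = NA_real_, ok = FALSE))
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # standard starting value
  if (!is.finite(a) || a <= 0) a <- a0
  ok <- FALSE
  for (it in seq_len(max_newton)) {
    g <- log(a) - digamma(a) - s
    gp <- 1 / a - trigamma(a)
    step <- g / gp
    a_new <- a - step
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    a <- min(max(a_new, 0.1), 500)
    if (abs(g) < 1e-12) { ok <- TRUE; break }
  }
  if (abs(log(a) - digamma(a) - s) < 1e-6) ok <- TRUE
  list(shape = a, ok = ok)
}

#' Fit a two-component mixture by expectation-maximization
#'
#' Models standardized Fisher-z partial-correlation values as
#' `p0 f0 + (1 - p0) f1`, where `f0` is the pseudo-null (Gaussian or Laplace)
#' and `f1` the positive signal component (Gamma or Inverse-Gamma). Values at
#' or below zero get zero signal responsibility (the signal support is
#' positive) but still inform the null location and scale. Null parameters are
#' updated by weighted maximum likelihood (weighted mean/SD for Gaussian,
#' weighted median and mean absolute deviation for Laplace); Gamma and
#' Inverse-Gamma shapes are updated by Newton iterations on the weighted
#' digamma score with a moment-matching fallback. Iteration stops when the
#' absolute change in total log-likelihood drops below `tol`.
#'
#' @param z_std numeric vector of standardized values (at least 10).
#' @param spec a [mixture_spec()].
#' @param tol convergence cut-off on the log-likelihood change.
#' @param max_iter maximum number of EM iterations.
#' @param tol_type `"absolute"` (default) or `"relative"` change.
#' @return an object of class `mixture_fit` with fields `p0`, `null_params`,
#'   `signal_params`, `loglik_trace`, `n_iter`, `converged`, `n`, `spec` and
#'   `flags`.
#' @export
em_fit <- function(z_std, spec, tol = 0.001, max_iter = 500L,
                   tol_type = c("absolute", "relative")) {
  stopifnot(inherits(spec, "mixture_spec"))
  tol_type <- match.arg(tol_type)
  x <- as.numeric(z_std)
  if (length(x) < 10) stop("em_fit needs at least 10 values")
  if (!all(is.finite(x))) stop("z_std contains non-finite values")

  init <- initialize_fit(spec)
  p0 <- init$p0
  np <- init$null_params
  sp <- init$signal_params
  pos <- x > 0
  flags <- character(0)
  ll_trace <- numeric(0)
  converged <- FALSE
  tiny <- 1e-300

  for (it in seq_len(max_iter)) {
    f0 <- component_pdf(spec$null_family, np, x)
    f1 <- component_pdf(spec$signal_family, sp, x)
    den <- p0 * f0 + (1 - p0) * f1
    den <- pmax(den, tiny)
    ll <- sum(log(den))
    if (!is.finite(ll))
      stop(sprintf("numerical error: non-finite likelihood at iteration %d", it))
    ll_trace <- c(ll_trace, ll)
    if (it > 1) {
      d <- abs(ll - ll_trace[it - 1])
      if (tol_type == "relative") d <- d / max(abs(ll_trace[it - 1]), tiny)
      if (d < tol) { converged <- TRUE; break }
    }

    # E-step
    r <- (1 - p0) * f1 / den
    r[!pos] <- 0

    # M-step
    p1 <- mean(r)
    if (p1 < 1e-8) {
      flags <- union(flags, "degenerate_p1")
      p1 <- 1e-8
    }
    p0 <- 1 - p1
    w0 <- 1 - r
    sw0 <- sum(w0)
    if (spec$null_family == "gaussian") {
      mu <- sum(w0 * x) / sw0
      s0 <- sqrt(sum(w0 * (x - mu)^2) / sw0)
      np <- c(mu, max(s0, 1e-6))
    } else {
      mu <- .weighted_median(x, w0)
      b <- sum(w0 * abs(x - mu)) / sw0
      np <- c(mu, max(b, 1e-6))
    }
    w1 <- r[pos]
    xp <- x[pos]
    sw1 <- sum(w1)
    if (sw1 > 1e-8) {
      if (spec$signal_family == "gamma") {
        m1 <- sum(w1 * xp) / sw1
        lm1 <- sum(w1 * log(xp)) / sw1
        s_stat <- log(m1) - lm1
        sh <- .gamma_shape_ml(s_stat, sp[1])
        if (is.finite(sh$shape) && sh$ok) {
          a <- sh$shape
        } else {
          # moment-matching fallback
          v1 <- sum(w1 * (xp - m1)^2) / sw1
          a <- min(max(m1^2 / max(v1, 1e-12), 0.1), 500)
          flags <- union(flags, "moment_fallback")
        }
        sp <- c(a, a / m1)
      } else {
        y <- 1 / xp
        my <- sum(w1 * y) / sw1
        lmy <- sum(w1 * log(y)) / sw1
        s_stat <- log(my) - lmy
        sh <- .gamma_shape_ml(s_stat, sp[1])
        if (is.finite(sh$shape) && sh$ok) {
          a <- sh$shape
        } else {
          vy <- sum(w1 * (y - my)^2) / sw1
          a <- min(max(my^2 / max(vy, 1e-12), 0.1), 500)
          flags <- union(flags, "moment_fallback")
        }
        sp <- c(a, a / my)  # scale of the inverse-gamma = rate of 1/x's gamma
      }
    } else {
      flags <- union(flags, "empty_signal")
    }
  }

  structure(list(p0 = p0,
                 null_params = setNames(np, c("location", "scale")),
                 signal_params = setNames(
                   sp, if (spec$signal_family == "gamma")
                     c("shape", "rate") else c("shape", "scale")),
                 loglik_trace = ll_trace,
                 n_iter = length(ll_trace),
                 converged = converged,
                 n = length(x),
                 spec = spec,
                 flags = flags),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: %s null + %s signal (cov: %s)\n",
              x$spec$null_family, x$spec$signal_family,
              x$spec$covariance_method))
  cat(sprintf("  p0 = %.4f; null = (%.4f, %.4f); signal = (%.4f, %.4f)\n",
              x$p0, x$null_params[1], x$null_params[2],
              x$signal_params[1], x$signal_params[2]))
  cat(sprintf("  logL = %.3f after %d iterations (%s)\n",
              tail(x$loglik_trace, 1), x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Bayesian Information Criterion of a mixture fit
#'
#' `BIC = k ln(n) - 2 logL` with `k = 5` free parameters (mixing weight, two
#' null parameters, two signal parameters).
#'
#' @param fit a [em_fit()] result.
#' @export
mixture_bic <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  5 * log(fit$n) - 2 * tail(fit$loglik_trace, 1)
}

#' Rank mixture variants by BIC
#'
#' All fits must be computed on the same number of values (the variants share
#' both the data size and the number of free parameters, so the BIC ranking
#' coincides with AIC's). Ties keep the input order.
#'
#' @param fits a named list of [em_fit()] results.
#' @return a data frame with one row per variant, sorted by ascending BIC.
#' @export
bic_select <- function(fits) {
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1)
    stop("comparison error: fits were computed on different numbers of values")
  bics <- vapply(fits, mixture_bic, numeric(1))
  nm <- names(fits)
  if (is.null(nm)) nm <- sprintf("fit%02d", seq_along(fits))
  out <- data.frame(variant = nm, bic = bics,
                    loglik = vapply(fits, function(f) tail(f$loglik_trace, 1),
                                    numeric(1)),
                    p0 = vapply(fits, function(f) f$p0, numeric(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$bic), , drop = FALSE]
}
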