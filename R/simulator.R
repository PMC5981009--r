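#' Simulation configuration for the synthetic BOLD benchmark
#'
#' Bundles the parameters of the benchmark generator: cohort size, network
#' size, session length, sampling rate, integration step, thermal noise level,
#' haemodynamic lag variability and the master seed. Defaults reproduce the
#' benchmark study conditions: 10-minute sessions sampled at TR = 3.0 s
#' (200 time points), 1% additive thermal noise, and haemodynamic lags with a
#' cross-node standard deviation of 0.5 s.
#'
#' @param n_subjects number of synthetic subjects.
#' @param n_nodes number of network nodes; must match the ground-truth network
#'   passed to [generate_cohort()].
#' @param duration_s session duration in seconds; must be an integer multiple
#'   of `TR_s`.
#' @param TR_s repetition (sampling) time in seconds.
#' @param dt_s integration step in seconds (fixed-step Euler).
#' @param thermal_noise_pct additive Gaussian noise SD as a percentage of each
#'   node's BOLD signal SD.
#' @param lag_jitter_sd_s target cross-node SD of the haemodynamic
#'   impulse-response peak latency, in seconds.
#' @param seed master RNG seed; per-subject streams are derived from it.
#' @param burn_in_s initial integration time discarded before sampling.
#' @param input_gain scalar gain on the external binary inputs (the input
#'   matrix is the identity scaled by this value; 0 silences all inputs).
#' @param neural_sigma rate constant of the neural dynamics `dz/dt = sigma A z
#'   + u`; the default 20 /s gives a ~50 ms neural time constant.
#' @param balloon named list of balloon-Windkessel constants `kappa`, `gamma`,
#'   `tau`, `alpha`, `E0`, `V0`.
#' @param input_mean_up,input_mean_down mean duration (s) of the on/off
#'   segments of the binary external input trains.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 500L, n_nodes = 50L,
                              duration_s = 600, TR_s = 3.0, dt_s = 0.005,
                              thermal_noise_pct = 1.0, lag_jitter_sd_s = 0.5,
                              seed = 1L, burn_in_s = 15, input_gain = 1.0,
                              neural_sigma = 20,
                              balloon = list(kappa = 0.65, gamma = 0.41,
                                             tau = 0.98, alpha = 0.32,
                                             E0 = 0.34, V0 = 0.02),
                              input_mean_up = 2.5, input_mean_down = 10) {
  stopifnot(n_subjects >= 1, n_nodes >= 2, duration_s > 0, TR_s > 0, dt_s > 0)
  if (dt_s > TR_s) stop("dt_s must not exceed TR_s")
  n_tp <- duration_s / TR_s
  if (abs(n_tp - round(n_tp)) > 1e-8)
    stop("duration_s must be an integer multiple of TR_s")
  if (thermal_noise_pct < 0 || lag_jitter_sd_s < 0)
    stop("noise and lag jitter must be non-negative")
  se <- TR_s / dt_s
  if (abs(se - round(se)) > 1e-6)
    stop("TR_s must be an integer multiple of dt_s")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_nodes = as.integer(n_nodes),
                 duration_s = duration_s, TR_s = TR_s, dt_s = dt_s,
                 thermal_noise_pct = thermal_noise_pct,
                 lag_jitter_sd_s = lag_jitter_sd_s, seed = as.integer(seed),
                 burn_in_s = burn_in_s, input_gain = input_gain,
                 neural_sigma = neural_sigma, balloon = balloon,
                 input_mean_up = input_mean_up,
                 input_mean_down = input_mean_down),
            class = "simulation_config")
}

#' Build a sparse directed ground-truth network
#'
#' Constructs the benchmark topology: modular feed-forward chains of five
#' nodes linked by sparse random inter-module edges. The undirected edge count
#' is fixed to `round(0.0625 * choose(n_nodes, 2))`, so the canonical 50-node
#' network has 77 of 1225 node pairs connected (density 6.25% to the printed
#' precision). Off-diagonal connection strengths are positive; the diagonal
#' holds the self-decay -1, and the weights are rescaled if needed so that
#' the continuous system `dz/dt = sigma A z` is stable.
#'
#' @param n_nodes number of nodes (at least 5).
#' @param seed RNG seed; the construction is deterministic given the seed.
#' @param weight_range range of off-diagonal connection strengths.
#' @return an object of class `ground_truth_network` with fields `n_nodes`,
#'   `A` (directed strength matrix), `truth_undirected` (symmetric logical),
#'   `density` and `n_edges`.
#' @export
build_topology <- function(n_nodes, seed = 1L, weight_range = c(0.3, 0.5)) {
  if (n_nodes < 5) stop("invalid size: n_nodes must be at least 5")
  n_nodes <- as.integer(n_nodes)
  set.seed(as.integer(seed))
  n_pairs <- choose(n_nodes, 2)
  target_edges <- max(1L, as.integer(round(0.0625 * n_pairs)))

  # five-node feed-forward modules (remainder nodes join the last module)
  n_mod <- max(1L, n_nodes %/% 5L)
  sizes <- rep(n_nodes %/% n_mod, n_mod)
  extra <- n_nodes - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  starts <- cumsum(c(1L, sizes[-n_mod]))
  intra <- do.call(rbind, lapply(seq_len(n_mod), function(m) {
    ids <- seq.int(starts[m], length.out = sizes[m])
    if (length(ids) < 2) return(NULL)
    cbind(ids[-length(ids)], ids[-1])
  }))

  edges <- intra
  if (nrow(edges) > target_edges) {
    edges <- edges[sort(sample.int(nrow(edges), target_edges)), , drop = FALSE]
  } else if (nrow(edges) < target_edges) {
    used <- matrix(FALSE, n_nodes, n_nodes)
    used[cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))] <- TRUE
    need <- target_edges - nrow(edges)
    added <- 0L
    extra_edges <- matrix(0L, need, 2)
    guard <- 0L
    while (added < need) {
      guard <- guard + 1L
      if (guard > 100000L) stop("internal error: could not place edges")
      i <- sample.int(n_nodes, 1L)
      j <- sample.int(n_nodes, 1L)
      if (i == j) next
      a <- min(i, j); b <- max(i, j)
      if (used[a, b]) next
      used[a, b] <- TRUE
      added <- added + 1L
      # random direction for inter-module links
      if (runif(1) < 0.5) extra_edges[added, ] <- c(a, b)
      else extra_edges[added, ] <- c(b, a)
    }
    edges <- rbind(edges, extra_edges)
  }

  A <- matrix(0, n_nodes, n_nodes)
  diag(A) <- -1
  w <- runif(nrow(edges), weight_range[1], weight_range[2])
  A[edges[, c(2, 1), drop = FALSE]] <- w  # A[i, j] != 0: j -> i

  # enforce stability of dz/dt = sigma A z (sigma > 0 does not change signs)
  for (k in seq_len(50)) {
    if (max(Re(eigen(A, only.values = TRUE)$values)) < 0) break
    off <- A; diag(off) <- 0
    A <- off * 0.9; diag(A) <- -1
    if (k == 50) stop("internal error: failed to stabilize network weights")
  }

  truth <- (A != 0) | (t(A) != 0)
  diag(truth) <- FALSE
  nodes <- sprintf("node%02d", seq_len(n_nodes))
  dimnames(A) <- dimnames(truth) <- list(nodes, nodes)
  structure(list(n_nodes = n_nodes, A = A, truth_undirected = truth,
                 n_edges = sum(truth[upper.tri(truth)]),
                 density = sum(truth[upper.tri(truth)]) / n_pairs,
                 seed = as.integer(seed)),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf("ground_truth_network: %d nodes, %d undirected edges (density %.4f)\n",
              x$n_nodes, x$n_edges, x$density))
  invisible(x)
}

# per-subject seed stream derived from the master seed
.subject_seed <- function(master, s) {
  as.integer((as.double(master) + 104729 * as.double(s)) %% 2147483647L)
}

# binary external input train: alternating off/on segments with exponential
# durations, sampled on the integration grid
.input_train <- function(n_steps, dt, mean_up, mean_down) {
  total <- n_steps * dt
  durs <- numeric(0)
  while (sum(durs) < total) {
    d <- rexp(16, 1 / mean_down)
    u <- rexp(16, 1 / mean_up)
    durs <- c(durs, as.vector(rbind(d, u)))
  }
  seg <- findInterval((seq_len(n_steps) - 1) * dt, cumsum(durs))
  as.numeric(seg %% 2 == 1)
}

# map from balloon transit time tau to BOLD impulse-response peak latency,
# used to realize a requested cross-node lag SD
.lag_tau_map <- function(cfg) {
  b <- cfg$balloon
  taus <- seq(0.3, 3.5, length.out = 25)
  lat <- vapply(taus, function(tt)
    hrf_peak_latency(tt, cfg$neural_sigma, b$kappa, b$gamma, b$alpha,
                     b$E0, b$V0, 0.005, 25), numeric(1))
  o <- order(lat)
  list(tau = taus[o], lat = lat[o])
}

#' Generate a synthetic benchmark cohort
#'
#' Simulates per-subject BOLD panels from a known ground-truth network:
#' binary external input trains with exponential on/off durations drive linear
#' neural dynamics `dz/dt = sigma A z + c u`, each node's neural series passes
#' through balloon-Windkessel haemodynamics with per-node transit-time jitter
#' calibrated to the requested haemodynamic-lag SD, the BOLD output is sampled
#' at the TR, and zero-mean Gaussian thermal noise is added in proportion to
#' each node's signal SD. Subjects are independent given per-subject seeds
#' derived from the master seed, so cohorts are reproducible.
#'
#' @param truth a [build_topology()] result (or compatible object).
#' @param cfg a [simulation_config()].
#' @return an object of class `bold_panel`: a list with `data` (subjects x
#'   nodes x timepoints array), `TR_s`, `subject_ids`, `lags` (subjects x
#'   nodes realized peak latencies, seconds) and the resolved `cfg`.
#' @export
generate_cohort <- function(truth, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (truth$n_nodes != cfg$n_nodes)
    stop("cfg$n_nodes does not match the ground-truth network")
  n <- truth$n_nodes
  b <- cfg$balloon
  n_tp <- as.integer(round(cfg$duration_s / cfg$TR_s))
  sample_every <- as.integer(round(cfg$TR_s / cfg$dt_s))
  burn_steps <- as.integer(round(cfg$burn_in_s / cfg$dt_s))
  steps <- burn_steps + n_tp * sample_every

  map <- NULL
  lag0 <- NULL
  if (cfg$lag_jitter_sd_s > 0) {
    map <- .lag_tau_map(cfg)
    lag0 <- approx(map$tau, map$lat, xout = b$tau, rule = 2)$y
  }

  nodes <- rownames(truth$A)
  if (is.null(nodes)) nodes <- sprintf("node%02d", seq_len(n))
  subj <- sprintf("subj%03d", seq_len(cfg$n_subjects))
  data <- array(NA_real_, dim = c(cfg$n_subjects, n, n_tp),
                dimnames = list(subj, nodes, NULL))
  lags <- matrix(NA_real_, cfg$n_subjects, n, dimnames = list(subj, nodes))

  for (s in seq_len(cfg$n_subjects)) {
    set.seed(.subject_seed(cfg$seed, s))
    u <- matrix(0, n, steps)
    if (cfg$input_gain != 0) {
      for (i in seq_len(n))
        u[i, ] <- cfg$input_gain *
          .input_train(steps, cfg$dt_s, cfg$input_mean_up, cfg$input_mean_down)
    }
    if (cfg$lag_jitter_sd_s > 0) {
      lag_s <- rnorm(n, lag0, cfg$lag_jitter_sd_s)
      lag_s <- pmin(pmax(lag_s, min(map$lat)), max(map$lat))
      tau_s <- approx(map$lat, map$tau, xout = lag_s, rule = 2)$y
    } else {
      lag_s <- rep(if (is.null(lag0)) NA_real_ else lag0, n)
      tau_s <- rep(b$tau, n)
    }
    bold <- tryCatch(
      sim_bold_core(truth$A, cfg$neural_sigma, u, tau_s, b$kappa, b$gamma,
                    b$alpha, b$E0, b$V0, cfg$dt_s, sample_every, burn_steps),
      error = function(e)
        stop(sprintf("simulation diverged for subject %d: %s",
                     s, conditionMessage(e)), call. = FALSE))
    if (cfg$thermal_noise_pct > 0) {
      sds <- apply(bold, 1, sd)
      noise <- matrix(rnorm(n * n_tp), n, n_tp) *
        (cfg$thermal_noise_pct / 100 * sds)
      bold <- bold + noise
    }
    data[s, , ] <- bold
    lags[s, ] <- lag_s
  }

  structure(list(data = data, TR_s = cfg$TR_s, subject_ids = subj,
                 lags = lags, cfg = cfg),
            class = "bold_panel")
}

#' @export
print.bold_panel <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_panel: %d subjects x %d nodes x %d timepoints (TR %.2f s)\n",
              d[1], d[2], d[3], x$TR_s))
  invisible(x)
}

#' Extract one subject's node-by-time matrix from a panel
#'
#' @param panel a `bold_panel`.
#' @param s subject index or id.
#' @return a nodes x timepoints numeric matrix.
#' @export
panel_ts <- function(panel, s) {
  m <- panel$data[s, , , drop = FALSE]
  dim(m) <- dim(panel$data)[2:3]
  rownames(m) <- dimnames(panel$data)[[2]]
  m
}

# admissible density band for a subnetwork of m nodes around `parent` density:
# +-2 percentage points, widened so at least one integer edge count fits
.density_band <- function(m, parent) {
  max(0.02, 1.5 / choose(m, 2))
}

#' Extract a smaller benchmark network by iterative node removal
#'
#' Removes nodes one at a time, uniformly at random given the seed, rejecting
#' any removal that would leave the surviving network without a single true
#' edge or push its edge density outside a tolerance band around the parent
#' network's density, so that subnetworks of every size remain comparable to
#' the full benchmark.
#'
#' @param panel a `bold_panel` simulated on the full network.
#' @param truth the matching `ground_truth_network`.
#' @param target_size desired number of nodes (at least 5, below `n_nodes`).
#' @param seed RNG seed for the removal order.
#' @param max_restarts bounded retries over whole removal sequences.
#' @return a list with elements `panel` and `truth` restricted to the
#'   surviving nodes.
#' @export
extract_subnetwork <- function(panel, truth, target_size, seed = 1L,
                               max_restarts = 20L) {
  n <- truth$n_nodes
  if (target_size < 5 || target_size >= n)
    stop("target_size must satisfy 5 <= target_size < n_nodes")
  parent <- truth$density
  ut <- function(M) M[upper.tri(M)]

  for (attempt in seq_len(max_restarts)) {
    set.seed(as.integer(seed) + (attempt - 1L) * 7919L)
    keep <- seq_len(n)
    ok <- TRUE
    while (length(keep) > target_size) {
      cand <- sample(keep)
      placed <- FALSE
      for (v in cand) {
        kk <- setdiff(keep, v)
        sub <- truth$truth_undirected[kk, kk, drop = FALSE]
        e <- sum(ut(sub))
        dens <- e / choose(length(kk), 2)
        if (e >= 1 && abs(dens - parent) <= .density_band(length(kk), parent)) {
          keep <- kk
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      keep <- sort(keep)
      A <- truth$A[keep, keep, drop = FALSE]
      tu <- truth$truth_undirected[keep, keep, drop = FALSE]
      m <- length(keep)
      sub_truth <- structure(
        list(n_nodes = m, A = A, truth_undirected = tu,
             n_edges = sum(ut(tu)), density = sum(ut(tu)) / choose(m, 2),
             seed = truth$seed), class = "ground_truth_network")
      sub_panel <- panel
      sub_panel$data <- panel$data[, keep, , drop = FALSE]
      sub_panel$lags <- panel$lags[, keep, drop = FALSE]
      return(list(panel = sub_panel, truth = sub_truth))
    }
  }
  stop("constraint error: no admissible removal sequence found")
}
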