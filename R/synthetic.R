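# Synthetic ground-truth populations and spike-train generation.
#
# Spikes are generated from condition-level rate functions, not from rendered
# pixel stimuli: every downstream analysis consumes only the condition labels
# (theta, B_theta, drift), so the generator needs to emulate the statistical
# structure of the responses, not the images.

#' Draw a ground-truth population of model neurons
#'
#' Samples \code{n_neurons} neurons split deterministically into the two
#' response archetypes: \emph{resilient} neurons keep orientation tuning at
#' high input variance (low Naka-Rushton exponent \eqn{n}, high changepoint
#' \eqn{B_{\theta 50}}, slightly lower \eqn{f_0}, late-ramping dynamics,
#' supragranular bias) and \emph{vulnerable} neurons lose tuning abruptly
#' (high \eqn{n}, low \eqn{B_{\theta 50}}, early-transient dynamics). The
#' archetype-conditional parameter distributions are centred on the two
#' published exemplar VTFs (log n = 2.4, B50 = 35, f0 = 0.3 resilient;
#' log n = 8.4, B50 = 14.7, f0 = 0.4 vulnerable) and are documented in the
#' methods vignette.
#'
#' @param n_neurons population size (>= 2).
#' @param resilient_fraction fraction of resilient neurons in [0, 1];
#'   the default mirrors the 85 / 249 split of the reference population.
#' @param seed integer seed; identical seeds give identical populations.
#' @param supragranular_prob probability that a resilient neuron sits above
#'   800 um depth.
#' @return data.frame of class \code{gt_population}, one row per neuron:
#'   identity, archetype, preferred orientation and drift, rates, VTF
#'   parameters (\code{f0}, \code{fmax}, \code{log_n}, \code{b_theta50}),
#'   temporal-profile parameters and laminar depth.
#' @export
sample_population <- function(n_neurons = 249L, resilient_fraction = 85 / 249,
                              seed = 1L, supragranular_prob = 0.8) {
  if (n_neurons < 2L) stop("`n_neurons` must be >= 2.")
  if (resilient_fraction < 0 || resilient_fraction > 1) {
    stop("`resilient_fraction` must lie in [0, 1].")
  }
  set.seed(seed)
  n_res <- round(n_neurons * resilient_fraction)
  archetype <- rep(c("resilient", "vulnerable"), c(n_res, n_neurons - n_res))

  rn <- function(n, mean, sd, lo, hi) clamp(stats::rnorm(n, mean, sd), lo, hi)
  res <- archetype == "resilient"
  log_n <- b50 <- f0 <- top <- depth <- numeric(n_neurons)

  log_n[res] <- rn(sum(res), 2.4, 0.6, 0.5, 4.2)
  b50[res]   <- rn(sum(res), 31, 4, 22, 42)
  f0[res]    <- rn(sum(res), 0.30, 0.07, 0.10, 0.55)
  log_n[!res] <- rn(sum(!res), 7.0, 1.0, 5.0, 9.8)
  b50[!res]   <- rn(sum(!res), 14.5, 2.5, 8, 21)
  f0[!res]    <- rn(sum(!res), 0.42, 0.07, 0.15, 0.65)
  top <- clamp(stats::rnorm(n_neurons, 0.93, 0.03), f0 + 0.2, 1)

  supra <- stats::runif(n_neurons) < ifelse(res, supragranular_prob,
                                            1 - supragranular_prob)
  depth <- ifelse(supra, stats::runif(n_neurons, 150, 800),
                  stats::runif(n_neurons, 800, 1600))

  # Temporal kernels: difference of exponentials; transient peaks < 100 ms,
  # ramping peaks > 200 ms. Mild per-neuron jitter keeps dynamics features
  # from being degenerate across the population.
  jit <- function(x, sd) x * exp(stats::rnorm(n_neurons, 0, sd))
  t0  <- ifelse(res, 50, 30) + stats::rnorm(n_neurons, 0, 5)
  tau_rise  <- jit(ifelse(res, 100, 5), 0.12)
  tau_decay <- jit(ifelse(res, 400, 40), 0.12)

  out <- data.frame(
    neuron_id = seq_len(n_neurons),
    archetype = archetype,
    theta_pref = stats::runif(n_neurons, 0, 180),
    pref_drift = sample(c(-1L, 1L), n_neurons, replace = TRUE),
    r_max = stats::rlnorm(n_neurons, log(28), 0.35),
    r_base = stats::runif(n_neurons, 0.5, 4),
    ds_index = stats::rbeta(n_neurons, 2, 8),
    f0 = f0, fmax = top - f0, log_n = log_n, b_theta50 = b50,
    profile = ifelse(res, "ramping", "transient"),
    latency_ms = pmax(t0, 10),
    tau_rise_ms = tau_rise, tau_decay_ms = tau_decay,
    layer_depth = depth,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gt_population", "data.frame")
  out
}

#' @export
print.gt_population <- function(x, ...) {
  cat(sprintf("Ground-truth population: %d neurons (%d resilient, %d vulnerable)\n",
              nrow(x), sum(x$archetype == "resilient"),
              sum(x$archetype == "vulnerable")))
  invisible(x)
}

# ---- rate model --------------------------------------------------------------

# Discrete-grid circular variance of a von Mises-shaped tuning curve: the
# quantity the analysis stage will measure on noiseless data.
grid_cv <- function(kappa, theta_pref, thetas_deg) {
  w <- exp(kappa * (cos(2 * deg2rad(thetas_deg - theta_pref)) - 1))
  1 - Mod(sum(w * exp(2i * deg2rad(thetas_deg))) / sum(w))
}

# Invert grid_cv in kappa so that the tuning curve built for one bandwidth
# has exactly the circular variance prescribed by the neuron's VTF.
kappa_for_cv <- function(target_cv, theta_pref, thetas_deg, kappa_max = 500) {
  cv_floor <- grid_cv(kappa_max, theta_pref, thetas_deg)
  cv_ceiling <- grid_cv(1e-7, theta_pref, thetas_deg)
  if (target_cv >= cv_ceiling) return(0)
  if (target_cv <= cv_floor) return(kappa_max)
  f <- function(lk) grid_cv(exp(lk), theta_pref, thetas_deg) - target_cv
  exp(stats::uniroot(f, c(log(1e-7), log(kappa_max)), tol = 1e-12)$root)
}

# Amplitude decay with bandwidth: calibrated so the peak response at
# B = 35 deg is ~27% of the low-variance peak (a 73% amplitude decrease).
amplitude_gain <- function(b_theta_deg, b_ref = 0.5, scale_deg = 26.3) {
  exp(-(b_theta_deg - b_ref) / scale_deg)
}

# Temporal kernel: latency-shifted difference of exponentials, cut by an
# offset decay after stimulus end, normalised to unit mean over [0, stim_ms].
temporal_kernel <- function(t_ms, latency, tau_rise, tau_decay,
                            stim_ms = 300, offset_tau = 50) {
  tt <- t_ms - latency
  k <- ifelse(tt > 0, exp(-tt / tau_decay) - exp(-tt / tau_rise), 0)
  k <- k * ifelse(t_ms > stim_ms, exp(-(t_ms - stim_ms) / offset_tau), 1)
  k
}

kernel_norm <- function(neuron, stim_ms = 300) {
  tg <- seq(0.5, stim_ms - 0.5, by = 1)
  mean(temporal_kernel(tg, neuron$latency_ms, neuron$tau_rise_ms,
                       neuron$tau_decay_ms, stim_ms))
}

#' Instantaneous firing rate of a model neuron
#'
#' \code{rate = r_base + gain(B) * vonMises(theta; theta_pref, kappa_eff(B)) *
#' kernel(t) * drift_gain}. The effective concentration
#' \eqn{\kappa_{eff}(B_\theta)} is chosen by root-finding so that the circular
#' variance of the 300-ms mean-rate tuning curve on the stimulus grid equals
#' the neuron's Naka-Rushton VTF at that bandwidth; the drift gain is 1 for
#' the preferred drift direction and \eqn{1 - D_s} for the opposite one.
#'
#' @param neuron one row of a \code{\link{sample_population}} data.frame.
#' @param theta_deg stimulus mean orientation (degrees).
#' @param b_theta_deg stimulus bandwidth (degrees).
#' @param drift +1 or -1.
#' @param t_ms vector of times (ms, relative to stimulus onset).
#' @param thetas_deg orientation grid used to calibrate \eqn{\kappa_{eff}}.
#' @param kappa_eff optional precomputed effective concentration.
#' @return vector of rates (Hz), \code{>= 0}, equal to \code{r_base} before
#'   stimulus onset.
#' @export
rate_function <- function(neuron, theta_deg, b_theta_deg, drift, t_ms,
                          thetas_deg = stimulus_grid()$theta_deg[1:12],
                          kappa_eff = NULL) {
  neuron <- as.list(neuron)
  if (is.null(kappa_eff)) {
    target <- naka_rushton(b_theta_deg, neuron$f0, neuron$fmax,
                           exp(neuron$log_n), neuron$b_theta50)
    kappa_eff <- kappa_for_cv(target, neuron$theta_pref, thetas_deg)
  }
  g <- exp(kappa_eff * (cos(2 * deg2rad(theta_deg - neuron$theta_pref)) - 1))
  dgain <- ifelse(drift == neuron$pref_drift, 1, 1 - neuron$ds_index)
  k <- temporal_kernel(t_ms, neuron$latency_ms, neuron$tau_rise_ms,
                       neuron$tau_decay_ms) / kernel_norm(neuron)
  pmax(neuron$r_base + neuron$r_max * amplitude_gain(b_theta_deg) * g * dgain * k, 0)
}

# Effective kappas for every neuron x bandwidth of a grid (calibration table).
population_kappas <- function(population, b_grid,
                              thetas_deg = stimulus_grid()$theta_deg[1:12]) {
  sapply(b_grid, function(b) {
    vapply(seq_len(nrow(population)), function(i) {
      nn <- population[i, ]
      target <- naka_rushton(b, nn$f0, nn$fmax, exp(nn$log_n), nn$b_theta50)
      kappa_for_cv(target, nn$theta_pref, thetas_deg)
    }, numeric(1L))
  })
}

#' Noiseless mean-rate tuning curves
#'
#' Analytic (infinite-trial) baseline-subtracted, drift-averaged mean-rate
#' tuning curves over the 300-ms stimulation window, per neuron and bandwidth.
#' Used for parameter-recovery checks without Poisson noise.
#'
#' @param population a \code{gt_population}.
#' @param grid stimulus grid (see \code{\link{stimulus_grid}}).
#' @return data.frame: \code{neuron_id}, \code{b_theta_deg}, \code{theta_deg},
#'   \code{rate}.
#' @export
rate_tuning_curves <- function(population, grid = stimulus_grid()) {
  thetas <- sort(unique(grid$theta_deg))
  b_grid <- sort(unique(grid$b_theta_deg))
  kap <- population_kappas(population, b_grid, thetas)
  out <- vector("list", nrow(population) * length(b_grid))
  idx <- 1L
  for (i in seq_len(nrow(population))) {
    nn <- population[i, ]
    dgain <- (1 + (1 - nn$ds_index)) / 2          # average of the two drifts
    for (j in seq_along(b_grid)) {
      g <- exp(kap[i, j] * (cos(2 * deg2rad(thetas - nn$theta_pref)) - 1))
      out[[idx]] <- data.frame(
        neuron_id = nn$neuron_id, b_theta_deg = b_grid[j], theta_deg = thetas,
        rate = nn$r_max * amplitude_gain(b_grid[j]) * dgain * g)
      idx <- idx + 1L
    }
  }
  do.call(rbind, out)
}

# ---- spike simulation --------------------------------------------------------

#' Simulate spike trains for a full trial table
#'
#' Inhomogeneous-Poisson sampling by thinning: per (neuron, condition, drift)
#' a homogeneous candidate stream at the rate ceiling is thinned by the ratio
#' of the instantaneous rate to the ceiling. Trial counts are exact; spike
#' counts in any window are Poisson with mean equal to the integrated rate.
#'
#' @param population a \code{\link{sample_population}} data.frame.
#' @param trials trial table from \code{\link{trial_table}}.
#' @param seed integer master seed; per-neuron streams are derived from it.
#' @param window_ms recording window, default c(-200, 450) ms.
#' @return object of class \code{spike_dataset}: list with \code{events}
#'   (data.frame neuron_id, stim_id, theta_deg, b_theta_deg, drift, trial,
#'   t_ms), \code{trials}, \code{window_ms}, \code{n_trials} and the ground
#'   truth \code{population}.
#' @export
simulate_trials <- function(population, trials = trial_table(), seed = 1L,
                            window_ms = c(-200, 450)) {
  thetas <- sort(unique(trials$theta_deg))
  b_grid <- sort(unique(trials$b_theta_deg))
  kap <- population_kappas(population, b_grid, thetas)
  span_s <- diff(window_ms) / 1000
  conds <- unique(trials[, c("stim_id", "theta_deg", "b_theta_deg", "drift")])
  n_rep <- max(trials$trial)
  tg <- seq(0.5, 449.5, by = 1)

  res <- vector("list", nrow(population))
  for (i in seq_len(nrow(population))) {
    nn <- population[i, ]
    set.seed(derive_seed(seed, "spikes", nn$neuron_id))
    knorm <- kernel_norm(nn)
    kmax <- max(temporal_kernel(tg, nn$latency_ms, nn$tau_rise_ms,
                                nn$tau_decay_ms)) / knorm
    ev <- vector("list", nrow(conds))
    for (cidx in seq_len(nrow(conds))) {
      cc <- conds[cidx, ]
      kap_b <- kap[i, match(cc$b_theta_deg, b_grid)]
      g <- exp(kap_b * (cos(2 * deg2rad(cc$theta_deg - nn$theta_pref)) - 1))
      dgain <- if (cc$drift == nn$pref_drift) 1 else 1 - nn$ds_index
      amp <- nn$r_max * amplitude_gain(cc$b_theta_deg) * g * dgain
      ceiling_hz <- nn$r_base + amp * kmax
      n_cand <- stats::rpois(n_rep, ceiling_hz * span_s)
      if (sum(n_cand) == 0L) next
      tr <- rep.int(seq_len(n_rep), n_cand)
      tt <- stats::runif(length(tr), window_ms[1L], window_ms[2L])
      k <- temporal_kernel(tt, nn$latency_ms, nn$tau_rise_ms,
                           nn$tau_decay_ms) / knorm
      rate <- pmax(nn$r_base + amp * k, 0)
      keep <- stats::runif(length(tr)) < rate / ceiling_hz
      if (!any(keep)) next
      ev[[cidx]] <- data.frame(
        neuron_id = nn$neuron_id, stim_id = cc$stim_id,
        theta_deg = cc$theta_deg, b_theta_deg = cc$b_theta_deg,
        drift = cc$drift, trial = tr[keep], t_ms = tt[keep])
    }
    res[[i]] <- do.call(rbind, ev)
  }
  events <- do.call(rbind, res)
  events <- events[order(events$neuron_id, events$stim_id, events$drift,
                         events$trial, events$t_ms), ]
  rownames(events) <- NULL
  structure(list(events = events, trials = trials, window_ms = window_ms,
                 n_trials = n_rep, population = population),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf(
    "Spike dataset: %d neurons, %d trials/neuron, %d spikes, window [%d, %d] ms\n",
    nrow(x$population), nrow(x$trials), nrow(x$events),
    x$window_ms[1L], x$window_ms[2L]))
  invisible(x)
}

#' Write / read a spike dataset as CSV + JSON
#'
#' The event list goes to \code{events.csv}, the trial table to
#' \code{trials.csv}, the ground truth to \code{population.csv} and scalar
#' metadata to \code{meta.json}.
#'
#' @param dataset a \code{spike_dataset}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_spike_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$events, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(dataset$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$population),
                   file.path(dir, "population.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(window_ms = dataset$window_ms, n_trials = dataset$n_trials),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_spike_dataset
#' @export
read_spike_dataset <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("missing input path: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pop <- utils::read.csv(file.path(dir, "population.csv"))
  class(pop) <- c("gt_population", "data.frame")
  structure(list(
    events = utils::read.csv(file.path(dir, "events.csv")),
    trials = utils::read.csv(file.path(dir, "trials.csv")),
    window_ms = meta$window_ms, n_trials = meta$n_trials,
    population = pop), class = "spike_dataset")
}
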