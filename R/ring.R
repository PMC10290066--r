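# Recurrent ring network of orientation-tuned rate units.

#' Ring-network configuration
#'
#' Units evenly tile the orientation space between \eqn{-\pi} and \eqn{\pi};
#' each unit is a passive membrane
#' \eqn{\tau\,dV/dt + V = V_{ff} + V_{exc} - V_{inh}} with instantaneous rate
#' \eqn{R = \alpha \max(V, 0)}. Recurrent drive is the spacing-weighted ring
#' sum of a difference-of-von-Mises (Mexican hat) kernel with the rates.
#' Default gains and time constant follow the published cat-V1
#' parameterisation (\eqn{\tau} = 10.8 ms, \eqn{\alpha} = 10.6 Hz/mV,
#' \eqn{J_{ff}} = 9.57 mV/Hz, \eqn{J_{exc}} = 1.71 Hz/mV,
#' \eqn{J_{inh}} = 2.0178 Hz/mV); the printed unit labels are internally
#' inconsistent and the gains are applied exactly as the equations compose.
#'
#' @param n_units ring size.
#' @param tau_m membrane time constant (ms).
#' @param alpha rate gain (Hz/mV).
#' @param j_ff feedforward gain.
#' @param j_exc,j_inh recurrent excitatory / inhibitory gains.
#' @param kappa_exc,kappa_inh concentrations of the recurrent kernels.
#' @param dt integration step (ms); must satisfy \code{dt <= tau_m / 10}.
#' @param t_max simulated span (ms).
#' @param steady_ms span at the end of the simulation averaged to define the
#'   steady state.
#' @return object of class \code{ring_config}.
#' @export
ring_config <- function(n_units = 256L, tau_m = 10.8, alpha = 10.6,
                        j_ff = 9.57, j_exc = 1.71, j_inh = 2.0178,
                        kappa_exc = 2.5, kappa_inh = 1.5,
                        dt = 0.5, t_max = 300, steady_ms = 50) {
  stopifnot(n_units >= 8L, tau_m > 0, alpha > 0, dt > 0, t_max > dt)
  if (dt > tau_m / 10) stop("`dt` must be <= tau_m / 10.")
  prefs <- seq(-pi, pi, length.out = n_units + 1L)[seq_len(n_units)]
  structure(list(n_units = as.integer(n_units), tau_m = tau_m, alpha = alpha,
                 j_ff = j_ff, j_exc = j_exc, j_inh = j_inh,
                 kappa_exc = kappa_exc, kappa_inh = kappa_inh,
                 dt = dt, t_max = t_max, steady_ms = steady_ms,
                 theta_prefs = prefs, spacing = 2 * pi / n_units),
            class = "ring_config")
}

#' @export
print.ring_config <- function(x, ...) {
  cat(sprintf(
    "Ring config: %d units, tau = %.1f ms, J_ff = %.2f, J_exc = %.2f (k = %.2f), J_inh = %.4f (k = %.2f)\n",
    x$n_units, x$tau_m, x$j_ff, x$j_exc, x$kappa_exc, x$j_inh, x$kappa_inh))
  invisible(x)
}

#' Feedforward input profile
#'
#' \deqn{V_{ff}(\theta_{pref}) = J_{ff} e^{\kappa_{ff}\cos(2(\theta - \theta_{pref}))} / (2\pi I_0(\kappa_{ff}))}
#' over the ring; the spacing-weighted ring sum equals \eqn{J_{ff}}.
#'
#' @param theta stimulus orientation (radians).
#' @param kappa_ff input concentration (from the bandwidth via
#'   \code{\link{kappa_from_btheta}}).
#' @param config a \code{\link{ring_config}}.
#' @return vector of inputs per unit.
#' @export
feedforward_input <- function(theta, kappa_ff, config) {
  if (!is.finite(kappa_ff) || kappa_ff < KAPPA_MIN) {
    stop(sprintf("`kappa_ff` must be >= %.6f.", KAPPA_MIN))
  }
  config$j_ff * vm_density(config$theta_prefs - theta, kappa_ff)
}

#' Recurrent connectivity kernel
#'
#' Difference of two normalised von Mises profiles,
#' \eqn{C_{tot} = J_{exc} C_{exc} - J_{inh} C_{inh}}, evaluated at the ring
#' offsets (circulant over the ring); with a concentrated excitatory and a
#' broad inhibitory profile this is the classic Mexican-hat kernel.
#'
#' @param config a \code{\link{ring_config}}.
#' @return vector of kernel values at offsets \code{config$theta_prefs}.
#' @export
connectivity_kernel <- function(config) {
  config$j_exc * vm_density(config$theta_prefs, config$kappa_exc) -
    config$j_inh * vm_density(config$theta_prefs, config$kappa_inh)
}

# Circulant kernel matrix: row i holds C_tot(theta_i - theta_j).
kernel_matrix <- function(config) {
  kern <- connectivity_kernel(config)
  n <- config$n_units
  idx <- outer(seq_len(n), seq_len(n), function(i, j) ((i - j) %% n) + 1L)
  matrix(kern[idx], n, n)
}

# Core integrator: exponential Euler on V' = (V_in - V)/tau with
# V_in = V_ff + spacing * C %*% (alpha * max(V, 0)). Operates on a matrix of
# stimulus columns simultaneously. Returns steady profiles, the full readout
# trajectory (unit with theta_pref = 0) and stability flags.
ring_integrate <- function(config, vff, diverge_at = 1e6, v0 = 0) {
  if (is.null(dim(vff))) vff <- matrix(vff, ncol = 1L)
  n_steps <- as.integer(round(config$t_max / config$dt))
  decay <- exp(-config$dt / config$tau_m)
  recurrent <- config$j_exc != 0 || config$j_inh != 0
  cmat <- if (recurrent) kernel_matrix(config) * config$spacing * config$alpha
  readout <- which.min(abs(config$theta_prefs))
  v <- matrix(v0, nrow(vff), ncol(vff))
  traj <- matrix(NA_real_, n_steps, ncol(vff))
  steady_from <- n_steps - as.integer(round(config$steady_ms / config$dt)) + 1L
  acc <- matrix(0, nrow(vff), ncol(vff)); n_acc <- 0L
  stable <- rep(TRUE, ncol(vff))
  for (s in seq_len(n_steps)) {
    vin <- if (recurrent) vff + cmat %*% pmax(v, 0) else vff
    v <- vin + (v - vin) * decay
    bad <- !is.finite(colSums(v)) | apply(abs(v), 2L, max) > diverge_at
    stable[bad] <- FALSE
    if (any(!stable)) v[, !stable] <- 0   # diverged columns stay frozen
    traj[s, ] <- config$alpha * pmax(v[readout, ], 0)
    if (s >= steady_from) { acc <- acc + v; n_acc <- n_acc + 1L }
  }
  v_steady <- acc / n_acc
  v_steady[, !stable] <- NA_real_
  traj[, !stable] <- NA_real_
  list(v_steady = v_steady, r_steady = config$alpha * pmax(v_steady, 0),
       readout_traj = traj, stable = stable,
       t = seq_len(n_steps) * config$dt, readout = readout)
}

tau_half_from_traj <- function(t, r) {
  r_inf <- mean(r[t >= max(t) - 50])
  if (!is.finite(r_inf) || r_inf <= 0) return(NA_real_)
  i <- which(r >= r_inf / 2)[1L]
  if (is.na(i)) NA_real_ else t[i]
}

#' Simulate the ring network for one stimulus
#'
#' Integrates the rate equations for a stimulus of orientation \code{theta}
#' and bandwidth \code{b_theta} (converted to the feedforward concentration
#' \eqn{\kappa_{ff}}), starting from rest, input switched on at t = 0.
#'
#' @param config a \code{\link{ring_config}}.
#' @param theta stimulus orientation, degrees.
#' @param b_theta stimulus bandwidth, degrees; alternatively pass
#'   \code{kappa_ff} directly.
#' @param kappa_ff optional explicit feedforward concentration.
#' @param rf_kappa optional receptive-field concentration: the input is
#'   circularly convolved with a normalised von Mises RF before driving the
#'   ring (feedforward mode of the model).
#' @return object of class \code{ring_result}: steady \code{V} and \code{R}
#'   profiles, readout rate trajectory, \code{tau_half} (ms to half the
#'   steady readout rate), \code{stable}.
#' @export
simulate_ring <- function(config, theta = 0, b_theta = NULL, kappa_ff = NULL,
                          rf_kappa = NULL) {
  stopifnot(inherits(config, "ring_config"))
  if (is.null(kappa_ff)) {
    if (is.null(b_theta)) stop("provide `b_theta` or `kappa_ff`.")
    kappa_ff <- kappa_from_btheta(deg2rad(b_theta))
  }
  vff <- feedforward_input(deg2rad(theta), kappa_ff, config)
  if (!is.null(rf_kappa)) vff <- ring_convolve(vff, rf_kappa, config)
  sim <- ring_integrate(config, vff)
  structure(list(
    theta = theta, b_theta = b_theta, kappa_ff = kappa_ff,
    theta_prefs = config$theta_prefs,
    v_steady = sim$v_steady[, 1L], r_steady = sim$r_steady[, 1L],
    t = sim$t, readout_rate = sim$readout_traj[, 1L],
    tau_half = tau_half_from_traj(sim$t, sim$readout_traj[, 1L]),
    stable = sim$stable[1L], config = config),
    class = "ring_result")
}

#' @export
print.ring_result <- function(x, ...) {
  cat(sprintf(
    "Ring simulation: stim theta = %.1f deg%s, peak steady rate %.1f Hz, tau_half = %s ms%s\n",
    x$theta,
    if (!is.null(x$b_theta)) sprintf(", B_theta = %.1f deg", x$b_theta) else "",
    max(x$r_steady), format(round(x$tau_half, 1)),
    if (!x$stable) " [UNSTABLE]" else ""))
  invisible(x)
}

#' Circular convolution with a von Mises receptive field
#'
#' Spacing-weighted circular convolution of a ring profile with a normalised
#' von Mises kernel (the feedforward receptive field of the network's
#' no-recurrence mode).
#'
#' @param x ring profile (length \code{n_units}).
#' @param rf_kappa RF concentration; its half-width at half-height follows
#'   \code{\link{hwhh}}.
#' @param config a \code{\link{ring_config}}.
#' @return convolved profile.
#' @export
ring_convolve <- function(x, rf_kappa, config) {
  rf <- vm_density(config$theta_prefs, rf_kappa) * config$spacing
  n <- config$n_units
  idx <- outer(seq_len(n), seq_len(n), function(i, j) ((i - j) %% n) + 1L)
  as.numeric(matrix(rf[idx], n, n) %*% x)
}

#' Model variance-tuning function
#'
#' Simulates the network over a grid of input bandwidths (one stimulus at
#' theta = 0 per bandwidth; the full tuning curve of the readout unit follows
#' from the network's rotational symmetry by reading the steady population
#' profile at the negated stimulus offsets), computes the circular variance
#' of each 32-point tuning curve over the [-75, 75) degree stimulus span, and
#' fits a Naka-Rushton function to the resulting CV-vs-bandwidth curve.
#'
#' @param config a \code{\link{ring_config}}.
#' @param b_grid bandwidth grid in degrees (default 20 values spanning the
#'   experimental range 0.5-35).
#' @param n_theta number of stimulus orientations tiling [-75, 75) degrees.
#' @param rf_kappa optional RF concentration (feedforward mode: set
#'   \code{j_exc = j_inh = 0} in the config and pass the RF here).
#' @return object of class \code{model_vtf}: \code{b_grid}, \code{cv},
#'   \code{nkr} (an \code{\link{fit_vtf}} object), \code{tau_half} per
#'   bandwidth, \code{stable} flags, \code{tuning} (bandwidths x
#'   orientations rate matrix).
#' @export
model_vtf <- function(config, b_grid = seq(0.5, 35, length.out = 20L),
                      n_theta = 32L, rf_kappa = NULL) {
  # half-open even tiling of [-75, 75): step 150/n_theta, includes 0
  theta_grid <- seq(-75, 75, length.out = n_theta + 1L)[seq_len(n_theta)]
  kff <- kappa_from_btheta(deg2rad(b_grid))
  vff <- sapply(kff, function(k) feedforward_input(0, k, config))
  if (!is.null(rf_kappa)) {
    vff <- apply(vff, 2L, ring_convolve, rf_kappa = rf_kappa, config = config)
  }
  sim <- ring_integrate(config, vff)
  tuning <- t(sapply(seq_along(b_grid), function(j) {
    circ_interp(config$theta_prefs, sim$r_steady[, j],
                -deg2rad(theta_grid), 2 * pi)
  }))
  cv <- apply(tuning, 1L, function(r) {
    if (any(!is.finite(r))) return(NA_real_)
    suppressWarnings(as.numeric(circular_variance(r, theta_grid)))
  })
  tau_half <- vapply(seq_along(b_grid), function(j) {
    tau_half_from_traj(sim$t, sim$readout_traj[, j])
  }, numeric(1L))
  ok <- sim$stable & is.finite(cv)
  nkr <- if (sum(ok) >= 4L) fit_vtf(b_grid[ok], cv[ok]) else NULL
  structure(list(b_grid = b_grid, theta_grid = theta_grid, cv = cv,
                 nkr = nkr, tau_half = tau_half, stable = sim$stable,
                 tuning = tuning, config = config, rf_kappa = rf_kappa),
            class = "model_vtf")
}

#' @export
print.model_vtf <- function(x, ...) {
  cat(sprintf("Model VTF over %d bandwidths (%d stable):\n",
              length(x$b_grid), sum(x$stable)))
  if (!is.null(x$nkr)) print(x$nkr)
  invisible(x)
}

#' @export
plot.model_vtf <- function(x, ...) {
  graphics::plot(x$b_grid, x$cv, pch = 16, xlab = "B_theta (deg)",
                 ylab = "circular variance", ylim = c(0, 1), ...)
  if (!is.null(x$nkr)) {
    bb <- seq(min(x$b_grid), max(x$b_grid), length.out = 200)
    graphics::lines(bb, predict(x$nkr, bb), col = "grey40")
  }
  invisible(x)
}

#' Feedforward-only mode
#'
#' Convenience wrapper: zeroes the recurrent gains and convolves the input
#' with a von Mises receptive field of concentration \code{rf_kappa} before
#' the feedforward drive.
#'
#' @param config a \code{\link{ring_config}} (its recurrent gains are
#'   ignored and set to 0).
#' @param rf_kappa receptive-field concentration.
#' @param ... passed to \code{\link{model_vtf}}.
#' @return a \code{model_vtf} with an extra \code{rf_hwhh} field (degrees).
#' @export
feedforward_mode <- function(config, rf_kappa, ...) {
  cfg <- config
  cfg$j_exc <- 0; cfg$j_inh <- 0
  out <- model_vtf(cfg, rf_kappa = rf_kappa, ...)
  out$rf_hwhh <- hwhh(rf_kappa)
  out
}

#' Scan the recurrent-connectivity plane
#'
#' Enumerates a \code{steps} x \code{steps} grid of
#' (\eqn{\kappa_{exc}}, \eqn{\kappa_{inh}}) pairs over \code{kappa_range}
#' (the full published scan is 200 x 200 = 40,000 configurations) and,
#' when \code{evaluate = TRUE}, simulates \code{\link{model_vtf}} at every
#' cell to map the VTF parameters (log n, \eqn{B_{\theta 50}}, \eqn{f_0})
#' and the mean delay to half-maximum rate. Unstable cells are recorded as
#' missing rather than failing the scan.
#'
#' @param kappa_range range of both concentrations.
#' @param steps grid resolution per axis (>= 2).
#' @param config base \code{\link{ring_config}} (gains, ring size, dt).
#' @param evaluate run the simulations (FALSE enumerates the grid only).
#' @param b_grid bandwidth grid forwarded to \code{\link{model_vtf}}.
#' @return data.frame of class \code{ring_scan}: \code{kappa_exc},
#'   \code{kappa_inh} and, when evaluated, \code{log_n}, \code{b_theta50},
#'   \code{f0}, \code{tau_half}, \code{stable}.
#' @export
ring_scan <- function(kappa_range = c(0.35, 7), steps = 200L,
                      config = ring_config(), evaluate = FALSE,
                      b_grid = seq(0.5, 35, length.out = 20L)) {
  if (steps < 2L) stop("`steps` must be >= 2.")
  ks <- seq(kappa_range[1L], kappa_range[2L], length.out = steps)
  grid <- expand.grid(kappa_exc = ks, kappa_inh = ks, KEEP.OUT.ATTRS = FALSE)
  if (evaluate) {
    vals <- t(vapply(seq_len(nrow(grid)), function(i) {
      cfg <- config
      cfg$kappa_exc <- grid$kappa_exc[i]; cfg$kappa_inh <- grid$kappa_inh[i]
      mv <- model_vtf(cfg, b_grid = b_grid)
      if (is.null(mv$nkr) || !all(mv$stable)) {
        return(c(NA_real_, NA_real_, NA_real_,
                 mean(mv$tau_half, na.rm = TRUE), 0))
      }
      c(mv$nkr$log_n, mv$nkr$b_theta50, mv$nkr$f0,
        mean(mv$tau_half, na.rm = TRUE), 1)
    }, numeric(5L)))
    grid$log_n <- vals[, 1L]; grid$b_theta50 <- vals[, 2L]
    grid$f0 <- vals[, 3L]; grid$tau_half <- vals[, 4L]
    grid$stable <- vals[, 5L] > 0
  }
  class(grid) <- c("ring_scan", "data.frame")
  grid
}
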