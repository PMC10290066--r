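# End-to-end single-neuron analysis of a spike dataset.

bin_counts <- function(t_ms, lo = 0, hi = 450, bin = 10) {
  # counts per bin for one spike-time vector
  tabulate(pmin(floor((t_ms[t_ms >= lo & t_ms < hi] - lo) / bin) + 1L,
                as.integer((hi - lo) / bin)),
           nbins = as.integer((hi - lo) / bin))
}

# Mean rates (Hz) in a window per (theta, drift), and per-trial rates,
# for the subset of events of one neuron at one bandwidth.
window_rates_by_theta <- function(ev, trials_b, win, baseline_hz = 0) {
  span_s <- diff(win) / 1000
  inwin <- ev$t_ms >= win[1L] & ev$t_ms < win[2L]
  key_ev <- interaction(ev$theta_deg[inwin], ev$drift[inwin], ev$trial[inwin],
                        drop = FALSE)
  key_tr <- interaction(trials_b$theta_deg, trials_b$drift, trials_b$trial)
  counts <- as.numeric(table(factor(key_ev, levels = levels(key_tr))))[
    match(key_tr, levels(key_tr))]
  counts[is.na(counts)] <- 0
  data.frame(theta_deg = trials_b$theta_deg, drift = trials_b$drift,
             trial = trials_b$trial, rate = counts / span_s - baseline_hz)
}

#' Single-neuron tuning and dynamics summaries
#'
#' Runs the full single-neuron analysis chain on every neuron of a spike
#' dataset: analysis-window selection (300 ms window of maximal
#' across-condition spike-count variance), baseline subtraction (mean rate in
#' [-200, 0) ms), per-bandwidth tuning curves averaged across drift directions
#' (preferred drift only when the direction-selectivity index exceeds
#' \code{ds_gate}), circular variance, von Mises fit at the lowest bandwidth
#' (exclusion flag when \eqn{R^2 < 0.75}), Naka-Rushton VTF fit, per-bandwidth
#' Wilcoxon tuning significance with the largest significant bandwidth
#' \eqn{B_{\theta max}}, direction selectivity, early/late spike-count log
#' ratios and delays to peak tuning amplitude at the lowest and highest
#' bandwidths, and the preferred-orientation shift between them.
#'
#' @param dataset a \code{\link{simulate_trials}} dataset (or any
#'   \code{spike_dataset} with the same fields).
#' @param alpha significance level for tuning significance.
#' @param ds_gate direction-selectivity threshold above which tuning curves
#'   use only the preferred drift direction.
#' @return data.frame of class \code{neuron_summaries}, one row per neuron,
#'   with attribute \code{cv_curves} (list of per-neuron (B, CV) tables).
#' @export
analyze_tuning <- function(dataset, alpha = 0.05, ds_gate = 0.5) {
  stopifnot(inherits(dataset, "spike_dataset"))
  trials <- dataset$trials
  thetas <- sort(unique(trials$theta_deg))
  b_grid <- sort(unique(trials$b_theta_deg))
  b_lo <- b_grid[1L]; b_hi <- b_grid[length(b_grid)]
  ev_by_neuron <- split(dataset$events, dataset$events$neuron_id)
  ids <- if (!is.null(dataset$population)) dataset$population$neuron_id else
    as.integer(names(ev_by_neuron))

  rows <- vector("list", length(ids))
  cv_curves <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    ev <- ev_by_neuron[[as.character(id)]]
    if (is.null(ev)) ev <- dataset$events[0, ]

    # analysis window: across-trial mean counts per condition x 10ms bin
    key <- interaction(ev$stim_id, ev$drift, drop = FALSE)
    cond_counts <- t(vapply(split(ev$t_ms, key), bin_counts,
                            numeric(45L))) / dataset$n_trials
    win_start <- if (nrow(cond_counts) && any(cond_counts > 0)) {
      as.numeric(best_window(cond_counts))
    } else 0
    win <- c(win_start, win_start + 300)

    n_all_trials <- nrow(trials)
    baseline <- sum(ev$t_ms >= -200 & ev$t_ms < 0) / (0.2 * n_all_trials)

    # direction selectivity at the lowest bandwidth, at the best orientation
    ev_lo <- ev[ev$b_theta_deg == b_lo, ]
    tr_lo <- trials[trials$b_theta_deg == b_lo, ]
    wr_lo <- window_rates_by_theta(ev_lo, tr_lo, win, baseline)
    mean_dir <- tapply(wr_lo$rate, list(wr_lo$theta_deg, wr_lo$drift), mean)
    th_best <- as.numeric(rownames(mean_dir))[which.max(rowMeans(mean_dir))]
    dir_rates <- mean_dir[as.character(th_best), ]
    ds <- suppressWarnings(
      direction_selectivity(max(dir_rates), min(dir_rates)))
    pref_drift_sign <- if (is.finite(ds) && which.max(dir_rates) == 1L) -1L else 1L

    curve_for <- function(b) {
      evb <- ev[ev$b_theta_deg == b, ]
      trb <- trials[trials$b_theta_deg == b, ]
      wr <- window_rates_by_theta(evb, trb, win, baseline)
      if (is.finite(ds) && ds > ds_gate) wr <- wr[wr$drift == pref_drift_sign, ]
      as.numeric(tapply(wr$rate, factor(wr$theta_deg, levels = thetas), mean))
    }

    curves <- lapply(b_grid, curve_for)
    cv <- vapply(curves, function(r) {
      suppressWarnings(as.numeric(circular_variance(r, thetas)))
    }, numeric(1L))

    vm <- fit_von_mises(curves[[1L]], thetas)
    excluded <- !isTRUE(vm$converged) || !is.finite(vm$r_squared) ||
      vm$r_squared < 0.75
    nkr <- fit_vtf(b_grid, cv)

    # per-bandwidth tuning significance: preferred vs orthogonal grid angle
    th_pref_grid <- thetas[which.min(abs((thetas - (vm$theta_pref %||% th_best) + 90) %% 180 - 90))]
    th_orth_grid <- thetas[which.min(abs((thetas - (th_pref_grid + 90)) %% 180))]
    pvals <- vapply(b_grid, function(b) {
      evb <- ev[ev$b_theta_deg == b, ]
      trb <- trials[trials$b_theta_deg == b, ]
      wr <- window_rates_by_theta(evb, trb, win, 0)
      pr <- wr$rate[wr$theta_deg == th_pref_grid]
      ot <- wr$rate[wr$theta_deg == th_orth_grid]
      tuning_significance(pr, ot)
    }, numeric(1L))
    bmax <- b_theta_max(b_grid, pvals, alpha)

    dyn <- function(b) {
      evb <- ev[ev$b_theta_deg == b & ev$t_ms >= 0, ]
      centers <- seq(50, 400, by = 10)
      trb <- trials[trials$b_theta_deg == b, ]
      wr_mat <- t(vapply(centers, function(ct) {
        w <- c(ct - 50, ct + 50)
        r <- window_rates_by_theta(evb, trb, w, 0)
        as.numeric(tapply(r$rate, factor(r$theta_deg, levels = thetas), mean))
      }, numeric(length(thetas))))
      dynamics_features(evb$t_ms, wr_mat, centers)
    }
    dyn_lo <- dyn(b_lo); dyn_hi <- dyn(b_hi)

    pref_shift <- NA_real_
    if (is.finite(bmax) && bmax != b_lo && !excluded) {
      vm_b <- fit_von_mises(curves[[match(bmax, b_grid)]], thetas)
      if (isTRUE(vm_b$converged)) {
        d <- (vm_b$theta_pref - vm$theta_pref + 90) %% 180 - 90
        pref_shift <- d
      }
    } else if (is.finite(bmax) && bmax == b_lo) pref_shift <- 0

    depth <- if (!is.null(dataset$population)) {
      dataset$population$layer_depth[match(id, dataset$population$neuron_id)]
    } else NA_real_

    rows[[i]] <- data.frame(
      neuron_id = id, window_start_ms = win[1L], baseline_hz = baseline,
      theta_pref = vm$theta_pref, kappa = vm$kappa, vm_r2 = vm$r_squared,
      excluded = excluded, ds_index = ds,
      f0 = nkr$f0, fmax = nkr$fmax, log_n = nkr$log_n,
      b_theta50 = nkr$b_theta50, nkr_r2 = nkr$r_squared,
      b_theta_max = bmax,
      cv_low = cv[1L], cv_high = cv[length(cv)],
      el_ratio_low = dyn_lo$early_late_ratio,
      el_ratio_high = dyn_hi$early_late_ratio,
      delay_low = dyn_lo$delay_to_peak, delay_high = dyn_hi$delay_to_peak,
      pref_shift_deg = pref_shift, layer_depth = depth)
    cv_curves[[i]] <- data.frame(b_theta_deg = b_grid, cv = cv, p_value = pvals)
  }
  out <- do.call(rbind, rows)
  attr(out, "cv_curves") <- stats::setNames(cv_curves, ids)
  attr(out, "b_grid") <- b_grid
  class(out) <- c("neuron_summaries", "data.frame")
  out
}

#' @export
print.neuron_summaries <- function(x, ...) {
  cat(sprintf("Neuron summaries: %d neurons (%d excluded by von Mises R^2 < 0.75)\n",
              nrow(x), sum(x$excluded)))
  cat(sprintf("  median log(n) = %.2f, median B50 = %.1f deg, median f0 = %.2f\n",
              stats::median(x$log_n, na.rm = TRUE),
              stats::median(x$b_theta50, na.rm = TRUE),
              stats::median(x$f0, na.rm = TRUE)))
  invisible(x)
}

#' Write neuron summaries to CSV
#' @param summaries output of \code{\link{analyze_tuning}}.
#' @param path file path.
#' @export
write_neuron_summaries <- function(summaries, path) {
  utils::write.csv(as.data.frame(summaries), path, row.names = FALSE)
  invisible(path)
}
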