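#' Circular variance of a tuning curve
#'
#' \deqn{CV = 1 - |\sum_k R(\theta_k) e^{2 i \theta_k} / \sum_k R(\theta_k)|}
#' where \eqn{R(\theta_k)} are baseline-subtracted rates. 0 means perfect
#' orientation selectivity, 1 means no tuning. Negative rates are clipped to 0
#' (the resultant requires non-negative weights); an all-zero curve is flagged
#' and reported as CV = 1.
#'
#' @param rates numeric vector of (baseline-subtracted) rates.
#' @param thetas stimulus orientations in degrees.
#' @return CV in [0, 1], with attribute \code{undefined = TRUE} when all
#'   clipped rates are zero.
#' @export
circular_variance <- function(rates, thetas) {
  stopifnot(length(rates) == length(thetas))
  r <- pmax(rates, 0)
  if (sum(r) <= 0) {
    warning("all rates are zero after clipping; CV undefined, reported as 1")
    return(structure(1, undefined = TRUE))
  }
  th <- deg2rad(thetas)
  1 - Mod(sum(r * exp(2i * th)) / sum(r))
}

#' Direction selectivity index
#'
#' \eqn{D_s = (R_{pref} - R_{null}) / R_{pref}} on baseline-subtracted rates.
#'
#' @param r_pref rate at the preferred drift direction (must be > 0).
#' @param r_null rate at the opposite drift direction.
#' @return \eqn{D_s}; \code{NA} with a warning when \code{r_pref <= 0}.
#' @export
direction_selectivity <- function(r_pref, r_null) {
  if (!is.finite(r_pref) || r_pref <= 0) {
    warning("r_pref <= 0; direction selectivity undefined")
    return(NA_real_)
  }
  (r_pref - r_null) / r_pref
}

#' Half-width at half-height of a von Mises tuning profile
#'
#' \deqn{HWHH = 0.5 \arccos((\log 0.5 + \kappa)/\kappa)} evaluated in radians
#' and returned in degrees. Defined for \eqn{\kappa \ge -\log(0.5)}.
#'
#' @param kappa concentration parameter(s).
#' @return HWHH in degrees.
#' @export
hwhh <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < -log(0.5))) {
    stop(sprintf("`kappa` must be >= -log(0.5) = %.6f.", -log(0.5)))
  }
  rad2deg(0.5 * acos((log(0.5) + kappa) / kappa))
}

#' Analysis window maximizing spike-count variance
#'
#' Slides a 300 ms window in 10 ms steps over [0, 450] ms and returns the
#' onset of the window whose variance (across conditions) of the across-trial
#' mean spike count is maximal; ties go to the earliest window.
#'
#' @param counts matrix of 10-ms binned spike counts, conditions (rows
#'   averaged across trials beforehand) x bins covering [0, 450] ms; or a
#'   3-d array trials x conditions x bins which is averaged over trials.
#' @param width_ms window width, default 300.
#' @param bin_ms bin size, default 10.
#' @return window onset in ms (attribute \code{window} gives c(start, end)).
#' @export
best_window <- function(counts, width_ms = 300, bin_ms = 10) {
  if (length(dim(counts)) == 3L) counts <- apply(counts, c(2L, 3L), mean)
  nb <- ncol(counts)
  wbins <- as.integer(width_ms / bin_ms)
  if (all(counts == 0)) {
    warning("all-zero counts; defaulting to window [0, 300] ms")
    return(structure(0, window = c(0, width_ms)))
  }
  cum <- t(apply(counts, 1L, cumsum))
  starts <- seq_len(nb - wbins + 1L) - 1L
  v <- vapply(starts, function(s) {
    w <- cum[, s + wbins] - if (s > 0) cum[, s] else 0
    stats::var(w)
  }, numeric(1L))
  s <- starts[which.max(v)] * bin_ms
  structure(s, window = c(s, s + width_ms))
}

# ---- von Mises tuning fit ---------------------------------------------------

vm_curve <- function(theta_deg, r0, r_max, theta_pref, kappa) {
  r0 + (r_max - r0) * exp(kappa * (cos(2 * deg2rad(theta_deg - theta_pref)) - 1))
}

#' Fit a von Mises tuning curve
#'
#' Least-squares fit of
#' \deqn{f(\theta) = R_0 + (R_{max} - R_0) \exp\{\kappa(\cos(2(\theta - \theta_{pref})) - 1)\}}
#' to mean rates over orientations. Initial \eqn{\theta_{pref}} is taken at the
#' curve maximum and refined with \code{minpack.lm}; neurons whose fit has
#' \eqn{R^2 < 0.75} at the lowest bandwidth are conventionally excluded from
#' downstream analyses (flag returned, not enforced here).
#'
#' @param rates mean (baseline-subtracted) rates per orientation.
#' @param thetas orientations in degrees (typically 12 values).
#' @return object of class \code{vm_fit}: list with \code{r0}, \code{r_max},
#'   \code{theta_pref} in [0, 180), \code{kappa}, \code{r_squared},
#'   \code{converged}.
#' @export
fit_von_mises <- function(rates, thetas) {
  stopifnot(length(rates) == length(thetas))
  tp0 <- thetas[which.max(rates)]
  start <- list(r0 = min(rates), r_max = max(rates), theta_pref = tp0, kappa = 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rates ~ vm_curve(thetas, r0, r_max, theta_pref, kappa),
      start = start,
      lower = c(-Inf, -Inf, tp0 - 90, 0), upper = c(Inf, Inf, tp0 + 90, 500),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(r0 = NA_real_, r_max = NA_real_,
                          theta_pref = NA_real_, kappa = NA_real_,
                          r_squared = NA_real_, converged = FALSE),
                     class = "vm_fit"))
  }
  p <- as.list(stats::coef(fit))
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((rates - mean(rates))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(r0 = p$r0, r_max = p$r_max,
                 theta_pref = p$theta_pref %% 180, kappa = p$kappa,
                 r_squared = r2, converged = TRUE),
            class = "vm_fit")
}

#' @export
print.vm_fit <- function(x, ...) {
  cat(sprintf("von Mises fit: theta_pref = %.1f deg, kappa = %.2f, R0 = %.2f, Rmax = %.2f, R^2 = %.3f\n",
              x$theta_pref, x$kappa, x$r0, x$r_max, x$r_squared))
  invisible(x)
}

#' @export
coef.vm_fit <- function(object, ...) {
  c(r0 = object$r0, r_max = object$r_max, theta_pref = object$theta_pref,
    kappa = object$kappa)
}

#' @export
predict.vm_fit <- function(object, thetas, ...) {
  vm_curve(thetas, object$r0, object$r_max, object$theta_pref, object$kappa)
}

# ---- Naka-Rushton variance-tuning function ----------------------------------

#' Naka-Rushton function
#'
#' \deqn{f(B) = f_0 + f_{max} B^n / (B^n + B_{50}^n)} evaluated in the
#' numerically stable logistic form
#' \eqn{f_0 + f_{max} / (1 + e^{-n(\log B - \log B_{50})})}, so that very
#' large exponents (near-step functions) do not overflow.
#'
#' @param b input variance values (degrees), positive.
#' @param f0 base value.
#' @param fmax amplitude above the base.
#' @param n exponent (> 0).
#' @param b50 half-saturation input (degrees).
#' @export
naka_rushton <- function(b, f0, fmax, n, b50) {
  f0 + fmax * stats::plogis(n * (log(b) - log(b50)))
}

NKR_BOUNDS <- list(f0 = c(0, 1), fmax = c(0, 1), log_n = c(0.1, 10),
                   b50 = c(0.01, 44))

#' Fit a Naka-Rushton variance-tuning function
#'
#' Bounded least-squares fit of \code{\link{naka_rushton}} to (\eqn{B_\theta},
#' CV) points. Initialisation uses the plateaus for \eqn{f_0} and
#' \eqn{f_{max}} and a logit-linearisation of the interior points for
#' (\eqn{n}, \eqn{B_{50}}): writing \eqn{p = (f - f_0)/f_{max}},
#' \eqn{\mathrm{logit}(p)} is linear in \eqn{\log B} with slope \eqn{n}. The
#' initial point is refined with bounded \code{optim(L-BFGS-B)}, keeping
#' whichever of initial/refined/fallback starts attains the lowest SSE, so a
#' saturated near-step VTF (flat SSE in \eqn{n}) retains the
#' linearisation-estimated exponent rather than drifting. Bounds:
#' \eqn{f_0, f_{max} \in [0,1]}, \eqn{\log n \in [0.1, 10]},
#' \eqn{B_{50} \in [0.01, 44]} degrees.
#'
#' @param b_theta input variance values (degrees).
#' @param cv circular variance at each \code{b_theta}.
#' @return object of class \code{nkr_fit}: \code{f0}, \code{fmax}, \code{n},
#'   \code{log_n}, \code{b_theta50}, \code{r_squared}, \code{pinned} (TRUE
#'   when \code{log_n} ended on a bound), \code{sse}.
#' @export
fit_vtf <- function(b_theta, cv) {
  stopifnot(length(b_theta) == length(cv), length(cv) >= 4L)
  o <- order(b_theta)
  b <- b_theta[o]; y <- cv[o]
  lb <- log(b)

  sse_of <- function(p) {
    pred <- naka_rushton(b, p[1L], p[2L], exp(p[3L]), p[4L])
    sum((pred - y)^2)
  }
  lower <- c(NKR_BOUNDS$f0[1L], NKR_BOUNDS$fmax[1L], NKR_BOUNDS$log_n[1L],
             NKR_BOUNDS$b50[1L])
  upper <- c(NKR_BOUNDS$f0[2L], NKR_BOUNDS$fmax[2L], NKR_BOUNDS$log_n[2L],
             NKR_BOUNDS$b50[2L])

  # Plateau + logit-linearisation initialiser.
  f0_i <- clamp(min(y[seq_len(max(1L, floor(length(y) / 4)))]), 0, 1)
  top_i <- clamp(max(y), f0_i + 1e-6, 1)
  fmax_i <- top_i - f0_i
  p_int <- (y - f0_i) / fmax_i
  use <- p_int > 1e-14 & p_int < 1 - 1e-14
  inits <- list()
  if (sum(use) >= 2L) {
    lf <- stats::lm.fit(cbind(1, lb[use]), stats::qlogis(p_int[use]))
    n_i <- lf$coefficients[2L]
    if (is.finite(n_i) && n_i > 0) {
      b50_i <- exp(-lf$coefficients[1L] / n_i)
      inits <- c(inits, list(c(f0_i, fmax_i,
                               clamp(log(n_i), lower[3L], upper[3L]),
                               clamp(b50_i, lower[4L], upper[4L]))))
    }
  }
  inits <- c(inits,
             list(c(f0_i, fmax_i, log(2), clamp(stats::median(b), lower[4L], upper[4L])),
                  c(f0_i, fmax_i, 1.5, 20)))

  best <- NULL
  for (p0 in inits) {
    cand <- list(par = p0, value = sse_of(p0))
    ref <- tryCatch(
      stats::optim(p0, sse_of, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    # strict improvement keeps a zero-residual initial point where SSE is flat
    if (!is.null(ref) && ref$value < cand$value - 1e-15) cand <- ref
    if (is.null(best) || cand$value < best$value - 1e-15) best <- cand
  }
  p <- unname(best$par)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    f0 = p[1L], fmax = p[2L], n = exp(p[3L]), log_n = p[3L],
    b_theta50 = p[4L], sse = best$value,
    r_squared = if (ss_tot > 0) 1 - best$value / ss_tot else NA_real_,
    pinned = p[3L] <= lower[3L] + 1e-8 || p[3L] >= upper[3L] - 1e-8),
    class = "nkr_fit")
}

#' @export
print.nkr_fit <- function(x, ...) {
  cat(sprintf("Naka-Rushton VTF: f0 = %.3f, fmax = %.3f, log(n) = %.2f, B50 = %.2f deg (R^2 = %.3f)%s\n",
              x$f0, x$fmax, x$log_n, x$b_theta50, x$r_squared,
              if (isTRUE(x$pinned)) " [n pinned at bound]" else ""))
  invisible(x)
}

#' @export
coef.nkr_fit <- function(object, ...) {
  c(f0 = object$f0, fmax = object$fmax, log_n = object$log_n,
    b_theta50 = object$b_theta50)
}

#' @export
predict.nkr_fit <- function(object, b_theta, ...) {
  naka_rushton(b_theta, object$f0, object$fmax, object$n, object$b_theta50)
}

# ---- significance & dynamics ------------------------------------------------

#' Orientation-tuning significance
#'
#' Two-sided Wilcoxon signed-rank test (continuity corrected, zero differences
#' discarded) comparing per-trial rates at the preferred vs. the orthogonal
#' orientation. With fewer than \code{min_pairs} informative (non-tied) pairs
#' the p value is undefined and the condition counts as not tuned.
#'
#' @param rates_pref,rates_ortho paired per-trial rates.
#' @param min_pairs minimum informative pairs, default 6.
#' @return p value, or \code{NA} when undefined.
#' @export
tuning_significance <- function(rates_pref, rates_ortho, min_pairs = 6L) {
  stopifnot(length(rates_pref) == length(rates_ortho))
  d <- rates_pref - rates_ortho
  if (sum(d != 0) < min_pairs) return(NA_real_)
  suppressWarnings(
    stats::wilcox.test(rates_pref, rates_ortho, paired = TRUE,
                       correct = TRUE, exact = FALSE)$p.value)
}

#' Largest bandwidth with significant tuning
#'
#' @param b_theta grid of bandwidths (degrees).
#' @param p_values tuning-significance p value per bandwidth.
#' @param alpha significance level.
#' @return largest \code{b_theta} with \code{p < alpha}, or \code{NA} when
#'   none is significant.
#' @export
b_theta_max <- function(b_theta, p_values, alpha = 0.05) {
  ok <- which(is.finite(p_values) & p_values < alpha)
  if (!length(ok)) return(NA_real_)
  max(b_theta[ok])
}

#' Response-dynamics features
#'
#' \code{early_late_ratio}: \eqn{\log((late + \epsilon)/(early + \epsilon))}
#' where early counts spikes before 100 ms and late after 200 ms
#' (additive smoothing \eqn{\epsilon} = 1 spike). \code{delay_to_peak}: centre
#' of the 100-ms sliding window (10 ms steps over [0, 450] ms) maximizing the
#' tuning-curve peak amplitude (max - min of mean rates over orientations).
#'
#' @param spike_times vector of spike times (ms) pooled over trials, for the
#'   early/late ratio.
#' @param window_rates optional matrix windows x orientations of mean rates
#'   (from preferred-bandwidth trials) for the delay; rows must correspond to
#'   \code{window_centers}.
#' @param window_centers centres (ms) of the rate windows.
#' @param eps additive smoothing, default 1 spike.
#' @param early_ms,late_ms boundaries of the early/late count windows.
#' @return list with \code{early_late_ratio} and \code{delay_to_peak} (NA when
#'   the corresponding input is missing/empty).
#' @export
dynamics_features <- function(spike_times, window_rates = NULL,
                              window_centers = NULL, eps = 1,
                              early_ms = 100, late_ms = 200) {
  early <- sum(spike_times >= 0 & spike_times < early_ms)
  late <- sum(spike_times > late_ms)
  ratio <- log((late + eps) / (early + eps))
  if (length(spike_times) == 0L) ratio <- NA_real_
  delay <- NA_real_
  if (!is.null(window_rates)) {
    amp <- apply(window_rates, 1L, function(r) max(r) - min(r))
    delay <- window_centers[which.max(amp)]
  }
  list(early_late_ratio = ratio, delay_to_peak = delay)
}
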