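thetas12 <- seq(0, 165, by = 15)

test_that("circular variance hits its limits and matches the complex-sum oracle", {
  expect_equal(as.numeric(circular_variance(rep(2, 12), thetas12)), 1)
  expect_equal(as.numeric(circular_variance(c(5, rep(0, 11)), thetas12)), 0)
  r <- c(2, 1, rep(0, 9), 1)  # symmetric about the first orientation
  oracle <- 1 - Mod(sum(r * exp(2i * deg2rad(thetas12))) / sum(r))
  expect_lt(abs(as.numeric(circular_variance(r, thetas12)) - oracle), 1e-12)
  expect_warning(cv0 <- circular_variance(rep(0, 12), thetas12), "undefined")
  expect_equal(as.numeric(cv0), 1)
  expect_true(attr(cv0, "undefined"))
})

test_that("circular variance is invariant to rate scaling and rotation", {
  set.seed(1)
  for (i in 1:20) {
    r <- stats::rgamma(12, 2)
    cv <- as.numeric(circular_variance(r, thetas12))
    expect_equal(as.numeric(circular_variance(7.3 * r, thetas12)), cv)
    expect_equal(as.numeric(circular_variance(r, thetas12 + 37)), cv)
  }
})

test_that("direction selectivity follows its definition and edge cases", {
  expect_equal(direction_selectivity(20, 20), 0)
  expect_equal(direction_selectivity(20, 0), 1)
  expect_equal(direction_selectivity(20, 5), 0.75)
  expect_warning(d <- direction_selectivity(0, 5), "undefined")
  expect_true(is.na(d))
})

test_that("half-width at half-height matches its closed form", {
  expect_equal(hwhh(-log(0.5)), 45)
  expect_equal(hwhh(2), rad2deg(0.5 * acos((log(0.5) + 2) / 2)))
  expect_lt(hwhh(1e6), 0.1)
  expect_error(hwhh(0.5), "0.69")
})

test_that("best window finds bursts, breaks ties early, handles silence", {
  nb <- 45L
  burst <- matrix(0, 2, nb); burst[1L, 21:25] <- 5   # burst at 200-250 ms
  w <- best_window(burst)
  expect_true(w <= 200 && w + 300 >= 250)
  stationary <- matrix(rep(c(1, 3), nb), 2, nb)
  expect_equal(as.numeric(best_window(stationary)), 0)
  expect_warning(w0 <- best_window(matrix(0, 2, nb)), "all-zero")
  expect_equal(attr(w0, "window"), c(0, 300))
  # early-transient response pulls the window to an early start
  tg <- seq(5, 445, by = 10)
  k <- orivar:::temporal_kernel(tg, 30, 5, 40)
  trans <- rbind(0.2 * k, 2 * k)
  expect_lt(as.numeric(best_window(trans)), 100)
})

test_that("von Mises fits recover noiseless parameters and flag flat curves", {
  truth <- list(r0 = 1, r_max = 20, theta_pref = 72.5, kappa = 2.3)
  y <- truth$r0 + (truth$r_max - truth$r0) *
    exp(truth$kappa * (cos(2 * deg2rad(thetas12 - truth$theta_pref)) - 1))
  fit <- fit_von_mises(y, thetas12)
  expect_equal(coef(fit)[["theta_pref"]], truth$theta_pref, tolerance = 1e-6)
  expect_equal(coef(fit)[["kappa"]], truth$kappa, tolerance = 1e-6)
  expect_equal(predict(fit, thetas12), y, tolerance = 1e-6)
  expect_gt(fit$r_squared, 0.999)

  flat <- fit_von_mises(rep(3, 12), thetas12)
  expect_true(!isTRUE(flat$converged) || !is.finite(flat$r_squared) ||
                flat$r_squared < 0.75)
})

test_that("von Mises fits on Poisson-noisy curves localise the preferred angle", {
  set.seed(11)
  hits <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    tp <- stats::runif(1, 0, 180)
    mu <- 2 + 18 * exp(2 * (cos(2 * deg2rad(thetas12 - tp)) - 1))
    y <- stats::rpois(12 * 15, rep(mu, each = 15))
    ybar <- colMeans(matrix(y, 15))
    fit <- fit_von_mises(ybar, thetas12)
    err <- abs((fit$theta_pref - tp + 90) %% 180 - 90)
    hits <- hits + (err <= 7.5)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("Naka-Rushton fit is self-consistent on the 8-point grid", {
  b8 <- unique(stimulus_grid()$b_theta_deg)
  y <- naka_rushton(b8, 0.3, 0.6, exp(2.4), 35)
  fit <- fit_vtf(b8, y)
  expect_equal(fit$f0, 0.3, tolerance = 0.01)
  expect_equal(fit$b_theta50, 35, tolerance = 0.35)
  expect_equal(fit$log_n, 2.4, tolerance = 0.05)
  # algebraic identity: f(B50) - f0 = fmax / 2 for any fitted parameters
  expect_equal(predict(fit, fit$b_theta50) - fit$f0, fit$fmax / 2,
               tolerance = 1e-12)
  # flat VTF collapses to fmax ~ 0
  flat <- fit_vtf(b8, rep(0.4, 8))
  expect_lt(flat$fmax, 0.02)
  expect_equal(flat$f0, 0.4, tolerance = 0.02)
  # fitted curve is monotone non-decreasing for n > 0
  bb <- seq(0.5, 44, length.out = 200)
  expect_true(all(diff(predict(fit, bb)) >= 0))
})

test_that("tuning significance discriminates strong tuning and honours pairing rules", {
  expect_true(is.na(tuning_significance(rep(5, 15), rep(5, 15))))
  set.seed(21)
  sig <- vapply(1:50, function(i) {
    p <- tuning_significance(stats::rpois(15, 30), stats::rpois(15, 2))
    is.finite(p) && p < 0.05
  }, logical(1L))
  expect_gte(mean(sig), 0.98)
  expect_true(is.na(tuning_significance(c(1, 2, 3, 1, 1), c(1, 2, 3, 1, 1) + 0)))
})

test_that("largest significantly tuned bandwidth is extracted correctly", {
  b8 <- unique(stimulus_grid()$b_theta_deg)
  p <- c(1e-5, 1e-4, 0.001, 0.03, 0.2, 0.01, 0.6, 0.7)
  expect_equal(b_theta_max(b8, p), 25)
  expect_true(is.na(b_theta_max(b8, rep(0.5, 8))))
})

test_that("dynamics features have the documented sign convention and delay", {
  early_only <- dynamics_features(runif(40, 5, 90))
  expect_lt(early_only$early_late_ratio, -2)
  ramp <- dynamics_features(runif(60, 210, 440))
  expect_gt(ramp$early_late_ratio, 2)
  centers <- seq(50, 400, 10)
  wr <- matrix(0, length(centers), 12)
  wr[centers == 250, 4L] <- 10   # impulse-like peak at 250 ms
  d <- dynamics_features(numeric(0), wr, centers)
  expect_equal(d$delay_to_peak, 250)
  expect_true(is.na(d$early_late_ratio))
})

test_that("end-to-end summaries recover ground truth on synthetic data", {
  fx <- small_dataset()
  sm <- small_summaries()
  expect_equal(nrow(sm), 16L)
  # preferred orientations held within half a grid step for clean fits
  err <- abs((sm$theta_pref - fx$pop$theta_pref + 90) %% 180 - 90)
  expect_gte(mean(err[!sm$excluded] <= 7.5), 0.9)
  # preferred orientation stable across bandwidths (small shift)
  expect_lt(median(abs(sm$pref_shift_deg), na.rm = TRUE), 10)
  # resilient neurons stay tuned to larger bandwidths than vulnerable ones
  res <- fx$pop$archetype == "resilient"
  expect_gt(median(sm$b_theta_max[res], na.rm = TRUE),
            median(sm$b_theta_max[!res], na.rm = TRUE) - 1e-9)
  # VTF changepoint recovered
  expect_lt(median(abs(sm$b_theta50 - fx$pop$b_theta50)), 4)
})
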