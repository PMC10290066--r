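test_that("feedforward profile peaks at the stimulus and integrates to J_ff", {
  cfg <- ring_config(n_units = 256)
  vff <- feedforward_input(0, 5, cfg)
  # pi-periodic profile: the unit at theta_pref = 0 sits on the peak
  expect_equal(vff[which.min(abs(cfg$theta_prefs))], max(vff))
  expect_equal(sum(vff) * cfg$spacing, cfg$j_ff, tolerance = 1e-3)
  # symmetric about the stimulus orientation (up to interpolation error)
  v2 <- feedforward_input(deg2rad(30), 3, cfg)
  interp <- function(x) orivar:::circ_interp(cfg$theta_prefs, v2, x, 2 * pi)
  offs <- seq(0.05, 1, length.out = 10)
  expect_equal(interp(deg2rad(30) + offs), interp(deg2rad(30) - offs),
               tolerance = 1e-2)
  expect_error(feedforward_input(0, 0.1, cfg), "kappa_ff")
})

test_that("connectivity kernel is a Mexican hat with the right mass", {
  cfg <- ring_config(kappa_exc = 5, kappa_inh = 1.5)
  kern <- connectivity_kernel(cfg)
  expect_equal(sum(kern) * cfg$spacing, cfg$j_exc - cfg$j_inh, tolerance = 1e-9)
  expect_gt(kern[which.min(abs(cfg$theta_prefs))], 0)           # centre +
  expect_lt(kern[which.min(abs(abs(cfg$theta_prefs) - pi / 4))], 0)  # surround -
  # equal gains and concentrations cancel exactly
  cfg0 <- ring_config(j_exc = 1.5, j_inh = 1.5, kappa_exc = 2, kappa_inh = 2)
  expect_equal(max(abs(connectivity_kernel(cfg0))), 0)
})

test_that("without recurrence the membrane relaxes to V_ff at rate tau_m", {
  cfg <- ring_config(j_exc = 0, j_inh = 0, n_units = 128)
  rr <- simulate_ring(cfg, theta = 0, b_theta = 10)
  vff <- feedforward_input(0, kappa_from_btheta(deg2rad(10)), cfg)
  expect_equal(rr$v_steady, vff, tolerance = 1e-6)
  expect_true(rr$stable)
  # at t = 3 tau the readout rate is within 5% of steady (1 - e^-3 = 0.950)
  i3 <- which.min(abs(rr$t - 3 * cfg$tau_m))
  steady <- max(rr$readout_rate)
  expect_lt(abs(rr$readout_rate[i3] - steady) / steady, 0.053)
  # half-rise time matches tau ln 2
  expect_equal(rr$tau_half, cfg$tau_m * log(2), tolerance = cfg$dt * 2)
})

test_that("zero input leaves the network silent", {
  cfg <- ring_config(j_ff = 0, n_units = 64)
  rr <- simulate_ring(cfg, theta = 0, b_theta = 10)
  expect_equal(max(abs(rr$v_steady)), 0)
  expect_equal(max(rr$readout_rate), 0)
})

test_that("steady state is insensitive to the time step and initial state", {
  cfg1 <- ring_config(n_units = 64, kappa_exc = 2.5, kappa_inh = 2, dt = 0.5)
  cfg2 <- ring_config(n_units = 64, kappa_exc = 2.5, kappa_inh = 2, dt = 0.25)
  r1 <- simulate_ring(cfg1, 0, b_theta = 15)
  r2 <- simulate_ring(cfg2, 0, b_theta = 15)
  expect_lt(max(abs(r1$r_steady - r2$r_steady)) / max(r2$r_steady), 1e-3)

  vff <- feedforward_input(0, kappa_from_btheta(deg2rad(15)), cfg1)
  s0 <- orivar:::ring_integrate(cfg1, vff)
  s1 <- orivar:::ring_integrate(cfg1, vff, v0 = 0.5)
  expect_lt(max(abs(s0$v_steady - s1$v_steady)), 1e-6)
})

test_that("rates are non-negative and diverging configurations are flagged", {
  rr <- simulate_ring(ring_config(n_units = 64, kappa_exc = 6, kappa_inh = 1),
                      0, b_theta = 20)
  expect_false(rr$stable)
  expect_true(all(is.na(rr$r_steady)))
  ok <- simulate_ring(ring_config(n_units = 64, kappa_exc = 3, kappa_inh = 3),
                      0, b_theta = 20)
  expect_true(ok$stable)
  expect_true(all(ok$r_steady >= 0))
  expect_true(all(ok$readout_rate >= 0))
})

test_that("ring convolution matches the brute-force circular sum", {
  cfg <- ring_config(n_units = 96)
  x <- feedforward_input(deg2rad(20), 8, cfg)
  got <- ring_convolve(x, 4, cfg)
  rf <- orivar:::vm_density(cfg$theta_prefs, 4)
  brute <- vapply(seq_len(96), function(i) {
    sum(rf[((i - seq_len(96)) %% 96) + 1L] * x) * cfg$spacing
  }, numeric(1L))
  expect_equal(got, brute, tolerance = 1e-10)
})

test_that("model VTF uses the published stimulus grids and flags untuned configs", {
  cfg <- ring_config(n_units = 64, kappa_exc = 3, kappa_inh = 3)
  mv <- model_vtf(cfg)
  expect_equal(length(mv$b_grid), 20L)
  expect_equal(length(mv$theta_grid), 32L)
  expect_true(0 %in% mv$theta_grid)
  expect_equal(min(mv$b_grid), 0.5)
  expect_equal(max(mv$b_grid), 35)

  # an untuned configuration (zero kernel, flat input) sits exactly at the
  # untuned ceiling of the 32-point [-75, 75) sampling; the full-circle CV
  # of 1 is unreachable on that sub-span
  cfg0 <- ring_config(n_units = 64, j_exc = 0, j_inh = 0)
  theta_grid <- mv$theta_grid
  ceiling_cv <- as.numeric(circular_variance(rep(1, 32), theta_grid))
  sim <- orivar:::ring_integrate(cfg0, matrix(1, 64))
  curve <- orivar:::circ_interp(cfg0$theta_prefs, sim$r_steady[, 1L],
                                -deg2rad(theta_grid), 2 * pi)
  cv_flat <- as.numeric(circular_variance(curve, theta_grid))
  expect_equal(cv_flat, ceiling_cv, tolerance = 1e-9)
  expect_equal(ceiling_cv, 0.8086, tolerance = 1e-3)
})

test_that("delta receptive field reproduces the unconvolved feedforward VTF", {
  cfg <- ring_config(n_units = 64)
  bg <- seq(5, 35, length.out = 6)
  plain <- feedforward_mode(cfg, rf_kappa = 1e6, b_grid = bg)
  cfg0 <- cfg; cfg0$j_exc <- 0; cfg0$j_inh <- 0
  raw <- model_vtf(cfg0, b_grid = bg)
  expect_equal(plain$cv, raw$cv, tolerance = 1e-4)
  # broad RF raises f0 relative to a narrow RF
  broad <- feedforward_mode(cfg, rf_kappa = 3, b_grid = bg)
  narrow <- feedforward_mode(cfg, rf_kappa = 40, b_grid = bg)
  expect_gt(broad$nkr$f0, narrow$nkr$f0)
  expect_gt(broad$rf_hwhh, narrow$rf_hwhh)
})

test_that("connectivity scan enumerates the grid and swaps antisymmetrically", {
  grid <- ring_scan(steps = 200L)
  expect_equal(nrow(grid), 40000L)
  expect_equal(length(unique(grid$kappa_exc)), 200L)
  expect_equal(range(grid$kappa_exc), c(0.35, 7))

  # swapping (kappa_exc, J_exc) <-> (kappa_inh, J_inh) flips the kernel sign
  a <- ring_config(j_exc = 1.7, j_inh = 2.1, kappa_exc = 4, kappa_inh = 1.2)
  b <- ring_config(j_exc = 2.1, j_inh = 1.7, kappa_exc = 1.2, kappa_inh = 4)
  expect_equal(connectivity_kernel(a), -connectivity_kernel(b), tolerance = 1e-12)

  small <- ring_scan(steps = 3L, config = ring_config(n_units = 48),
                     evaluate = TRUE, b_grid = seq(2, 35, length.out = 6))
  expect_equal(nrow(small), 9L)
  expect_true(any(small$stable))
  expect_true(all(is.na(small$log_n[!small$stable])))
})
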