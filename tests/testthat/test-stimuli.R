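test_that("orientation envelope peaks at theta, dips orthogonally, is pi-periodic", {
  b <- deg2rad(10)
  th <- deg2rad(45)
  expect_equal(orientation_envelope(th, b, th), exp(1 / (4 * b^2)))
  expect_equal(orientation_envelope(th, b, th + pi / 2), exp(-1 / (4 * b^2)))
  grid <- seq(0, pi, length.out = 181)
  env <- orientation_envelope(th, b, grid)
  expect_equal(env, orientation_envelope(th, b, grid + pi))
  # symmetric about theta
  expect_equal(orientation_envelope(th, b, th + grid),
               orientation_envelope(th, b, th - grid))
  expect_error(orientation_envelope(th, -0.1, grid), "positive")
})

test_that("envelope mass matches brute-force quadrature at two resolutions", {
  th <- deg2rad(45); b <- deg2rad(10)
  mass <- function(n) {
    g <- seq(0, pi, length.out = n + 1L)[seq_len(n)]
    mean(orientation_envelope(th, b, g)) * pi
  }
  # trapezoid rule on a periodic integrand converges spectrally
  expect_lt(abs(mass(4096) - mass(16384)), 1e-10)
})

test_that("cloud synthesis is deterministic with constant frame luminance", {
  sp <- stimulus_spec(45, 10)
  c1 <- synthesize_cloud(sp, 64, seed = 7)
  c2 <- synthesize_cloud(sp, 64, seed = 7)
  expect_identical(c1$frames, c2$frames)
  expect_true(all(c1$frames >= 0 & c1$frames <= 1))
  # drift is a pure Fourier phase shift: per-frame mean equals global mean
  means <- apply(c1$frames, 1L, mean)
  expect_lt(diff(range(means)), 1e-10)
  expect_error(synthesize_cloud(sp, 16), ">= 32")
})

test_that("realised angular bandwidth grows monotonically over the grid", {
  bs <- unique(stimulus_grid()$b_theta_deg)
  cvs <- vapply(bs, function(b) {
    angular_spectrum(synthesize_cloud(stimulus_spec(45, b), 48, seed = 3))$circ_var
  }, numeric(1L))
  expect_equal(stats::cor(bs, cvs, method = "spearman"), 1)
})

test_that("radially averaged power follows the band-pass design", {
  cl <- synthesize_cloud(stimulus_spec(0, 20), 128, seed = 1)
  fr <- cl$frames[1, , ]
  n <- 128L
  f1 <- c(0:(n / 2), (-(n / 2) + 1):-1) / n
  rr <- sqrt(outer(f1^2, f1^2, "+"))
  sel <- rr > 0 & rr <= 0.5
  pw <- tapply(Mod(stats::fft(fr))[sel]^2,
               cut(rr[sel], seq(0, 0.5, 0.025)), mean)
  centres <- seq(0.0125, 0.4875, 0.025)
  # peak at the design frequency (0.9 cpd x 0.1 deg/px = 0.09 cyc/px) ...
  expect_lt(abs(centres[which.max(pw)] - 0.09), 0.03)
  # ... and decaying on both sides of it (band-pass, not white)
  expect_gt(max(pw), 10 * pw[[length(pw) - 1L]])
  expect_gt(max(pw), 10 * pw[[1L]])
})

test_that("stimulus grid enumerates 12 x 8 conditions and 2880 trials", {
  g <- stimulus_grid()
  expect_equal(nrow(g), 96L)
  expect_equal(nrow(unique(g[, c("theta_deg", "b_theta_deg")])), 96L)
  expect_equal(length(unique(g$theta_deg)), 12L)
  expect_equal(sort(unique(diff(sort(unique(g$theta_deg))))), 15)
  expect_equal(length(unique(g$b_theta_deg)), 8L)
  expect_equal(min(g$b_theta_deg), 0.5)
  expect_equal(max(g$b_theta_deg), 35)
  expect_equal(nrow(trial_table(g, 15L)), 2880L)
})

test_that("bandwidth <-> concentration conversions invert each other", {
  expect_equal(btheta_from_kappa(-log(0.5)), 0.7526918, tolerance = 1e-6)
  b <- deg2rad(c(5, 10, 15, 20, 25, 30, 35))
  expect_equal(btheta_from_kappa(kappa_from_btheta(b)), b, tolerance = 1e-8)
  # kappa -> Inf gives B -> 0 (slowly, as kappa^(-1/4))
  expect_lt(btheta_from_kappa(1e8), 0.01)
  expect_lt(btheta_from_kappa(1e8), btheta_from_kappa(1e4) / 3)
  expect_error(btheta_from_kappa(0.2), "0.34")  # domain bound named
  expect_error(kappa_from_btheta(2), "radians")
})

test_that("exact bandwidth relation and 1/sqrt(kappa) rule cross near 24 deg", {
  ks <- c(0.5, 1, 2, 5.54, 10, 20, 100)
  exact <- btheta_from_kappa(ks)
  rule <- 1 / sqrt(ks)
  # both strictly decreasing in kappa
  expect_true(all(diff(exact) < 0) && all(diff(rule) < 0))
  # they coincide only around B ~ 24.5 deg (kappa ~ 5.54) ...
  expect_lt(abs(exact[4L] - rule[4L]) / exact[4L], 0.02)
  # ... and separate away from the crossing (rule overestimates below,
  # underestimates above)
  expect_gt(rule[1L], exact[1L])
  expect_lt(rule[6L], exact[6L])
})
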