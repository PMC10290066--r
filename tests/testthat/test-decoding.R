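test_that("windowed counts expose 61 windows and the right class structure", {
  fx <- small_dataset()
  scm <- windowed_counts(fx$ds, "theta", b_theta = 0.5)
  expect_equal(length(scm$onsets), 61L)
  expect_equal(nlevels(scm$labels), 12L)
  expect_equal(nrow(scm$cum), 360L)

  scj <- windowed_counts(fx$ds, "joint", onsets = 0)
  expect_equal(nlevels(scj$labels), 96L)
  expect_equal(nrow(scj$cum), 2880L)

  scb <- windowed_counts(fx$ds, "btheta", onsets = 0)
  expect_equal(nlevels(scb$labels), 8L)
  expect_error(windowed_counts(fx$ds, "speed"), "arg")

  # counts are non-negative integers and additive over sub-windows
  x <- window_counts(scm, 100)
  expect_true(all(x >= 0) && all(x == round(x)))
})

test_that("a silent-baseline neuron contributes an all-zero pre-onset column", {
  pop <- sample_population(2, 0, seed = 13)
  pop$r_base[] <- 0
  ds <- simulate_trials(pop, trial_table(stimulus_grid()[1:4, ], 5L), seed = 14)
  scm <- windowed_counts(ds, "btheta", onsets = c(-150, 100))
  expect_true(all(window_counts(scm, -150) == 0))
})

test_that("softmax of zero coefficients is the uniform distribution", {
  p <- orivar:::softmax(matrix(0, 5, 4))
  expect_equal(p, matrix(0.25, 5, 4))
})

test_that("decoder is perfect on separable data with calibrated probabilities", {
  set.seed(31)
  labs <- factor(rep(c("a", "b", "c"), each = 40))
  x <- 10 * outer(as.integer(labs), 1:3, function(i, j) as.numeric(i == j)) +
    matrix(rnorm(120 * 3, 0, 0.1), 120)
  fit <- fit_decoder(x, labs, seed = 2)
  expect_equal(fit$balanced_accuracy, 1)
  expect_equal(unname(rowSums(fit$test_probs)), rep(1, nrow(fit$test_probs)),
               tolerance = 1e-9)
  ptc <- population_tuning_curve(fit)
  expect_equal(ptc$offset[which.max(ptc$likelihood)], 0)
  expect_equal(sum(ptc$likelihood), 1, tolerance = 1e-9)

  # one trial per class cannot be stratified
  expect_error(fit_decoder(x[c(1, 41, 81), ], labs[c(1, 41, 81)]),
               "fewer than 2")
  expect_error(fit_decoder(x[1:3, ], droplevels(labs[1:3])), "2 classes")
})

test_that("uniform joint posteriors marginalize to uniform orientation posteriors", {
  grid <- stimulus_grid()
  classes <- unique(paste(grid$theta_deg, grid$b_theta_deg, sep = "|"))
  set.seed(5)
  truth <- factor(sample(classes, 50, replace = TRUE), levels = classes)
  fake <- structure(list(
    classes = classes,
    test_probs = matrix(1 / 96, 50, 96, dimnames = list(NULL, classes)),
    test_truth = truth), class = "decoder_fit")
  m <- marginalize_joint(fake)
  expect_equal(unname(m$probs), matrix(1 / 12, 50, 12), tolerance = 1e-12)
  expect_equal(m$balanced_accuracy, 1 / 12, tolerance = 1e-12)
})

test_that("marginalizing a real joint decoder cannot hurt orientation accuracy", {
  fx <- small_dataset()
  scj <- windowed_counts(fx$ds, "joint", onsets = 150)
  fit <- fit_decoder(window_counts(scj, 150), scj$labels, seed = 4)
  m <- marginalize_joint(fit)
  expect_gte(m$balanced_accuracy, fit$balanced_accuracy - 1e-12)
})

test_that("sigmoid time-course fits recover step, flat and noiseless curves", {
  t <- seq(0, 300, by = 10)
  step <- ifelse(t < 150, 0.1, 0.7)
  fs <- fit_timecourse(t, step)
  expect_equal(fs$tau, 150, tolerance = 15)

  flat <- fit_timecourse(t, rep(0.5, length(t)))
  expect_false(flat$converged)

  y <- 0.6 / (1 + exp(-0.05 * (t - 120))) + 0.08
  fy <- fit_timecourse(t, y)
  expect_equal(fy$k, 0.05, tolerance = 0.001)
  expect_equal(fy$tau, 120, tolerance = 2.4)
  expect_equal(fy$max_acc, 0.6, tolerance = 0.012)
})

test_that("windows are fitted independently: onset order permutes outputs only", {
  fx <- small_dataset()
  s1 <- windowed_counts(fx$ds, "theta", b_theta = 0.5, onsets = c(0, 120))
  s2 <- windowed_counts(fx$ds, "theta", b_theta = 0.5, onsets = c(120, 0))
  r1 <- decode_timecourse(s1, seed = 6)
  r2 <- decode_timecourse(s2, seed = 6)
  expect_equal(r1$accuracy, rev(r2$accuracy))
})

test_that("identical groups never reach significance; masks are reproducible", {
  fx <- small_dataset()
  scm <- windowed_counts(fx$ds, "theta", b_theta = 0.5,
                         onsets = seq(60, 90, 10))
  ids <- fx$pop$neuron_id
  gc1 <- group_comparison(scm, ids, ids, n_group = 10, reps = 5, seed = 8)
  expect_false(any(gc1$significant))
  gc2 <- group_comparison(scm, ids, ids, n_group = 10, reps = 5, seed = 8)
  expect_identical(gc1$significant, gc2$significant)
  expect_identical(gc1$accuracy1, gc2$accuracy1)
  expect_error(group_comparison(scm, 1L, ids), "at least 2")
})

test_that("a doubled-rate group is detected over consecutive windows", {
  fx <- small_dataset()
  boosted <- fx$ds
  g1 <- 1:8
  extra <- boosted$events[boosted$events$neuron_id %in% g1, ]
  boosted$events <- rbind(boosted$events, extra)   # 2x spike counts for g1
  # contrast at an intermediate bandwidth, away from the accuracy ceiling
  scm <- windowed_counts(boosted, "theta", b_theta = 20,
                         onsets = seq(50, 110, 10))
  gc <- group_comparison(scm, g1, 9:16, n_group = 12, reps = 10, seed = 9,
                         p_threshold = 0.01)
  expect_true(any(gc$significant))
})

test_that("score-sorted groups are deterministic and sized as requested", {
  fx <- small_dataset()
  scm <- windowed_counts(fx$ds, "theta", b_theta = 0.5, onsets = c(80, 120))
  sc <- stats::setNames(seq(1, 0, length.out = 16), fx$pop$neuron_id)
  out <- score_sorted_decoding(scm, sc, n_group = 10, n_groups = 4, seed = 10)
  expect_equal(length(out$members), 4L)
  expect_true(all(vapply(out$members, length, integer(1L)) == 10L))
  expect_identical(out$members[[1L]], fx$pop$neuron_id[order(-sc)][1:10])
  # most-vulnerable group sits at the top of the ranking, scores decrease
  expect_true(all(diff(out$group_score) <= 0))
  expect_warning(
    score_sorted_decoding(scm, sc, n_group = 15, n_groups = 7, seed = 1),
    "too small")
})

test_that("maximum orientation accuracy declines with input bandwidth", {
  fx <- study_dataset()
  b8 <- unique(fx$ds$trials$b_theta_deg)
  acc <- vapply(b8, function(b) {
    scm <- windowed_counts(fx$ds, "theta", b_theta = b, onsets = c(100, 150))
    max(decode_timecourse(scm, seed = 12)$accuracy)
  }, numeric(1L))
  expect_lt(cor(b8, acc, method = "spearman"), 0)
  expect_gt(acc[1L], 3 / 12)          # well above chance at low bandwidth
})
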