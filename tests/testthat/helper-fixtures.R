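# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small population + spike dataset for module-level tests.
small_dataset <- function() {
  if (is.null(.fixtures$small)) {
    pop <- sample_population(16, resilient_fraction = 0.375, seed = 41L)
    ds <- simulate_trials(pop, seed = 42L)
    .fixtures$small <- list(pop = pop, ds = ds)
  }
  .fixtures$small
}

small_summaries <- function() {
  if (is.null(.fixtures$small_sm)) {
    fx <- small_dataset()
    .fixtures$small_sm <- analyze_tuning(fx$ds)
  }
  .fixtures$small_sm
}

# Study-scale fixture for the acceptance checks: 60 neurons under the default
# generator conditions (resilient fraction 85/249, 15 trials, full grid).
study_dataset <- function() {
  if (is.null(.fixtures$study)) {
    pop <- sample_population(60, seed = 101L)
    ds <- simulate_trials(pop, seed = 102L)
    .fixtures$study <- list(pop = pop, ds = ds)
  }
  .fixtures$study
}

study_summaries <- function() {
  if (is.null(.fixtures$study_sm)) {
    fx <- study_dataset()
    .fixtures$study_sm <- analyze_tuning(fx$ds)
  }
  .fixtures$study_sm
}

# Hand-built neuron summaries with two well-separated archetype blobs.
blob_summaries <- function(n_per = 12L, gap = 4, seed = 7L) {
  set.seed(seed)
  n <- 2L * n_per
  grp <- rep(c(0, 1), each = n_per)
  noise <- function() stats::rnorm(n, 0, 0.3)
  data.frame(
    neuron_id = seq_len(n),
    log_n = 3 + gap * grp + noise(),
    b_theta50 = 30 - 10 * grp + noise(),
    f0 = 0.3 + 0.1 * grp + 0.05 * noise(),
    b_theta_max = 30 - 15 * grp + noise(),
    cv_low = 0.3 + 0.1 * grp + 0.05 * noise(),
    cv_high = 0.9 + 0.02 * noise(),
    el_ratio_low = 0.5 - grp + 0.2 * noise(),
    el_ratio_high = 0.3 - 0.5 * grp + 0.2 * noise(),
    delay_low = 150 + 50 * grp + 10 * noise(),
    delay_high = 200 + 20 * grp + 10 * noise(),
    truth = ifelse(grp == 0, "resilient", "vulnerable"))
}

# Adjusted Rand index between two labelings (mclust is the oracle).
ari <- function(a, b) mclust::adjustedRandIndex(as.character(a), as.character(b))
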