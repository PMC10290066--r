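# End-to-end pipeline: synthetic data -> tuning -> clustering -> decoding ->
# ring model, communicating only through returned objects and file artifacts.

default_pipeline_config <- function() {
  list(
    n_neurons = 60L,
    resilient_fraction = 85 / 249,
    n_trials = 15L,
    decode_onsets = seq(-200, 400, by = 20),
    decode_b = NULL,              # defaults to lowest + highest grid bandwidth
    ring = list(resilient = c(kappa_exc = 3, kappa_inh = 3),
                vulnerable = c(kappa_exc = 6, kappa_inh = 4)),
    ring_n_units = 128L,
    ring_n_b = 10L
  )
}

#' Run the analysis pipeline end to end
#'
#' Executes (any subset of) the stages \code{data} (synthetic population +
#' spike simulation), \code{tuning} (per-neuron summaries), \code{clustering}
#' (archetypes + vulnerability scores), \code{decoding}
#' (bandwidth-specific orientation decoders with sigmoid time-course fits)
#' and \code{ring} (model VTFs for a balanced and an excitation-dominated
#' connectivity), writing CSV/JSON artifacts and a run manifest to
#' \code{outdir}. Identical configuration and seed give byte-identical
#' summary tables.
#'
#' @param outdir output directory (created).
#' @param seed master seed; all stage seeds derive from it.
#' @param stages character vector of stages to run.
#' @param config named list overriding entries of the default configuration
#'   (population size, trial counts, decoding windows, ring settings).
#' @return invisible list with the in-memory stage results.
#' @export
run_pipeline <- function(outdir, seed = 1L,
                         stages = c("data", "tuning", "clustering",
                                    "decoding", "ring"),
                         config = list()) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) message(sprintf("[orivar] %s", sprintf(...)))
  res <- list()

  if ("data" %in% stages) {
    log_line("stage data: %d neurons, %d trials/condition",
             cfg$n_neurons, cfg$n_trials)
    pop <- sample_population(cfg$n_neurons, cfg$resilient_fraction,
                             seed = derive_seed(seed, "pop"))
    ds <- simulate_trials(pop, trial_table(n_trials = cfg$n_trials),
                          seed = derive_seed(seed, "spk"))
    write_spike_dataset(ds, file.path(outdir, "data"))
    res$dataset <- ds
  }
  if ("tuning" %in% stages) {
    if (is.null(res$dataset)) {
      res$dataset <- read_spike_dataset(file.path(outdir, "data"))
    }
    log_line("stage tuning")
    res$summaries <- analyze_tuning(res$dataset)
    write_neuron_summaries(res$summaries,
                           file.path(outdir, "neuron_summaries.csv"))
  }
  if ("clustering" %in% stages) {
    if (is.null(res$summaries)) {
      res$summaries <- utils::read.csv(file.path(outdir, "neuron_summaries.csv"))
    }
    log_line("stage clustering")
    feats <- assemble_features(res$summaries)
    res$clusters <- cluster_archetypes(feats, seed = derive_seed(seed, "km"))
    write_cluster_model(res$clusters, res$summaries, outdir)
  }
  if ("decoding" %in% stages) {
    log_line("stage decoding")
    bs <- cfg$decode_b %||% range(res$dataset$trials$b_theta_deg)
    acc <- lapply(bs, function(b) {
      scm <- windowed_counts(res$dataset, "theta", b_theta = b,
                             onsets = cfg$decode_onsets)
      run <- decode_timecourse(scm, seed = derive_seed(seed, "dec", b))
      sig <- fit_timecourse(run$onsets, run$accuracy)
      list(b = b, run = run, sigmoid = sig)
    })
    tab <- do.call(rbind, lapply(acc, function(a) {
      data.frame(b_theta_deg = a$b, onset_ms = a$run$onsets,
                 balanced_accuracy = a$run$accuracy, chance = a$run$chance)
    }))
    utils::write.csv(tab, file.path(outdir, "decoding_accuracy.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(acc, function(a) list(b_theta_deg = a$b,
                                   tau_ms = a$sigmoid$tau, k = a$sigmoid$k,
                                   max_acc = a$sigmoid$max_acc,
                                   min_acc = a$sigmoid$min_acc)),
      file.path(outdir, "decoding_timecourse.json"),
      auto_unbox = TRUE, digits = NA)
    res$decoding <- acc
  }
  if ("ring" %in% stages) {
    log_line("stage ring: %d units, %d bandwidths", cfg$ring_n_units, cfg$ring_n_b)
    bgrid <- seq(0.5, 35, length.out = cfg$ring_n_b)
    vtfs <- lapply(names(cfg$ring), function(nm) {
      kk <- cfg$ring[[nm]]
      cfgr <- ring_config(n_units = cfg$ring_n_units,
                          kappa_exc = kk[["kappa_exc"]],
                          kappa_inh = kk[["kappa_inh"]])
      mv <- model_vtf(cfgr, b_grid = bgrid)
      data.frame(profile = nm, kappa_exc = kk[["kappa_exc"]],
                 kappa_inh = kk[["kappa_inh"]], b_theta_deg = mv$b_grid,
                 cv = mv$cv, tau_half_ms = mv$tau_half,
                 log_n = if (!is.null(mv$nkr)) mv$nkr$log_n else NA_real_,
                 b_theta50 = if (!is.null(mv$nkr)) mv$nkr$b_theta50 else NA_real_,
                 f0 = if (!is.null(mv$nkr)) mv$nkr$f0 else NA_real_)
    })
    utils::write.csv(do.call(rbind, vtfs), file.path(outdir, "ring_vtf.csv"),
                     row.names = FALSE)
    res$ring <- vtfs
  }

  manifest <- list(
    package = "orivar",
    version = as.character(utils::packageVersion("orivar")),
    seed = seed, stages = stages,
    config_hash = digest_fnv(paste(deparse(cfg), collapse = "")),
    config = cfg[setdiff(names(cfg), "ring")])
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
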