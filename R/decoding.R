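# Sliding-window multinomial logistic population decoding.

#' Sliding-window spike-count matrices
#'
#' Bins every trial's spikes per neuron into 10-ms bins over the recording
#' window and exposes counts for 100-ms windows slid from -200 to +400 ms in
#' 10-ms steps (61 windows; windows reaching past the recording edge are
#' truncated). The decoding task fixes the class labels: \code{"theta"}
#' (12 orientations; trials restricted to one bandwidth so that
#' bandwidth-specific orientation decoders can be trained), \code{"btheta"}
#' (8 bandwidths) or \code{"joint"} (96 orientation x bandwidth classes).
#'
#' @param dataset a \code{\link{simulate_trials}} spike dataset.
#' @param task one of \code{"theta"}, \code{"btheta"}, \code{"joint"}.
#' @param b_theta for the \code{"theta"} task, the bandwidth (degrees) whose
#'   trials are decoded; ignored otherwise.
#' @param neurons optional vector of neuron ids (columns) to keep.
#' @param onsets window onsets in ms.
#' @param width_ms window width.
#' @return object of class \code{spike_count_matrix}: window counts are
#'   materialised lazily via \code{window_counts(x, onset)}.
#' @export
windowed_counts <- function(dataset, task = c("theta", "btheta", "joint"),
                            b_theta = NULL, neurons = NULL,
                            onsets = seq(-200, 400, by = 10), width_ms = 100) {
  task <- match.arg(task)
  trials <- dataset$trials
  if (task == "theta") {
    if (is.null(b_theta)) b_theta <- min(trials$b_theta_deg)
    keep_tr <- trials$b_theta_deg == b_theta
  } else keep_tr <- rep(TRUE, nrow(trials))
  trials <- trials[keep_tr, ]
  labels <- switch(task,
    theta = factor(trials$theta_deg),
    btheta = factor(trials$b_theta_deg),
    joint = factor(paste(trials$theta_deg, trials$b_theta_deg, sep = "|")))

  ids <- neurons %||% sort(unique(dataset$events$neuron_id))
  lo <- dataset$window_ms[1L]; hi <- dataset$window_ms[2L]
  nb <- as.integer((hi - lo) / 10)
  trial_key <- with(trials, paste(stim_id, drift, trial))
  ev <- dataset$events[dataset$events$neuron_id %in% ids, ]
  ev_key <- paste(ev$stim_id, ev$drift, ev$trial)
  row <- match(ev_key, trial_key)
  okev <- !is.na(row)
  col <- match(ev$neuron_id[okev], ids)
  bin <- pmin(floor((ev$t_ms[okev] - lo) / 10) + 1L, nb)

  # cumulative counts over bins: trials x neurons x bins, built from the
  # linearised (trial, neuron, bin) index of every spike
  ntr <- nrow(trials); nne <- length(ids)
  li <- row[okev] + (col - 1L) * ntr + (bin - 1L) * ntr * nne
  cum <- array(tabulate(li, nbins = ntr * nne * nb), dim = c(ntr, nne, nb))
  cum <- aperm(apply(cum, c(1L, 2L), cumsum), c(2L, 3L, 1L))

  structure(list(cum = cum, onsets = onsets, width_ms = width_ms,
                 labels = labels, neuron_ids = ids, trials = trials,
                 task = task, b_theta = b_theta, bin_lo = lo, nb = nb),
            class = "spike_count_matrix")
}

#' @export
print.spike_count_matrix <- function(x, ...) {
  cat(sprintf(
    "Spike-count matrix: task %s (K = %d), %d trials x %d neurons, %d windows of %d ms\n",
    x$task, nlevels(x$labels), nrow(x$cum), length(x$neuron_ids),
    length(x$onsets), x$width_ms))
  invisible(x)
}

#' Spike counts for one window
#'
#' @param scm a \code{\link{windowed_counts}} object.
#' @param onset window onset in ms.
#' @param neurons optional subset of neuron ids.
#' @return integer matrix trials x neurons of counts in [onset, onset + width).
#' @export
window_counts <- function(scm, onset, neurons = NULL) {
  b0 <- as.integer((onset - scm$bin_lo) / 10)       # bins strictly before
  b1 <- min(b0 + as.integer(scm$width_ms / 10), scm$nb)
  b0 <- max(b0, 0L)
  m <- scm$cum[, , b1, drop = FALSE][, , 1L] -
    (if (b0 > 0L) scm$cum[, , b0, drop = FALSE][, , 1L] else 0L)
  cols <- if (is.null(neurons)) seq_along(scm$neuron_ids) else
    match(neurons, scm$neuron_ids)
  m[, cols, drop = FALSE]
}

# Stratified train/test split: indices of test trials.
stratified_test_idx <- function(labels, test_frac, seed) {
  set.seed(seed)
  unlist(lapply(split(seq_along(labels), labels), function(ix) {
    if (length(ix) < 2L) stop("class with fewer than 2 trials; cannot stratify.")
    sample(ix, max(1L, round(test_frac * length(ix))))
  }), use.names = FALSE)
}

balanced_accuracy <- function(truth, predicted) {
  mean(vapply(levels(truth), function(cl) {
    sel <- truth == cl
    if (!any(sel)) return(NA_real_)
    mean(predicted[sel] == cl)
  }, numeric(1L)), na.rm = TRUE)
}

#' Fit a multinomial logistic decoder for one window
#'
#' Softmax regression \eqn{P(y = k | X) \propto \exp\{\langle\beta_k, X\rangle\}}
#' with an l2 penalty, fitted with \code{glmnet} (\code{alpha = 0},
#' \code{lambda = 1/(C n_{train})}, matching the "regularization strength
#' C = 1" convention of the usual scikit-learn parameterisation) on a
#' stratified train/test split. Performance is the balanced accuracy
#' (unweighted mean of per-class recall) on the held-out split.
#'
#' @param x trials x neurons count matrix for one window.
#' @param labels factor of class labels, one per trial.
#' @param C inverse regularization strength.
#' @param test_frac held-out fraction (stratified by class).
#' @param seed split seed.
#' @return object of class \code{decoder_fit}: \code{balanced_accuracy},
#'   \code{coefficients} (neurons x classes), \code{test_probs} (held-out
#'   trials x classes), \code{test_truth}, \code{test_pred}.
#' @export
fit_decoder <- function(x, labels, C = 1, test_frac = 0.15, seed = 1L) {
  stopifnot(nrow(x) == length(labels))
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes.")
  test <- stratified_test_idx(labels, test_frac, seed)
  xtr <- x[-test, , drop = FALSE]; ytr <- labels[-test]
  if (nlevels(droplevels(ytr)) < nlevels(labels)) {
    stop("a class is absent from the training split.")
  }
  lam <- 1 / (C * nrow(xtr))
  # warm-started decreasing path down to the target lambda: a lone small
  # ridge lambda makes the coordinate descent diverge
  lams <- exp(seq(log(lam * 1000), log(lam), length.out = 20L))
  glmnet_converged <- TRUE
  fit <- withCallingHandlers(
    glmnet::glmnet(xtr, ytr, family = "multinomial", alpha = 0,
                   lambda = lams, standardize = FALSE,
                   type.multinomial = "grouped"),
    warning = function(w) {
      if (grepl("Convergence", conditionMessage(w))) {
        glmnet_converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  pr <- predict(fit, newx = x[test, , drop = FALSE], type = "response",
                s = lam)[, , 1L]
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L, dimnames = list(NULL, names(pr)))
  truth <- labels[test]
  pred <- factor(colnames(pr)[max.col(pr, ties.method = "first")],
                 levels = levels(labels))
  beta <- do.call(cbind, lapply(fit$beta, function(b) as.numeric(b[, ncol(b)])))
  dimnames(beta) <- list(colnames(x), levels(labels))
  structure(list(balanced_accuracy = balanced_accuracy(truth, pred),
                 coefficients = beta, intercepts = fit$a0[, ncol(fit$a0)],
                 test_probs = pr[, levels(labels), drop = FALSE],
                 test_truth = truth, test_pred = pred, classes = levels(labels),
                 solver_converged = glmnet_converged),
            class = "decoder_fit")
}

#' Decode across all sliding windows
#'
#' Fits an independent decoder per window (a new stratified split per window,
#' seeded deterministically) and assembles the balanced-accuracy time course.
#'
#' @param scm a \code{\link{windowed_counts}} object.
#' @param neurons optional subset of neuron ids.
#' @param C,test_frac,seed see \code{\link{fit_decoder}}.
#' @param keep_fits keep the per-window \code{decoder_fit} objects.
#' @return object of class \code{decoder_run}: \code{onsets},
#'   \code{accuracy}, \code{chance}, optional \code{fits}.
#' @export
decode_timecourse <- function(scm, neurons = NULL, C = 1, test_frac = 0.15,
                              seed = 1L, keep_fits = FALSE) {
  fits <- lapply(seq_along(scm$onsets), function(i) {
    fit_decoder(window_counts(scm, scm$onsets[i], neurons), scm$labels,
                C = C, test_frac = test_frac,
                seed = derive_seed(seed, "win", scm$onsets[i]))
  })
  acc <- vapply(fits, `[[`, numeric(1L), "balanced_accuracy")
  structure(list(onsets = scm$onsets, accuracy = acc,
                 chance = 1 / nlevels(scm$labels), task = scm$task,
                 b_theta = scm$b_theta,
                 fits = if (keep_fits) fits else NULL),
            class = "decoder_run")
}

#' @export
print.decoder_run <- function(x, ...) {
  cat(sprintf(
    "Decoder run (%s task): max balanced accuracy %.3f (%.1fx chance %.4f) at %d ms\n",
    x$task, max(x$accuracy), max(x$accuracy) / x$chance, x$chance,
    x$onsets[which.max(x$accuracy)]))
  invisible(x)
}

#' @export
plot.decoder_run <- function(x, ...) {
  graphics::plot(x$onsets, x$accuracy, type = "l", lwd = 2,
                 xlab = "window onset (ms)", ylab = "balanced accuracy", ...)
  graphics::abline(h = x$chance, lty = 2, col = "grey50")
  invisible(x)
}

#' Population tuning curve of a fitted decoder
#'
#' Averages the held-out class-probability vectors after re-centering each on
#' its trial's true class, giving the likelihood of decoding every class
#' offset. For orientation tasks the offset axis is circular; the curve's
#' sharpness is summarised by its circular variance.
#'
#' @param fit a \code{\link{fit_decoder}} object for a task with ordered,
#'   evenly spaced classes (theta or btheta).
#' @return list with \code{offset} (class steps), \code{likelihood}, and
#'   \code{sharpness} (circular variance of the curve; \code{NA} when fewer
#'   than 3 classes).
#' @export
population_tuning_curve <- function(fit) {
  k <- length(fit$classes)
  pr <- fit$test_probs
  truth_idx <- match(as.character(fit$test_truth), fit$classes)
  centred <- t(vapply(seq_len(nrow(pr)), function(i) {
    shift <- (seq_len(k) - 1 + (truth_idx[i] - 1) - floor(k / 2)) %% k + 1
    pr[i, shift]
  }, numeric(k)))
  curve <- colMeans(centred)
  offs <- seq_len(k) - 1 - floor(k / 2)
  sharp <- if (k >= 3L) {
    as.numeric(circular_variance(curve, offs * 180 / k))
  } else NA_real_
  list(offset = offs, likelihood = curve, sharpness = sharp)
}

#' Marginalize a joint decoder over bandwidth
#'
#' Collapses the 96-class joint posterior \eqn{P(\theta, B_\theta | X)} to
#' \eqn{P(\theta | X) = \sum_{B_\theta} P(\theta, B_\theta | X)} and scores
#' the orientation prediction against the 1/12 chance level.
#'
#' @param fit a \code{decoder_fit} from the \code{"joint"} task (class labels
#'   of the form \code{"theta|btheta"}).
#' @return list with \code{balanced_accuracy}, \code{probs} (held-out trials
#'   x orientations), \code{truth}.
#' @export
marginalize_joint <- function(fit) {
  parts <- do.call(rbind, strsplit(fit$classes, "|", fixed = TRUE))
  theta_of <- parts[, 1L]
  thetas <- sort(unique(as.numeric(theta_of)))
  pm <- sapply(thetas, function(th) {
    rowSums(fit$test_probs[, theta_of == as.character(th), drop = FALSE])
  })
  colnames(pm) <- thetas
  truth <- factor(sub("\\|.*", "", as.character(fit$test_truth)),
                  levels = as.character(thetas))
  pred <- factor(colnames(pm)[max.col(pm, ties.method = "first")],
                 levels = levels(truth))
  list(balanced_accuracy = balanced_accuracy(truth, pred), probs = pm,
       truth = truth)
}

#' Sigmoid fit of an accuracy time course
#'
#' Least-squares fit of
#' \eqn{\sigma(t) = max_{acc} / (1 + e^{-k (t - \tau)}) + min_{acc}} to the
#' accuracy curve restricted to [0, 300] ms. \eqn{\tau} is the time constant
#' (half-rise time) and \eqn{k} the steepness.
#'
#' @param onsets window onsets (ms).
#' @param accuracy balanced accuracy per window.
#' @return object of class \code{sigmoid_fit}: \code{max_acc},
#'   \code{min_acc}, \code{k}, \code{tau}, \code{converged} (FALSE when the
#'   curve is flat or the fit fails).
#' @export
fit_timecourse <- function(onsets, accuracy) {
  keep <- onsets >= 0 & onsets <= 300
  t <- onsets[keep]; y <- accuracy[keep]
  if (length(t) < 4L || stats::sd(y) < 1e-10) {
    return(structure(list(max_acc = NA_real_, min_acc = min(y),
                          k = NA_real_, tau = NA_real_, converged = FALSE),
                     class = "sigmoid_fit"))
  }
  half <- min(y) + (max(y) - min(y)) / 2
  tau0 <- t[which.min(abs(y - half))]
  start <- list(max_acc = max(y) - min(y), min_acc = min(y),
                k = 0.05, tau = tau0)
  lower <- c(0, -1, 1e-4, -200); upper <- c(2, 1, 1, 600)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ max_acc / (1 + exp(-k * (t - tau))) + min_acc,
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- as.list(stats::coef(fit))
    return(structure(list(max_acc = p$max_acc, min_acc = p$min_acc, k = p$k,
                          tau = p$tau, converged = TRUE),
                     class = "sigmoid_fit"))
  }
  # Levenberg-Marquardt can hit a singular gradient when the curve does not
  # rise inside [0, 300] ms; fall back to bounded quasi-Newton least squares.
  obj <- function(p) sum((p[1L] / (1 + exp(-p[3L] * (t - p[4L]))) + p[2L] - y)^2)
  op <- tryCatch(
    stats::optim(unlist(start), obj, method = "L-BFGS-B",
                 lower = lower, upper = upper),
    error = function(e) NULL)
  if (is.null(op)) {
    return(structure(list(max_acc = NA_real_, min_acc = NA_real_,
                          k = NA_real_, tau = NA_real_, converged = FALSE),
                     class = "sigmoid_fit"))
  }
  structure(list(max_acc = unname(op$par[1L]), min_acc = unname(op$par[2L]),
                 k = unname(op$par[3L]), tau = unname(op$par[4L]),
                 converged = op$convergence == 0),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("Sigmoid time course: tau = %.0f ms, k = %.3f /ms, range [%.3f, %.3f]\n",
              x$tau, x$k, x$min_acc, x$min_acc + x$max_acc))
  invisible(x)
}

#' Compare decoding between two neuron groups
#'
#' Resamples (with replacement) \code{n_group} neurons per group \code{reps}
#' times, decodes each resample across windows, and tests per-window accuracy
#' differences with a paired Wilcoxon signed-rank test across resamples.
#' Significance is only reported for runs of at least
#' \code{min_consecutive} consecutive windows below \code{p_threshold}
#' (20 ms or more at the default window step).
#'
#' @param scm a \code{\link{windowed_counts}} object covering all neurons.
#' @param group1,group2 neuron-id vectors.
#' @param n_group resampled group size.
#' @param reps number of resamples.
#' @param seed integer seed.
#' @param p_threshold per-window significance threshold.
#' @param min_consecutive minimum run length of significant windows.
#' @return list with \code{accuracy1}, \code{accuracy2} (reps x windows),
#'   \code{p_values}, \code{significant} (logical per window, run-filtered).
#' @export
group_comparison <- function(scm, group1, group2, n_group = 100L, reps = 5L,
                             seed = 1L, p_threshold = 0.01,
                             min_consecutive = 2L) {
  if (length(group1) < 2L || length(group2) < 2L) {
    stop("each group needs at least 2 neurons.")
  }
  run_group <- function(ids, tag) {
    t(vapply(seq_len(reps), function(r) {
      set.seed(derive_seed(seed, tag, r))
      pick <- sample(ids, n_group, replace = TRUE)
      cols <- match(pick, scm$neuron_ids)
      vapply(scm$onsets, function(o) {
        x <- window_counts(scm, o)[, cols, drop = FALSE]
        fit_decoder(x, scm$labels, seed = derive_seed(seed, tag, r, o))$balanced_accuracy
      }, numeric(1L))
    }, numeric(length(scm$onsets))))
  }
  a1 <- run_group(group1, "g1")
  a2 <- run_group(group2, "g2")
  pv <- vapply(seq_along(scm$onsets), function(j) {
    d <- a1[, j] - a2[, j]
    if (all(d == 0)) return(1)
    suppressWarnings(stats::wilcox.test(a1[, j], a2[, j], paired = TRUE,
                                        exact = TRUE)$p.value)
  }, numeric(1L))
  sig_raw <- is.finite(pv) & pv < p_threshold
  runs <- rle(sig_raw)
  runs$values <- runs$values & runs$lengths >= min_consecutive
  list(onsets = scm$onsets, accuracy1 = a1, accuracy2 = a2, p_values = pv,
       significant = inverse.rle(runs))
}

#' Score-sorted decoding
#'
#' Ranks neurons by descending vulnerability score, forms \code{n_groups}
#' overlapping groups of \code{n_group} along the ranking (even stride from
#' the most vulnerable to the most resilient end), decodes each group, and
#' relates each group's maximum accuracy to its mean score with a linear
#' regression and a Spearman rank correlation.
#'
#' @param scm a \code{\link{windowed_counts}} object.
#' @param scores vulnerability scores named by neuron id.
#' @param n_group neurons per group.
#' @param n_groups number of overlapping groups.
#' @param seed integer seed for the per-window splits.
#' @return list with \code{group_score}, \code{group_accuracy} (max over
#'   windows), \code{slope}, \code{spearman_rho}, \code{spearman_p},
#'   \code{members}.
#' @export
score_sorted_decoding <- function(scm, scores, n_group = 100L, n_groups = 7L,
                                  seed = 1L) {
  ids <- scm$neuron_ids
  sc <- scores[as.character(ids)]
  ranked <- ids[order(-sc)]
  n <- length(ranked)
  if (n < n_group) stop("fewer neurons than `n_group`.")
  max_groups <- min(n_groups, n - n_group + 1L)
  if (max_groups < n_groups) {
    warning("population too small for ", n_groups, " groups; using ", max_groups)
  }
  starts <- if (max_groups == 1L) 1L else
    round(seq(1L, n - n_group + 1L, length.out = max_groups))
  members <- lapply(starts, function(s) ranked[s:(s + n_group - 1L)])
  res <- t(vapply(seq_along(members), function(g) {
    acc <- vapply(scm$onsets, function(o) {
      x <- window_counts(scm, o, members[[g]])
      fit_decoder(x, scm$labels, seed = derive_seed(seed, "ssd", g, o))$balanced_accuracy
    }, numeric(1L))
    c(score = mean(scores[as.character(members[[g]])]), accuracy = max(acc))
  }, numeric(2L)))
  fit <- stats::lm(res[, "accuracy"] ~ res[, "score"])
  ct <- suppressWarnings(
    stats::cor.test(res[, "score"], res[, "accuracy"], method = "spearman"))
  list(group_score = res[, "score"], group_accuracy = res[, "accuracy"],
       slope = unname(stats::coef(fit)[2L]), spearman_rho = unname(ct$estimate),
       spearman_p = ct$p.value, members = members)
}
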