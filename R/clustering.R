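# Archetype clustering: PCA + K-means over neuron summaries, and the
# continuous vulnerability score.

FEATURE_COLUMNS <- c("log_n", "b_theta50", "f0", "b_theta_max",
                     "cv_low", "cv_high", "el_ratio_low", "el_ratio_high",
                     "delay_low", "delay_high")

#' Assemble the clustering feature matrix
#'
#' Extracts the ten clustering variables from neuron summaries in a fixed,
#' documented column order (VTF parameters, largest significantly tuned
#' bandwidth, circular variances and dynamics features at the lowest and
#' highest bandwidths), imputes flagged-undefined entries with the column
#' median and z-scores every column. A column with more than
#' \code{max_missing} missing entries raises an error; a constant column
#' z-scores to zeros with a warning.
#'
#' @param summaries output of \code{\link{analyze_tuning}} (or a data.frame
#'   with the same columns).
#' @param max_missing maximum tolerated fraction of missing values per column.
#' @return matrix of class \code{feature_matrix} (neurons x 10), z-scored,
#'   with attributes \code{center}, \code{scale} and \code{raw}.
#' @export
assemble_features <- function(summaries, max_missing = 0.2) {
  miss <- vapply(FEATURE_COLUMNS, function(cn) {
    if (!cn %in% names(summaries)) stop("missing summary column: ", cn)
    mean(!is.finite(summaries[[cn]]))
  }, numeric(1L))
  if (any(miss > max_missing)) {
    stop("more than ", round(100 * max_missing), "% missing in column(s): ",
         paste(FEATURE_COLUMNS[miss > max_missing], collapse = ", "))
  }
  raw <- sapply(FEATURE_COLUMNS, function(cn) {
    x <- summaries[[cn]]
    x[!is.finite(x)] <- stats::median(x[is.finite(x)])
    x
  })
  ctr <- colMeans(raw)
  scl <- apply(raw, 2L, stats::sd)
  if (any(scl == 0)) {
    warning("constant feature column(s): ",
            paste(FEATURE_COLUMNS[scl == 0], collapse = ", "))
  }
  z <- sweep(sweep(raw, 2L, ctr), 2L, ifelse(scl > 0, scl, 1), "/")
  rownames(z) <- summaries$neuron_id
  structure(z, center = ctr, scale = scl, raw = raw,
            class = c("feature_matrix", class(z)))
}

#' Cluster the population into two archetypes
#'
#' Projects the z-scored features on their first two principal components and
#' K-means clusters the scores (k-means++-like behaviour approximated by
#' \code{n_start} random restarts under a fixed seed). The cluster whose
#' members have the larger mean \eqn{B_{\theta max}} is labelled
#' \emph{resilient}, the other \emph{vulnerable}. The within-cluster
#' sum-of-squares (WCSS) curve is reported for k = 1..8.
#'
#' @param features a \code{\link{assemble_features}} matrix.
#' @param k number of clusters (the analysis uses 2).
#' @param seed integer seed for the K-means restarts.
#' @param n_start number of K-means restarts.
#' @return object of class \code{cluster_model}: \code{labels} (factor
#'   vulnerable/resilient), \code{pc_scores}, \code{loadings} (PC1/PC2),
#'   \code{explained_var}, \code{centers}, \code{wcss} (k = 1..8) and
#'   \code{score_weights} (see \code{\link{vulnerability_score}}).
#' @export
cluster_archetypes <- function(features, k = 2L, seed = 1L, n_start = 50L) {
  if (nrow(features) < 2L * k) stop("need at least 2k neurons to cluster.")
  if (all(apply(features, 2L, stats::sd) == 0)) {
    stop("degenerate feature matrix: all columns constant.")
  }
  pca <- stats::prcomp(features, center = FALSE, scale. = FALSE)
  scores <- pca$x[, 1:2, drop = FALSE]
  expl <- pca$sdev^2 / sum(pca$sdev^2)

  set.seed(seed)
  km <- stats::kmeans(scores, centers = k, nstart = n_start, iter.max = 100L)
  wcss <- vapply(1:8, function(kk) {
    if (kk >= nrow(features)) return(NA_real_)
    stats::kmeans(scores, centers = kk, nstart = 10L, iter.max = 100L)$tot.withinss
  }, numeric(1L))

  bmax_z <- features[, "b_theta_max"]
  resilient_cluster <- which.max(tapply(bmax_z, km$cluster, mean))
  labels <- factor(ifelse(km$cluster == resilient_cluster,
                          "resilient", "vulnerable"),
                   levels = c("vulnerable", "resilient"))

  loadings <- pca$rotation[, 1:2, drop = FALSE]
  w_all <- rowMeans(abs(loadings))
  score_vars <- c("b_theta50", "log_n", "f0", "b_theta_max",
                  "cv_low", "el_ratio_low", "delay_low")
  w <- w_all[score_vars] / sum(w_all[score_vars])

  structure(list(labels = labels, pc_scores = scores, loadings = loadings,
                 explained_var = expl[1:2], centers = km$centers, wcss = wcss,
                 score_weights = w, k = k, seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("Archetype clustering (k = %d): %d vulnerable, %d resilient\n",
              x$k, tab[["vulnerable"]], tab[["resilient"]]))
  cat(sprintf("  PC1 + PC2 explain %.1f%% of the feature variance\n",
              100 * sum(x$explained_var)))
  invisible(x)
}

#' @export
plot.cluster_model <- function(x, ...) {
  cols <- c(vulnerable = "#c0392b", resilient = "#2980b9")
  graphics::plot(x$pc_scores, col = cols[as.character(x$labels)], pch = 16,
                 xlab = sprintf("PC1 (%.0f%%)", 100 * x$explained_var[1L]),
                 ylab = sprintf("PC2 (%.0f%%)", 100 * x$explained_var[2L]), ...)
  graphics::points(x$centers, pch = 4, cex = 2, lwd = 2)
  invisible(x)
}

#' Continuous vulnerability score
#'
#' Summarises each neuron on a [0, 1] axis from most resilient (0) to most
#' vulnerable (1). Seven variables (\eqn{B_{\theta 50}}, log n, \eqn{f_0},
#' \eqn{B_{\theta max}}, CV, early/late ratio and delay at the lowest
#' bandwidth) are min-max normalised over the population, oriented so that
#' larger means more resilient (\eqn{B_{\theta 50}}, \eqn{B_{\theta max}},
#' early/late ratio and delay enter directly; log n, \eqn{f_0} and CV enter
#' as one minus their normalised value), combined as a weighted sum with
#' weights \eqn{W_i} equal to the normalised mean absolute PC-1/PC-2 loading
#' of the matching feature, subtracted from 1, and affinely rescaled to
#' [0, 1].
#'
#' @param summaries output of \code{\link{analyze_tuning}}.
#' @param model a \code{\link{cluster_archetypes}} model (source of the
#'   weights); alternatively pass \code{weights} directly.
#' @param weights optional named weight vector overriding the model's.
#' @return numeric vector of scores in [0, 1], named by neuron id.
#' @export
vulnerability_score <- function(summaries, model = NULL, weights = NULL) {
  w <- weights %||% model$score_weights
  if (is.null(w)) stop("provide `model` or `weights`.")
  vars <- names(w)
  mm <- sapply(vars, function(cn) {
    x <- summaries[[cn]]
    x[!is.finite(x)] <- stats::median(x[is.finite(x)])
    rng <- range(x)
    if (diff(rng) == 0) rep(0.5, length(x)) else (x - rng[1L]) / diff(rng)
  })
  toward_resilient <- mm
  flip <- intersect(c("log_n", "f0", "cv_low"), vars)
  toward_resilient[, flip] <- 1 - mm[, flip]
  raw <- 1 - as.numeric(toward_resilient %*% w)
  rng <- range(raw)
  out <- if (diff(rng) > 0) (raw - rng[1L]) / diff(rng) else rep(0.5, length(raw))
  stats::setNames(out, summaries$neuron_id)
}

#' Export a cluster model to CSV / JSON
#'
#' Writes labels + PC scores + scores as CSV and loadings/weights as JSON.
#'
#' @param model a \code{cluster_model}.
#' @param summaries the summaries that produced it.
#' @param dir output directory.
#' @export
write_cluster_model <- function(model, summaries, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scores <- vulnerability_score(summaries, model)
  utils::write.csv(
    data.frame(neuron_id = summaries$neuron_id,
               label = as.character(model$labels),
               pc1 = model$pc_scores[, 1L], pc2 = model$pc_scores[, 2L],
               vulnerability = scores),
    file.path(dir, "clusters.csv"), row.names = FALSE)
  utils::write.csv(data.frame(k = 1:8, wcss = model$wcss),
                   file.path(dir, "wcss.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(loadings = as.data.frame(model$loadings),
         explained_var = model$explained_var,
         score_weights = as.list(model$score_weights)),
    file.path(dir, "cluster_model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
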