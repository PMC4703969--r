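#' Run the full unsupervised deconvolution pipeline
#'
#' Chains the stages: gene filtering by signal-intensity quantiles,
#' optional sample-dimension reduction, sum standardization onto the
#' scatter simplex, affinity-propagation aggregation into `n_clusters`
#' representative centers, exhaustive vertex search (at a fixed `k`, or
#' over `k_range` with MDL model selection), marker assignment from the
#' vertex clusters, proportion estimation by standardized marker
#' averaging, and per-gene non-negative least-squares profile recovery.
#'
#' @param expr expression matrix (genes x samples, linear scale).
#' @param k fixed number of subpopulations; if `NULL` (default), K is
#'   selected by MDL over `k_range`.
#' @param k_range candidate K values for model selection (default 2:8;
#'   clipped to `[2, min(J, M)]`).
#' @param n_clusters target number of APC clusters M (default 50).
#' @param filter_low_q,filter_high_q gene-filter quantiles (defaults
#'   0.05 / 0.95); set to 0 / 1 to disable filtering.
#' @param reduction,target_dim sample-dimension reduction mode and size
#'   (default `"none"`).
#' @param norm marker-averaging norm, `"L1"` (default) or `"L2"`.
#' @param damping,max_iter,stable_iter APC controls.
#' @param subset_budget cap on enumerated vertex subsets per K.
#' @param seed recorded in the result for provenance; the pipeline
#'   itself is deterministic.
#' @param verbose emit one timing line per stage.
#' @return a `cam_fit` object: `selected_K`, `mdl` curve, `A_hat`
#'   (proportions), `marker_sets`, `S_hat` + `residual` (profiles, when
#'   `J >= K`), `clusters`, `model`, and the echoed `config`.
#' @export
cam_run <- function(expr, k = NULL, k_range = 2:8, n_clusters = 50,
                    filter_low_q = 0.05, filter_high_q = 0.95,
                    reduction = c("none", "sample_cluster", "pca"),
                    target_dim = NULL, norm = c("L1", "L2"),
                    damping = 0.5, max_iter = 1000L, stable_iter = 10L,
                    subset_budget = 5e6, seed = 1L, verbose = FALSE) {
  reduction <- match.arg(reduction)
  norm <- match.arg(norm)
  expr <- expression_matrix(expr)
  t0 <- proc.time()[[3]]

  filtered <- filter_genes(expr, filter_low_q, filter_high_q)
  stage_log(verbose, "filter", t0,
            nrow(filtered), "of", nrow(expr), "genes kept")

  reduced <- reduce_samples(filtered, reduction, target_dim)
  vectors <- sum_normalize(reduced)
  stage_log(verbose, "normalize", t0, nrow(vectors), "x", ncol(vectors))

  pref <- tune_preference(vectors, n_clusters, damping = damping,
                          max_iter = max_iter, stable_iter = stable_iter)
  clusters <- affinity_propagation(vectors, pref, damping = damping,
                                   max_iter = max_iter,
                                   stable_iter = stable_iter)
  stage_log(verbose, "cluster", t0, nrow(clusters$centers), "clusters")

  M <- nrow(clusters$centers); J <- ncol(clusters$centers)
  if (!is.null(k)) {
    model <- find_vertices(clusters, k, subset_budget = subset_budget)
    m <- compute_mdl(clusters, model)
    mdl <- data.frame(K = as.integer(k),
                      neg_log_likelihood = m$neg_log_likelihood,
                      penalty = m$penalty, total = m$total,
                      selected = TRUE)
    selected_K <- as.integer(k)
  } else {
    sel <- select_model(clusters, k_range, subset_budget = subset_budget)
    model <- sel$model
    mdl <- sel$curve
    selected_K <- sel$selected_K
  }
  stage_log(verbose, "vertices", t0, "K =", selected_K,
            "fit error", signif(model$fit_error, 4))

  marker_sets <- identify_markers(model, clusters)
  A_hat <- estimate_proportions(filtered, marker_sets, norm = norm)
  stage_log(verbose, "proportions", t0, sum(lengths(marker_sets)), "markers")

  S_hat <- NULL; residual <- NULL
  if (ncol(expr) >= selected_K) {
    prof <- estimate_profiles(expr, A_hat)
    S_hat <- prof$S_hat
    residual <- prof$residual
  } else {
    warning("fewer samples than subpopulations; ",
            "profiles not estimated", call. = FALSE)
  }
  stage_log(verbose, "profiles", t0, "done")

  structure(list(selected_K = selected_K,
                 mdl = mdl,
                 A_hat = A_hat,
                 marker_sets = marker_sets,
                 S_hat = S_hat,
                 residual = residual,
                 clusters = clusters,
                 model = model,
                 config = list(k = k, k_range = k_range,
                               n_clusters = n_clusters,
                               filter_low_q = filter_low_q,
                               filter_high_q = filter_high_q,
                               reduction = reduction,
                               target_dim = target_dim, norm = norm,
                               damping = damping,
                               subset_budget = subset_budget,
                               seed = seed)),
            class = "cam_fit")
}

#' @export
print.cam_fit <- function(x, ...) {
  cat(sprintf(paste0("cam_fit: K = %d subpopulations, %d marker genes, ",
                     "%d samples\n"),
              x$selected_K, sum(lengths(x$marker_sets)), nrow(x$A_hat)))
  cat("proportions (A_hat):\n")
  print(round(x$A_hat, 4))
  invisible(x)
}
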