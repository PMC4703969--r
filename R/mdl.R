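#' Description length of a fitted simplex model
#'
#' The data term is an isotropic Gaussian residual model on the M cluster
#' centers: each center is reconstructed by its non-negative projection
#' onto the model simplex (convex hull of the selected vertices), the
#' residual sum of squares gives the plug-in variance, and the negative
#' log-likelihood is \eqn{(MJ/2)(\ln(2\pi\hat\sigma^2) + 1)} nats. The
#' coding penalty charges \eqn{(K-1)J\ln(M)/2} for the mixing matrix
#' ((K-1)J free parameters, each estimated from M centers) plus
#' \eqn{KM\ln(J)/2} for the per-cluster source values (KM parameters,
#' each estimated from J samples). Natural logarithms are used
#' throughout; the argmin over K is base-invariant.
#'
#' @param clusters `cam_clusters` the model was fitted on.
#' @param model `cam_simplex` for one candidate K.
#' @param eps_floor variance floor applied when the model reconstructs
#'   the centers exactly (RSS ~ 0), keeping the total finite.
#' @return list with `neg_log_likelihood`, `penalty`, `total` (nats),
#'   `rss`, and `floor_triggered`.
#' @export
compute_mdl <- function(clusters, model, eps_floor = 1e-12) {
  stopifnot(inherits(clusters, "cam_clusters"),
            inherits(model, "cam_simplex"))
  G <- clusters$centers
  M <- nrow(G); J <- ncol(G); K <- model$K
  V <- G[model$vertex_idx, , drop = FALSE]
  pr <- cpp_hull_project(V, G)
  rss <- sum((G - pr$recon)^2)
  sigma2 <- max(rss / (M * J), eps_floor)
  nll <- (M * J / 2) * (log(2 * pi * sigma2) + 1)
  penalty <- (K - 1) * J * log(M) / 2 + K * M * log(J) / 2
  list(neg_log_likelihood = nll,
       penalty = penalty,
       total = nll + penalty,
       rss = rss,
       floor_triggered = rss / (M * J) < eps_floor)
}

#' Select the number of subpopulations by minimum description length
#'
#' Runs the exhaustive vertex search for each candidate K and scores each
#' fitted model with [compute_mdl()]; the K minimizing the total
#' description length is selected (ties within 1e-12 go to the smaller
#' K, the more parsimonious model).
#'
#' @param clusters `cam_clusters` object.
#' @param k_range integer vector of candidate K values, within
#'   `[2, min(J, M)]`.
#' @param subset_budget per-K cap on enumerated subsets, as in
#'   [find_vertices()].
#' @return list with `curve` (data.frame: K, neg_log_likelihood, penalty,
#'   total, selected), `selected_K`, and `model` (the winning
#'   `cam_simplex`).
#' @export
select_model <- function(clusters, k_range, subset_budget = 5e6) {
  stopifnot(inherits(clusters, "cam_clusters"))
  M <- nrow(clusters$centers); J <- ncol(clusters$centers)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2L & k_range <= min(J, M)]
  if (length(k_range) == 0L)
    stop("empty feasible K range (need 2 <= K <= min(J, M) = ",
         min(J, M), ")", call. = FALSE)
  models <- vector("list", length(k_range))
  rows <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    fit_k <- tryCatch(
      find_vertices(clusters, K, subset_budget = subset_budget),
      error = function(e) {
        if (grepl("no rank", conditionMessage(e))) {
          warning("K = ", K, " exceeds the affine rank of the cluster ",
                  "centers; skipped", call. = FALSE)
          NULL
        } else stop(e)
      })
    if (is.null(fit_k)) next
    models[[i]] <- fit_k
    m <- compute_mdl(clusters, models[[i]])
    rows[[i]] <- data.frame(K = K,
                            neg_log_likelihood = m$neg_log_likelihood,
                            penalty = m$penalty,
                            total = m$total)
  }
  keep <- !vapply(rows, is.null, logical(1L))
  if (!any(keep))
    stop("no candidate K admits a full-rank vertex subset", call. = FALSE)
  k_range <- k_range[keep]
  models <- models[keep]
  curve <- do.call(rbind, rows[keep])
  best_i <- which(curve$total <= min(curve$total) + 1e-12)[1L]
  curve$selected <- seq_len(nrow(curve)) == best_i
  list(curve = curve,
       selected_K = k_range[best_i],
       model = models[[best_i]])
}
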