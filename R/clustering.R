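# Collapse duplicate gene vectors (within ~9 significant digits, so rows
# identical up to float round-off merge) to single weighted points.
dedup_vectors <- function(vectors) {
  keyed <- signif(vectors, 9)
  key <- do.call(paste, c(as.data.frame(keyed), sep = "\r"))
  rep_idx <- which(!duplicated(key))
  grp <- match(key, key[rep_idx])
  list(U = vectors[rep_idx, , drop = FALSE],
       grp = grp,
       rep_idx = rep_idx,
       counts = tabulate(grp, nbins = length(rep_idx)))
}

#' Aggregate gene vectors by affinity propagation
#'
#' Sum-standardized gene vectors are clustered by affinity propagation
#' (APC) with negative squared Euclidean similarity, reducing thousands of
#' genes to a manageable set of representative cluster centers for the
#' vertex search. APC needs no random initialization, so the result is
#' deterministic given the input order. Exactly duplicated gene vectors
#' (common in noise-free data, where all markers of one subpopulation
#' collapse onto the same vertex) are collapsed to a single point before
#' message passing — duplicated points create exactly symmetric messages
#' that oscillate at damping 0.5 — and re-expanded afterwards. If message
#' passing still fails to converge, the run is retried at damping 0.7 and
#' 0.9 before returning the current assignment with a warning.
#'
#' @param vectors matrix of gene vectors (rows on the unit simplex), e.g.
#'   from [sum_normalize()].
#' @param preference exemplar preference (diagonal similarity); more
#'   negative values give fewer clusters. See [tune_preference()].
#' @param damping message damping factor in `[0.5, 1)`; default 0.5.
#' @param max_iter maximum message-passing iterations (default 1000).
#' @param stable_iter stop once the exemplar set is unchanged for this
#'   many consecutive iterations (default 10).
#' @param oscillation_cap iterations granted to the first attempt before
#'   an oscillating run is restarted at damping 0.9 (default 250).
#' @return a `cam_clusters` object: `centers` (M x samples, rows
#'   re-normalized to unit sum), `exemplar_ids`, `membership` (gene ->
#'   cluster index), `sizes`, `converged`.
#' @export
affinity_propagation <- function(vectors, preference, damping = 0.5,
                                 max_iter = 1000L, stable_iter = 10L,
                                 oscillation_cap = 250L) {
  if (damping < 0.5 || damping >= 1)
    stop("`damping` must be in [0.5, 1)", call. = FALSE)
  stopifnot(is.matrix(vectors), nrow(vectors) >= 1L)
  if (is.null(rownames(vectors)))
    rownames(vectors) <- paste0("g", seq_len(nrow(vectors)))

  dd <- dedup_vectors(vectors)
  U <- dd$U; grp <- dd$grp; counts <- dd$counts

  if (nrow(U) == 1L) {
    assign_u <- rep(1L, 1L)
    exemplars_u <- 1L
    converged <- TRUE
  } else {
    # a collapsed point standing for c genes shares the exemplar penalty
    # among its members, hence preference / c
    pref_vec <- preference / counts
    res <- cpp_apc(U, pref_vec, damping,
                   as.integer(min(max_iter, oscillation_cap)),
                   as.integer(stable_iter))
    if (!res$converged && damping < 0.9) {
      res <- cpp_apc(U, pref_vec, 0.9, as.integer(max_iter),
                     as.integer(stable_iter))
    }
    converged <- res$converged
    if (!converged)
      warning("affinity propagation did not converge; ",
              "returning current assignment", call. = FALSE)
    assign_u <- res$assignment
    exemplars_u <- res$exemplars
  }

  membership <- assign_u[grp]
  names(membership) <- rownames(vectors)
  M <- length(exemplars_u)
  sizes <- tabulate(membership, nbins = M)
  centers <- rowsum(vectors, membership) / sizes
  centers <- centers / rowSums(centers)
  rownames(centers) <- paste0("c", seq_len(M))
  structure(list(centers = centers,
                 exemplar_ids = rownames(vectors)[dd$rep_idx[exemplars_u]],
                 membership = membership,
                 sizes = sizes,
                 preference = preference,
                 damping = damping,
                 converged = converged),
            class = "cam_clusters")
}

#' @export
print.cam_clusters <- function(x, ...) {
  cat(sprintf("cam_clusters: %d clusters over %d genes (%d samples)%s\n",
              nrow(x$centers), length(x$membership), ncol(x$centers),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Tune the APC preference toward a target cluster count
#'
#' Affinity propagation does not take a cluster count directly; the
#' preference controls it monotonically (more negative, fewer clusters).
#' This bisects the preference (on the log scale of its magnitude, since
#' the cluster count responds roughly as a power law) until the resulting
#' number of clusters is within 10% of `target_M`, the bracket collapses
#' (the achievable counts jump across the target), or 25 steps have
#' elapsed, returning the best preference found. Probes run from cold
#' starts at damping 0.9, where message passing converges quickly
#' regardless of near-duplicate structure, so the count reported for the
#' returned preference is reproduced by an independent APC run at that
#' preference.
#'
#' @param vectors gene-vector matrix as in [affinity_propagation()].
#' @param target_M desired number of clusters (2 to gene count).
#' @param damping accepted for interface symmetry; probes use 0.9.
#' @param max_iter,stable_iter passed to the APC probes.
#' @return the chosen preference (numeric scalar) with attribute
#'   `achieved_M`, the cluster count it produced.
#' @export
tune_preference <- function(vectors, target_M, damping = 0.5,
                            max_iter = 1000L, stable_iter = 10L) {
  stopifnot(is.matrix(vectors))
  N <- nrow(vectors)
  if (target_M < 2 || target_M > N)
    stop("`target_M` must be in [2, ", N, "]", call. = FALSE)

  dd <- dedup_vectors(vectors)
  U <- dd$U
  Nu <- nrow(U)
  if (target_M >= Nu) {
    # every unique point its own exemplar: preference above all similarities
    return(structure(0, achieved_M = Nu))
  }

  sub <- U[seq(1L, Nu, length.out = min(Nu, 300L)), , drop = FALSE]
  d2 <- as.matrix(dist(sub))^2
  med <- stats::median(-d2[upper.tri(d2)])
  if (!is.finite(med) || med == 0) med <- -1e-6

  probe_iter <- as.integer(min(max_iter, 400L))
  count_at <- function(p) {
    res <- cpp_apc(U, p / dd$counts, 0.9, probe_iter,
                   as.integer(stable_iter))
    length(res$exemplars)
  }

  lo <- 20 * med   # strongly negative: few clusters
  hi <- med / 50   # mildly negative: many clusters
  for (i in 1:6) {  # widen the bracket if needed
    if (count_at(lo) <= target_M * 1.1) break
    lo <- lo * 10
  }
  best_p <- lo; best_m <- NA_integer_; best_gap <- Inf
  l_lo <- log(-lo); l_hi <- log(-hi)
  for (step in 1:25) {
    p <- -exp((l_lo + l_hi) / 2)
    m <- count_at(p)
    if (abs(m - target_M) < best_gap) {
      best_gap <- abs(m - target_M); best_p <- p; best_m <- m
    }
    if (abs(m - target_M) <= 0.1 * target_M)
      return(structure(p, achieved_M = m))
    if (m > target_M) l_hi <- log(-p) else l_lo <- log(-p)
    if (abs(l_lo - l_hi) < 0.05) break  # counts jump across the target
  }
  if (is.na(best_m) || abs(best_m - target_M) > 0.25 * target_M)
    warning("preference tuning did not reach the target cluster count; ",
            "returning best found (", best_m, " clusters)", call. = FALSE)
  structure(best_p, achieved_M = best_m)
}
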