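#' Margin-of-error of a point with respect to candidate vertices
#'
#' The margin-of-error is the Euclidean distance from a sum-standardized
#' vector to the convex hull of a candidate vertex set: the minimum of
#' \eqn{\|g - \sum_k \alpha_k v_k\|_2} over \eqn{\alpha_k \ge 0,
#' \sum_k \alpha_k = 1}. It is zero (up to 1e-9) exactly when `g` lies
#' inside the hull, and it is the fitting criterion the vertex search
#' minimizes over the "exterior" cluster centers.
#'
#' @param g numeric vector on the unit simplex.
#' @param vertices matrix with one candidate vertex per row (unit-sum
#'   rows), or a single vector.
#' @return non-negative scalar distance.
#' @export
margin_of_error <- function(g, vertices) {
  if (is.vector(vertices)) vertices <- matrix(vertices, nrow = 1L)
  if (length(g) != ncol(vertices))
    stop("dimension mismatch: point has length ", length(g),
         ", vertices have ", ncol(vertices), call. = FALSE)
  cpp_hull_project(vertices, matrix(g, nrow = 1L))$margin[1L]
}

#' Locate the K scatter-simplex vertices among cluster centers
#'
#' Enumerates every subset of K cluster centers (all `choose(M, K)`
#' combinations) and scores it by the summed margin-of-error of the
#' remaining M - K exterior centers; the minimizing subset is the vertex
#' set. Subsets whose center matrix is numerically rank-deficient cannot
#' define a K-vertex simplex and are skipped. Ties within 1e-12 resolve
#' to the lexicographically smallest index set, making the search
#' deterministic.
#'
#' The mixing-matrix estimate stacks the selected centers as columns and
#' applies the rescaling that makes the rows (per-sample proportions) sum
#' to one: since each center estimates a mixing column up to a positive
#' scale, per-column scales are recovered by non-negative least squares
#' against the all-ones vector, followed by an exact row renormalization.
#'
#' @param clusters a `cam_clusters` object.
#' @param K number of vertices (subpopulations), `2 <= K <= M`.
#' @param subset_budget maximum number of subsets that may be enumerated
#'   (default 5e6); exceeding it is an error suggesting a smaller M or K.
#' @param rank_tol Cholesky pivot tolerance for the rank screen.
#' @return a `cam_simplex` object: `K`, `vertex_idx` (cluster indices),
#'   `A` (samples x K mixing-proportion estimate, rows summing to 1),
#'   `fit_error` (minimal exterior margin sum).
#' @export
find_vertices <- function(clusters, K, subset_budget = 5e6,
                          rank_tol = 1e-8) {
  stopifnot(inherits(clusters, "cam_clusters"))
  M <- nrow(clusters$centers)
  K <- as.integer(K)
  if (K < 1L || K > M)
    stop("`K` must be in [1, ", M, "]", call. = FALSE)
  n_subsets <- choose(M, K)
  if (n_subsets > subset_budget)
    stop(sprintf(paste0("exhaustive search over C(%d, %d) = %.3g subsets ",
                        "exceeds the budget of %.3g; lower the number of ",
                        "clusters M or K, or raise `subset_budget`"),
                 M, K, n_subsets, subset_budget), call. = FALSE)
  res <- cpp_find_vertices(clusters$centers, K, rank_tol)
  if (length(res$vertex_idx) == 0L)
    stop("no rank-", K, " vertex subset found among the cluster centers",
         call. = FALSE)
  vidx <- as.integer(res$vertex_idx)
  A <- estimate_mixing_from_vertices(t(clusters$centers[vidx, , drop = FALSE]))
  colnames(A) <- paste0("subpop", seq_len(K))
  rownames(A) <- colnames(clusters$centers)
  structure(list(K = K,
                 vertex_idx = vidx,
                 A = A,
                 fit_error = res$fit_error,
                 n_evaluated = res$n_evaluated,
                 n_rank_skipped = res$n_rank_skipped),
            class = "cam_simplex")
}

#' @export
print.cam_simplex <- function(x, ...) {
  cat(sprintf("cam_simplex: K = %d, vertex clusters {%s}, fit error %.6g\n",
              x$K, paste(x$vertex_idx, collapse = ", "), x$fit_error))
  invisible(x)
}

# Columns of C estimate mixing columns up to positive scale. Solve for the
# scales c >= 0 that best satisfy (C diag(c)) 1 = 1 (rows are proportions),
# then renormalize rows exactly. Exact on noise-free data.
estimate_mixing_from_vertices <- function(C) {
  scales <- drop(cpp_nnls(C, matrix(1, nrow(C), 1L)))
  if (all(scales == 0)) scales <- rep(1, ncol(C))
  scales[scales == 0] <- min(scales[scales > 0])
  A <- C * rep(scales, each = nrow(C))
  A / rowSums(A)
}

#' Assign marker genes from vertex clusters
#'
#' Genes belonging to a cluster whose center is a selected simplex vertex
#' are the subpopulation-specific marker genes for that vertex; genes in
#' interior clusters are co-expressed and contribute no markers.
#'
#' @param model a `cam_simplex` from [find_vertices()].
#' @param clusters the `cam_clusters` the model was fitted on.
#' @return named list (one element per subpopulation) of marker gene ids.
#' @export
identify_markers <- function(model, clusters) {
  stopifnot(inherits(model, "cam_simplex"),
            inherits(clusters, "cam_clusters"))
  if (any(model$vertex_idx > nrow(clusters$centers)))
    stop("model vertex indices do not match the cluster set", call. = FALSE)
  out <- lapply(model$vertex_idx, function(m)
    names(clusters$membership)[clusters$membership == m])
  names(out) <- colnames(model$A)
  out
}
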