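#' Estimate constituent proportions from marker-gene expressions
#'
#' Each marker gene's raw expression vector across samples, once
#' normalized, estimates its subpopulation's mixing column up to scale;
#' standardized averaging over the markers of each subpopulation gives
#' the column estimate \eqn{\hat a_k = (1/n_k)\sum_{i \in MG_k}
#' x(i)/\|x(i)\|}. Columns are then rescaled so that each sample's
#' proportions sum to one (per-column scales solved by non-negative
#' least squares, then exact row renormalization).
#'
#' @param expr raw (linear-scale) expression matrix containing the
#'   marker genes.
#' @param marker_sets named list mapping each subpopulation to its marker
#'   gene ids; all sets must be non-empty.
#' @param norm `"L1"` (default; marker vectors then live on the same
#'   unit-sum simplex as the proportions) or `"L2"`.
#' @return mixing-proportion matrix (samples x subpopulations), rows
#'   summing to 1.
#' @export
estimate_proportions <- function(expr, marker_sets, norm = c("L1", "L2")) {
  norm <- match.arg(norm)
  stopifnot(is.list(marker_sets), length(marker_sets) >= 1L)
  if (is.null(names(marker_sets)))
    names(marker_sets) <- paste0("subpop", seq_along(marker_sets))
  empty <- lengths(marker_sets) == 0L
  if (any(empty))
    stop("empty marker set for subpopulation: ",
         paste(names(marker_sets)[empty], collapse = ", "), call. = FALSE)
  missing <- setdiff(unlist(marker_sets), rownames(expr))
  if (length(missing))
    stop("marker genes absent from the expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)

  cols <- vapply(marker_sets, function(genes) {
    X <- expr[genes, , drop = FALSE]
    nrm <- if (norm == "L1") rowSums(abs(X)) else sqrt(rowSums(X^2))
    if (any(nrm == 0))
      stop("marker gene with all-zero expression: ",
           genes[which(nrm == 0)[1L]], call. = FALSE)
    colMeans(X / nrm)
  }, numeric(ncol(expr)))
  A <- estimate_mixing_from_vertices(cols)
  dimnames(A) <- list(colnames(expr), names(marker_sets))
  A
}

#' Recover subpopulation-specific profiles by non-negative least squares
#'
#' Given the mixing proportions, each gene's profile across
#' subpopulations is the solution of an independent non-negative least
#' squares problem \eqn{\min_{s \ge 0} \|x(i) - A s\|_2^2} on the raw
#' expression scale, so the recovered profiles keep interpretable
#' intensity units. With fewer samples than subpopulations the per-gene
#' systems are underdetermined and profile estimation is refused.
#'
#' @param expr raw expression matrix (genes x samples).
#' @param A_hat mixing-proportion matrix (samples x K), full column rank.
#' @return list with `S_hat` (genes x K non-negative profiles) and
#'   `residual` (per-gene Euclidean residual norms).
#' @export
estimate_profiles <- function(expr, A_hat) {
  stopifnot(is.matrix(A_hat))
  J <- nrow(A_hat); K <- ncol(A_hat)
  if (ncol(expr) != J)
    stop("sample dimension mismatch between `expr` and `A_hat`",
         call. = FALSE)
  if (J < K)
    stop("underdetermined system: ", J, " samples < ", K,
         " subpopulations; profiles cannot be estimated", call. = FALSE)
  if (qr(A_hat)$rank < K)
    stop("`A_hat` is rank deficient", call. = FALSE)
  S <- t(cpp_nnls(A_hat, t(expr)))
  dimnames(S) <- list(rownames(expr), colnames(A_hat))
  resid <- sqrt(rowSums((expr - S %*% t(A_hat))^2))
  list(S_hat = S, residual = resid)
}

#' Profile recovery with externally supplied proportions
#'
#' The known-composition supervised baseline: identical to
#' [estimate_profiles()] but with proportions provided from outside
#' (e.g. measured compositions), used for comparisons against the
#' unsupervised estimates.
#'
#' @inheritParams estimate_profiles
#' @param A_known externally supplied proportion matrix (samples x K).
#' @return as [estimate_profiles()].
#' @export
supervised_profiles_baseline <- function(expr, A_known) {
  estimate_profiles(expr, A_known)
}
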