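#' Filter unreliable genes by signal-intensity quantiles
#'
#' Genes whose overall signal intensity (row-vector norm) is very low are
#' noise-dominated, and genes with extreme intensity are outliers; both
#' degrade the simplex geometry. The norm distribution over all genes is
#' cut at the `low_q` and `high_q` quantiles and only genes strictly
#' inside the band are kept (row order preserved).
#'
#' @param expr expression matrix (genes x samples).
#' @param low_q,high_q quantile fractions in `[0, 1]`, `low_q < high_q`.
#'   Defaults 0.05 and 0.95.
#' @param norm `"L2"` (default) or `"L1"` row norm as the intensity
#'   measure.
#' @return the surviving submatrix.
#' @export
filter_genes <- function(expr, low_q = 0.05, high_q = 0.95,
                         norm = c("L2", "L1")) {
  norm <- match.arg(norm)
  stopifnot(low_q >= 0, high_q <= 1)
  if (!(low_q < high_q))
    stop("`low_q` must be smaller than `high_q`", call. = FALSE)
  nrm <- if (norm == "L2") sqrt(rowSums(expr^2)) else rowSums(abs(expr))
  cuts <- quantile(nrm, c(low_q, high_q), names = FALSE)
  keep <- nrm >= cuts[1L] & nrm <= cuts[2L]
  if (!any(keep)) stop("empty matrix after filtering", call. = FALSE)
  expr[keep, , drop = FALSE]
}

#' Sum-standardize gene vectors onto the scatter simplex
#'
#' Each gene's expression vector across samples is divided by its sum, so
#' all genes lie on the unit simplex in sample space; the simplex vertices
#' then correspond to the normalized mixing-matrix columns. Genes with a
#' zero row sum carry no information and are dropped (with a message).
#'
#' @param expr non-negative expression matrix.
#' @return matrix of gene vectors, one row per retained gene, each row
#'   summing to 1.
#' @export
sum_normalize <- function(expr) {
  rs <- rowSums(expr)
  zero <- rs == 0
  if (any(zero)) {
    message("dropping ", sum(zero), " zero-sum gene(s): ",
            paste(utils::head(rownames(expr)[zero], 5L), collapse = ", "),
            if (sum(zero) > 5L) ", ..." else "")
    expr <- expr[!zero, , drop = FALSE]
    rs <- rs[!zero]
  }
  expr / rs
}

#' Reduce the sample dimension of an expression matrix
#'
#' With many more samples than expected subpopulations, the vertex search
#' benefits from a lower-dimensional sample space. `sample_cluster` groups
#' samples (columns) by Ward hierarchical clustering and replaces each
#' group with its mean column, which preserves non-negativity and is the
#' recommended mode (replicate averaging). `pca` projects onto the top
#' components and clamps negative loadings to zero with a warning, since
#' convex analysis requires non-negative data.
#'
#' @param expr expression matrix (genes x samples).
#' @param mode `"none"`, `"sample_cluster"` or `"pca"`.
#' @param target_dim number of output columns (`>= 2`, `<=` sample count).
#' @return reduced expression matrix.
#' @export
reduce_samples <- function(expr, mode = c("none", "sample_cluster", "pca"),
                           target_dim = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(expr)
  J <- ncol(expr)
  if (is.null(target_dim)) stop("`target_dim` is required", call. = FALSE)
  if (target_dim < 2 || target_dim > J)
    stop("`target_dim` must be in [2, ", J, "]", call. = FALSE)
  if (mode == "sample_cluster") {
    hc <- hclust(dist(t(expr)), method = "ward.D2")
    grp <- cutree(hc, k = target_dim)
    out <- vapply(seq_len(target_dim),
                  function(g) rowMeans(expr[, grp == g, drop = FALSE]),
                  numeric(nrow(expr)))
    colnames(out) <- vapply(seq_len(target_dim), function(g)
      paste(colnames(expr)[grp == g], collapse = "+"), "")
    rownames(out) <- rownames(expr)
    out
  } else {
    pc <- prcomp(expr, center = FALSE, scale. = FALSE)
    out <- pc$x[, seq_len(target_dim), drop = FALSE]
    nneg <- sum(out < 0)
    if (nneg > 0)
      warning(nneg, " negative PCA loadings clamped to 0; ",
              "'sample_cluster' preserves non-negativity", call. = FALSE)
    out[out < 0] <- 0
    colnames(out) <- paste0("PC", seq_len(target_dim))
    rownames(out) <- rownames(expr)
    out
  }
}
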