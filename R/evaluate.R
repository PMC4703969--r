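#' Cross-talk (E1) criterion between estimated and true mixing matrices
#'
#' Computes \eqn{P = A_{est}^{+} A_{true}} (Moore-Penrose pseudo-inverse)
#' and sums, over rows and over columns of P, the absolute off-dominance
#' \eqn{\sum |p| / \max |p| - 1}. The index is invariant to column
#' permutation and positive column rescaling of the estimate and equals
#' zero exactly when the estimation is perfect up to those ambiguities.
#'
#' @param A_hat estimated mixing matrix (samples x K), full column rank.
#' @param A_true true mixing matrix of the same shape.
#' @return non-negative scalar; 0 means perfect recovery.
#' @export
compute_e1 <- function(A_hat, A_true) {
  stopifnot(is.matrix(A_hat), is.matrix(A_true))
  if (!all(dim(A_hat) == dim(A_true)))
    stop("`A_hat` and `A_true` must have the same shape", call. = FALSE)
  if (qr(A_hat)$rank < ncol(A_hat))
    stop("`A_hat` is rank deficient", call. = FALSE)
  P <- abs(MASS::ginv(A_hat) %*% A_true)
  row_term <- sum(rowSums(P) / apply(P, 1L, max) - 1)
  col_term <- sum(colSums(P) / apply(P, 2L, max) - 1)
  row_term + col_term
}

#' Sensitivity, specificity and Venn counts of detected marker genes
#'
#' Detected and ground-truth marker sets are first aligned by the label
#' permutation maximizing total overlap (exact enumeration), then pooled:
#' a detected gene counts as a true positive only if it is a marker of
#' the matched subpopulation. Specificity is computed over the non-marker
#' part of the gene universe.
#'
#' @param predicted named list of detected marker sets.
#' @param truth named list of ground-truth marker sets (non-empty).
#' @param universe character vector of all gene ids under consideration.
#' @return list with `sensitivity`, `specificity` and `venn_counts`
#'   (`both`, `cam_only`, `truth_only`).
#' @export
marker_confusion <- function(predicted, truth, universe) {
  stopifnot(is.list(predicted), is.list(truth))
  if (sum(lengths(truth)) == 0L)
    stop("ground-truth marker sets are empty", call. = FALSE)
  K <- length(truth)
  if (length(predicted) != K)
    stop("`predicted` and `truth` must have the same number of ",
         "subpopulations", call. = FALSE)
  perm <- align_subpopulations(predicted, truth, by = "overlap")
  pred <- predicted[perm]
  tp <- sum(vapply(seq_len(K), function(k)
    length(intersect(pred[[k]], truth[[k]])), 0L))
  n_truth <- sum(lengths(truth))
  n_pred <- sum(lengths(pred))
  truth_union <- unique(unlist(truth))
  pred_union <- unique(unlist(pred))
  negatives <- setdiff(universe, truth_union)
  tn <- length(setdiff(negatives, pred_union))
  list(sensitivity = tp / n_truth,
       specificity = if (length(negatives)) tn / length(negatives) else 1,
       venn_counts = c(both = tp,
                       cam_only = n_pred - tp,
                       truth_only = n_truth - tp))
}

#' One-versus-everyone fold-change markers from pure profiles
#'
#' The gold-standard construction for evaluating unsupervised marker
#' detection: gene i is a marker of subpopulation k when its pure
#' expression there is at least `fc_threshold` times its maximum
#' expression in every other subpopulation (and positive).
#'
#' @param pure_profiles non-negative genes x K profile matrix.
#' @param fc_threshold fold-change threshold > 1 (default 2).
#' @return named list of marker gene ids per subpopulation.
#' @export
fold_change_markers <- function(pure_profiles, fc_threshold = 2) {
  stopifnot(is.matrix(pure_profiles), ncol(pure_profiles) >= 2L,
            fc_threshold > 1)
  S <- pure_profiles
  if (is.null(rownames(S))) rownames(S) <- paste0("g", seq_len(nrow(S)))
  if (is.null(colnames(S))) colnames(S) <- paste0("subpop", seq_len(ncol(S)))
  top_k <- max.col(S, ties.method = "first")
  top_v <- S[cbind(seq_len(nrow(S)), top_k)]
  second <- vapply(seq_len(nrow(S)),
                   function(i) max(S[i, -top_k[i]]), numeric(1L))
  is_marker <- top_v > 0 & top_v >= fc_threshold * second &
    rowSums(S == top_v) == 1L  # a tied maximum is never exclusive
  out <- lapply(seq_len(ncol(S)), function(k)
    rownames(S)[is_marker & top_k == k])
  names(out) <- colnames(S)
  out
}

#' Randomly perturb a proportion matrix
#'
#' Adds independent uniform noise in `[-magnitude, magnitude]` to every
#' entry, clamps at zero and renormalizes rows to unit sum. Used for the
#' stability analysis of supervised deconvolution under inaccurate
#' composition priors.
#'
#' @param A proportion matrix (rows sum to 1).
#' @param magnitude perturbation half-width in `[0, 0.5]`.
#' @param seed RNG seed (reproducible).
#' @return perturbed proportion matrix.
#' @export
perturb_proportions <- function(A, magnitude, seed) {
  stopifnot(magnitude >= 0, magnitude <= 0.5)
  if (magnitude == 0) return(A)
  with_seed(seed, {
    P <- A + matrix(runif(length(A), -magnitude, magnitude),
                    nrow(A), ncol(A))
    P[P < 0] <- 0
    zero <- rowSums(P) == 0
    P[zero, ] <- 1 / ncol(P)
    P / rowSums(P)
  })
}

#' Randomly perturb reference signatures
#'
#' Multiplies every entry by `1 + u` with `u` uniform in `[-pct, pct]`,
#' clamping at zero. Used for the stability analysis of supervised
#' deconvolution under inaccurate reference signatures.
#'
#' @param S signature/profile matrix (non-negative).
#' @param pct relative perturbation fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return perturbed matrix.
#' @export
perturb_signatures <- function(S, pct, seed) {
  stopifnot(pct >= 0, pct <= 1)
  if (pct == 0) return(S)
  with_seed(seed, {
    out <- S * (1 + matrix(runif(length(S), -pct, pct), nrow(S), ncol(S)))
    out[out < 0] <- 0
    out
  })
}

#' Score a deconvolution result against ground truth
#'
#' Aligns estimated subpopulations to the truth (permutation maximizing
#' mixing-column correlation) and reports the complementary criteria:
#' the E1 cross-talk index and pooled Pearson correlation for the
#' proportions, per-subpopulation profile correlations over marker genes
#' and over all genes (the latter is inflated by co-expression and
#' reported only for contrast), and marker sensitivity/specificity with
#' Venn counts.
#'
#' @param A_hat,S_hat estimated proportions (samples x K) and profiles
#'   (genes x K); `S_hat` may be `NULL`.
#' @param marker_sets detected marker sets (named list), or `NULL`.
#' @param truth list with elements `A_true`, `S_true`, `marker_truth` (as
#'   produced by [simulate_mixture()]).
#' @param universe gene universe for specificity; defaults to the rows of
#'   `truth$S_true`.
#' @return list of criteria (`e1`, `pearson_proportions`,
#'   `pearson_profiles_markers`, `pearson_profiles_all`,
#'   `marker_sensitivity`, `marker_specificity`, `venn_counts`).
#' @export
evaluate_deconvolution <- function(A_hat, S_hat = NULL, marker_sets = NULL,
                                   truth, universe = rownames(truth$S_true)) {
  stopifnot(is.list(truth), !is.null(truth$A_true))
  A_true <- truth$A_true
  perm <- align_subpopulations(A_hat, A_true, by = "correlation")
  A_al <- A_hat[, perm, drop = FALSE]
  out <- list(
    e1 = compute_e1(A_hat, A_true),
    pearson_proportions = cor(as.vector(A_al), as.vector(A_true)))
  if (!is.null(S_hat) && !is.null(truth$S_true)) {
    S_al <- S_hat[, perm, drop = FALSE]
    common <- intersect(rownames(S_al), rownames(truth$S_true))
    S_al <- S_al[common, , drop = FALSE]
    S_tr <- truth$S_true[common, , drop = FALSE]
    K <- ncol(S_al)
    mk <- lapply(truth$marker_truth, intersect, y = common)
    out$pearson_profiles_markers <- vapply(seq_len(K), function(k) {
      g <- mk[[k]]
      if (length(g) < 3L) return(NA_real_)
      cor(S_al[g, k], S_tr[g, k])
    }, numeric(1L))
    out$pearson_profiles_all <- vapply(seq_len(K), function(k)
      cor(S_al[, k], S_tr[, k]), numeric(1L))
  }
  if (!is.null(marker_sets) && !is.null(truth$marker_truth)) {
    conf <- marker_confusion(marker_sets, truth$marker_truth, universe)
    out$marker_sensitivity <- conf$sensitivity
    out$marker_specificity <- conf$specificity
    out$venn_counts <- conf$venn_counts
  }
  out
}
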