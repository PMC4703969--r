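#' Generate pure subpopulation profiles with planted marker genes
#'
#' Marker genes are exclusively expressed: positive (log-normal) in
#' exactly one subpopulation and exactly zero in the others. A
#' `coexpression_fraction` of the remaining genes are co-expressed —
#' non-negative combinations of at least two subpopulations, placing
#' them strictly inside the scatter simplex; their weights are Dirichlet
#' draws redrawn until no single subpopulation contributes more than
#' `max_weight` of the gene's expression. Any remainder is expressed in
#' one random subpopulation. All magnitudes share one log-normal
#' distribution, so markers are not systematically brighter than other
#' genes.
#'
#' @param n_genes total genes (>= `K * n_markers_per_k`).
#' @param K number of subpopulations (>= 2).
#' @param n_markers_per_k planted markers per subpopulation.
#' @param coexpression_fraction fraction of non-marker genes that are
#'   co-expressed (default 1).
#' @param seed RNG seed.
#' @param meanlog,sdlog log-normal magnitude parameters (defaults
#'   `log(150)`, 0.6, arbitrary intensity units).
#' @param max_weight cap on any subpopulation's share of a co-expressed
#'   gene (default 0.7).
#' @return list with `S_true` (genes x K) and `marker_truth` (named list
#'   of planted marker ids per subpopulation).
#' @export
generate_profiles <- function(n_genes, K, n_markers_per_k,
                              coexpression_fraction = 1, seed = 1,
                              meanlog = log(150), sdlog = 0.6,
                              max_weight = 0.7) {
  if (K < 2) stop("`K` must be at least 2", call. = FALSE)
  n_mark <- K * n_markers_per_k
  if (n_genes < n_mark)
    stop("`n_genes` must be at least K * n_markers_per_k = ", n_mark,
         call. = FALSE)
  stopifnot(coexpression_fraction >= 0, coexpression_fraction <= 1)
  with_seed(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    S <- matrix(0, n_genes, K,
                dimnames = list(gene_ids, paste0("subpop", seq_len(K))))
    magnitude <- rlnorm(n_genes, meanlog, sdlog)
    marker_pos <- sample.int(n_genes, n_mark)
    marker_sub <- rep(seq_len(K), each = n_markers_per_k)
    S[cbind(marker_pos, marker_sub)] <- magnitude[marker_pos]
    marker_truth <- split(gene_ids[marker_pos], marker_sub)
    names(marker_truth) <- colnames(S)

    rest <- setdiff(seq_len(n_genes), marker_pos)
    n_co <- round(coexpression_fraction * length(rest))
    co <- if (n_co > 0) rest[seq_len(n_co)] else integer(0)
    single <- setdiff(rest, co)
    for (i in co) {
      size <- if (K == 2) 2L else sample(2:K, 1L)
      sub <- if (size == K) seq_len(K) else sample.int(K, size)
      repeat {
        w <- rgamma(size, shape = 2)
        w <- w / sum(w)
        if (max(w) <= max_weight) break
      }
      S[i, sub] <- magnitude[i] * w
    }
    if (length(single))
      S[cbind(single, sample.int(K, length(single), replace = TRUE))] <-
        magnitude[single]
    list(S_true = S, marker_truth = marker_truth)
  })
}

#' Generate a full-rank non-negative mixing matrix at a given rotation
#'
#' Mixing diversity controls identifiability: the smaller the minimal
#' pairwise angle between mixing-matrix columns, the more compressed the
#' mixed-expression simplex and the harder the vertex detection. Rows
#' (per-sample proportions) are convex combinations \eqn{(1-w) e_{g(j)} +
#' w d_j} of a subpopulation indicator (samples assigned round-robin)
#' and a Dirichlet draw; the blend `w` is solved by root finding so the
#' minimal pairwise column angle matches `rotation_deg` (within 0.5
#' degrees). At `rotation_deg = 90` with `J = K` the construction
#' reduces to the identity (maximally separated vertices).
#'
#' @param J number of samples (>= K).
#' @param K number of subpopulations.
#' @param rotation_deg target minimal pairwise column angle in (0, 90].
#' @param seed RNG seed.
#' @param max_tries resampling attempts before giving up.
#' @return mixing matrix (J x K), rows summing to 1, full column rank.
#' @export
generate_mixing <- function(J, K, rotation_deg, seed = 1, max_tries = 25L) {
  if (J < K) stop("`J` must be at least `K`", call. = FALSE)
  if (rotation_deg <= 0 || rotation_deg > 90)
    stop("`rotation_deg` must be in (0, 90]", call. = FALSE)
  grp <- rep_len(seq_len(K), J)
  base <- diag(K)[grp, , drop = FALSE]

  min_angle <- function(A) {
    Cn <- sweep(A, 2L, sqrt(colSums(A^2)), "/")
    G <- crossprod(Cn)
    cosmax <- max(G[upper.tri(G)])
    acos(min(max(cosmax, -1), 1)) * 180 / pi
  }

  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      D <- matrix(rgamma(J * K, shape = 1), J, K)
      D <- D / rowSums(D)
      # blend target: mostly the simplex centroid (drives columns parallel,
      # angle -> 0 as w -> 1) plus a Dirichlet jitter for genericity
      Tgt <- 0.75 / K + 0.25 * D
      f <- function(w) min_angle((1 - w) * base + w * Tgt) - rotation_deg
      w <- if (abs(f(0)) < 1e-9) 0
      else if (f(0) < 0 || f(0.999) > 0) NA_real_
      else uniroot(f, c(0, 0.999), tol = 1e-10)$root
      if (is.na(w)) next
      A <- (1 - w) * base + w * Tgt
      ok_angle <- abs(min_angle(A) - rotation_deg) <= 0.5
      ok_rank <- qr(A)$rank == K
      if (ok_angle && ok_rank) {
        dimnames(A) <- list(sprintf("s%02d", seq_len(J)),
                            paste0("subpop", seq_len(K)))
        return(A)
      }
    }
    stop("could not achieve a ", rotation_deg,
         " degree rotation with J = ", J, ", K = ", K, call. = FALSE)
  })
}

#' Mix pure profiles into heterogeneous samples
#'
#' Applies the linear latent variable model \eqn{X = S A^T} and adds
#' optional noise. Additive noise is Gaussian with standard deviation
#' `noise_sd` times the mean of the noise-free mixture, truncated at
#' zero; the multiplicative model scales each entry by a log-normal
#' factor with `sdlog = noise_sd` instead.
#'
#' @param S_true genes x K pure profile matrix.
#' @param A_true J x K mixing matrix.
#' @param noise_sd noise level relative to the mean signal (0 = exact).
#' @param seed RNG seed.
#' @param noise_model `"additive"` (default) or `"multiplicative"`.
#' @return expression matrix (genes x J).
#' @export
mix <- function(S_true, A_true, noise_sd = 0, seed = 1,
                noise_model = c("additive", "multiplicative")) {
  noise_model <- match.arg(noise_model)
  stopifnot(ncol(S_true) == ncol(A_true), noise_sd >= 0)
  X0 <- S_true %*% t(A_true)
  X <- if (noise_sd == 0) X0 else with_seed(seed, {
    if (noise_model == "additive") {
      pmax(X0 + rnorm(length(X0), sd = noise_sd * mean(X0)), 0)
    } else {
      X0 * rlnorm(length(X0), meanlog = 0, sdlog = noise_sd)
    }
  })
  expression_matrix(X, rownames(S_true), rownames(A_true))
}

#' Simulate a ground-truthed synthetic mixture panel
#'
#' One-call generator combining [generate_profiles()],
#' [generate_mixing()] and [mix()]. The defaults mirror the validation
#' design used throughout the package: three subpopulations, nine
#' samples, 2000 genes with 30 planted exclusive markers per
#' subpopulation, a 45-degree simplex rotation and 1% additive noise.
#'
#' @param n_genes,K,J,n_markers_per_k,rotation_deg,noise_sd,
#'   coexpression_fraction see the component generators.
#' @param seed master seed; component seeds are derived as `seed`,
#'   `seed + 1`, `seed + 2`.
#' @return list with `expr` (the mixed expression matrix) and `truth`
#'   (`S_true`, `A_true`, `marker_truth`, `noise_sd`, `seed`).
#' @export
simulate_mixture <- function(n_genes = 2000, K = 3, J = 9,
                             n_markers_per_k = 30, rotation_deg = 45,
                             noise_sd = 0.01, coexpression_fraction = 1,
                             seed = 1) {
  prof <- generate_profiles(n_genes, K, n_markers_per_k,
                            coexpression_fraction, seed = seed)
  A <- generate_mixing(J, K, rotation_deg, seed = seed + 1)
  expr <- mix(prof$S_true, A, noise_sd, seed = seed + 2)
  list(expr = expr,
       truth = list(S_true = prof$S_true, A_true = A,
                    marker_truth = prof$marker_truth,
                    noise_sd = noise_sd, seed = seed))
}
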