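# Independent brute-force oracles, deliberately written with different
# algorithms than the package internals.

# Distance of g to the convex hull of the rows of V by exhaustive
# enumeration of all faces: on each face solve the equality-constrained
# least squares via the KKT system and keep feasible solutions.
oracle_margin <- function(g, V) {
  K <- nrow(V)
  best <- Inf
  for (sz in seq_len(K)) {
    for (Fs in utils::combn(K, sz, simplify = FALSE)) {
      Vf <- V[Fs, , drop = FALSE]
      nf <- length(Fs)
      Kmat <- rbind(cbind(2 * Vf %*% t(Vf), 1), c(rep(1, nf), 0))
      sol <- tryCatch(solve(Kmat, c(2 * Vf %*% g, 1)),
                      error = function(e) NULL)
      if (is.null(sol)) next
      a <- sol[seq_len(nf)]
      if (all(a >= -1e-9)) {
        r <- g - drop(t(Vf) %*% a)
        best <- min(best, sqrt(sum(r * r)))
      }
    }
  }
  best
}

# Exhaustive vertex search over combn(M, K) scoring each subset with the
# face-enumeration margin oracle; skips rank-deficient subsets.
oracle_find_vertices <- function(centers, K, rank_tol = 1e-8) {
  M <- nrow(centers)
  best <- Inf
  best_idx <- NULL
  for (idx in utils::combn(M, K, simplify = FALSE)) {
    V <- centers[idx, , drop = FALSE]
    if (qr(t(V), tol = rank_tol)$rank < K) next
    s <- 0
    for (m in setdiff(seq_len(M), idx))
      s <- s + oracle_margin(centers[m, ], V)
    if (s < best - 1e-12) {
      best <- s
      best_idx <- idx
    }
  }
  list(vertex_idx = best_idx, fit_error = best)
}

# Random points on the unit simplex (rows)
rsimplex <- function(n, d) {
  x <- matrix(rexp(n * d), n, d)
  x / rowSums(x)
}

# A small noise-free mixture panel for fast end-to-end checks.
small_panel <- function(K = 3, J = 3 * K, n_genes = 400, noise_sd = 0,
                        seed = 1, rotation_deg = 45) {
  simulate_mixture(n_genes = n_genes, K = K, J = J, n_markers_per_k = 10,
                   rotation_deg = rotation_deg, noise_sd = noise_sd,
                   seed = seed)
}
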