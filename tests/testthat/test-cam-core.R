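test_that("margin-of-error matches analytic and degenerate cases", {
  v <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  expect_equal(margin_of_error(c(0.8, 0.2), v), 0, tolerance = 1e-9)
  expect_equal(margin_of_error(0.5 * v[1, ] + 0.5 * v[2, ], v), 0,
               tolerance = 1e-9)
  # g outside the segment projects onto the nearest endpoint
  expect_equal(margin_of_error(c(1, 0), v), sqrt(0.2^2 + 0.2^2),
               tolerance = 1e-9)
  expect_error(margin_of_error(c(1, 0, 0), v), "dimension mismatch")
})

test_that("margin-of-error agrees with the face-enumeration oracle", {
  set.seed(21)
  for (rep in 1:20) {
    K <- sample(2:5, 1)
    J <- sample(K:8, 1)
    V <- rsimplex(K, J)
    g <- if (rep %% 2 == 0) rsimplex(1, J)[1, ]
         else drop(t(V) %*% rsimplex(1, K)[1, ])  # inside the hull
    m <- margin_of_error(g, V)
    expect_gte(m, 0)
    expect_equal(m, oracle_margin(g, V), tolerance = 1e-7)
    # invariance to vertex ordering
    expect_equal(m, margin_of_error(g, V[sample(K), , drop = FALSE]),
                 tolerance = 1e-9)
  }
})

test_that("points inside the hull have zero margin, outside positive", {
  set.seed(33)
  V <- rsimplex(4, 6)
  inside <- t(V) %*% rsimplex(10, 4)[1, ]
  expect_lt(margin_of_error(drop(inside), V), 1e-9)
  # a vertex pushed outward along its direction from the centroid
  ctr <- colMeans(V)
  out <- V[1, ] + 0.5 * (V[1, ] - ctr)
  expect_gt(margin_of_error(out / sum(out) * sum(V[1, ]), V), 1e-6)
})

fake_clusters <- function(centers, membership = NULL) {
  rownames(centers) <- paste0("c", seq_len(nrow(centers)))
  if (is.null(membership)) {
    membership <- seq_len(nrow(centers))
    names(membership) <- paste0("g", seq_len(nrow(centers)))
  }
  structure(list(centers = centers,
                 exemplar_ids = names(membership)[seq_len(nrow(centers))],
                 membership = membership,
                 sizes = tabulate(membership, nrow(centers)),
                 preference = NA, damping = 0.5, converged = TRUE),
            class = "cam_clusters")
}

test_that("the exhaustive search recovers known vertices among interior points", {
  set.seed(10)
  A <- generate_mixing(6, 3, 50, seed = 2)
  Vn <- t(apply(t(A), 1, function(a) a / sum(a)))  # normalized columns
  interior <- t(t(Vn) %*% t(rsimplex(7, 3)))
  centers <- rbind(Vn, interior)
  cl <- fake_clusters(centers)
  fit <- find_vertices(cl, 3)
  expect_identical(sort(fit$vertex_idx), 1:3)
  expect_lt(fit$fit_error, 1e-9)
  # the rescaled mixing estimate reproduces A up to column order
  perm <- align_subpopulations(fit$A, A)
  expect_lt(max(abs(fit$A[, perm] - A)), 1e-9)
})

test_that("forced choice M == K returns the only subset with zero error", {
  set.seed(12)
  centers <- rsimplex(3, 5)
  fit <- find_vertices(fake_clusters(centers), 3)
  expect_identical(fit$vertex_idx, 1:3)
  expect_identical(fit$fit_error, 0)
})

test_that("search agrees with the brute-force oracle on random instances", {
  set.seed(77)
  for (rep in 1:10) {
    M <- sample(6:10, 1)
    K <- sample(2:4, 1)
    centers <- rsimplex(M, K + 2)
    fit <- find_vertices(fake_clusters(centers), K)
    ora <- oracle_find_vertices(centers, K)
    expect_identical(fit$vertex_idx, as.integer(ora$vertex_idx))
    expect_equal(fit$fit_error, ora$fit_error, tolerance = 1e-7)
  }
})

test_that("ties resolve to the lexicographically smallest subset", {
  set.seed(3)
  V <- rsimplex(2, 4)
  mid <- 0.5 * V[1, ] + 0.5 * V[2, ]
  # centers 3 and 4 duplicate the midpoint: {1,2} beats everything, and
  # among equal-error duplicates the smaller index set must win
  centers <- rbind(V, mid, mid)
  fit <- find_vertices(fake_clusters(centers), 2)
  expect_identical(fit$vertex_idx, 1:2)
  # duplicated-point subsets {3,4} are rank-deficient and skipped
  expect_gte(fit$n_rank_skipped, 1)
})

test_that("the subset budget guards the combinatorial explosion", {
  centers <- rsimplex(30, 5)
  expect_error(find_vertices(fake_clusters(centers), 4,
                             subset_budget = 1000),
               "budget")
})

test_that("marker genes are exactly the members of vertex clusters", {
  set.seed(14)
  A <- generate_mixing(6, 3, 55, seed = 4)
  Vn <- t(apply(t(A), 1, function(a) a / sum(a)))
  interior <- t(t(Vn) %*% t(rsimplex(5, 3)))
  centers <- rbind(Vn, interior)
  membership <- c(1L, 1L, 2L, 3L, 4:8)  # genes g1,g2 -> cluster 1 etc.
  names(membership) <- paste0("g", 1:9)
  cl <- fake_clusters(centers, membership)
  cl$sizes <- tabulate(membership, nrow(centers))
  fit <- find_vertices(cl, 3)
  mk <- identify_markers(fit, cl)
  expect_named(mk, colnames(fit$A))
  expect_setequal(mk[[1]], c("g1", "g2"))
  expect_setequal(mk[[2]], "g3")
  expect_setequal(mk[[3]], "g4")
  # interior genes appear in no marker set
  expect_false(any(paste0("g", 5:9) %in% unlist(mk)))
  # marker sets are pairwise disjoint
  expect_identical(anyDuplicated(unlist(mk)), 0L)
})
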