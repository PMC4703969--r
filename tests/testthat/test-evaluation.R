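test_that("the E1 index is zero exactly for permuted/scaled recovery", {
  A <- generate_mixing(6, 3, 50, seed = 51)
  expect_equal(compute_e1(A, A), 0, tolerance = 1e-9)
  perm <- c(2, 3, 1)
  D <- diag(c(0.5, 2, 7))
  expect_equal(compute_e1(A[, perm] %*% D, A), 0, tolerance = 1e-9)
  expect_error(compute_e1(A[, c(1, 1, 2)], A), "rank")
  expect_error(compute_e1(A[, 1:2], A), "shape")
})

test_that("E1 evaluates the cross-talk formula on a hand-worked case", {
  # choose A_hat so that pinv(A_hat) %*% A_true equals P = [[1,1],[0,1]]
  A_true <- generate_mixing(5, 2, 60, seed = 53)
  P <- rbind(c(1, 1), c(0, 1))
  A_hat <- A_true %*% solve(P)
  expect_equal(compute_e1(A_hat, A_true), 2, tolerance = 1e-9)
})

test_that("E1 is non-negative on random estimates", {
  set.seed(55)
  for (i in 1:20) {
    K <- sample(2:4, 1)
    A_true <- generate_mixing(K + 3, K, 50, seed = i)
    A_hat <- abs(A_true + matrix(rnorm(length(A_true), 0, 0.2),
                                 nrow(A_true)))
    A_hat <- A_hat / rowSums(A_hat)
    if (qr(A_hat)$rank < K) next
    expect_gte(compute_e1(A_hat, A_true), 0)
  }
})

test_that("marker confusion counts match hand-tallied sets", {
  universe <- paste0("g", 1:10)
  truth <- list(k1 = c("g1", "g2", "g3", "g4"))
  pred <- list(k1 = c("g1", "g2", "g5"))
  conf <- marker_confusion(pred, truth, universe)
  expect_equal(conf$sensitivity, 0.5)
  expect_equal(conf$specificity, 5 / 6)
  expect_identical(unname(conf$venn_counts), c(2L, 1L, 2L))

  same <- marker_confusion(truth, truth, universe)
  expect_identical(same$sensitivity, 1)
  expect_identical(same$specificity, 1)
  expect_identical(unname(same$venn_counts), c(4L, 0L, 0L))

  none <- marker_confusion(list(k1 = character(0)), truth, universe)
  expect_identical(none$sensitivity, 0)
  expect_identical(none$specificity, 1)

  expect_error(marker_confusion(pred, list(k1 = character(0)), universe),
               "empty")
})

test_that("confusion aligns labels by maximum overlap before scoring", {
  universe <- paste0("g", 1:8)
  truth <- list(a = c("g1", "g2"), b = c("g3", "g4"))
  pred_swapped <- list(x = c("g3", "g4"), y = c("g1", "g2"))
  conf <- marker_confusion(pred_swapped, truth, universe)
  expect_identical(conf$sensitivity, 1)
})

test_that("one-versus-everyone fold change builds the expected gold standard", {
  S <- rbind(c(10, 0, 0), c(4, 3, 3), c(9, 4, 1), c(0, 0, 0))
  rownames(S) <- paste0("g", 1:4)
  mk <- fold_change_markers(S, 2)
  expect_identical(mk[[1]], c("g1", "g3"))  # 10 vs 0; 9 >= 2*4
  expect_identical(unname(lengths(mk)[2:3]), c(0L, 0L))
})

test_that("fold-change markers shrink monotonically with the threshold", {
  set.seed(57)
  S <- matrix(rexp(300) * 10, 100, 3,
              dimnames = list(paste0("g", 1:100), NULL))
  sizes <- vapply(c(1.5, 2, 3, 5, 10), function(th)
    sum(lengths(fold_change_markers(S, th))), integer(1L))
  expect_true(all(diff(sizes) <= 0))
  # and every set at a higher threshold is nested in the lower one
  mk2 <- fold_change_markers(S, 2)
  mk5 <- fold_change_markers(S, 5)
  for (k in 1:3) expect_true(all(mk5[[k]] %in% mk2[[k]]))
})

test_that("proportion perturbation is seeded, bounded and row-stochastic", {
  A <- generate_mixing(6, 3, 50, seed = 59)
  expect_identical(perturb_proportions(A, 0, 1), A)
  P1 <- perturb_proportions(A, 0.2, 42)
  P2 <- perturb_proportions(A, 0.2, 42)
  expect_identical(P1, P2)
  expect_true(all(P1 >= 0))
  expect_equal(unname(rowSums(P1)), rep(1, 6), tolerance = 1e-12)
  expect_false(identical(P1, perturb_proportions(A, 0.2, 43)))
})

test_that("signature perturbation is seeded and non-negative", {
  S <- matrix(rexp(60) * 5, 20, 3)
  expect_identical(perturb_signatures(S, 0, 1), S)
  S1 <- perturb_signatures(S, 0.5, 7)
  expect_identical(S1, perturb_signatures(S, 0.5, 7))
  expect_true(all(S1 >= 0))
  expect_true(all(abs(S1 - S) <= 0.5 * S + 1e-12))
})

test_that("the supervised baseline degrades as its prior degrades", {
  sim <- small_panel(K = 3, n_genes = 300, noise_sd = 0.02, seed = 61)
  A <- sim$truth$A_true
  S <- sim$truth$S_true
  mk <- unlist(sim$truth$marker_truth)
  exact <- supervised_profiles_baseline(sim$expr, A)
  base_cor <- cor(as.vector(exact$S_hat[mk, ]), as.vector(S[mk, ]))
  expect_gt(base_cor, 0.99)
  cors <- vapply(c(0.05, 0.15, 0.3), function(mag) {
    mean(vapply(1:5, function(s) {
      Ap <- perturb_proportions(A, mag, s)
      est <- supervised_profiles_baseline(sim$expr, Ap)
      cor(as.vector(est$S_hat[mk, ]), as.vector(S[mk, ]))
    }, numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(cors) < 0))
  expect_true(all(cors < base_cor))
  expect_error(supervised_profiles_baseline(sim$expr[, 1:2], A),
               "mismatch|underdetermined")
})

test_that("all-gene profile correlation is inflated by co-expression", {
  # between two DIFFERENT subpopulations' pure profiles, correlation over
  # all genes stays high (co-expressed genes track both), while the
  # marker-restricted correlation exposes the mismatch — the reason both
  # are reported separately
  sim <- small_panel(K = 3, n_genes = 500, noise_sd = 0.02, seed = 63)
  S <- sim$truth$S_true
  mk <- sim$truth$marker_truth
  cross_all <- cor(S[, 1], S[, 2])
  m12 <- c(mk[[1]], mk[[2]])
  cross_mk <- cor(S[m12, 1], S[m12, 2])
  expect_gt(cross_all, cross_mk + 0.2)

  # and the evaluation report carries both flavors for a correct estimate
  fitA <- estimate_proportions(sim$expr, mk)
  pr <- estimate_profiles(sim$expr, fitA)
  ev <- evaluate_deconvolution(fitA, pr$S_hat, mk, truth = sim$truth)
  expect_true(all(ev$pearson_profiles_markers > 0.95))
  expect_length(ev$pearson_profiles_all, 3L)
  expect_identical(ev$marker_sensitivity, 1)
})
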