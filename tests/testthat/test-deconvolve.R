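test_that("marker averaging recovers proportions exactly on clean mixtures", {
  sim <- small_panel(K = 3, n_genes = 300, noise_sd = 0, seed = 31)
  A <- sim$truth$A_true
  # one marker per subpopulation suffices
  mk1 <- lapply(sim$truth$marker_truth, `[`, 1L)
  A_hat <- estimate_proportions(sim$expr, mk1)
  perm <- align_subpopulations(A_hat, A)
  expect_lt(max(abs(A_hat[, perm] - A)), 1e-9)
  expect_equal(unname(rowSums(A_hat)), rep(1, nrow(A_hat)),
               tolerance = 1e-9)
  # full marker sets give the same answer
  A_hat2 <- estimate_proportions(sim$expr, sim$truth$marker_truth)
  expect_lt(max(abs(A_hat2[, perm] - A)), 1e-9)
})

test_that("standardized averaging normalizes markers before averaging", {
  # two samples, two subpopulations, single markers with L1 norms 4 and 4
  expr <- expression_matrix(rbind(c(3, 1), c(1, 3)),
                            c("m1", "m2"), c("s1", "s2"))
  A <- estimate_proportions(expr, list(a = "m1", b = "m2"), norm = "L1")
  expect_equal(unname(A), rbind(c(0.75, 0.25), c(0.25, 0.75)),
               tolerance = 1e-12)
})

test_that("duplicating a marker gene leaves the estimate unchanged", {
  sim <- small_panel(K = 2, J = 4, n_genes = 200, noise_sd = 0, seed = 37)
  mk <- sim$truth$marker_truth
  A1 <- estimate_proportions(sim$expr, mk)
  mk_dup <- mk
  mk_dup[[1]] <- c(mk[[1]], mk[[1]][1])  # same vector twice in the average
  expr2 <- sim$expr[c(rownames(sim$expr), mk[[1]][1]), ]
  rownames(expr2) <- make.unique(rownames(expr2))
  mk_dup[[1]] <- c(mk[[1]], paste0(mk[[1]][1], ".1"))
  A2 <- estimate_proportions(expression_matrix(expr2), mk_dup)
  # adding an identical marker vector shifts the average by nothing new
  expect_lt(max(abs(A1 - A2)), 1e-9)
})

test_that("empty marker sets are rejected by name", {
  expr <- expression_matrix(matrix(1:4 + 0, 2, 2,
                                   dimnames = list(c("g1", "g2"),
                                                   c("s1", "s2"))))
  expect_error(estimate_proportions(expr, list(x = "g1", y = character(0))),
               "y")
  expect_error(estimate_proportions(expr, list(x = "g1", y = "gZ")),
               "absent")
})

test_that("profile recovery is exact when an exact solution exists", {
  sim <- small_panel(K = 3, n_genes = 300, noise_sd = 0, seed = 41)
  pr <- estimate_profiles(sim$expr, sim$truth$A_true)
  S <- sim$truth$S_true
  rel <- max(abs(pr$S_hat - S)) / max(S)
  expect_lt(rel, 1e-6)
  expect_lt(max(pr$residual), 1e-6)
  expect_true(all(pr$S_hat >= 0))
})

test_that("an all-zero gene gets a zero profile and zero residual", {
  A <- generate_mixing(5, 2, 60, seed = 3)
  expr <- expression_matrix(rbind(c(1, 2, 3, 4, 5), rep(0, 5)),
                            c("g1", "gz"), rownames(A))
  pr <- estimate_profiles(expr, A)
  expect_identical(unname(pr$S_hat["gz", ]), c(0, 0))
  expect_identical(unname(pr$residual["gz"]), 0)
})

test_that("per-gene NNLS matches an independent solver on noisy genes", {
  skip_if_not_installed("pracma")
  set.seed(43)
  A <- generate_mixing(4, 2, 50, seed = 9)
  expr <- expression_matrix(
    matrix(rexp(40) * 10, 10, 4,
           dimnames = list(paste0("g", 1:10), rownames(A))))
  pr <- estimate_profiles(expr, A)
  for (i in 1:10) {
    ref <- pracma::lsqnonneg(A, expr[i, ])$x
    expect_equal(unname(pr$S_hat[i, ]), ref, tolerance = 1e-6)
  }
})

test_that("profile estimation refuses underdetermined systems", {
  A <- matrix(runif(6), 2, 3)
  A <- A / rowSums(A)
  expr <- expression_matrix(matrix(1:6 + 0, 3, 2,
                                   dimnames = list(paste0("g", 1:3),
                                                   c("s1", "s2"))))
  expect_error(estimate_profiles(expr, A), "underdetermined")
  # rank-deficient square case
  A2 <- cbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_error(estimate_profiles(expr, A2), "rank deficient")
})

test_that("deconvolution is equivariant and scale-consistent", {
  sim <- small_panel(K = 3, n_genes = 200, noise_sd = 0.02, seed = 47)
  A <- sim$truth$A_true
  pr <- estimate_profiles(sim$expr, A)
  # permuting subpopulation labels permutes the recovered profiles
  p <- c(3, 1, 2)
  pr_p <- estimate_profiles(sim$expr, A[, p])
  expect_equal(pr_p$S_hat, pr$S_hat[, p], tolerance = 1e-8,
               ignore_attr = TRUE)
  # scaling the expression scales profiles, proportions are unchanged
  pr_c <- estimate_profiles(expression_matrix(sim$expr * 3.7), A)
  expect_equal(pr_c$S_hat, 3.7 * pr$S_hat, tolerance = 1e-8)
  mk <- sim$truth$marker_truth
  A1 <- estimate_proportions(sim$expr, mk)
  A2 <- estimate_proportions(expression_matrix(sim$expr * 3.7), mk)
  expect_equal(A1, A2, tolerance = 1e-12)
})
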