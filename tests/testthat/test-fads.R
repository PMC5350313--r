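test_that("preprocessing averages 32-frame pairs and drops the last frame", {
  arr32 <- array(0, c(32, 2, 2))
  for (q in 1:32) arr32[q, , ] <- q
  s32 <- gated_series(arr32)
  p <- preprocess_frames(s32)
  expect_equal(p$frames, 15)
  # pair means 1.5, 3.5, ..., 29.5 (the 16th pair is dropped)
  expect_equal(p$counts[, 1, 1], seq(1.5, 29.5, by = 2))

  const <- preprocess_frames(gated_series(array(7, c(32, 2, 2))))
  expect_true(all(const$counts == 7))

  arr16 <- array(rpois(16 * 4, 20), c(16, 2, 2))
  arr16[16, , ] <- 0
  p16 <- preprocess_frames(gated_series(arr16))
  expect_equal(p16$frames, 15)
  expect_identical(p16$counts, arr16[1:15, , , drop = FALSE])

  expect_error(preprocess_frames(gated_series(array(1, c(12, 2, 2)))),
               "16 or 32")
})

test_that("TAC matrix follows the row-major pixel index and inverts", {
  arr <- array(0, c(2, 2, 2))
  arr[1, , ] <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
  arr[2, , ] <- matrix(c(5, 6, 7, 8), 2, byrow = TRUE)
  tac <- build_tac_matrix(gated_series(arr))
  expect_equal(tac$X, cbind(1:4, 5:8))
  expect_equal(tac_to_frames(tac), arr)

  s <- generate_series(quick_params(seed = 3))
  tac <- build_tac_matrix(s)
  expect_equal(dim(tac$X), c(4096, 16))
  expect_equal(tac_to_frames(tac), s$counts)
})

test_that("uncentered FADS reconstructs exactly and matches the SVD oracle", {
  set.seed(10)
  for (rep in 1:25) {
    P <- sample(5:40, 1); Q <- sample(3:8, 1)
    X <- matrix(rnorm(P * Q, sd = sample(c(0.1, 1, 50), 1)), P, Q)
    tac <- structure(list(X = X, grid = c(P, 1)), class = "tac_matrix")
    f <- fads_decompose(tac)
    expect_lt(norm(fads_reconstruct(f) - X, "F") / norm(X, "F"), 1e-10)
    # orthonormal coefficients, ordered nonnegative eigenvalues
    expect_equal(crossprod(f$coefficients), diag(Q), tolerance = 1e-8)
    expect_true(all(diff(f$eigenvalues) <= 1e-8))
    expect_true(all(f$eigenvalues >= 0))
    # independent oracle: eigenvalues are squared singular values
    d2 <- svd(X)$d^2
    if (length(d2) < Q) d2 <- c(d2, rep(0, Q - length(d2)))
    expect_equal(f$eigenvalues, d2, tolerance = 1e-8)
    expect_equal(sum(f$contributions), 100, tolerance = 1e-6)
  }
})

test_that("rank-1 input concentrates all contribution in factor 1", {
  u <- 1:12; v <- c(2, 5, 1, 4)
  tac <- structure(list(X = outer(u, v), grid = c(12, 1)),
                   class = "tac_matrix")
  f <- fads_decompose(tac)
  expect_equal(factor_contributions(f, 1), 100, tolerance = 1e-9)
  expect_lt(f$eigenvalues[2] / f$eigenvalues[1], 1e-12)
})

test_that("centered mode restores the stored column means", {
  set.seed(2)
  X <- matrix(rnorm(60), 15, 4) + 100
  tac <- structure(list(X = X, grid = c(15, 1)), class = "tac_matrix")
  f <- fads_decompose(tac, mode = "centered")
  expect_equal(fads_reconstruct(f), X, tolerance = 1e-10)
  expect_equal(f$center, colMeans(X))
})

test_that("coefficient sign convention makes repeated decompositions identical", {
  s <- generate_series(quick_params(seed = 21, lvrv_delay_deg = 45))
  tac <- build_tac_matrix(preprocess_frames(s))
  f1 <- fads_decompose(tac); f2 <- fads_decompose(tac)
  expect_identical(f1$coefficients, f2$coefficients)
  for (j in 1:3) {
    cj <- f1$coefficients[, j]
    expect_gt(cj[which.max(abs(cj))], 0)
  }
})

test_that("contributions are invariant to pixel permutation", {
  set.seed(5)
  X <- matrix(rpois(200, 30), 40, 5)
  t1 <- structure(list(X = X, grid = c(40, 1)), class = "tac_matrix")
  t2 <- structure(list(X = X[sample(40), ], grid = c(40, 1)),
                  class = "tac_matrix")
  expect_equal(fads_decompose(t1)$contributions,
               fads_decompose(t2)$contributions, tolerance = 1e-10)
})

test_that("top_factors truncates consistently with factor_contributions", {
  s <- generate_series(quick_params(seed = 8))
  f <- fads_decompose(build_tac_matrix(preprocess_frames(s)))
  top <- top_factors(f, 3)
  expect_equal(ncol(top$coefficients), 3)
  expect_equal(nrow(top$coefficients), 15)
  expect_equal(sum(top$contributions), factor_contributions(f, 3))
  expect_equal(factor_contributions(top, 3), factor_contributions(f, 3))
  # k = Q is the identity
  expect_identical(top_factors(f, length(f$eigenvalues))$coefficients,
                   f$coefficients)
  expect_error(factor_contributions(fads_decompose(structure(
    list(X = matrix(0, 6, 3), grid = c(6, 1)), class = "tac_matrix")), 1),
    "degenerate")
})

test_that("factor images localize: F1 in ventricles, F2 in atria", {
  lab <- default_masks$labels
  hits1 <- 0; hits2 <- 0
  for (seed in 1:5) {
    s <- generate_series(subject_params(ef_true = 0.6, seed = seed))
    f <- fads_decompose(build_tac_matrix(preprocess_frames(s)))
    if (lab[which.max(factor_image(f, 1))] %in% c(1L, 2L)) hits1 <- hits1 + 1
    if (lab[which.max(factor_image(f, 2))] == 3L) hits2 <- hits2 + 1
  }
  expect_equal(hits1, 5)
  expect_equal(hits2, 5)
})
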