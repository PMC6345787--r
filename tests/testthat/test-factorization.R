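test_that("l1 k-means finds the exhaustive-oracle partition on two clouds", {
  set.seed(21)
  for (case in 1:3) {
    M <- 6L
    c1 <- rnorm(M); c2 <- c1 + 4
    C <- cbind(sapply(1:5, function(i) c1 + 0.2 * rnorm(M)),
               sapply(1:5, function(i) c2 + 0.2 * rnorm(M)))
    fit <- fit_kmeans_l1(C, 2, n_rep = 20, seed = case)
    oracle <- kmeans_l1_oracle_k2(C)
    expect_equal(fit$objective, oracle$objective, tolerance = 1e-10)
    # centroids are the per-cloud component-wise medians
    for (g in 1:2) {
      cols <- C[, fit$assignment == g, drop = FALSE]
      expect_equal(fit$D[, g], apply(cols, 1, median))
    }
  }
})

test_that("l1 k-means honors degenerate k", {
  set.seed(22)
  C <- matrix(rnorm(8 * 10), 8, 10)
  one <- fit_kmeans_l1(C, 1, n_rep = 1, seed = 1)
  expect_equal(one$D[, 1], apply(C, 1, median))
  full <- fit_kmeans_l1(C, 10, n_rep = 5, seed = 1)
  expect_equal(full$objective, 0, tolerance = 1e-12)
  expect_true(all(colSums(full$A) == 1))      # one-hot occupancy
})

test_that("best k-means replicate beats or matches single replicates", {
  set.seed(23)
  C <- matrix(rnorm(10 * 30), 10, 30)
  best <- fit_kmeans_l1(C, 4, n_rep = 25, seed = 7)
  singles <- vapply(1:8, function(s)
    fit_kmeans_l1(C, 4, n_rep = 1, seed = s)$objective, numeric(1))
  expect_true(all(best$objective <= singles + 1e-10))
})

test_that("PCA states are orthonormal and explain SVD variance", {
  set.seed(24)
  C <- matrix(rnorm(20 * 15), 20, 15)
  fit <- fit_pca(C, 5)
  expect_equal(crossprod(fit$D), diag(5), tolerance = 1e-10)
  sv <- svd(C - rowMeans(C))
  expect_equal(fit$explained_var, sv$d[1:5]^2 / 14, tolerance = 1e-10)
  # rank-1 input is reconstructed exactly by the first state
  C1 <- outer(rnorm(20), rnorm(15)) + rnorm(20)  # rank 1 + row offsets
  f1 <- fit_pca(C1, 3)
  Cc <- C1 - rowMeans(C1)
  expect_lt(norm(Cc - f1$D[, 1, drop = FALSE] %*% f1$A[1, , drop = FALSE],
                 "F"), 1e-8)
  expect_equal(sort(f1$degenerate), 2:3)
  expect_error(fit_pca(C, 40), "min")
})

test_that("lasso coding satisfies stationarity and matches the oracle", {
  set.seed(25)
  for (case in 1:6) {
    M <- sample(4:8, 1); k <- sample(2:5, 1)
    D <- unit_cols(matrix(rnorm(M * k), M, k))
    C <- matrix(rnorm(M * 3), M, 3)
    lambda <- runif(1, 0.05, 0.6)
    A <- sparse_code_l1(C, D, lambda)
    for (t in 1:3) {
      expect_lt(lasso_kkt_gap(C[, t], D, A[, t], lambda), 1e-6)
      a_or <- lasso_oracle(C[, t], D, lambda)
      expect_equal(A[, t], a_or, tolerance = 1e-5)
    }
  }
})

test_that("lasso coding has the known closed forms", {
  set.seed(26)
  M <- 6
  D <- unit_cols(matrix(rnorm(M * 3), M, 3))
  c_vec <- rnorm(M)
  # lambda = 0 with full column rank -> least squares
  expect_equal(drop(sparse_code_l1(cbind(c_vec), D, 0)),
               drop(qr.coef(qr(D), c_vec)), tolerance = 1e-8)
  # lambda above lambda_max -> all-zero code
  lam_max <- max(abs(crossprod(D, c_vec)))
  expect_true(all(sparse_code_l1(cbind(c_vec), D, lam_max * 1.001) == 0))
  # single atom -> soft thresholding of the inner product
  d1 <- D[, 1, drop = FALSE]
  for (lam in c(0.1, 0.5, 2)) {
    z <- drop(crossprod(d1, c_vec))
    expect_equal(drop(sparse_code_l1(cbind(c_vec), d1, lam)),
                 sign(z) * max(abs(z) - lam, 0), tolerance = 1e-10)
  }
})

test_that("lasso support shrinks (on average) as lambda grows", {
  set.seed(27)
  C <- random_C(M = 25, T_w = 30, seed = 5)
  D <- fit_pca(C, 6)$D
  grid <- auto_lambda_grid(C, D)
  expect_length(grid, 5L)
  expect_true(all(diff(grid) > 0))
  supp <- vapply(grid, function(l)
    mean(colSums(sparse_code_l1(C, D, l) != 0)), numeric(1))
  expect_true(all(diff(supp) <= 0))
})

test_that("OMP recovers sparse combinations of orthogonal atoms", {
  D <- diag(6)[, 1:4]                          # orthonormal atoms
  c_vec <- 2 * D[, 1] + 3 * D[, 2]
  A <- sparse_code_l0(cbind(c_vec), D, 2)
  expect_equal(drop(A), c(2, 3, 0, 0), tolerance = 1e-12)
  # single-atom input
  A1 <- sparse_code_l0(cbind(D[, 3]), D, 1)
  expect_equal(which(A1 != 0), 3L)
  expect_equal(A1[3, 1], 1)
  # support bound holds on random input
  set.seed(28)
  Dr <- unit_cols(matrix(rnorm(10 * 6), 10, 6))
  Cr <- matrix(rnorm(10 * 12), 10, 12)
  for (s in 1:4)
    expect_true(all(colSums(sparse_code_l0(Cr, Dr, s) != 0) <= s))
  expect_error(sparse_code_l0(Cr, Dr, 7), "in \\[1, k\\]")
})

test_that("dictionary update attains the least-squares optimum", {
  set.seed(29)
  M <- 12; k <- 4; T_w <- 20
  C <- matrix(rnorm(M * T_w), M, T_w)
  A <- matrix(rnorm(k * T_w), k, T_w)          # full rank, fixed
  D0 <- unit_cols(matrix(rnorm(M * k), M, k))
  upd <- update_dictionary(C, A, D0)
  D_ls <- t(solve(tcrossprod(A), A %*% t(C)))  # normal-equations oracle
  expect_equal(norm(C - upd$D %*% upd$A, "F"), norm(C - D_ls %*% A, "F"),
               tolerance = 1e-6)
  expect_equal(colSums(upd$D^2), rep(1, k), tolerance = 1e-10)
  # A = I -> D is column-normalized C
  Ck <- C[, 1:k]
  upd2 <- update_dictionary(Ck, diag(k), D0)
  expect_equal(upd2$D, unit_cols(Ck), tolerance = 1e-10)
  # an unused atom is re-seeded at the worst-reconstructed column
  A_dead <- A; A_dead[2, ] <- 0
  upd3 <- update_dictionary(C, A_dead, D0)
  resid <- colSums((C - upd3$D[, -2] %*% upd3$A[-2, ])^2)
  expect_equal(upd3$D[, 2], C[, which.max(resid)] /
                 sqrt(sum(C[, which.max(resid)]^2)), tolerance = 1e-8)
})

test_that("alternating minimization never raises the recorded objective", {
  set.seed(30)
  for (case in 1:20) {
    C <- random_C(M = 15, T_w = 18, k_true = 3, seed = case, noise = 0.3)
    norm_type <- if (case %% 2 == 0) "l1" else "l0"
    lam <- if (norm_type == "l1") runif(1, 0.02, 0.3) else sample(2:3, 1)
    fit <- suppressWarnings(
      fit_dl(C, 4, lam, norm = norm_type,
             init = c("random", "kcl", "pca")[1 + case %% 3],
             n_iter = 30, seed = case))
    expect_true(all(diff(fit$objective_trace) <= 1e-12))
    expect_equal(colSums(fit$D^2), rep(1, 4), tolerance = 1e-8)
    if (norm_type == "l0")
      expect_true(all(colSums(fit$A != 0) <= lam))
  }
})

test_that("PCA initialization with zero iterations returns the PCA states", {
  set.seed(31)
  C <- random_C(M = 20, T_w = 25, seed = 9)
  fit <- fit_dl(C, 3, 0.1, norm = "l1", init = "pca", n_iter = 0)
  expect_equal(fit$D, fit_pca(C, 3)$D, tolerance = 1e-12)
})

test_that("dictionary learning recovers planted states at low noise", {
  sc <- synth_scene(R = 30, K = 4, T_scan = 300, fs = 60, noise_sigma = 0.1,
                    seed = 6)
  d <- build_dfc(sc$bold, L = 15, s = 2)
  grid <- auto_lambda_grid(d$C, fit_pca(d$C, 4)$D)
  fit <- suppressWarnings(fit_dl(d$C, 4, grid[2], norm = "l1", init = "pca",
                                 seed = 1))
  mm <- match_states(fit$D, sc$states)
  expect_true(all(mm$abs_cor >= 0.8))
})

test_that("non-sparse weights are window-state correlations", {
  set.seed(32)
  C <- matrix(rnorm(10 * 6), 10, 6)
  D <- matrix(rnorm(10 * 3), 10, 3)
  W <- nonsparse_weights(C, D)
  expect_equal(W, t(cor(C, D)), tolerance = 1e-12)
  expect_true(all(W >= -1 & W <= 1))
  # affine invariance: c = 2 d + 3 -> correlation 1
  C2 <- cbind(2 * D[, 1] + 3, C[, -1])
  expect_equal(nonsparse_weights(C2, D)[1, 1], 1)
  # orthogonal-to-centered case gives 0
  d_o <- rnorm(10)
  c_o <- residuals(lm(rnorm(10) ~ d_o))
  expect_equal(nonsparse_weights(cbind(c_o), cbind(d_o))[1, 1], 0,
               tolerance = 1e-10)
  expect_error(nonsparse_weights(matrix(1, 10, 2), D), "zero-variance")
})

test_that("fits are reproducible given identical seeds", {
  set.seed(33)
  C <- random_C(M = 20, T_w = 24, seed = 11)
  f1 <- suppressWarnings(fit_dl(C, 3, 0.1, init = "random", seed = 5))
  f2 <- suppressWarnings(fit_dl(C, 3, 0.1, init = "random", seed = 5))
  expect_identical(f1$D, f2$D)
  k1 <- fit_kmeans_l1(C, 3, n_rep = 10, seed = 5)
  k2 <- fit_kmeans_l1(C, 3, n_rep = 10, seed = 5)
  expect_identical(k1$D, k2$D)
})
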