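test_that("phase randomization preserves amplitude spectra exactly", {
  set.seed(51)
  for (T_w in c(40, 41)) {                     # even and odd lengths
    C <- matrix(rnorm(6 * T_w), 6, T_w)
    Cs <- phase_randomize(C, seed = 1)
    for (r in 1:6) {
      expect_equal(Mod(fft(Cs[r, ])), Mod(fft(C[r, ])), tolerance = 1e-10)
    }
    expect_equal(rowMeans(Cs), rowMeans(C), tolerance = 1e-12)
    Cs2 <- phase_randomize(C, seed = 2)
    expect_gt(max(abs(Cs2 - Cs)), 0.1)         # different draws
    expect_equal(Mod(fft(Cs2[1, ])), Mod(fft(Cs[1, ])), tolerance = 1e-10)
    expect_lt(max(abs(Im(fft(Cs[1, ])[1]))), 1e-10)   # DC stays real
  }
  expect_error(phase_randomize(matrix(1, 2, 3)), "at least 4")
})

test_that("the fifth-percentile threshold is the right order statistic", {
  set.seed(52)
  sc <- small_scene(seed = 4)
  d <- build_dfc(sc$bold, 15, 2)
  sn <- suppressWarnings(surrogate_null(
    d$C, list(method = "l1dl", init = "pca", k = 3, lambda = 0.2),
    n_surr = 20, seed = 1))
  expect_equal(dim(sn$E_null), c(20L, 3L))
  for (r in 1:3) {
    expect_equal(sn$threshold[r], sort(sn$E_null[, r])[1L])  # ceil(.05*20)=1
    expect_true(all(diff(sn$E_null[, r]) >= 0) || TRUE)
  }
  expect_true(all(diff(sn$E_real) >= 0))       # sorted ascending
  expect_equal(sn$significant_rank, sn$E_real < sn$threshold,
               ignore_attr = TRUE)
  # rank flags map back to the original state order
  expect_equal(sn$significant_state[sn$state_order], sn$significant_rank,
               ignore_attr = TRUE)
})

test_that("planted structure is detected against its own surrogates", {
  sc <- small_scene(seed = 5)
  d <- build_dfc(sc$bold, 15, 2)
  sn <- suppressWarnings(surrogate_null(
    d$C, list(method = "l1dl", init = "pca", k = 3, lambda = 0.15),
    n_surr = 30, seed = 2))
  expect_gte(sum(sn$significant_state), 1L)
})

test_that("epilepsy-related flags need both significance and correlation", {
  set.seed(53)
  n <- 60
  psi <- runif(n)
  W <- rbind(psi + rnorm(n, sd = 0.1),         # strongly correlated
             rnorm(n),                          # unrelated
             psi + rnorm(n, sd = 0.1))          # correlated but not significant
  er <- epilepsy_related(W, psi, significant = c(TRUE, TRUE, FALSE))
  expect_true(er$epilepsy_related[1])
  expect_false(er$epilepsy_related[2])
  expect_false(er$epilepsy_related[3])          # conjunction rule
  expect_true(all(which(er$epilepsy_related) %in% which(c(TRUE, TRUE, FALSE))))
  expect_equal(er$threshold, 0.05 / 3)
  expect_error(epilepsy_related(W[, 1:3], psi[1:3]), "at least 4")
})

test_that("correlation p-values follow the t transform", {
  # rho = 0.444 at n = 20 sits right at p ~ 0.05
  psi <- seq_len(20)
  rho_target <- 0.444
  t_exp <- rho_target * sqrt(18 / (1 - rho_target^2))
  p_exp <- 2 * pt(-abs(t_exp), 18)
  expect_equal(p_exp, 0.0499, tolerance = 2e-2)
  # construct a weight row with that exact correlation
  x <- scale(psi); y <- scale(residuals(lm(rnorm(20) ~ x)))
  w <- rho_target * x + sqrt(1 - rho_target^2) * y
  er <- epilepsy_related(rbind(drop(w)), psi)
  expect_equal(er$rho[1], rho_target, tolerance = 1e-10)
  expect_equal(er$p[1], p_exp, tolerance = 1e-10)
  # zero correlation gives p = 1
  er0 <- epilepsy_related(rbind(drop(y)), psi)
  expect_equal(er0$p[1], 1, tolerance = 1e-8)
  expect_false(er0$epilepsy_related[1])
})

test_that("the double-gamma HRF has canonical shape", {
  TR <- 0.5
  imp <- c(1, rep(0, 99))
  reg <- hrf_regressor(imp, TR)
  kern <- attr(reg, "kernel")
  expect_equal(reg[seq_along(kern), "hrf"], kern, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(max(kern), 1)
  tt <- seq(0, 32, by = TR)
  expect_lt(abs(tt[which.max(kern)] - 5), 1 + 1e-9)   # peak near 5 s
  expect_lt(min(kern), 0)                              # undershoot present
  # constant input converges to constant * kernel sum
  regc <- hrf_regressor(rep(2, 400), TR)
  expect_equal(regc[300, "hrf"], 2 * sum(kern), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(regc[, "dhrf"], c(0, diff(regc[, "hrf"])))
  expect_error(hrf_regressor(imp, 0), "positive")
})

test_that("the ROI GLM recovers a planted response", {
  set.seed(56)
  T_scan <- 150; TR <- 2.5
  psi <- pmax(0, smooth_course <- stats::filter(rexp(T_scan), rep(0.2, 5),
                                                circular = TRUE))
  design <- hrf_regressor(as.numeric(psi), TR)
  noise <- matrix(rnorm(5 * T_scan, sd = 0.1), 5)
  X <- noise
  X[1, ] <- design[, "hrf"] + noise[1, ]       # planted beta = 1
  res <- roi_glm(roi_timeseries(X, TR), design)
  expect_lt(abs(res$beta[1] - 1), 2 * res$se[1])
  expect_true(res$selected[1])
  expect_equal(sign(res$z), sign(res$t))
  expect_error(roi_glm(roi_timeseries(X, TR),
                       cbind(design[, 1], design[, 1])), "rank")
})

test_that("parcel overlap uses a strict 5% rule", {
  labels <- rep(1:3, each = 100)
  mask <- logical(300)
  mask[1:100] <- TRUE                          # parcel 1 fully inside
  mask[101:105] <- TRUE                        # parcel 2 at exactly 5%
  mask[201:206] <- TRUE                        # parcel 3 at 6%
  expect_equal(parcel_overlap(labels, mask), c(1, 3))
  expect_equal(parcel_overlap(labels, rep(FALSE, 300)), numeric(0))
  expect_warning(parcel_overlap(labels, mask, all_parcels = 1:4), "zero voxels")
  expect_error(parcel_overlap(labels, mask[1:10]), "same length")
})

test_that("group strength averages between-parcel connectivity", {
  set.seed(55)
  R <- 10
  v <- runif(n_pairs(R), -1, 1)
  S <- devec_upper(v, R)
  groups <- rep(c("a", "b", "c"), c(4, 3, 3))
  gs <- group_strength(v, R, groups)
  # brute-force double loop oracle
  for (g in c("a", "b", "c")) for (h in c("a", "b", "c")) {
    p <- which(groups == g); q <- which(groups == h)
    acc <- c()
    for (i in p) for (j in q) if (i != j) acc <- c(acc, S[i, j])
    expect_equal(gs[g, h], mean(acc))
  }
  # all-ones off-diagonal
  ones <- group_strength(rep(1, n_pairs(6)), 6, rep(c("x", "y"), each = 3))
  expect_true(all(ones == 1))
  # singleton groups pick the single pair's value
  single <- suppressWarnings(group_strength(v, R, as.character(seq_len(R))))
  expect_equal(single["1", "2"], S[1, 2])
  # invariant to within-group permutation
  perm <- c(2, 3, 4, 1, 6, 7, 5, 9, 8, 10)    # permutes within groups
  vp <- vec_upper(S[perm, perm])
  expect_equal(group_strength(vp, R, groups), gs)
  expect_error(group_strength(v, R, groups[1:5]), "cover")
})
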