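# Shared fixtures: all synthetic, generated at test time.

# Small scene exercising the whole pipeline quickly.
small_scene <- function(seed = 2L, R = 12L, K = 3L, T_scan = 150L, fs = 60) {
  synth_scene(R = R, K = K, T_scan = T_scan, fs = fs, seed = seed)
}

# Random dFC-like matrix: smooth mixtures of a few planted patterns plus
# noise, columns loosely in [-1, 1].
random_C <- function(M = 30L, T_w = 40L, k_true = 3L, seed = 1L,
                     noise = 0.1) {
  set.seed(seed)
  D <- matrix(stats::rnorm(M * k_true), M, k_true)
  D <- sweep(D, 2L, sqrt(colSums(D^2)), "/")
  A <- matrix(stats::rexp(k_true * T_w), k_true, T_w)
  D %*% A + noise * matrix(stats::rnorm(M * T_w), M, T_w)
}

unit_cols <- function(X) sweep(X, 2L, sqrt(colSums(X^2)), "/")

# Exhaustive-search lasso oracle for tiny instances: enumerates supports and
# sign patterns, solves the stationarity system and keeps the feasible
# solution with the lowest objective.
lasso_oracle <- function(c_vec, D, lambda) {
  k <- ncol(D)
  obj <- function(a) 0.5 * sum((c_vec - D %*% a)^2) + lambda * sum(abs(a))
  best <- rep(0, k)
  best_obj <- obj(best)
  for (size in seq_len(k)) {
    for (supp in utils::combn(k, size, simplify = FALSE)) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), size)))
      for (r in seq_len(nrow(signs))) {
        s <- signs[r, ]
        Ds <- D[, supp, drop = FALSE]
        a_s <- try(solve(crossprod(Ds), crossprod(Ds, c_vec) - lambda * s),
                   silent = TRUE)
        if (inherits(a_s, "try-error")) next
        if (any(sign(a_s) * s < 0)) next            # sign-consistency
        a <- rep(0, k); a[supp] <- a_s
        o <- obj(a)
        if (o < best_obj - 1e-12) { best <- a; best_obj <- o }
      }
    }
  }
  best
}

# Max KKT violation of a lasso solution (0 = exact stationarity).
lasso_kkt_gap <- function(c_vec, D, a, lambda) {
  g <- crossprod(D, c_vec - D %*% a)   # = lambda * sign(a_j) on the support
  gap <- 0
  for (j in seq_along(a)) {
    gap <- max(gap, if (a[j] != 0) abs(g[j] - lambda * sign(a[j]))
               else max(0, abs(g[j]) - lambda))
  }
  gap
}

# Exhaustive l1 k-means oracle for k = 2: tries every assignment.
kmeans_l1_oracle_k2 <- function(C) {
  T_w <- ncol(C)
  best_obj <- Inf
  best <- NULL
  for (code in 1:(2^T_w - 2)) {
    asg <- as.integer(intToBits(code))[seq_len(T_w)] + 1L
    if (length(unique(asg)) < 2L) next
    obj <- 0
    for (g in 1:2) {
      block <- C[, asg == g, drop = FALSE]
      med <- apply(block, 1L, stats::median)
      obj <- obj + sum(abs(block - med))
    }
    if (obj < best_obj) { best_obj <- obj; best <- asg }
  }
  list(objective = best_obj, assignment = best)
}
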