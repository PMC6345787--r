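# Factorization of the dFC matrix C (M x T) into states D (M x k) and weight
# time-courses A (k x T):  C ~ D A.
#
# Four routes, all special cases of the same reconstruction objective
# ||C - DA||_F^2 under different constraints on A:
#   * k-means with l1 distance (k-CL): A one-hot, D the cluster medians;
#   * PCA: D orthonormal eigenvectors, A dense projections;
#   * l0-DL: per-column support |a_i|_0 <= s, coded by orthogonal matching
#     pursuit;
#   * l1-DL: per-column lasso penalty lambda * |a_i|_1, coded by coordinate
#     descent.
# The DL routes alternate sparse coding and dictionary update (batch
# alternating minimization); an acceptance test keeps the recorded objective
# trace non-increasing.

new_state_set <- function(D, A, method, init = NA_character_, k = ncol(D),
                          lambda = NA_real_, objective_trace = numeric(0),
                          seed = NA_integer_, converged = TRUE,
                          degenerate = integer(0), extra = list()) {
  structure(c(list(D = D, A = A, method = method, init = init, k = k,
                   lambda = lambda, objective_trace = objective_trace,
                   seed = seed, converged = converged, degenerate = degenerate),
              extra),
            class = "state_set")
}

#' @export
print.state_set <- function(x, ...) {
  cat(sprintf("dFC state set: method %s%s, k = %d, M = %d, T = %d%s\n",
              x$method,
              if (!is.na(x$init)) paste0(" (init ", x$init, ")") else "",
              x$k, nrow(x$D), ncol(x$A),
              if (!is.na(x$lambda)) sprintf(", lambda = %g", x$lambda) else ""))
  invisible(x)
}

# Flip each state so its largest-magnitude entry is positive (PCA/DL signs
# are arbitrary); the matching A row is negated to keep the product fixed.
fix_signs <- function(D, A) {
  for (j in seq_len(ncol(D))) {
    peak <- which.max(abs(D[, j]))
    if (D[peak, j] < 0) {
      D[, j] <- -D[, j]
      A[j, ] <- -A[j, ]
    }
  }
  list(D = D, A = A)
}

#' k-means clustering of dFC windows with l1 distance
#'
#' Lloyd iterations under the l1 metric: assignment to the nearest centroid
#' in l1 distance, centroid update by the component-wise median.  The best of
#' `n_rep` random restarts (by total l1 objective) is returned.  An emptied
#' cluster is re-seeded at the column farthest (l1) from its current
#' centroid.
#'
#' @param C M x T dFC matrix.
#' @param k number of clusters (1 <= k <= T).
#' @param n_rep random restarts (default 100).
#' @param max_iter Lloyd iterations per restart.
#' @param seed integer seed.
#' @return A `state_set` with `D` = centroids, `A` = one-hot occupancy,
#'   `objective_trace` = the winning restart's objective per iteration, and
#'   `extra` fields `assignment`, `objective`.
#' @export
fit_kmeans_l1 <- function(C, k, n_rep = 100L, max_iter = 100L, seed = 1L) {
  C <- as.matrix(C)
  T_w <- ncol(C)
  if (k < 1L || k > T_w) stop("k must be in [1, T]")
  best <- NULL
  with_seed(seed, {
    for (rep in seq_len(n_rep)) {
      res <- kmeans_l1_once(C, k, max_iter)
      if (is.null(best) || res$objective < best$objective) best <- res
    }
  })
  A <- matrix(0, k, T_w)
  A[cbind(best$assignment, seq_len(T_w))] <- 1
  new_state_set(best$centroids, A, method = "kcl", k = k, seed = seed,
                objective_trace = best$trace,
                extra = list(assignment = best$assignment,
                             objective = best$objective))
}

kmeans_l1_once <- function(C, k, max_iter) {
  T_w <- ncol(C)
  D <- C[, sample.int(T_w, k), drop = FALSE]
  assign_old <- rep(0L, T_w)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dist <- l1_dist_to_centroids(C, D)
    assignment <- max.col(-t(dist), ties.method = "first")
    # re-seed empty clusters at the worst-fit column
    for (j in which(tabulate(assignment, k) == 0L)) {
      far <- which.max(dist[cbind(assignment, seq_len(T_w))])
      assignment[far] <- j
      dist[j, far] <- 0
    }
    for (j in seq_len(k)) {
      D[, j] <- apply(C[, assignment == j, drop = FALSE], 1L, stats::median)
    }
    obj <- sum(l1_dist_to_centroids(C, D)[cbind(assignment, seq_len(T_w))])
    trace <- c(trace, obj)
    if (identical(assignment, assign_old)) break
    assign_old <- assignment
  }
  list(centroids = D, assignment = assignment, objective = obj, trace = trace)
}

l1_dist_to_centroids <- function(C, D) {
  t(vapply(seq_len(ncol(D)),
           function(j) colSums(abs(C - D[, j])), numeric(ncol(C))))
}

#' PCA factorization of the dFC matrix
#'
#' Rows of C are centered across windows; states are the top-k left singular
#' vectors (unit norm, ordered by decreasing explained variance) and weights
#' the projections of the centered matrix onto them.
#'
#' @param C M x T dFC matrix.
#' @param k number of components (default 20, <= min(M, T)).
#' @return A `state_set` with extra fields `explained_var` (variance per
#'   component) and `center` (row means); components beyond the numerical
#'   rank are listed in `degenerate`.
#' @export
fit_pca <- function(C, k = 20L) {
  C <- as.matrix(C)
  if (k > min(dim(C))) stop("k must be <= min(M, T)")
  ctr <- rowMeans(C)
  Cc <- C - ctr
  sv <- svd(Cc, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  degenerate <- which(d < max(sv$d) * 1e-12)
  D <- sv$u
  A <- d * t(sv$v)           # D^T Cc = diag(d) V^T
  fx <- fix_signs(D, A)
  new_state_set(fx$D, fx$A, method = "pca", k = k,
                degenerate = degenerate,
                extra = list(explained_var = d^2 / (ncol(C) - 1L),
                             center = ctr))
}

#' Lasso sparse coding of dFC windows against a fixed dictionary
#'
#' Solves, per column c of C,
#' `argmin_a 0.5 * ||c - D a||_2^2 + lambda * ||a||_1`
#' by cyclic coordinate descent (vectorized across columns), iterated until
#' the KKT stationarity conditions hold within `kkt_tol`.
#'
#' @param C M x T matrix.
#' @param D M x k dictionary with unit-l2-norm columns.
#' @param lambda nonnegative l1 penalty.
#' @param A_init optional warm start (k x T).
#' @param kkt_tol stationarity tolerance.
#' @param max_sweeps coordinate sweeps cap.
#' @return k x T coefficient matrix.
#' @export
sparse_code_l1 <- function(C, D, lambda, A_init = NULL, kkt_tol = 1e-7,
                           max_sweeps = 5000L) {
  if (lambda < 0) stop("lambda must be >= 0")
  k <- ncol(D)
  T_w <- ncol(C)
  G <- crossprod(D)
  B <- crossprod(D, C)
  A <- if (is.null(A_init)) matrix(0, k, T_w) else A_init
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(k)) {
      r <- B[j, ] - G[j, ] %*% A + G[j, j] * A[j, ]
      a_new <- soft_threshold(drop(r), lambda) / G[j, j]
      delta <- max(delta, max(abs(a_new - A[j, ])))
      A[j, ] <- a_new
    }
    if (delta < kkt_tol * 0.1) break
  }
  A
}

soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

#' Orthogonal matching pursuit coding with fixed support size
#'
#' Per column, greedily selects up to `s` atoms by maximal absolute
#' correlation with the residual; coefficients are the least-squares fit on
#' the selected support.
#'
#' @param C M x T matrix.
#' @param D M x k dictionary with unit-norm columns.
#' @param s maximum nonzeros per column (1 <= s <= k).
#' @return k x T coefficient matrix with column support <= s.
#' @export
sparse_code_l0 <- function(C, D, s) {
  k <- ncol(D)
  if (s < 1L || s > k) stop("s must be in [1, k]")
  A <- matrix(0, k, ncol(C))
  for (t in seq_len(ncol(C))) {
    c_t <- C[, t]
    res <- c_t
    supp <- integer(0)
    for (step in seq_len(s)) {
      corr <- abs(crossprod(D, res))
      corr[supp] <- -Inf
      j <- which.max(corr)
      supp <- c(supp, j)
      coef <- stats::lm.fit(D[, supp, drop = FALSE], c_t)$coefficients
      res <- c_t - D[, supp, drop = FALSE] %*% coef
      if (sum(res^2) < 1e-20) break
    }
    A[supp, t] <- coef
  }
  A
}

#' Dictionary update for fixed sparse codes
#'
#' Minimizes `||C - D A||_F^2` over D for fixed A — by the normal equations
#' when `A A^T` is well conditioned, otherwise by block coordinate descent
#' over atoms with residual re-fit — then rescales each atom to unit l2 norm
#' with the matching row of A rescaled inversely (the product D A is
#' unchanged).  Atoms whose A row is all zero are re-seeded at the
#' worst-reconstructed column of C.
#'
#' @param C M x T matrix.
#' @param A k x T coefficient matrix (fixed).
#' @param D_prev previous dictionary (used for unused-atom re-seeding and as
#'   the block-descent start).
#' @return List with updated `D` (unit-norm columns) and rescaled `A`.
#' @export
update_dictionary <- function(C, A, D_prev) {
  k <- nrow(A)
  D <- D_prev
  used <- rowSums(A != 0) > 0L
  if (any(used)) {
    Au <- A[used, , drop = FALSE]
    F_ <- tcrossprod(Au)
    E_ <- tcrossprod(C, Au)
    if (rcond(F_) > 1e-12) {
      D[, used] <- t(solve(F_, t(E_)))
    } else {
      for (pass in 1:10) {
        for (j in which(used)) {
          a_j <- A[j, ]
          R_j <- C - D %*% A + outer(D[, j], a_j)
          D[, j] <- R_j %*% a_j / sum(a_j^2)
        }
      }
    }
  }
  # re-seed unused atoms at the worst-reconstructed column
  if (any(!used)) {
    resid <- colSums((C - D %*% A)^2)
    for (j in which(!used)) {
      w <- which.max(resid)
      D[, j] <- C[, w]
      resid[w] <- -Inf
    }
  }
  nrm <- sqrt(colSums(D^2))
  nrm[nrm == 0] <- 1
  D <- sweep(D, 2L, nrm, "/")
  A <- A * nrm
  list(D = D, A = A)
}

dl_objective <- function(C, D, A, lambda, norm) {
  recon <- 0.5 * sum((C - D %*% A)^2)
  pen <- if (norm == "l1") lambda * sum(abs(A)) else 0
  (recon + pen) / ncol(C)
}

#' Dictionary learning of dFC states by alternating minimization
#'
#' Alternates sparse coding (lasso coordinate descent for `norm = "l1"`, OMP
#' for `norm = "l0"`) with the dictionary update of [update_dictionary()]
#' until the relative objective change falls below `tol` or `n_iter` is
#' reached.  An iterate that would raise the objective is rejected and the
#' previous one returned, so `objective_trace` is non-increasing.
#'
#' @param C M x T dFC matrix.
#' @param k number of states (<= T).
#' @param lambda l1 penalty (`norm = "l1"`), or integer support size s
#'   (`norm = "l0"`, in `[2, min(k - 1, 6)]` for the standard grid; any value
#'   in `[1, k]` is accepted).
#' @param norm `"l1"` or `"l0"`.
#' @param init dictionary initialization: `"random"` (k distinct columns of
#'   C), `"kcl"` (normalized l1 k-means centroids) or `"pca"` (top-k
#'   eigenvectors).
#' @param n_iter maximum alternations.
#' @param tol relative objective-change convergence tolerance.
#' @param seed integer seed (random init and the k-means initializer).
#' @param init_nrep restarts for the k-means initializer.
#' @return A `state_set` with unit-norm states (largest-magnitude entry
#'   positive), sparse weights `A`, `objective_trace`, and `converged`.
#' @export
fit_dl <- function(C, k, lambda, norm = c("l1", "l0"),
                   init = c("random", "kcl", "pca"), n_iter = 100L,
                   tol = 1e-5, seed = 1L, init_nrep = 10L) {
  C <- as.matrix(C)
  norm <- match.arg(norm)
  init <- match.arg(init)
  if (k > ncol(C)) stop("k must be <= T")
  if (norm == "l0") {
    lambda <- as.integer(lambda)
    if (lambda < 1L || lambda > k) stop("l0 sparsity must be in [1, k]")
  }
  D <- switch(init,
    random = with_seed(seed, {
      D0 <- C[, sample.int(ncol(C), k), drop = FALSE]
      sweep(D0, 2L, pmax(sqrt(colSums(D0^2)), 1e-12), "/")
    }),
    kcl = {
      ks <- fit_kmeans_l1(C, k, n_rep = init_nrep, seed = seed)
      sweep(ks$D, 2L, pmax(sqrt(colSums(ks$D^2)), 1e-12), "/")
    },
    pca = fit_pca(C, k)$D)
  code <- function(C, D, A_init) {
    if (norm == "l1") sparse_code_l1(C, D, lambda, A_init = A_init)
    else sparse_code_l0(C, D, lambda)
  }
  A <- code(C, D, NULL)
  obj <- dl_objective(C, D, A, lambda, norm)
  trace <- obj
  converged <- FALSE
  if (n_iter > 0L) {
    for (it in seq_len(n_iter)) {
      upd <- update_dictionary(C, A, D)
      A_new <- code(C, upd$D, upd$A)
      obj_new <- dl_objective(C, upd$D, A_new, lambda, norm)
      if (obj_new > obj) { converged <- TRUE; break }  # monotone safeguard
      rel <- (obj - obj_new) / max(obj, .Machine$double.eps)
      D <- upd$D; A <- A_new; obj <- obj_new
      trace <- c(trace, obj)
      if (rel < tol) { converged <- TRUE; break }
    }
  } else converged <- TRUE
  if (!converged) warning("dictionary learning did not converge in n_iter iterations")
  fx <- fix_signs(D, A)
  new_state_set(fx$D, fx$A, method = if (norm == "l1") "l1dl" else "l0dl",
                init = init, k = k, lambda = lambda, objective_trace = trace,
                seed = seed, converged = converged,
                extra = list(objective = obj))
}

#' Non-sparse state weights
#'
#' `W[i, t]` is the Pearson correlation over the M connectivity pairs between
#' state i and window t — a dense expression time-course comparable across
#' all factorization methods.
#'
#' @param C M x T dFC matrix (M >= 3).
#' @param D M x k state matrix.
#' @return k x T matrix in `[-1, 1]`.
#' @export
nonsparse_weights <- function(C, D) {
  C <- as.matrix(C); D <- as.matrix(D)
  if (nrow(C) < 3L) stop("need M >= 3 connectivity pairs")
  if (any(apply(D, 2L, stats::sd) == 0)) stop("zero-variance state")
  if (any(apply(C, 2L, stats::sd) == 0)) stop("zero-variance dFC column")
  t(stats::cor(C, D))
}

#' Match estimated states to reference states by spatial correlation
#'
#' Greedy one-to-one assignment: the (reference, estimate) pair with the
#' largest absolute Pearson correlation is matched first, both are removed,
#' and so on.  Used to compare a fit against planted ground truth despite
#' arbitrary state order and sign.
#'
#' @param D_est M x k estimated state matrix.
#' @param reference list of reference state vectors (or M x K matrix).
#' @return data.frame with columns `reference`, `estimate`, `abs_cor`.
#' @export
match_states <- function(D_est, reference) {
  if (is.list(reference)) reference <- do.call(cbind, reference)
  cm <- abs(stats::cor(reference, D_est))
  K <- ncol(reference)
  out <- data.frame(reference = integer(0), estimate = integer(0),
                    abs_cor = numeric(0))
  for (step in seq_len(min(K, ncol(D_est)))) {
    idx <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    out <- rbind(out, data.frame(reference = idx[1L], estimate = idx[2L],
                                 abs_cor = cm[idx[1L], idx[2L]]))
    cm[idx[1L], ] <- NA
    cm[, idx[2L]] <- NA
  }
  out[order(out$reference), ]
}

#' Automatic lasso penalty grid
#'
#' Five log-spaced values in `[0.05, 0.5] * median(lambda_max)` where
#' `lambda_max` of a column c is `max |D^T c|`, the smallest penalty that
#' zeroes its code — a reproducible stand-in for per-dataset hand tuning
#' that keeps solutions at intermediate sparsity.
#'
#' @param C M x T matrix.
#' @param D_init dictionary used to gauge the penalty scale (unit-norm
#'   columns; typically the PCA initialization at the largest k).
#' @param n grid size.
#' @param range multiplier range on the median `lambda_max`.
#' @return Increasing numeric vector of length `n`.
#' @export
auto_lambda_grid <- function(C, D_init, n = 5L, range = c(0.05, 0.5)) {
  lmax <- apply(abs(crossprod(D_init, C)), 2L, max)
  med <- stats::median(lmax)
  exp(seq(log(range[1L] * med), log(range[2L] * med), length.out = n))
}
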