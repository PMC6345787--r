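# EEG-informed model selection: correlate each state's non-sparse weight
# time-course with the window-aligned EEG-PSI metric, grid-search k (and the
# sparsity penalty for dictionary learning), and apply the parsimony rule —
# the smallest k reaching 90% of the best correlation found anywhere on the
# grid.

#' Align a per-TR EEG-PSI metric to sliding windows
#'
#' @param psi_metric numeric vector, one value per TR.
#' @param windows window list from [make_windows()] (0-based, half-open).
#' @param method `"mean"` (average over in-window TRs, default) or
#'   `"center"` (the window's central TR).
#' @return Numeric vector, one value per window.
#' @export
psi_to_windows <- function(psi_metric, windows, method = c("mean", "center")) {
  method <- match.arg(method)
  last_end <- max(vapply(windows, `[`, numeric(1L), 2L))
  if (length(psi_metric) < last_end)
    stop(sprintf("psi metric has %d TRs but windows extend to %d",
                 length(psi_metric), last_end))
  vapply(windows, function(w) {
    idx <- (w[1L] + 1L):w[2L]
    if (method == "mean") mean(psi_metric[idx])
    else psi_metric[idx[ceiling(length(idx) / 2)]]
  }, numeric(1L))
}

#' Correlation of state weight time-courses with the EEG-PSI metric
#'
#' @param W k x T non-sparse weight matrix (see [nonsparse_weights()]).
#' @param psi_win window-aligned PSI vector (length T, >= 3 windows).
#' @param use_abs report `|rho|` (for PCA, whose state signs are arbitrary).
#' @return List with `rho` (per state), `best` (argmax index), and
#'   `rho_best`.
#' @export
state_psi_rho <- function(W, psi_win, use_abs = FALSE) {
  if (length(psi_win) < 3L) stop("need at least 3 windows")
  if (stats::sd(psi_win) == 0) stop("zero-variance PSI window vector")
  rho <- unname(apply(W, 1L, function(w) {
    if (stats::sd(w) == 0) return(NA_real_)
    stats::cor(w, psi_win)
  }))
  if (use_abs) rho <- abs(rho)
  best <- which.max(rho)
  list(rho = rho, best = best, rho_best = rho[best])
}

#' Apply the parsimony selection rule to a correlation table
#'
#' `chosen_k` is the minimum k whose best rho (over lambda) reaches 90% of
#' the global maximum; `chosen_lambda` maximizes rho at that k.
#'
#' @param rho_table data.frame with columns `k`, `lambda`, `rho`.
#' @param frac fraction of the global maximum to reach (default 0.9).
#' @return List with `rho_max`, `chosen_k`, `chosen_lambda`, `rho_star_max`.
#' @export
apply_selection_rule <- function(rho_table, frac = 0.9) {
  valid <- rho_table[is.finite(rho_table$rho), , drop = FALSE]
  if (nrow(valid) == 0L) stop("no valid grid cell")
  rho_max <- max(valid$rho)
  per_k <- vapply(split(valid$rho, valid$k), max, numeric(1L))
  ks <- as.numeric(names(per_k))
  chosen_k <- min(ks[per_k >= frac * rho_max])
  at_k <- valid[valid$k == chosen_k, , drop = FALSE]
  chosen <- at_k[which.max(at_k$rho), ]
  list(rho_max = rho_max, chosen_k = as.integer(chosen_k),
       chosen_lambda = chosen$lambda, rho_star_max = chosen$rho)
}

#' Grid search over k (and lambda) guided by the EEG-PSI metric
#'
#' Fits the requested factorization for every k in `k_range` (and every
#' lambda for the DL methods), correlates non-sparse weights with the
#' window-aligned EEG-PSI, and applies the parsimony rule of
#' [apply_selection_rule()].  For PCA a single k = max(k_range) fit is
#' reused, truncated to the leading k components; absolute correlations are
#' used there since component signs are arbitrary.
#'
#' @param C M x T dFC matrix.
#' @param psi_win window-aligned EEG-PSI (length T).
#' @param method `"l1dl"`, `"l0dl"`, `"kcl"` or `"pca"`.
#' @param k_range integer vector of k values (default 2:20; 3:20 is the
#'   conventional range for `"l0dl"`).
#' @param lambda_grid for `"l1dl"` a numeric grid (default: the automatic
#'   grid of [auto_lambda_grid()] on the PCA initialization); for `"l0dl"`
#'   integer support sizes (default per k: `2:min(k - 1, 6)`); ignored
#'   otherwise.
#' @param init DL initialization (default `"pca"`).
#' @param seed integer seed.
#' @param n_rep k-means restarts (method `"kcl"` or init `"kcl"`).
#' @param n_iter,tol DL iteration controls, see [fit_dl()].
#' @return An object of class `selection_report`: list with `rho_table`
#'   (k, lambda, rho, best_state per cell), `rho_max`, `rho_star_max`,
#'   `chosen_k`, `chosen_lambda`, `best_state` (index within the chosen
#'   fit), `fit` (the chosen `state_set`), `W` (its non-sparse weights),
#'   `psi_win`, `method`, `init`, `use_abs`.
#' @export
grid_select <- function(C, psi_win, method = c("l1dl", "l0dl", "kcl", "pca"),
                        k_range = 2:20, lambda_grid = NULL, init = "pca",
                        seed = 1L, n_rep = 100L, n_iter = 100L, tol = 1e-5) {
  method <- match.arg(method)
  C <- as.matrix(C)
  if (length(k_range) == 0L) stop("empty k_range")
  use_abs <- method == "pca"
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range <= ncol(C)]
  rows <- list()
  fits <- list()
  top <- if (method %in% c("pca", "l1dl")) fit_pca(C, max(k_range)) else NULL
  if (method == "pca") {
    for (k in k_range) {
      W <- nonsparse_weights(C, top$D[, seq_len(k), drop = FALSE])
      sr <- state_psi_rho(W, psi_win, use_abs = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(k = k, lambda = NA_real_,
                                              rho = sr$rho_best,
                                              best_state = sr$best)
    }
  } else if (method == "kcl") {
    for (k in k_range) {
      fit <- try(fit_kmeans_l1(C, k, n_rep = n_rep, seed = seed), silent = TRUE)
      rows[[length(rows) + 1L]] <- grid_cell(fit, C, psi_win, k, NA_real_,
                                             use_abs)
      fits[[cell_key(k, NA_real_)]] <- fit
    }
  } else {
    if (method == "l1dl" && is.null(lambda_grid))
      lambda_grid <- auto_lambda_grid(C, top$D)
    for (k in k_range) {
      grid_k <- if (method == "l0dl") {
        g <- if (is.null(lambda_grid)) {
          if (min(k - 1L, 6L) >= 2L) 2L:min(k - 1L, 6L) else integer(0)
        } else as.integer(lambda_grid)
        g[g >= 1L & g <= k]
      } else lambda_grid
      if (length(grid_k) == 0L) next
      for (lam in grid_k) {
        fit <- try(fit_dl(C, k, lam, norm = substr(method, 1L, 2L),
                          init = init, n_iter = n_iter, tol = tol,
                          seed = seed, init_nrep = n_rep),
                   silent = TRUE)
        rows[[length(rows) + 1L]] <- grid_cell(fit, C, psi_win, k, lam,
                                               use_abs)
        fits[[cell_key(k, lam)]] <- fit
      }
    }
  }
  rho_table <- do.call(rbind, rows)
  sel <- apply_selection_rule(rho_table)
  chosen_fit <- if (method == "pca") {
    new_state_set(top$D[, seq_len(sel$chosen_k), drop = FALSE],
                  top$A[seq_len(sel$chosen_k), , drop = FALSE],
                  method = "pca", k = sel$chosen_k,
                  extra = list(center = top$center))
  } else {
    fits[[cell_key(sel$chosen_k, sel$chosen_lambda)]]
  }
  W <- nonsparse_weights(C, chosen_fit$D)
  best_state <- rho_table$best_state[
    rho_table$k == sel$chosen_k &
      (is.na(rho_table$lambda) |
         (!is.na(sel$chosen_lambda) & rho_table$lambda == sel$chosen_lambda))][1L]
  structure(list(rho_table = rho_table, rho_max = sel$rho_max,
                 rho_star_max = sel$rho_star_max, chosen_k = sel$chosen_k,
                 chosen_lambda = sel$chosen_lambda, best_state = best_state,
                 fit = chosen_fit, W = W, psi_win = psi_win, method = method,
                 init = if (method %in% c("l1dl", "l0dl")) init else NA,
                 use_abs = use_abs, seed = seed),
            class = "selection_report")
}

cell_key <- function(k, lambda) sprintf("k%d_l%.8g", k, lambda)

grid_cell <- function(fit, C, psi_win, k, lam, use_abs) {
  if (inherits(fit, "try-error")) {
    warning(sprintf("fit failed at k=%d lambda=%s; cell marked invalid",
                    k, format(lam)))
    return(data.frame(k = k, lambda = lam, rho = NA_real_,
                      best_state = NA_integer_))
  }
  W <- nonsparse_weights(C, fit$D)
  sr <- state_psi_rho(W, psi_win, use_abs = use_abs)
  data.frame(k = k, lambda = lam, rho = sr$rho_best, best_state = sr$best)
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(
    "Model selection (%s): chosen k = %d%s, rho*_max = %.3f (rho_max = %.3f), best state #%d\n",
    x$method, x$chosen_k,
    if (!is.na(x$chosen_lambda)) sprintf(", lambda = %.4g", x$chosen_lambda) else "",
    x$rho_star_max, x$rho_max, x$best_state))
  invisible(x)
}

#' Spatial correlation of the best state with high-PSI windows
#'
#' Scans thresholds `pct * max(psi_win)` for pct over `pct_range` in steps
#' of 0.01, keeps the pct whose surviving-window count is closest to
#' `target_n` (ties to the higher pct), and correlates the best state with
#' the mean dFC column over those windows.  High-PSI windows are taken as
#' representative of intense epileptiform activity.
#'
#' @param C M x T dFC matrix.
#' @param psi_win window-aligned PSI vector.
#' @param d_state the best state's M-vector (dFC_max).
#' @param pct_range threshold scan range (default `c(0.90, 0.95)`).
#' @param target_n desired number of surviving windows (default 5).
#' @return List with `pct` (threshold used), `windows` (surviving indices),
#'   `rho_dfc`.
#' @export
rho_dfc <- function(C, psi_win, d_state, pct_range = c(0.90, 0.95),
                    target_n = 5L) {
  if (target_n < 2L) stop("target_n must be >= 2")
  pcts <- seq(pct_range[1L], pct_range[2L], by = 0.01)
  counts <- vapply(pcts, function(p) sum(psi_win >= p * max(psi_win)),
                   numeric(1L))
  if (all(counts == 0L)) stop("no window survives any threshold")
  dev <- abs(counts - target_n)
  best <- which(dev == min(dev))
  pct <- pcts[max(best)]                      # ties -> higher pct
  surv <- which(psi_win >= pct * max(psi_win))
  avg <- rowMeans(C[, surv, drop = FALSE])
  list(pct = pct, windows = surv, rho_dfc = stats::cor(d_state, avg))
}

#' Control correlation with low-PSI windows
#'
#' Correlates the best state with the mean dFC column over windows whose PSI
#' lies at or below `factor` times its minimum — periods essentially free of
#' epileptiform activity.  The minimizing window always qualifies.
#'
#' @param C M x T dFC matrix.
#' @param psi_win window-aligned PSI vector.
#' @param d_state the best state's M-vector.
#' @param factor multiple of the minimum PSI (default 1.10).
#' @return List with `windows` and `rho_ctrl`.
#' @export
rho_ctrl <- function(C, psi_win, d_state, factor = 1.10) {
  surv <- which(psi_win <= factor * min(psi_win))
  avg <- rowMeans(C[, surv, drop = FALSE])
  list(windows = surv, rho_ctrl = stats::cor(d_state, avg))
}
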