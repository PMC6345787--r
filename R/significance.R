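# Statistical assessment of estimated dFC states.
#
# Significance is established against phase-randomized surrogates of C: each
# connectivity pair keeps its amplitude spectrum but gets fresh uniform
# phases, destroying the temporal structure the factorization exploits.
# Because state labels are arbitrary across fits, real and null per-state
# reconstruction errors are matched purely by sorted rank.  Epilepsy-related
# states are the surrogate-significant ones whose non-sparse weights
# correlate with the EEG-PSI metric at Bonferroni-corrected significance.

#' Phase-randomized surrogate of a dFC matrix
#'
#' Per row: DFT, an independent uniform(0, 2pi) phase added to every
#' positive-frequency bin, conjugate-mirrored to negative frequencies; DC
#' (and Nyquist for even T) stay real.  Row amplitude spectra — and hence
#' row means and autocovariance — are preserved exactly.
#'
#' @param C numeric matrix (rows are connectivity pairs, columns windows,
#'   T >= 4).
#' @param seed integer seed.
#' @return Real matrix of the same dimensions.
#' @export
phase_randomize <- function(C, seed = 1L) {
  C <- as.matrix(C)
  n <- ncol(C)
  if (n < 4L) stop("need at least 4 columns")
  half <- (n - 1L) %/% 2L                     # strictly positive, non-Nyquist
  with_seed(seed, {
    out <- t(apply(C, 1L, function(row) {
      X <- stats::fft(row)
      theta <- stats::runif(half, 0, 2 * pi)
      pos <- 2L:(half + 1L)
      X[pos] <- X[pos] * exp(1i * theta)
      X[n + 2L - pos] <- Conj(X[pos])         # mirror; DC/Nyquist untouched
      Re(stats::fft(X, inverse = TRUE)) / n
    }))
    out
  })
}

#' Surrogate null distribution of per-state reconstruction errors
#'
#' Refits the chosen factorization on `n_surr` phase-randomized copies of C.
#' For every fit (real and surrogate) the single-state reconstruction error
#' `E(i) = ||C - d_i a_i||_F^2` is computed and sorted ascending; rank r of
#' the real fit is tested against the empirical fifth percentile (the
#' `ceiling(0.05 * n_surr)`-th smallest value) of the null at the same rank.
#'
#' @param C M x T dFC matrix.
#' @param fit_params list with `method` (`"l1dl"` or `"l0dl"`), `init`, `k`,
#'   `lambda` — typically the chosen model of a [grid_select()] report (a
#'   `selection_report` is accepted directly).
#' @param n_surr number of surrogates (default 100).
#' @param seed integer seed.
#' @param alpha percentile level of the threshold (default 0.05).
#' @return An object of class `surrogate_null`: list with `E_real` (sorted),
#'   `state_order` (state index per rank), `E_null` (n_ok x k, rows sorted),
#'   `threshold` (per rank), `significant_rank`, `significant_state`
#'   (per original state index), `n_surr`, `seed`.
#' @export
surrogate_null <- function(C, fit_params, n_surr = 100L, seed = 1L,
                           alpha = 0.05) {
  C <- as.matrix(C)
  if (inherits(fit_params, "selection_report")) {
    fit_params <- list(method = fit_params$method, init = fit_params$init,
                       k = fit_params$chosen_k,
                       lambda = fit_params$chosen_lambda)
  }
  fitter <- function(X, s) {
    switch(fit_params$method,
      l1dl = fit_dl(X, fit_params$k, fit_params$lambda, norm = "l1",
                    init = fit_params$init, seed = s),
      l0dl = fit_dl(X, fit_params$k, fit_params$lambda, norm = "l0",
                    init = fit_params$init, seed = s),
      kcl = fit_kmeans_l1(X, fit_params$k, seed = s),
      pca = fit_pca(X, fit_params$k),
      stop("unsupported method: ", fit_params$method))
  }
  real_fit <- fitter(C, seed)
  E_real_raw <- state_errors(C, real_fit$D, real_fit$A)
  ord <- order(E_real_raw)
  E_real <- E_real_raw[ord]
  k <- fit_params$k
  E_null <- matrix(NA_real_, n_surr, k)
  for (i in seq_len(n_surr)) {
    Cs <- phase_randomize(C, seed = seed + i)
    fit <- try(fitter(Cs, seed + i), silent = TRUE)
    if (inherits(fit, "try-error")) next
    E_null[i, ] <- sort(state_errors(Cs, fit$D, fit$A))
  }
  ok <- stats::complete.cases(E_null)
  if (mean(ok) < 0.9)
    stop(sprintf("only %d/%d surrogate fits succeeded (need >= 90%%)",
                 sum(ok), n_surr))
  if (any(!ok)) warning(sprintf("%d surrogate fit(s) failed and were dropped",
                                sum(!ok)))
  E_null <- E_null[ok, , drop = FALSE]
  q_idx <- max(1L, ceiling(alpha * nrow(E_null)))
  threshold <- apply(E_null, 2L, function(col) sort(col)[q_idx])
  significant_rank <- E_real < threshold
  significant_state <- logical(k)
  significant_state[ord] <- significant_rank
  structure(list(E_real = E_real, state_order = ord, E_null = E_null,
                 threshold = threshold, significant_rank = significant_rank,
                 significant_state = significant_state,
                 n_surr = nrow(E_null), seed = seed, fit = real_fit),
            class = "surrogate_null")
}

# E(i) = ||C - d_i a_i||_F^2 for each state alone.
state_errors <- function(C, D, A) {
  vapply(seq_len(ncol(D)),
         function(i) sum((C - outer(D[, i], A[i, ]))^2), numeric(1L))
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf("Surrogate test: %d/%d states significant (n_surr = %d)\n",
              sum(x$significant_state), length(x$significant_state), x$n_surr))
  invisible(x)
}

#' Flag epilepsy-related states
#'
#' Among surrogate-significant states, those whose non-sparse weight
#' time-course correlates with the EEG-PSI metric at Bonferroni-corrected
#' significance (two-sided p of the Pearson correlation via
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`, threshold `alpha / k`).
#'
#' @param W k x T non-sparse weight matrix.
#' @param psi_win window-aligned EEG-PSI vector (length T, n >= 4).
#' @param significant logical vector of surrogate-significant flags (per
#'   state); defaults to all `TRUE` (no surrogate gating).
#' @param alpha family-wise level (default 0.05).
#' @param use_abs use `|rho|` (PCA).
#' @return List with `rho`, `p` (uncorrected, two-sided), `threshold`
#'   (`alpha / k`), `epilepsy_related` (logical per state).
#' @export
epilepsy_related <- function(W, psi_win, significant = rep(TRUE, nrow(W)),
                             alpha = 0.05, use_abs = FALSE) {
  n <- length(psi_win)
  if (n < 4L) stop("need at least 4 windows")
  k <- nrow(W)
  rho <- unname(apply(W, 1L, function(w)
    if (stats::sd(w) == 0) NA_real_ else stats::cor(w, psi_win)))
  if (use_abs) rho <- abs(rho)
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  flags <- significant & !is.na(p) & p < alpha / k
  list(rho = rho, p = p, threshold = alpha / k, epilepsy_related = flags)
}

#' HRF-convolved design columns for an EEG-PSI regressor
#'
#' Convolves the metric with a canonical double-gamma hemodynamic response
#' function (response peak delay 6 s, undershoot delay 16 s, unit
#' dispersions, undershoot ratio 1/6, 32 s support, peak normalized to 1),
#' causally and truncated to the input length, and appends the first
#' difference as a temporal-derivative column.
#'
#' @param psi_metric numeric vector, one value per TR.
#' @param TR repetition time in seconds.
#' @return Matrix with columns `hrf` and `dhrf`; the sampled kernel is
#'   attached as attribute `"kernel"`.
#' @export
hrf_regressor <- function(psi_metric, TR) {
  if (TR <= 0) stop("TR must be positive")
  tt <- seq(0, 32, by = TR)
  kern <- tt^5 * exp(-tt) / gamma(6) - (1 / 6) * tt^15 * exp(-tt) / gamma(16)
  kern <- kern / max(kern)
  n <- length(psi_metric)
  conv <- stats::convolve(c(psi_metric, rep(0, length(kern))),
                          rev(kern), type = "open")[seq_len(n)]
  deriv <- c(0, diff(conv))
  out <- cbind(hrf = conv, dhrf = deriv)
  attr(out, "kernel") <- kern
  out
}

#' Per-ROI GLM for the HRF-convolved EEG-PSI regressor
#'
#' Ordinary least squares of each ROI time course on the design (an
#' intercept is added internally); reports the beta, t and Z statistic of
#' the first design column (the convolved regressor).  ROIs with
#' `|Z| > z_thresh` (default 2.3) form the estimated epileptic network.
#'
#' @param ts a [roi_timeseries] (or R x T matrix).
#' @param design T x p design matrix, e.g. from [hrf_regressor()]; must be
#'   full column rank.
#' @param z_thresh selection threshold on `|Z|`.
#' @return data.frame with columns `roi`, `beta`, `se`, `t`, `z`,
#'   `selected`.
#' @export
roi_glm <- function(ts, design, z_thresh = 2.3) {
  Y <- if (inherits(ts, "roi_timeseries")) t(ts$data) else t(as.matrix(ts))
  roi_names <- if (inherits(ts, "roi_timeseries")) ts$roi_names
               else paste0("ROI", seq_len(ncol(Y)))
  X <- cbind(`(Intercept)` = 1, design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  df <- nrow(X) - ncol(X)
  coefs <- qr.coef(qrX, Y)
  resid <- Y - X %*% coefs
  sigma2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  tval <- coefs[2L, ] / se
  z <- sign(tval) * stats::qnorm(stats::pt(abs(tval), df, lower.tail = FALSE),
                                 lower.tail = FALSE)
  data.frame(roi = roi_names, beta = coefs[2L, ], se = se, t = tval, z = z,
             selected = abs(z) > z_thresh, row.names = NULL)
}

#' Map a voxel-wise network mask onto parcels
#'
#' A parcel is selected when strictly more than `frac` of its voxels belong
#' to the mask.
#'
#' @param voxel_labels integer/character vector: parcel id per voxel (0 or
#'   NA = outside any parcel).
#' @param network_mask logical vector of the same length.
#' @param frac overlap fraction (default 0.05; strict inequality).
#' @param all_parcels optional vector of parcel ids expected to exist;
#'   parcels with zero voxels are excluded with a warning.
#' @return Vector of selected parcel ids.
#' @export
parcel_overlap <- function(voxel_labels, network_mask, frac = 0.05,
                           all_parcels = NULL) {
  if (length(voxel_labels) != length(network_mask))
    stop("labels and mask must have the same length")
  keep <- !is.na(voxel_labels) & voxel_labels != 0
  labs <- voxel_labels[keep]
  msk <- network_mask[keep]
  tot <- table(labs)
  hit <- tapply(msk, labs, sum)
  if (!is.null(all_parcels)) {
    missing_p <- setdiff(as.character(all_parcels), names(tot))
    if (length(missing_p))
      warning("parcel(s) with zero voxels excluded: ",
              paste(missing_p, collapse = ", "))
  }
  sel <- names(tot)[hit / as.numeric(tot) > frac]
  if (is.numeric(voxel_labels)) as.numeric(sel) else sel
}

#' Average connectivity strength between parcel groups
#'
#' Devectorizes a state and averages its entries over all between-parcel
#' pairs (p in g, q in h, p != q) for each selected group g against every
#' group h.  With left/right frontal, limbic, occipital, parietal, temporal,
#' non-thalamic subcortical and thalamus groups this is the conventional
#' 14-group summary.
#'
#' @param state_vector vectorized state (length `(R^2 - R)/2`).
#' @param R parcel count.
#' @param parcel_groups factor/character vector of length R mapping each
#'   parcel to a group; every parcel must be assigned.
#' @param selected_groups groups to report rows for (default: all).
#' @return Matrix `length(selected_groups)` x `nlevels(groups)`; entries for
#'   group pairs with no qualifying parcel pair are `NA`.
#' @export
group_strength <- function(state_vector, R, parcel_groups,
                           selected_groups = NULL) {
  if (length(parcel_groups) != R) stop("parcel_groups must cover all R parcels")
  if (anyNA(parcel_groups)) stop("every parcel must map to exactly one group")
  S <- devec_upper(state_vector, R)
  groups <- factor(parcel_groups)
  lev <- levels(groups)
  if (is.null(selected_groups)) selected_groups <- lev
  selected_groups <- as.character(selected_groups)
  if (!all(selected_groups %in% lev))
    stop("selected group(s) not present in parcel_groups")
  out <- matrix(NA_real_, length(selected_groups), length(lev),
                dimnames = list(selected_groups, lev))
  for (g in selected_groups) for (h in lev) {
    p <- which(groups == g)
    q <- which(groups == h)
    vals <- S[p, q, drop = FALSE]
    if (g == h) {
      if (length(p) < 2L) next                 # no between-parcel pair
      vals <- vals[upper.tri(vals) | lower.tri(vals)]
    }
    out[g, h] <- mean(vals)
  }
  if (anyNA(out))
    warning("group pair(s) without qualifying parcel pairs reported as NA")
  out
}
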