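#' ROI-averaged BOLD time series
#'
#' Container for a parcel-averaged BOLD matrix (regions x timepoints) with its
#' repetition time.  Zero-variance rows are rejected at construction because a
#' constant ROI makes windowed Pearson correlation undefined.
#'
#' @param data numeric matrix, regions x timepoints.
#' @param TR repetition time in seconds.
#' @param roi_names optional character vector of region names (defaults to
#'   `ROI1..ROIR`).
#' @return An object of class `roi_timeseries` with elements `data`, `TR`,
#'   `roi_names`.
#' @export
roi_timeseries <- function(data, TR, roi_names = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data)))
    stop("BOLD matrix must be numeric and finite")
  if (nrow(data) < 2L) stop("need at least 2 ROIs")
  if (!is.numeric(TR) || length(TR) != 1L || TR <= 0) stop("TR must be a positive scalar")
  v <- apply(data, 1L, stats::var)
  if (any(v == 0)) {
    if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(nrow(data)))
    stop("zero-variance ROI(s): ", paste(roi_names[v == 0], collapse = ", "))
  }
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(nrow(data)))
  if (length(roi_names) != nrow(data)) stop("roi_names length must match row count")
  structure(list(data = data, TR = TR, roi_names = roi_names),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: %d regions x %d timepoints, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$TR))
  invisible(x)
}

#' Zero-phase low-pass filter of ROI BOLD signals
#'
#' Applies a 4th-order Butterworth low-pass filter forward and backward
#' (zero phase) to each ROI, preserving the DC component.  Synchronized BOLD
#' fluctuations of neuronal origin are mainly confined below 0.1 Hz, the
#' default cutoff.
#'
#' @param ts a [roi_timeseries].
#' @param cutoff_hz cutoff frequency in Hz; must lie below Nyquist,
#'   `1 / (2 * TR)`.
#' @param order Butterworth order.
#' @return A filtered [roi_timeseries].
#' @export
lowpass_bold <- function(ts, cutoff_hz = 0.1, order = 4L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nyq <- 1 / (2 * ts$TR)
  if (cutoff_hz >= nyq)
    stop(sprintf("cutoff %.4g Hz must be below Nyquist %.4g Hz", cutoff_hz, nyq))
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  filt <- t(apply(ts$data, 1L, function(row) {
    mu <- mean(row)
    mu + signal::filtfilt(bf, row - mu)
  }))
  roi_timeseries(filt, ts$TR, ts$roi_names)
}

#' Sliding-window bounds
#'
#' Windows are 0-based and half-open: `[0, L), [s, s + L), ...`, all fully
#' inside `[0, T_scan)`.  The count is `floor((T_scan - L) / s) + 1`.
#'
#' @param T_scan number of scan timepoints (TRs).
#' @param L window length in TRs (default 15, i.e. 37.5 s at TR = 2.5 s).
#' @param s step in TRs (default 2, i.e. 5 s at TR = 2.5 s).
#' @return A list of `c(start, end)` integer pairs (half-open, 0-based).
#' @export
make_windows <- function(T_scan, L = 15L, s = 2L) {
  if (L > T_scan) stop("window length L exceeds T_scan")
  if (L < 2L) stop("window length L must be >= 2")
  if (s < 1L) stop("step s must be >= 1")
  n <- (T_scan - L) %/% s + 1L
  lapply(seq_len(n) - 1L, function(i) c(start = i * s, end = i * s + L))
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Pairs are ordered row-major over (i, j) with i < j (0-based):
#' (0,1), (0,2), ..., (0,R-1), (1,2), ...  The diagonal is dropped; a
#' correlation matrix carries no information there.
#'
#' @param S symmetric R x R matrix (checked to tolerance 1e-8).
#' @return Numeric vector of length `M = (R^2 - R) / 2`.
#' @seealso [devec_upper()]
#' @export
vec_upper <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8)
    stop("S must be symmetric")
  S[upper.tri(S)][pair_index(nrow(S))$cm_pos]
}

# Row-major (i < j) pair bookkeeping.  upper.tri() extracts column-major;
# cm_pos[m] is the column-major slot of the m-th row-major pair, so
# v_rowmajor = v_colmajor[cm_pos].  i, j are 1-based and in row-major order.
pair_index <- function(R) {
  idx <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)  # column-major
  cm_pos <- order(idx[, 1L], idx[, 2L])
  list(i = idx[cm_pos, 1L], j = idx[cm_pos, 2L], cm_pos = cm_pos)
}

#' Rebuild a symmetric matrix from its vectorized upper triangle
#'
#' Inverse of [vec_upper()]; the diagonal is set to 1 (self-correlation).
#'
#' @param v vector of length `(R^2 - R) / 2` in row-major pair order.
#' @param R matrix dimension.
#' @return Symmetric R x R matrix with unit diagonal.
#' @export
devec_upper <- function(v, R) {
  M <- (R * R - R) %/% 2L
  if (length(v) != M)
    stop(sprintf("length %d does not match M = %d for R = %d", length(v), M, R))
  S <- matrix(0, R, R)
  v_cm <- numeric(M)
  v_cm[pair_index(R)$cm_pos] <- v
  S[upper.tri(S)] <- v_cm
  S <- S + t(S)
  diag(S) <- 1
  S
}

#' Number of connectivity pairs for R regions
#' @param R region count.
#' @return `(R^2 - R) / 2`.
#' @export
n_pairs <- function(R) (R * R - R) %/% 2L

#' Sliding-window dynamic functional connectivity matrix
#'
#' For each rectangular (untapered) window, the pairwise Pearson correlation
#' of the ROI signals is computed and its upper triangle vectorized, yielding
#' `C` of size M x T with `M = (R^2 - R)/2` and `T = floor((T_scan - L)/s) + 1`.
#'
#' @param ts a [roi_timeseries].
#' @param L window length in TRs.
#' @param s step size in TRs.
#' @return An object of class `dfc_matrix`: list with `C` (M x T), `windows`
#'   (from [make_windows()]), `window_len_tr`, `step_tr`, `R`, `TR`.
#' @export
build_dfc <- function(ts, L = 15L, s = 2L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  windows <- make_windows(ncol(ts$data), L, s)
  R <- nrow(ts$data)
  C <- vapply(windows, function(w) {
    seg <- ts$data[, (w[1L] + 1L):w[2L], drop = FALSE]
    sdv <- apply(seg, 1L, stats::sd)
    if (any(sdv == 0))
      stop(sprintf("zero-variance ROI %s within window [%d,%d)",
                   paste(ts$roi_names[sdv == 0], collapse = ","), w[1L], w[2L]))
    vec_upper(stats::cor(t(seg)))
  }, numeric(n_pairs(R)))
  structure(list(C = C, windows = windows, window_len_tr = as.integer(L),
                 step_tr = as.integer(s), R = R, TR = ts$TR),
            class = "dfc_matrix")
}

#' @export
print.dfc_matrix <- function(x, ...) {
  cat(sprintf("dFC matrix: %d pairs x %d windows (R = %d, L = %d TR, step = %d TR)\n",
              nrow(x$C), ncol(x$C), x$R, x$window_len_tr, x$step_tr))
  invisible(x)
}
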