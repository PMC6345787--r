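# EEG phase synchronization index (PSI).
#
# For channels l, m, segment j and frequency bin f,
#   PSI_lm(j, f) = sqrt(X_lm(j, f)^2 + Y_lm(j, f)^2),
# where X and Y are the means of cos and sin of the instantaneous phase
# difference over the N samples of segment j.  PSI = 1 means perfect phase
# locking within the segment, ~1/sqrt(N) is the noise floor for independent
# phases.  Segments are consecutive, non-overlapping, aligned to sample 0;
# with the default 2.5 s duration the metric has one value per fMRI TR.

#' Multichannel EEG recording
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param channel_names optional channel labels.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("EEG contains NaN/NA samples")
  if (nrow(data) < 2L) stop("need at least 2 channels")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names length must match channel count")
  structure(list(data = data, fs = fs, channel_names = channel_names),
            class = "eeg_recording")
}

#' Local-average re-referencing (Hjorth style)
#'
#' Subtracts from each channel the mean of its listed neighbors.  A light
#' stand-in for spatial sharpening of scalp recordings; off by default in the
#' pipeline.  Note the transform is not idempotent.
#'
#' @param eeg an [eeg_recording].
#' @param neighbor_map named list: for every channel name, a character vector
#'   of neighbor channel names (non-empty).
#' @return A re-referenced [eeg_recording].
#' @export
local_reference <- function(eeg, neighbor_map) {
  stopifnot(inherits(eeg, "eeg_recording"))
  missing_ch <- setdiff(eeg$channel_names, names(neighbor_map))
  if (length(missing_ch))
    stop("neighbor_map missing channel(s): ", paste(missing_ch, collapse = ", "))
  out <- eeg$data
  for (i in seq_along(eeg$channel_names)) {
    nb <- neighbor_map[[eeg$channel_names[i]]]
    if (length(nb) == 0L)
      stop("empty neighbor list for channel ", eeg$channel_names[i])
    nb_idx <- match(nb, eeg$channel_names)
    if (anyNA(nb_idx))
      stop("unknown neighbor(s) for channel ", eeg$channel_names[i])
    out[i, ] <- eeg$data[i, ] -
      colMeans(eeg$data[nb_idx, , drop = FALSE])
  }
  eeg_recording(out, eeg$fs, eeg$channel_names)
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves the signal with complex Morlet wavelets
#' `exp(2i*pi*f*t) * exp(-t^2 / (2*sigma_t^2))`, `sigma_t = n_cycles/(2*pi*f)`,
#' truncated at 3.5 sigma_t, 'same' alignment.  The coefficient phase at bin
#' f tracks the phase of an f-Hz component of the signal.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param freqs frequency bins in Hz, all below Nyquist.
#' @param n_cycles wavelet width in cycles (>= 3 for usable frequency
#'   resolution).
#' @return Complex matrix, `length(freqs)` x `length(x)`.
#' @export
morlet_decompose <- function(x, fs, freqs, n_cycles = 6) {
  if (max(freqs) >= fs / 2)
    stop(sprintf("frequency %g Hz at or above Nyquist %g Hz", max(freqs), fs / 2))
  if (n_cycles < 3) stop("n_cycles must be >= 3")
  out <- matrix(complex(real = 0), length(freqs), length(x))
  for (b in seq_along(freqs)) {
    f <- freqs[b]
    sigma_t <- n_cycles / (2 * pi * f)
    half <- max(1L, ceiling(3.5 * sigma_t * fs))
    tt <- (-half:half) / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2))
    w <- w / sum(abs(w))
    out[b, ] <- conv_same(x, w)
  }
  out
}

# FFT-based 'same' convolution of a real signal with a centered
# odd-length complex kernel.
conv_same <- function(x, h) {
  n <- length(x)
  m <- length(h)
  L <- stats::nextn(n + m - 1L, 2L)
  X <- stats::fft(c(x, rep(0, L - n)))
  H <- stats::fft(c(h, rep(0, L - m)))
  full <- stats::fft(X * H, inverse = TRUE) / L
  half <- (m - 1L) %/% 2L
  full[(half + 1L):(half + n)]
}

#' Segment-wise phase synchronization index for all channel pairs
#'
#' @param phases channels x freqs x time array of instantaneous phases
#'   (radians), e.g. `Arg()` of [morlet_decompose()] output per channel.
#' @param segment_samples N, samples per segment (>= 2).  A trailing partial
#'   segment is discarded.
#' @return List with `psi` (pairs x segments x freqs array in `[0, 1]`) and
#'   `pairs` (2-column matrix of channel indices, row-major `l < m` order).
#' @export
psi_pairwise <- function(phases, segment_samples) {
  d <- dim(phases)
  if (length(d) != 3L) stop("phases must be channels x freqs x time")
  n_ch <- d[1L]; n_f <- d[2L]; n_t <- d[3L]
  N <- as.integer(segment_samples)
  if (N < 2L) stop("segment_samples must be >= 2")
  if (N > n_t) stop("segment longer than recording")
  n_seg <- n_t %/% N
  pi_idx <- pair_index(n_ch)
  n_pair <- length(pi_idx$i)
  psi <- array(0, dim = c(n_pair, n_seg, n_f))
  keep <- seq_len(n_seg * N)
  for (p in seq_len(n_pair)) {
    dphi <- phases[pi_idx$i[p], , keep, drop = TRUE] -
            phases[pi_idx$j[p], , keep, drop = TRUE]
    if (n_f == 1L) dphi <- matrix(dphi, nrow = 1L)
    for (b in seq_len(n_f)) {
      X <- .colMeans(cos(dphi[b, ]), N, n_seg)
      Y <- .colMeans(sin(dphi[b, ]), N, n_seg)
      psi[p, , b] <- sqrt(X^2 + Y^2)
    }
  }
  list(psi = psi, pairs = cbind(l = pi_idx$i, m = pi_idx$j))
}

#' Average PSI across a frequency band
#'
#' Arithmetic mean over bins with `band[1] <= f <= band[2]` (inclusive
#' endpoints).
#'
#' @param psi pairs x segments x freqs array.
#' @param freqs Hz per bin.
#' @param band `c(lo, hi)` in Hz; default the 3-10 Hz band covering typical
#'   epileptiform spectral content.
#' @return pairs x segments matrix.
#' @export
band_average <- function(psi, freqs, band = c(3, 10)) {
  sel <- which(freqs >= band[1L] & freqs <= band[2L])
  if (length(sel) == 0L) stop("no frequency bin inside band")
  apply(psi[, , sel, drop = FALSE], c(1L, 2L), mean)
}

#' Select the channel pair with maximal PSI temporal variance
#'
#' @param psi_band pairs x segments matrix of band-averaged PSI.
#' @return Index (row of the pair table) of the pair whose PSI time course
#'   has the largest sample variance; ties break to the lowest index.
#' @export
select_pair <- function(psi_band) {
  if (ncol(psi_band) < 2L) stop("need at least 2 segments")
  v <- apply(psi_band, 1L, stats::var)
  if (all(v == 0)) {
    warning("all pairs have constant PSI; returning the first pair")
    return(1L)
  }
  which.max(v)  # which.max returns the first maximum -> lowest pair index
}

#' EEG-PSI metric: band-averaged PSI of the most variable channel pair
#'
#' Full pipeline stage: Morlet decomposition of each channel, segment-wise
#' PSI for every channel pair and bin, band averaging, then selection of the
#' pair with the highest temporal variance.  With `segment_sec` equal to the
#' fMRI TR the metric has one value per scan volume.
#'
#' @param eeg an [eeg_recording] (or channels x samples matrix with `fs`).
#' @param fs sampling rate, required when `eeg` is a bare matrix.
#' @param segment_sec segment duration in seconds (default 2.5).
#' @param band frequency band `c(lo, hi)` Hz for averaging.
#' @param freqs Morlet bin centers in Hz.
#' @param n_cycles Morlet cycles.
#' @param neighbor_map optional: apply [local_reference()] first.
#' @return An object of class `psi_series`: list with `psi`
#'   (pairs x segments x freqs), `band_psi` (pairs x segments), `pairs`,
#'   `selected_pair` (index and channel pair), `metric`
#'   (segments vector, the EEG-PSI), `freqs`, `band`, `segment_sec`, `fs`.
#' @export
eeg_psi <- function(eeg, fs = NULL, segment_sec = 2.5, band = c(3, 10),
                    freqs = 2:20, n_cycles = 6, neighbor_map = NULL) {
  if (!inherits(eeg, "eeg_recording")) {
    if (is.null(fs)) stop("fs required when eeg is a matrix")
    eeg <- eeg_recording(eeg, fs)
  }
  if (!is.null(neighbor_map)) eeg <- local_reference(eeg, neighbor_map)
  n_ch <- nrow(eeg$data)
  n_t <- ncol(eeg$data)
  phases <- array(0, dim = c(n_ch, length(freqs), n_t))
  for (ch in seq_len(n_ch)) {
    phases[ch, , ] <- Arg(morlet_decompose(eeg$data[ch, ], eeg$fs, freqs,
                                           n_cycles))
  }
  N <- round(segment_sec * eeg$fs)
  pp <- psi_pairwise(phases, N)
  band_psi <- band_average(pp$psi, freqs, band)
  sel <- select_pair(band_psi)
  structure(list(psi = pp$psi, band_psi = band_psi, pairs = pp$pairs,
                 selected_pair = list(index = sel, channels = pp$pairs[sel, ]),
                 metric = band_psi[sel, ], freqs = freqs, band = band,
                 segment_sec = segment_sec, fs = eeg$fs),
            class = "psi_series")
}

#' @export
print.psi_series <- function(x, ...) {
  cat(sprintf(
    "EEG-PSI: %d pairs x %d segments x %d bins; selected pair (%d, %d), band %g-%g Hz\n",
    dim(x$psi)[1L], dim(x$psi)[2L], dim(x$psi)[3L],
    x$selected_pair$channels[1L], x$selected_pair$channels[2L],
    x$band[1L], x$band[2L]))
  invisible(x)
}
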