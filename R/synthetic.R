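# Seeded synthetic EEG-fMRI scenes with planted connectivity states.
#
# Forward model: at each TR the BOLD vector is drawn from a zero-mean
# multivariate normal whose covariance is a convex combination of the planted
# state matrices (weights normalized per column), projected to positive
# definite by eigenvalue clipping, plus isotropic noise.  The EEG carries a
# common narrow-band oscillation on one channel pair whose envelope follows a
# chosen state's weight course, so inter-channel phase locking "bursts" in
# step with that state.

# Evaluate `code` under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random disjoint block specification for planted states
#'
#' Draws, for each of K states, a few disjoint parcel blocks with a target
#' within-block correlation, for use with [gen_states()].
#'
#' @param R parcel count.
#' @param K state count.
#' @param block_size parcels per block (vector recycled over blocks).
#' @param n_blocks blocks per state.
#' @param r_within target within-block correlation.
#' @param seed integer seed.
#' @return A list of length K; each element a list of blocks
#'   `list(parcels =, r =)`.
#' @export
random_block_spec <- function(R, K, block_size = max(4L, R %/% 3L),
                              n_blocks = 2L, r_within = 0.9, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(K), function(k) {
      parcels <- sample.int(R, min(R, block_size * n_blocks))
      split_blocks <- split(parcels, rep(seq_len(n_blocks), each = block_size,
                                         length.out = length(parcels)))
      lapply(split_blocks, function(p) list(parcels = sort(p), r = r_within))
    })
  })
}

#' Generate planted connectivity states
#'
#' Each state is a vectorized correlation matrix built from parcel blocks:
#' entries inside a block are set to the block's target correlation, the rest
#' to ~0, then the matrix is projected to positive definite by eigenvalue
#' clipping and rescaled to unit diagonal.  Distinct states must have pairwise
#' spatial correlation below `max_cross_corr`; with a random specification the
#' draw is rejected and redrawn, with a user-supplied one violation is an
#' error.
#'
#' @param R parcel count (>= 4).
#' @param K state count (>= 1).
#' @param block_spec list of length K as from [random_block_spec()]; `NULL`
#'   draws a random specification.
#' @param seed integer seed.
#' @param max_cross_corr rejection cap on between-state spatial correlation.
#' @return List of K vectors, each of length `(R^2 - R)/2` (see [vec_upper()]).
#' @export
gen_states <- function(R, K, block_spec = NULL, seed = 1L, max_cross_corr = 0.5) {
  if (R < 4L) stop("R must be >= 4")
  if (K < 1L) stop("K must be >= 1")
  random_spec <- is.null(block_spec)
  for (attempt in seq_len(if (random_spec) 100L else 1L)) {
    spec <- if (random_spec)
      random_block_spec(R, K, seed = seed + 1000L * (attempt - 1L))
    else block_spec
    if (length(spec) != K) stop("block_spec must have one element per state")
    states <- lapply(seq_len(K), function(k) state_from_blocks(R, spec[[k]], k))
    ok <- TRUE
    if (K > 1L) {
      for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
        if (abs(stats::cor(states[[a]], states[[b]])) > max_cross_corr) ok <- FALSE
      }
    }
    if (ok) return(states)
    if (!random_spec)
      stop("block_spec yields states with spatial correlation above ",
           max_cross_corr)
  }
  stop("could not draw K states under the cross-correlation cap after 100 tries")
}

state_from_blocks <- function(R, blocks, state_id) {
  S <- diag(R)
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    p <- blk$parcels
    if (any(p < 1L | p > R))
      stop(sprintf("state %d block %d: parcel index out of range", state_id, b))
    if (abs(blk$r) > 1)
      stop(sprintf("state %d block %d: correlation %g outside [-1, 1]",
                   state_id, b, blk$r))
    S[p, p] <- blk$r
  }
  diag(S) <- 1
  S <- pd_clip(S)
  S <- stats::cov2cor(S)
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 0)
    stop(sprintf("state %d: block specification infeasible (not PSD after projection)",
                 state_id))
  vec_upper(S)
}

# Eigenvalue clipping at floor eps: the cheapest deterministic PD projection.
pd_clip <- function(S, eps = 1e-3) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, eps)
  e$vectors %*% (v * t(e$vectors))
}

#' Generate state weight time-courses
#'
#' @param T_scan number of TRs.
#' @param K number of states.
#' @param regime `"separate"` (exactly one active state per TR), `"joint"`
#'   (all states positive every TR) or `"mixed"` (variable support).
#' @param burst optional `c(state, onset, duration, amplitude)`: a smoothed
#'   boxcar added to that state's baseline course (TR units, 0-based onset).
#' @param seed integer seed.
#' @param dwell mean dwell time in TRs for the separate/mixed regimes.
#' @return Nonnegative K x T_scan matrix.
#' @export
gen_weight_courses <- function(T_scan, K, regime = c("separate", "joint", "mixed"),
                               burst = NULL, seed = 1L, dwell = 20L) {
  if (K < 1L) stop("K must be >= 1")
  regime <- match.arg(regime)
  if (!is.null(burst)) {
    if (length(burst) != 4L) stop("burst must be c(state, onset, duration, amplitude)")
    if (burst[1L] < 1 || burst[1L] > K) stop("burst state index out of range")
    if (burst[2L] < 0 || burst[2L] + burst[3L] > T_scan)
      stop("burst interval outside [0, T_scan)")
  }
  A <- with_seed(seed, {
    A <- matrix(0, K, T_scan)
    if (regime == "separate") {
      t0 <- 1L
      while (t0 <= T_scan) {
        len <- min(T_scan - t0 + 1L, max(2L, stats::rgeom(1L, 1 / dwell) + 1L))
        st <- sample.int(K, 1L)
        A[st, t0:(t0 + len - 1L)] <- stats::runif(1L, 0.6, 1)
        t0 <- t0 + len
      }
      A
    } else if (regime == "joint") {
      raw <- matrix(stats::rnorm(K * T_scan), K, T_scan)
      sm <- t(apply(raw, 1L, smooth_ma, width = 11L))
      A <- exp(0.5 * sm)
      A <- sweep(A, 2L, colSums(A), "/")
    } else {
      raw <- matrix(stats::rnorm(K * T_scan), K, T_scan)
      sm <- t(apply(raw, 1L, smooth_ma, width = 11L))
      A <- pmax(sm - 0.05, 0)
      # guarantee non-empty support per column
      empty <- colSums(A) == 0
      if (any(empty)) A[cbind(sample.int(K, sum(empty), replace = TRUE),
                              which(empty))] <- 0.5
      A
    }
  })
  if (!is.null(burst)) {
    box <- numeric(T_scan)
    idx <- (burst[2L] + 1L):(burst[2L] + burst[3L])
    box[idx] <- 1
    box <- smooth_ma(box, width = 5L) / max(smooth_ma(box, width = 5L)) * burst[4L]
    A[burst[1L], ] <- A[burst[1L], ] + box
  }
  # bound total expression per TR
  cs <- colSums(A)
  over <- cs > 2
  if (any(over)) A[, over] <- sweep(A[, over, drop = FALSE], 2L, cs[over] / 2, "/")
  A
}

smooth_ma <- function(x, width = 5L) {
  kern <- rep(1 / width, width)
  as.numeric(stats::filter(x, kern, sides = 2L, circular = TRUE))
}

#' Simulate ROI BOLD from planted states and weights
#'
#' Each TR's sample is drawn from N(0, Sigma_t) with
#' `Sigma_t = sum_k w_k(t) * devec(state_k)` (weights normalized to sum 1 per
#' column), projected to positive definite by eigenvalue clipping at
#' `eps = 1e-3`, plus `noise_sigma^2 * I`.  Columns with all-zero weights fall
#' back to the isotropic floor.
#'
#' @param states list of K vectorized states (from [gen_states()]).
#' @param weights K x T_scan nonnegative matrix.
#' @param TR repetition time in seconds (stored, not used in sampling).
#' @param noise_sigma isotropic noise standard deviation.
#' @param seed integer seed.
#' @return A [roi_timeseries] with R rows and T_scan columns.
#' @export
gen_bold <- function(states, weights, TR = 2.5, noise_sigma = 0.1, seed = 1L) {
  K <- length(states)
  if (nrow(weights) != K) stop("weights rows must match number of states")
  M <- length(states[[1L]])
  R <- round((1 + sqrt(1 + 8 * M)) / 2)
  mats <- lapply(states, devec_upper, R = R)
  T_scan <- ncol(weights)
  eps <- 1e-3
  with_seed(seed, {
    X <- matrix(0, R, T_scan)
    for (t in seq_len(T_scan)) {
      w <- weights[, t]
      if (sum(w) > 0) {
        w <- w / sum(w)
        Sig <- Reduce(`+`, Map(`*`, mats, w))
        Sig <- pd_clip(Sig, eps)
      } else {
        Sig <- diag(eps, R)
      }
      Sig <- Sig + diag(noise_sigma^2, R)
      X[, t] <- drop(crossprod(chol(Sig), stats::rnorm(R)))
    }
    roi_timeseries(X, TR)
  })
}

#' Simulate multichannel EEG with drive-locked phase synchronization
#'
#' Channels carry 1/f-shaped background noise; channels `sync_pair` share a
#' common sinusoid at `sync_freq_hz` whose envelope follows `drive`
#' (one value per TR, values in `[0, 1]`), with independent slow amplitude
#' jitter per channel so the pair's phase difference is near-constant while
#' the drive is high.
#'
#' @param T_scan number of TRs.
#' @param TR repetition time (s).
#' @param fs EEG sampling rate (Hz); must be at least `4 * sync_freq_hz`.
#' @param n_channels channel count (>= 2).
#' @param sync_pair integer pair `c(l, m)` of synchronized channels.
#' @param sync_freq_hz oscillation frequency (default 6 Hz, inside the
#'   3-10 Hz band used by the PSI metric).
#' @param drive length-`T_scan` vector in `[0, 1]`.
#' @param gain oscillation amplitude relative to the unit-variance background.
#' @param seed integer seed.
#' @return List with `eeg` (channels x samples matrix), `fs`, `psi_true`
#'   (= `drive`).
#' @export
gen_eeg <- function(T_scan, TR = 2.5, fs = 100, n_channels = 4L,
                    sync_pair = c(1L, 2L), sync_freq_hz = 6, drive = NULL,
                    gain = 3, seed = 1L) {
  if (any(sync_pair < 1L) || any(sync_pair > n_channels) ||
      sync_pair[1L] == sync_pair[2L])
    stop("sync_pair out of range")
  if (fs < 4 * sync_freq_hz) stop("fs must be >= 4 * sync_freq_hz")
  if (is.null(drive)) drive <- rep(0.1, T_scan)
  if (length(drive) != T_scan) stop("drive must have one value per TR")
  if (any(drive < 0 | drive > 1)) stop("drive values must lie in [0, 1]")
  S <- round(T_scan * TR * fs)
  per_tr <- S / T_scan
  with_seed(seed, {
    eeg <- t(vapply(seq_len(n_channels), function(ch) pink_noise(S),
                    numeric(S)))
    env <- stats::approx(x = (seq_len(T_scan) - 0.5) * per_tr,
                         y = drive, xout = seq_len(S), rule = 2L)$y
    tt <- (seq_len(S) - 1L) / fs
    carrier <- sin(2 * pi * sync_freq_hz * tt + stats::runif(1L, 0, 2 * pi))
    for (ch in sync_pair) {
      jitter <- 1 + 0.2 * smooth_ma(stats::rnorm(S), width = round(fs))
      eeg[ch, ] <- eeg[ch, ] + gain * pmax(jitter, 0.2) * env * carrier
    }
    list(eeg = eeg, fs = fs, psi_true = drive)
  })
}

# Spectrally shaped (1/f amplitude) Gaussian noise, unit variance.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, pmax(n - f, 1))      # symmetric frequency index
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Generate a complete synthetic EEG-fMRI scene
#'
#' The default scene plants K = 4 states over R = 30 parcels across
#' T_scan = 600 TRs (TR = 2.5 s) in the separate-expression regime, adds a
#' burst of state 1 (onset TR 400, 80 TRs), and synthesizes EEG whose
#' 3-10 Hz phase locking on one channel pair follows state 1's weight course.
#'
#' @param R,K,T_scan,TR,fs,n_channels scene dimensions.
#' @param noise_sigma BOLD noise level.
#' @param regime weight regime, see [gen_weight_courses()].
#' @param burst burst specification `c(state, onset, duration, amplitude)`;
#'   the default places a burst of state 1 at two thirds of the scan
#'   lasting ~13% of it (TRs 400-480 for the default 600-TR scene).
#'   `NULL` disables the burst.
#' @param sync_pair,sync_freq_hz EEG synchronization parameters.
#' @param seed integer seed; sub-seeds for each generator are derived from it.
#' @return An object of class `synthetic_scene`: list with `states`
#'   (list of vectorized state matrices), `weights` (K x T_scan), `bold`
#'   (a [roi_timeseries]), `eeg`, `fs`, `psi_true`, `params`, `seed`.
#' @export
synth_scene <- function(R = 30L, K = 4L, T_scan = 600L, TR = 2.5, fs = 100,
                        n_channels = 4L, noise_sigma = 0.1,
                        regime = "separate",
                        burst = c(1L, floor(T_scan * 2 / 3),
                                  max(10L, round(T_scan * 2 / 15)), 1),
                        sync_pair = c(1L, 2L), sync_freq_hz = 6, seed = 1L) {
  states <- gen_states(R, K, seed = seed)
  weights <- gen_weight_courses(T_scan, K, regime = regime, burst = burst,
                                seed = seed + 1L)
  bold <- gen_bold(states, weights, TR = TR, noise_sigma = noise_sigma,
                   seed = seed + 2L)
  drive_state <- if (is.null(burst)) 1L else as.integer(burst[1L])
  drive <- weights[drive_state, ]
  drive <- drive / max(drive)
  ee <- gen_eeg(T_scan, TR = TR, fs = fs, n_channels = n_channels,
                sync_pair = sync_pair, sync_freq_hz = sync_freq_hz,
                drive = drive, seed = seed + 3L)
  structure(list(states = states, weights = weights, bold = bold,
                 eeg = ee$eeg, fs = ee$fs, psi_true = ee$psi_true,
                 params = list(R = R, K = K, T_scan = T_scan, TR = TR, fs = fs,
                               n_channels = n_channels,
                               noise_sigma = noise_sigma, regime = regime,
                               burst = burst, sync_pair = sync_pair,
                               sync_freq_hz = sync_freq_hz,
                               drive_state = drive_state),
                 seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Synthetic scene: R = %d parcels, K = %d states, T_scan = %d TRs (TR = %g s),\n  EEG %d channels at %g Hz, regime '%s', seed %d\n",
    p$R, p$K, p$T_scan, p$TR, p$n_channels, p$fs, p$regime, x$seed))
  invisible(x)
}

#' Write a scene to a directory (bold.tsv, eeg.tsv, truth.json)
#'
#' @param scene a [synth_scene()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_matrix(scene$bold$data, file.path(dir, "bold.tsv"),
                   row_label = "roi")
  write_tsv_matrix(scene$eeg, file.path(dir, "eeg.tsv"), row_label = "channel")
  truth <- list(states = scene$states, weights = scene$weights,
                psi_true = scene$psi_true, params = scene$params,
                seed = scene$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}
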