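test_that("PSI is the resultant length of the phase-difference distribution", {
  # two channels, one bin; phases crafted directly
  T_len <- 1000L
  ph <- array(0, dim = c(2, 1, T_len))
  ph[1, 1, ] <- seq(0, 20, length.out = T_len)
  ph[2, 1, ] <- ph[1, 1, ] - 0.7              # constant lag 0.7 rad
  r <- psi_pairwise(ph, segment_samples = 100)
  expect_equal(as.numeric(r$psi), rep(1, 10), tolerance = 1e-12)
  # alternating {0, pi} lag cancels exactly
  ph[2, 1, ] <- ph[1, 1, ] - rep(c(0, pi), T_len / 2)
  r0 <- psi_pairwise(ph, segment_samples = 100)
  expect_equal(as.numeric(r0$psi), rep(0, 10), tolerance = 1e-12)
  expect_error(psi_pairwise(ph, segment_samples = 2000), "longer")
  expect_error(psi_pairwise(ph, segment_samples = 1), ">= 2")
})

test_that("PSI of independent phases matches the random-resultant level", {
  # E[PSI^2] for N i.i.d. uniform phase differences is 1/N
  set.seed(11)
  N <- 625L; n_seg <- 100L
  ph <- array(0, dim = c(2, 1, N * n_seg))
  ph[1, 1, ] <- runif(N * n_seg, 0, 2 * pi)
  ph[2, 1, ] <- runif(N * n_seg, 0, 2 * pi)
  r <- psi_pairwise(ph, segment_samples = N)
  expect_equal(mean(r$psi^2), 1 / N, tolerance = 0.2)
  expect_true(all(r$psi >= 0 & r$psi <= 1))
})

test_that("PSI is invariant to a common phase offset", {
  set.seed(12)
  ph <- array(runif(2 * 3 * 400, 0, 2 * pi), dim = c(2, 3, 400))
  r1 <- psi_pairwise(ph, 100)
  ph2 <- ph + 1.234                            # same constant on both channels
  r2 <- psi_pairwise(ph2, 100)
  expect_equal(r1$psi, r2$psi, tolerance = 1e-10)
})

test_that("Morlet coefficients localize and track frequency", {
  fs <- 200
  tt <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 10 * tt)
  co <- morlet_decompose(x, fs, freqs = c(5, 10, 15))
  pow <- rowMeans(abs(co[, 400:1600])^2)
  expect_equal(which.max(pow), 2L)
  # phase at the matching bin advances with the signal's phase
  mid <- 400:1600
  err <- Arg(exp(1i * (Arg(co[2, mid]) - 2 * pi * 10 * tt[mid])))
  expect_lt(max(abs(err - mean(err))), 0.05)
  expect_true(all(abs(morlet_decompose(rep(0, 500), fs, c(5, 10))) == 0))
  expect_error(morlet_decompose(x, fs, freqs = c(10, 120)), "Nyquist")
  expect_error(morlet_decompose(x, fs, freqs = 10, n_cycles = 2), "n_cycles")
})

test_that("a chirp's ridge frequency increases monotonically", {
  fs <- 100
  tt <- seq(0, 20, by = 1 / fs)
  f_inst <- 5 + 0.5 * tt                       # 5 -> 15 Hz
  x <- sin(2 * pi * (5 * tt + 0.25 * tt^2))
  freqs <- seq(4, 16, by = 1)
  co <- morlet_decompose(x, fs, freqs)
  probe <- seq(200, length(tt) - 200, by = 100)
  ridge <- freqs[apply(abs(co[, probe]), 2, which.max)]
  expect_true(all(diff(ridge) >= 0))
  # ridge matches the instantaneous frequency within one bin
  expect_true(all(abs(ridge - f_inst[probe]) <= 1.5))
})

test_that("band averaging is an inclusive-endpoint mean", {
  psi <- array(0, dim = c(1, 2, 4))
  psi[1, , ] <- rbind(c(0.2, 0.4, 0.6, 0.8), c(0.2, 0.4, 0.6, 0.8))
  freqs <- c(3, 5, 7, 9)
  expect_equal(as.numeric(band_average(psi, freqs, c(3, 10))), c(0.5, 0.5))
  expect_equal(as.numeric(band_average(psi, freqs, c(5, 5))), c(0.4, 0.4))
  expect_equal(as.numeric(band_average(psi, c(3, 5, 7, 10), c(3, 10))),
               c(0.5, 0.5))                    # 10 Hz endpoint included
  expect_error(band_average(psi, freqs, c(10.5, 11)), "no frequency bin")
})

test_that("pair selection maximizes temporal variance with tie-breaks", {
  flat <- matrix(0.4, 3, 50)
  burst <- flat
  burst[2, 20:30] <- 0.9
  expect_equal(select_pair(burst), 2L)
  expect_equal(select_pair(matrix(runif(10), 1)), 1L)
  expect_warning(sel <- select_pair(flat), "constant")
  expect_equal(sel, 1L)
  same <- matrix(rep(runif(20), each = 3), 3)
  expect_equal(select_pair(same), 1L)          # exact tie -> lowest pair
})

test_that("local-average referencing subtracts neighbor means", {
  X <- matrix(rnorm(3 * 100), 3, 100)
  rec <- eeg_recording(X, fs = 100, channel_names = c("a", "b", "c"))
  nm <- list(a = "b", b = c("a", "c"), c = "b")
  ref <- local_reference(rec, nm)
  expect_equal(ref$data[1, ], X[1, ] - X[2, ])
  expect_equal(ref$data[2, ], X[2, ] - (X[1, ] + X[3, ]) / 2)
  # identical channels -> all zero
  same <- eeg_recording(rbind(X[1, ], X[1, ], X[1, ]), 100, c("a", "b", "c"))
  expect_true(all(local_reference(same, nm)$data == 0))
  # not idempotent
  twice <- local_reference(ref, nm)
  expect_gt(max(abs(twice$data - ref$data)), 1e-8)
  expect_error(local_reference(rec, list(a = "b", b = "a", c = character(0))),
               "empty neighbor")
  expect_error(local_reference(rec, list(a = "b")), "missing channel")
})

test_that("the EEG-PSI metric has one value per segment and tracks bursts", {
  T_scan <- 60
  drive <- rep(0.05, T_scan); drive[20:35] <- 1
  ee <- gen_eeg(T_scan, TR = 2.5, fs = 60, drive = drive, seed = 4)
  ps <- eeg_psi(ee$eeg, fs = 60)
  expect_length(ps$metric, floor(ncol(ee$eeg) / (60 * 2.5)))
  expect_true(all(ps$psi >= 0 & ps$psi <= 1))
  expect_equal(sort(unname(ps$selected_pair$channels)), c(1, 2))
  expect_gte(cor(ps$metric, drive), 0.6)
})
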