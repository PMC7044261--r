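test_that("the AM waveform has the documented envelope and phase", {
  # sin(0) carrier factor: zero at t = 0 regardless of depth
  for (m in c(0, 0.5, 1)) expect_equal(am_waveform(0, m), 0)
  t <- seq(0, 0.5, by = 1 / 44100)
  # m = 0: pure carrier of amplitude 0.5
  w0 <- am_waveform(t, 0)
  expect_equal(max(abs(w0)), 0.5, tolerance = 1e-4)
  # envelope bound and onset minimum (envelope phase pi)
  w <- am_waveform(t, 0.8, f_m = 40)
  expect_true(all(abs(w) <= 0.5 * 1.8 + 1e-12))
  env_onset <- max(abs(w[t < 0.002]))
  env_peak <- max(abs(w))
  expect_lt(env_onset, 0.15)
  expect_equal(env_peak, 0.9, tolerance = 5e-3)
  expect_error(am_waveform(0.1, 1.2), "\\[0, 1\\]")
})

test_that("noiseless synthesis puts a single line at the tag frequency", {
  pars <- table1_params("6d")
  ts <- synth_trial("BIN", 100, pars, gain = 0.01, noise_sd = 0,
                    n_reps = 3, seed = 2)
  spec <- coherent_average(ts)
  i40 <- round(40 / spec$df) + 1
  expect_equal(spec$amplitude[i40],
               0.01 * gain_control_response(100, 100, pars),
               tolerance = 1e-9)
  # everything else is numerically zero
  expect_lt(max(spec$amplitude[-i40]), 1e-10)
  # doubling the gain doubles the line amplitude
  ts2 <- synth_trial("BIN", 100, pars, gain = 0.02, noise_sd = 0,
                     n_reps = 3, seed = 2)
  expect_equal(coherent_average(ts2)$amplitude[i40],
               2 * spec$amplitude[i40], tolerance = 1e-9)
  # depth 0 with no masker: pure noise (here, pure zeros)
  ts0 <- synth_trial("MON", 0, pars, gain = 0.01, noise_sd = 0,
                     n_reps = 2, seed = 2)
  expect_equal(max(abs(ts0$trials)), 0)
  # seeded synthesis is reproducible
  a <- synth_trial("DICH", 50, pars, noise_sd = 1, n_reps = 2, seed = 9)
  b <- synth_trial("DICH", 50, pars, noise_sd = 1, n_reps = 2, seed = 9)
  expect_identical(a$trials, b$trials)
})

test_that("coherent averaging is phase-aware", {
  fs <- 1000
  t <- seq(0, 11 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 40 * t + 0.7)
  # N identical trials: spectrum equals the single-trial spectrum
  one <- coherent_average(matrix(x, nrow = 1), fs = fs)
  four <- coherent_average(matrix(rep(x, each = 4), nrow = 4, byrow = FALSE),
                           fs = fs)
  expect_equal(four$amplitude, one$amplitude, tolerance = 1e-12)
  i40 <- round(40 / one$df) + 1
  expect_equal(one$amplitude[i40], 1, tolerance = 1e-9)
  # an antiphase pair cancels exactly
  anti <- coherent_average(rbind(x, -x), fs = fs)
  expect_lt(anti$amplitude[i40], 1e-12)
  # bin bookkeeping: 0.1 Hz grid puts 40 Hz at index 401
  expect_equal(one$df, 0.1)
  expect_equal(one$freq[401], 40)
  expect_error(coherent_average(rbind(x, -x)), "fs must be supplied")
})

test_that("the transform path conserves energy (Parseval)", {
  set.seed(5)
  x <- rnorm(11000)
  spec <- coherent_average(matrix(x, nrow = 1), fs = 1000)
  seg <- x[1001:11000]
  N <- length(seg)
  # one-sided amplitudes: mean square of the signal equals DC^2 + Nyquist^2
  # plus half the squared interior amplitudes
  a <- spec$amplitude
  energy_spec <- a[1]^2 + a[N / 2 + 1]^2 + sum(a[2:(N / 2)]^2) / 2
  expect_equal(mean(seg^2), energy_spec, tolerance = 1e-9)
})

test_that("the noise floor falls as the square root of repetitions", {
  floors <- vapply(c(4, 16, 64), function(R) {
    mean(vapply(1:40, function(i) {
      set.seed(R * 1000 + i)
      x <- matrix(rnorm(R * 11000), nrow = R)
      spec <- coherent_average(x, fs = 1000)
      mean(spec$amplitude[seq(300, 500)])
    }, numeric(1)))
  }, numeric(1))
  slope <- coef(lm(log(floors) ~ log(c(4, 16, 64))))[[2]]
  expect_lt(abs(slope + 0.5), 0.05)
})

test_that("neighbour-bin SNR does its arithmetic and guards division", {
  spec <- structure(list(freq = seq(0, 500, by = 0.1), df = 0.1,
                         amplitude = rep(2, 5001)),
                    class = "spectrum_estimate")
  spec$amplitude[401] <- 10
  expect_equal(snr_at_frequency(spec, 40), 5)
  spec$amplitude[] <- 0
  spec$amplitude[401] <- 1
  expect_error(snr_at_frequency(spec, 40), "noiseless")
  expect_error(snr_at_frequency(spec, 40.03), "bin grid")
})

test_that("the SNR statistic is unbiased and location-invariant for noise", {
  snrs <- vapply(1:100, function(i) {
    set.seed(i)
    x <- matrix(rnorm(5 * 11000), nrow = 5)
    spec <- coherent_average(x, fs = 1000)
    c(snr_at_frequency(spec, 40), snr_at_frequency(spec, 35))
  }, numeric(2))
  expect_lt(abs(mean(snrs[1, ]) - 1), 0.1)
  expect_lt(abs(mean(snrs[2, ]) - 1), 0.1)
  # same statistics at the two tag frequencies
  expect_lt(abs(mean(snrs[1, ]) - mean(snrs[2, ])), 0.1)
})

test_that("the analysis pipeline aggregates participants", {
  pars <- table1_params("6d")
  sets <- lapply(1:2, function(part) {
    lapply(c(12.5, 50), function(d) {
      synth_trial("BIN", d, pars, gain = eeg_gain_for(pars, n_reps = 4),
                  noise_sd = 1, n_reps = 4, seed = part * 10 + d)
    })
  })
  ds <- analyze_experiment(sets)
  expect_s3_class(ds, "eeg_dataset")
  expect_equal(nrow(ds), 4)  # 2 depths x 2 tags
  expect_equal(unique(ds$n_participants), 2)
  expect_setequal(ds$freq, c("F40", "F35"))
  # 40-Hz SNR grows with depth; 35-Hz stays near baseline in BIN
  s40 <- ds$snr[ds$freq == "F40"]
  expect_gt(s40[ds$depth_pct[ds$freq == "F40"] == 50],
            s40[ds$depth_pct[ds$freq == "F40"] == 12.5])
  expect_lt(max(ds$snr[ds$freq == "F35"]), 2)
})

test_that("simulated EEG experiments are seed-reproducible", {
  pars <- table1_params("6d")
  a <- simulate_eeg_experiment(pars, depths = c(25, 100),
                               conditions = c("MON", "BIN"), n_reps = 3,
                               n_participants = 2, seed = 21)
  b <- simulate_eeg_experiment(pars, depths = c(25, 100),
                               conditions = c("MON", "BIN"), n_reps = 3,
                               n_participants = 2, seed = 21)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
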