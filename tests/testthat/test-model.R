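test_that("gain-control response obeys its closed-form identities", {
  toy <- model_params(2, 2, 10, 1, 0.01, strict = FALSE)
  expect_identical(gain_control_response(0, 0, toy), 0)
  # p = q = 2, Z = 10, omega = 1, C = 10 each: 2*100/(100+100+100)
  expect_equal(gain_control_response(10, 10, toy), 2 / 3,
               tolerance = 1e-12)
  # swap symmetry, exactly
  pars <- table1_params("6a")
  for (C in c(0.5, 3, 20, 64)) {
    expect_identical(gain_control_response(C, 0, pars),
                     gain_control_response(0, C, pars))
  }
  expect_identical(gain_control_response(7, 31, pars),
                   gain_control_response(31, 7, pars))
  # high-precision scalar evaluation, pinned
  expect_equal(gain_control_response(50, 50, pars), 8.84452,
               tolerance = 1e-6)
  expect_error(gain_control_response(-1, 0, pars), "non-negative")
  expect_error(gain_control_response(Inf, 0, pars), "finite")
})

test_that("linear-summation response depends only on the summed depth", {
  toy <- model_params(2, 2, 10, 0, 0.01, strict = FALSE)
  expect_identical(linear_sum_response(0, 0, toy), 0)
  # p = q = 2, Z = 10, C_L = C_R = 5: 100/(100+100)
  expect_equal(linear_sum_response(5, 5, toy), 0.5, tolerance = 1e-12)
  pars <- table1_params("7a")
  for (C in c(1, 8, 40)) {
    a <- linear_sum_response(C, 0, pars)
    expect_identical(linear_sum_response(0, C, pars), a)
    expect_identical(linear_sum_response(C / 2, C / 2, pars), a)
  }
})

test_that("responses are finite, non-negative and monotone where expected", {
  set.seed(41)
  grid <- expand.grid(L = c(0, 0.1, 1, 10, 50, 100),
                      R = c(0, 0.1, 1, 10, 50, 100))
  for (i in 1:10) {
    pars <- random_params()
    r <- gain_control_response(grid$L, grid$R, pars)
    expect_true(all(is.finite(r)) && all(r >= 0))
  }
  # strictly increasing in each input when omega = 0
  pars0 <- model_params(2.6, 2.2, 12, 0, 0.5)
  L <- seq(0, 100, by = 2)
  r <- gain_control_response(L, 30, pars0)
  expect_true(all(diff(r) > 0))
  # near-monotone over the stimulus range for the shipped fits: with
  # omega = 1 the own-channel gain in excitation can be fractionally
  # undercut by the suppression it exerts on the other channel, but any
  # decrement stays below 0.2% of the response range
  for (nm in fixture_names()) {
    pars <- table1_params(nm)
    for (R in c(0, 10, 50, 100)) {
      r <- gain_control_response(seq(0, 100, by = 1), R, pars)
      expect_true(all(diff(r) >= -2e-3 * max(r)),
                  label = paste("near-monotone", nm, "at R =", R))
      if (pars$omega < 0.5) {
        expect_true(all(diff(r) >= 0),
                    label = paste("monotone", nm, "at R =", R))
      }
    }
  }
})

test_that("tagged response generalises the single-frequency model", {
  pars <- table1_params("6d")
  m <- 25
  # both ears at the readout tag: exactly the gain-control response
  expect_equal(tagged_response(ear_signal(m, "F40"), ear_signal(m, "F40"),
                               "F40", pars),
               gain_control_response(m, m, pars), tolerance = 1e-14)
  # cross-binaural at the signal tag: one excitatory term, full suppression
  got <- tagged_response(ear_signal(m, "F40"), ear_signal(m, "F35"),
                         "F40", pars)
  expected <- m^pars$p / (pars$Z^pars$q + m^pars$q + pars$omega * m^pars$q)
  expect_equal(got, expected, tolerance = 1e-14)
  # pinned scalar: cross-dichotic read at the masker frequency
  expect_equal(tagged_response(ear_signal(100, "F40"), ear_signal(50, "F35"),
                               "F35", pars),
               3.092615, tolerance = 1e-6)
  expect_error(tagged_response(ear_signal(10, "F40"), ear_signal(0, "NONE"),
                               "F20", pars),
               "unknown readout tag")
})

test_that("the SNR transform is affine with baseline 1", {
  expect_identical(snr_transform(0, 2.5), 1)
  expect_identical(snr_transform(2.5, 2.5), 2)
  r <- seq(0, 10, by = 0.5)
  s <- snr_transform(r, 1.85)
  expect_true(all(diff(s) > 0))
  expect_equal(diff(s), rep(0.5 / 1.85, length(r) - 1))
  # pinned scalar: dichotic masker-only response at 40 Hz
  pars <- table1_params("6d")
  resp <- tagged_response(ear_signal(0, "NONE"), ear_signal(50, "F40"),
                          "F40", pars)
  expect_equal(snr_transform(resp, pars$sigma40), 3.565058,
               tolerance = 1e-6)
  expect_error(snr_transform(1, 0), "positive")
})

test_that("stimulus arrangements resolve to the documented ear mappings", {
  expect_equal(psy_arrangement("MON", 8, 2),
               list(standard = c(8, 0), signal = c(10, 0)))
  expect_equal(psy_arrangement("BIN", 8, 2),
               list(standard = c(8, 8), signal = c(10, 10)))
  expect_equal(psy_arrangement("DICH", 8, 2),
               list(standard = c(8, 0), signal = c(8, 2)))
  expect_equal(psy_arrangement("HALF_BIN", 8, 2),
               list(standard = c(8, 8), signal = c(10, 8)))
  # at pedestal 0, MON / DICH / HALF_BIN are the same stimulus up to ear swap
  mon <- psy_arrangement("MON", 0, 3)
  dich <- psy_arrangement("DICH", 0, 3)
  half <- psy_arrangement("HALF_BIN", 0, 3)
  expect_equal(sort(mon$signal), sort(dich$signal))
  expect_equal(mon$signal, half$signal)
  arr <- eeg_arrangement("CROSS_DICH", 100)
  expect_equal(arr$left$tag, "F40")
  expect_equal(arr$right, list(depth = 50, tag = "F35"))
  expect_equal(eeg_arrangement("MON", 0)$left$tag, "NONE")
})
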