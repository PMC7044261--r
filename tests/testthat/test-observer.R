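test_that("the 2AFC decision rule maps response differences to accuracy", {
  pars <- table1_params("6a")
  expect_equal(prob_correct_2afc(0, pars), 0.5)
  expect_equal(prob_correct_2afc(1e6, pars), 1.0)
  # at delta = sigma40 the observer is at the normal CDF of 1/sqrt(2)
  expect_equal(prob_correct_2afc(pars$sigma40, pars), pnorm(1 / sqrt(2)),
               tolerance = 1e-12)
  expect_equal(prob_correct_2afc(pars$sigma40, pars), 0.7602499,
               tolerance = 1e-6)
})

test_that("the staircase follows the 3-down-1-up rule and terminates", {
  pars <- table1_params("6a")
  cfg <- staircase_config()
  # an always-correct observer: level drops 3 dB after every 3rd trial,
  # no reversals, runs to the trial cap
  tr <- run_staircase("BIN", 0, pars, cfg, observer = function(dm) 1,
                      start_db = 30, seed = 1, quiet = TRUE)
  expect_equal(tr$target_db[1:9], c(30, 30, 30, 27, 27, 27, 24, 24, 24))
  expect_equal(nrow(tr), cfg$max_trials)
  expect_equal(sum(tr$reversal), 0)
  # an always-wrong observer: level rises 3 dB every trial, clipped at 100%
  tr2 <- run_staircase("BIN", 0, pars, cfg, observer = function(dm) 0,
                       start_db = 0, seed = 1, quiet = TRUE)
  expect_equal(tr2$target_db[1:5], c(0, 3, 6, 9, 12))
  expect_true(any(tr2$clipped))
  expect_true(all(tr2$target_pct <= 100))
  # stochastic observers terminate at the lesser of 70 trials / 12 reversals
  for (seed in 1:5) {
    tr3 <- run_staircase("MON", 8, pars, cfg, seed = seed, quiet = TRUE)
    expect_lte(nrow(tr3), cfg$max_trials)
    expect_lte(sum(tr3$reversal), cfg$max_reversals)
    expect_true(nrow(tr3) == cfg$max_trials ||
                  sum(tr3$reversal) == cfg$max_reversals)
  }
})

test_that("staircases converge on the 79.4%-correct tracking level", {
  # the 3-down-1-up rule tracks the level where p(correct) = 0.5^(1/3)
  pars <- table1_params("6a")
  target <- 20 * log10(binsum:::observer_level_at("BIN", 8, pars,
                                                  0.5^(1 / 3)))
  rev_means <- vapply(1:100, function(i) {
    tr <- run_staircase("BIN", 8, pars, seed = i, quiet = TRUE)
    mean(utils::tail(tr$target_db[tr$reversal], 8))
  }, numeric(1))
  expect_lt(abs(mean(rev_means) - target), 1.5)
})

test_that("probit fits recover a known psychometric function", {
  # proportions generated exactly on the curve recover mu as the threshold
  x <- seq(-6, 18, by = 3)
  mu <- 7.2; s <- 5
  p <- 0.5 + 0.5 * pnorm((x - mu) / s)
  n <- 200
  trials <- do.call(rbind, lapply(seq_along(x), function(i) {
    k <- round(n * p[i])
    data.frame(target_db = x[i], correct = rep(c(TRUE, FALSE),
                                               c(k, n - k)))
  }))
  fit <- pool_fit_probit(trials)
  expect_equal(fit$threshold_db, mu, tolerance = 0.05)
  expect_equal(fit$sd, s, tolerance = 0.3)
  expect_equal(fit$threshold_pct, db_to_depth(fit$threshold_db))
  # degenerate data signal rather than fit
  allc <- data.frame(target_db = c(0, 3), correct = TRUE)
  expect_error(pool_fit_probit(allc[c(1, 1, 2, 2), ]), "non-identifiable")
})

test_that("staircase-sampled probit thresholds calibrate to the observer", {
  # one cell's worth of trials (a staircase pair, three repetitions) is
  # fit per cell in the full design. Monte-Carlo calibration: threshold
  # estimates are unbiased, and their spread sits near the information
  # limit for this observer — the expected-Fisher-information bound on
  # SE(mu) is about 1.3 dB for a couple of hundred trials at this cell's
  # shallow effective slope, so the achievable spread cannot be much
  # below that
  pars <- table1_params("6a")
  analytic <- 20 * log10(binsum:::observer_level_at("BIN", 8, pars, 0.75))
  errs <- vapply(1:200, function(run) {
    trials <- do.call(rbind, lapply(1:6, function(k) {
      run_staircase("BIN", 8, pars, seed = run * 101 + k, quiet = TRUE)
    }))
    pool_fit_probit(trials)$threshold_db - analytic
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.5)
  expect_lt(stats::sd(errs), 1.8)
  # and within twice the information bound the calibration is tight
  expect_gte(mean(abs(errs) <= 2.6), 0.95)
})

test_that("the simulated experiment is reproducible and pools detection", {
  pars <- table1_params("6a")
  ds1 <- simulate_experiment(pars, n_reps = 1, seed = 11,
                             pedestals = c(0, 8, 64))
  ds2 <- simulate_experiment(pars, n_reps = 1, seed = 11,
                             pedestals = c(0, 8, 64))
  expect_identical(as.data.frame(ds1), as.data.frame(ds2))
  # pooled detection rows share one threshold across the three conditions
  det <- ds1[ds1$pedestal_pct == 0 & ds1$condition != "BIN", ]
  expect_true(all(det$pooled))
  expect_equal(length(unique(det$threshold_db)), 1)
  expect_false(any(ds1$pooled[ds1$condition == "BIN"]))
  # thresholds sit near the generating observer's dipper predictions
  pred <- dipper_curve("BIN", c(0, 8, 64), pars)
  got <- ds1$threshold_db[ds1$condition == "BIN"]
  expect_true(all(abs(got - pred) < 4))
})

test_that("simulated binaural thresholds sit below monaural everywhere", {
  ds <- simulate_experiment(table1_params("6a"), n_reps = 3, seed = 3)
  wide <- reshape(as.data.frame(ds)[, c("condition", "pedestal_pct",
                                        "threshold_db")],
                  idvar = "pedestal_pct", timevar = "condition",
                  direction = "wide")
  expect_true(all(wide$threshold_db.BIN < wide$threshold_db.MON))
})
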