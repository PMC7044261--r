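test_that("the RMSE metrics do their arithmetic", {
  expect_equal(rmse_db(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse_db(c(5, 7), c(3, 5)), 2)
  expect_equal(rmse_db(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmse_snr(c(1.5, 2.5), c(1, 2)), 0.5)
  expect_equal(rmse_snr(c(2, 0, 1, 1), c(1, 1, 1, 1)), sqrt(2 / 4))
  expect_error(rmse_db(1:3, 1:4), "index sets differ")
})

test_that("noiseless dipper data refit to the generating parameters", {
  truth <- table1_params("6a")
  data <- noiseless_dipper(truth)
  fit <- fit_dipper(data, n_restarts = 12, seed = 1)
  expect_lt(fit$rmse, 0.05)
  expect_gt(fit$params$omega, truth$omega * 0.5)
  expect_lt(fit$params$omega, truth$omega * 2)
  expect_equal(fit$params$Z, truth$Z, tolerance = 0.05)
  # fixing omega = 1 on weak-suppression data must fit worse
  fit_w1 <- fit_dipper(data, fix = list(omega = 1), n_restarts = 8,
                       seed = 1)
  expect_gt(fit_w1$rmse, fit$rmse + 1)
  expect_equal(fit_w1$params$omega, 1)
})

test_that("noiseless EEG data refit to the generating parameters", {
  truth <- table1_params("6d")
  data <- noiseless_eeg(truth)
  fit <- fit_eeg(data, n_restarts = 12, seed = 1)
  expect_lt(fit$rmse, 0.02)
  expect_gt(fit$params$omega, truth$omega * 0.5)
  expect_lt(fit$params$omega, truth$omega * 2)
  fit_w1 <- fit_eeg(data, fix = list(omega = 1), n_restarts = 8, seed = 1)
  expect_gt(fit_w1$rmse, fit$rmse + 0.1)
})

test_that("fits honour the parameter constraints exactly", {
  set.seed(13)
  data <- noiseless_dipper(random_params())
  for (seed in 1:3) {
    fit <- fit_dipper(data, n_restarts = 4, seed = seed, maxit = 200)
    expect_gte(fit$params$q, 2)
    expect_gt(fit$params$p, fit$params$q)
    expect_gt(fit$params$Z, 0)
    expect_gte(fit$params$omega, 0)
    expect_gt(fit$params$sigma40, 0)
  }
})

test_that("fitting is deterministic given data, spec and seed", {
  data <- noiseless_dipper(table1_params("6a"))
  a <- fit_dipper(data, n_restarts = 4, seed = 5, maxit = 200)
  b <- fit_dipper(data, n_restarts = 4, seed = 5, maxit = 200)
  expect_identical(unclass(a$params), unclass(b$params))
  expect_identical(a$rmse, b$rmse)
})

test_that("evaluate_fixed recomputes without optimising", {
  truth <- table1_params("6a")
  data <- noiseless_dipper(truth)
  # empty override reproduces the source parameters' RMSE (about zero here)
  same <- evaluate_fixed(truth, list(), data)
  expect_lt(same$rmse, 1e-5)
  expect_equal(same$n_restarts, 0)
  # raising omega to 1 on weak-suppression data degrades the description
  worse <- evaluate_fixed(truth, list(omega = 1), data)
  expect_gt(worse$rmse, same$rmse + 1)
  expect_equal(worse$params$omega, 1)
  expect_equal(worse$params$p, truth$p)
  # same contract on EEG data
  truth_e <- table1_params("6d")
  data_e <- noiseless_eeg(truth_e)
  expect_lt(evaluate_fixed(truth_e, list(), data_e)$rmse, 1e-9)
  expect_gt(evaluate_fixed(truth_e, list(omega = 1), data_e)$rmse, 0.1)
})

test_that("the nested-model RMSE inequality holds", {
  # free fit <= omega-fixed refit <= omega-overridden evaluation
  truth <- table1_params("6a")
  data <- noiseless_dipper(truth)
  free <- fit_dipper(data, n_restarts = 8, seed = 2)
  fixed <- fit_dipper(data, fix = list(omega = 1), n_restarts = 8, seed = 2)
  override <- evaluate_fixed(free$params, list(omega = 1), data)
  expect_lte(free$rmse, fixed$rmse + 1e-3)
  expect_lte(fixed$rmse, override$rmse + 1e-3)
})

test_that("the comparison table is self-consistent", {
  # empty input: an empty table with the full header
  empty <- table1_report(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("label", "p", "q", "Z", "omega", "rmse", "units") %in%
                    names(empty)))
  truth <- table1_params("6a")
  data <- noiseless_dipper(truth)
  fits <- list(free = evaluate_fixed(truth, list(), data),
               strong = evaluate_fixed(truth, list(omega = 1), data),
               linear = fit_dipper(data, "linear_sum", n_restarts = 6,
                                   seed = 1))
  report <- table1_report(fits, datasets = list(dipper = data))
  expect_equal(nrow(report), 3)
  # each row's RMSE recomputes from its own parameters (no warning fired)
  expect_warning(table1_report(fits, datasets = list(dipper = data)), NA)
  # linear-summation rows do not report a suppression weight
  expect_true(is.na(report$omega[report$label == "linear"]))
  # on noiseless gain-control data the generating model beats linear summation
  expect_lt(report$rmse[report$label == "free"],
            report$rmse[report$label == "linear"])
})
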