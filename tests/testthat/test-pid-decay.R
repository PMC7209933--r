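# Trial extraction, volatile summaries, the first-exposure regression and
# mono/bi-exponential decay fitting.

noiseless_trace <- function(seed = 1, A2 = 8, k2 = 0.02, n_trials = 35) {
  cfg <- generator_config(seed = seed)
  cfg$pid$noise_sd_mv <- 0
  cfg$pid$A2 <- A2
  cfg$pid$k2 <- k2
  cfg$pid$n_trials <- as.integer(n_trials)
  simulate_pid_trace(cfg)
}

test_that("a flat trace yields zero responses and offsets cancel", {
  tr <- noiseless_trace()
  flat <- tr
  flat$signal <- rep(0, length(tr$signal))
  expect_true(all(extract_trials(flat)$response_mv == 0))
  shifted <- tr
  shifted$signal <- tr$signal + 7.5
  expect_equal(extract_trials(shifted)$response_mv,
               extract_trials(tr)$response_mv, tolerance = 1e-9)
})

test_that("extraction round-trips the generator's closed-form amplitudes", {
  cfg <- generator_config(seed = 5)
  tr <- noiseless_trace(seed = 5)
  trials <- extract_trials(tr)
  expected <- cfg$pid$A1 * exp(-cfg$pid$k1 * trials$onset_s / 60) +
    8 * exp(-0.02 * trials$onset_s / 60)
  expect_equal(trials$response_mv, expected, tolerance = 1e-9)
})

test_that("windows outside the trace span are rejected per trial", {
  tr <- noiseless_trace()
  expect_error(extract_trials(tr, baseline_window_s = 1e5), "span")
  expect_error(extract_trials(tr, response_window_s = 1e5), "span")
  expect_error(extract_trials(tr, baseline_window_s = -1), "positive")
})

test_that("volatile summaries use linear-interpolation quantiles", {
  trials <- data.frame(response_mv = c(5, 7, 9, 11, 30),
                       emotion = "fear")
  s <- summarize_volatiles(trials)
  expect_equal(s$median_mv, 9)
  expect_equal(s$q25_mv, 7)
  expect_equal(s$q75_mv, 11)
  one <- summarize_volatiles(data.frame(response_mv = 4.2, emotion = "x"))
  expect_equal(one$median_mv, 4.2)
  expect_equal(one$q25_mv, one$q75_mv)
})

test_that("grouped summaries rank heavier pads above lighter ones", {
  cfg <- generator_config(seed = 2)
  pads <- rbind(
    extract_trials(simulate_pid_trace(cfg, list(weight_mg = 43,
      emotion = "fear", freshness = "first_use", donor_pool_id = "a"))),
    extract_trials(simulate_pid_trace(cfg, list(weight_mg = 113,
      emotion = "fear", freshness = "first_use", donor_pool_id = "b"))))
  s <- summarize_volatiles(pads, group_by = "weight_mg")
  s <- s[order(s$weight_mg), ]
  expect_gt(s$median_mv[2], s$median_mv[1])
})

test_that("the first-exposure regression recovers exact and noisy structure", {
  # exact linear data -> R2 = 1
  d <- expand.grid(weight_mg = c(40, 80, 120),
                   emotion = c("fear", "neutral"),
                   freshness = c("first_use", "second_use"))
  d$response_mv <- 0.1 * d$weight_mg + 4 * (d$emotion == "fear") +
    3 * (d$freshness == "first_use") + 2
  r <- suppressWarnings(volatile_regression(d))  # exact fit
  expect_equal(r$r2, 1, tolerance = 1e-10)
  expect_equal(unname(r$coefficients[, "Estimate"]), c(2, 0.1, 4, 3),
               tolerance = 1e-8)
  # with noise: recovery within the confidence intervals, matches an
  # explicit normal-equations oracle
  set.seed(50)
  d$response_mv <- d$response_mv + rnorm(nrow(d), sd = 0.5)
  r2 <- volatile_regression(d)
  X <- cbind(1, d$weight_mg, d$emotion == "fear", d$freshness == "first_use")
  beta <- solve(crossprod(X), crossprod(X, d$response_mv))
  expect_equal(unname(r2$coefficients[, "Estimate"]), drop(beta),
               tolerance = 1e-8)
  est <- r2$coefficients[, "Estimate"]; se <- r2$coefficients[, "Std. Error"]
  truth <- c(2, 0.1, 4, 3)
  expect_true(all(abs(est - truth) < 3 * se))
})

test_that("permuted responses give near-zero expected R2 and singularity errors", {
  set.seed(51)
  d <- expand.grid(weight_mg = c(40, 80, 120, 160),
                   emotion = c("fear", "neutral"),
                   freshness = c("first_use", "second_use"))
  d$response_mv <- 0.1 * d$weight_mg + rnorm(nrow(d))
  r2s <- replicate(30, {
    dp <- d; dp$response_mv <- sample(d$response_mv)
    volatile_regression(dp)$r2
  })
  # E[R2] = p / (n - 1) under the null
  expect_lt(abs(mean(r2s) - 3 / (nrow(d) - 1)), 0.1)
  dsing <- d[d$emotion == "fear", ]  # emotion constant -> aliased column
  expect_error(volatile_regression(dsing), "singular")
})

test_that("noiseless mono-exponential data are recovered to high precision", {
  cfg <- generator_config(seed = 1)
  cfg$pid$noise_sd_mv <- 0
  cfg$pid$A2 <- 0
  tr <- simulate_pid_trace(cfg)
  fit <- fit_decay(extract_trials(tr), model = "mono")
  expect_true(fit$converged)
  expect_equal(unname(fit$parameters["A"]), cfg$pid$A1, tolerance = 1e-6)
  expect_equal(unname(fit$parameters["k"]), cfg$pid$k1, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("noiseless bi-exponential parameters are recovered within 1%", {
  # rate separation k1/k2 = 10
  cfg <- generator_config(seed = 2)
  cfg$pid$noise_sd_mv <- 0
  cfg$pid$A1 <- 20; cfg$pid$k1 <- 0.5
  cfg$pid$A2 <- 10; cfg$pid$k2 <- 0.05
  trials <- extract_trials(simulate_pid_trace(cfg))
  bi <- fit_decay(trials, model = "bi")
  expect_true(bi$converged)
  expect_equal(unname(bi$parameters), c(20, 0.5, 10, 0.05),
               tolerance = 0.01)
  mono <- fit_decay(trials, model = "mono")
  expect_lt(mono$r2, bi$r2)
})

test_that("the bi-exponential fit never scores below the nested mono fit", {
  for (s in 1:3) {
    cfg <- generator_config(seed = s)
    trials <- extract_trials(simulate_pid_trace(cfg))
    bi <- fit_decay(trials, model = "bi")
    mono <- fit_decay(trials, model = "mono")
    expect_gte(bi$r2, mono$r2 - 1e-6)
    # positive parameters, fast component first, decreasing fit
    expect_true(all(bi$parameters > 0))
    expect_gt(bi$parameters[["k1"]], bi$parameters[["k2"]])
    ft <- predict(bi, t_min = seq(0, 30, by = 1))
    expect_true(all(diff(ft) <= 0) && all(ft >= 0))
  }
})

test_that("default synthetic traces show the bi-over-mono decay signature", {
  cfg <- generator_config(seed = 3)
  trials <- extract_trials(simulate_pid_trace(cfg))
  bi <- fit_decay(trials, model = "bi")
  mono <- fit_decay(trials, model = "mono")
  expect_gte(bi$r2, 0.95)
  expect_lt(mono$r2, bi$r2 - 0.05)
})

test_that("too few trials are rejected", {
  trials <- data.frame(onset_s = seq(30, 180, by = 30),
                       response_mv = 10 * exp(-0.1 * seq(30, 180, by = 30) / 60))
  expect_error(fit_decay(trials[1:4, ], model = "mono"), "at least 5")
  expect_error(fit_decay(trials, model = "bi"), "at least 7")
})
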