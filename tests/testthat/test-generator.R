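# Synthetic donor generator: reproducibility, configured moments, effect
# directions, correlation structure and the latent intensity construction.

test_that("same seed and config give byte-identical donor datasets", {
  cfg <- generator_config(n_donors = 12, seed = 7)
  expect_identical(simulate_donors(cfg), simulate_donors(cfg))
  d2 <- simulate_donors(generator_config(n_donors = 12, seed = 8))
  expect_false(identical(simulate_donors(cfg), d2))
})

test_that("degenerate noise reproduces the configured means exactly", {
  cfg <- degenerate_config()
  d <- simulate_donors(cfg)
  fear <- d[d$condition == "fear", ]
  ph <- cfg$physio
  for (i in seq_len(nrow(ph))) {
    expect_equal(unique(fear[[ph$variable[i]]]), ph$fear_mean[i])
  }
  it <- cfg$item_clusters
  clusters <- fearscore:::fear_item_clusters()
  for (k in seq_len(nrow(it))) {
    for (item in clusters[[it$cluster[k]]]) {
      expect_equal(unique(fear[[paste0("item_", item)]]), it$fear_mean[k])
    }
  }
  expect_true(all(fear$latent_intensity == 1))
})

test_that("fear means exceed neutral means in the documented directions", {
  d <- simulate_donors(generator_config(n_donors = 200, seed = 3))
  fear <- d[d$condition == "fear", ]
  neut <- d[d$condition == "neutral", ]
  for (v in c("scl_tonic", "scr_count", "hr", "rr", "sweat_mg")) {
    expect_gt(mean(fear[[v]]), mean(neut[[v]]))
  }
  ha_neg <- paste0("item_", fearscore:::fear_item_clusters()$ha_neg)
  la_pos <- paste0("item_", fearscore:::fear_item_clusters()$la_pos)
  expect_gt(mean(as.matrix(fear[, ha_neg])), mean(as.matrix(neut[, ha_neg])))
  expect_lt(mean(as.matrix(fear[, la_pos])), mean(as.matrix(neut[, la_pos])))
})

test_that("Monte-Carlo moments match the configuration at large n", {
  cfg <- generator_config(n_donors = 1000, seed = 13)
  d <- simulate_donors(cfg)
  fear_sweat <- d$sweat_mg[d$condition == "fear"]
  mu <- cfg$physio$fear_mean[cfg$physio$variable == "sweat_mg"]
  # total sweat SD includes the intensity-factor share on top of the noise SD
  se <- stats::sd(fear_sweat) / sqrt(length(fear_sweat))
  expect_lt(abs(mean(fear_sweat) - mu), 3 * se)
})

test_that("latent intensity tertiles order every fear endpoint", {
  d <- simulate_donors(generator_config(n_donors = 300, seed = 5))
  fear <- d[d$condition == "fear", ]
  tert <- cut(rank(fear$latent_intensity, ties.method = "first"), 3,
              labels = c("low", "medium", "high"))
  m <- tapply(fear$sweat_mg, tert, mean)
  expect_true(all(diff(m) > 0))
  for (v in c("scl_tonic", "scr_count", "hr", "rr")) {
    expect_gt(cor(fear$latent_intensity, fear[[v]]), 0)
  }
})

test_that("neutral-condition correlations converge to the configured matrix", {
  cfg <- generator_config(n_donors = 2000, seed = 17)
  d <- simulate_donors(cfg)
  neut <- d[d$condition == "neutral", ]
  # continuous physiological block (items are attenuated by discretization)
  phys <- as.matrix(neut[, c("scl_tonic", "scr_count", "hr", "rr", "sweat_mg")])
  r <- cor(phys)
  # entrywise sampling error at n = 2000 is ~0.02, plus a small attenuation
  # from clipping counts/masses at zero
  expect_lt(mean(abs(r[upper.tri(r)] - cfg$cross_cor)), 0.05)
  expect_lt(max(abs(r[upper.tri(r)] - cfg$cross_cor)), 0.08)
  # within-cluster item correlation stays high; rounding ratings to the 0-5
  # integer scale attenuates the latent 0.8 by up to ~0.12 at item SD 0.7
  ha <- as.matrix(neut[, paste0("item_", fearscore:::fear_item_clusters()$la_pos)])
  rr <- cor(ha)
  expect_gt(mean(rr[upper.tri(rr)]), cfg$within_cluster_cor - 0.15)
})

test_that("an indefinite correlation assembly is rejected with the block named", {
  expect_error(
    simulate_donors(generator_config(cross_cor = 0.95,
                                     within_cluster_cor = -0.9)),
    "positive semi-definite")
})

test_that("config invariants are enforced", {
  expect_error(generator_config(n_donors = 2), "n_donors")
  expect_error(generator_config(cross_cor = 1.5), "correlations")
  ph <- fearscore:::default_physio_moments(); ph$fear_sd[1] <- -1
  expect_error(generator_config(physio = ph), "SDs")
  expect_error(generator_config(pid = list(k1 = 0.01, k2 = 0.3)),
               "fast rate constant")
})

test_that("PID traces are reproducible and amplitudes follow the closed form", {
  cfg <- generator_config(seed = 21)
  expect_identical(simulate_pid_trace(cfg), simulate_pid_trace(cfg))

  cfg0 <- cfg
  cfg0$pid$noise_sd_mv <- 0
  cfg0$pid$A2 <- 0
  pm <- list(weight_mg = 50, emotion = "neutral", freshness = "second_use",
             donor_pool_id = "x")
  tr <- simulate_pid_trace(cfg0, pm)
  trials <- extract_trials(tr)
  mult <- (50 / cfg$pid$reference_weight_mg) * cfg$pid$neutral_ratio *
    cfg$pid$second_use_ratio
  expected <- cfg$pid$A1 * exp(-cfg$pid$k1 * trials$onset_s / 60) * mult
  expect_equal(trials$response_mv, expected, tolerance = 1e-9)
  # first trial is the largest when the envelope decays
  expect_equal(which.max(trials$response_mv), 1L)
})

test_that("heavier pads emit more volatiles", {
  cfg <- generator_config(seed = 2)
  light <- extract_trials(simulate_pid_trace(
    cfg, list(weight_mg = 43, emotion = "fear", freshness = "first_use",
              donor_pool_id = "a")))
  heavy <- extract_trials(simulate_pid_trace(
    cfg, list(weight_mg = 113, emotion = "fear", freshness = "first_use",
              donor_pool_id = "b")))
  expect_gt(median(heavy$response_mv), median(light$response_mv))
})

test_that("non-positive trial count and bad pad metadata are rejected", {
  cfg <- generator_config()
  cfg$pid$n_trials <- 0L
  expect_error(simulate_pid_trace(cfg), "n_trials")
  expect_error(simulate_pid_trace(generator_config(),
                                  list(weight_mg = 10, emotion = "angry",
                                       freshness = "first_use",
                                       donor_pool_id = "x")),
               "emotion")
})

test_that("the mid-session break produces a flagged rebound trial", {
  cfg <- generator_config(seed = 4)
  cfg$pid$break_after_trial <- 10L
  tr <- simulate_pid_trace(cfg)
  expect_identical(which(tr$events$post_break), 11L)
  gaps <- diff(tr$events$onset_s)
  expect_gt(gaps[10], cfg$pid$break_duration_s)
})
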