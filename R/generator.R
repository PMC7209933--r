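# Synthetic donor datasets and photo-ionization-detector (PID) traces with
# the statistical structure the downstream analysis assumes: two
# within-subject conditions (fear vs neutral), moderate cross-variable
# correlations, strongly correlated questionnaire items within circumplex
# clusters, a latent per-donor fear intensity that co-drives every
# fear-condition endpoint, and PID trial amplitudes that scale with pad
# weight/emotion/freshness and decay bi-exponentially over a session.

# Canonical circumplex membership of the 20 questionnaire items:
# high/low arousal crossed with positive/negative affect.
fear_item_clusters <- function() {
  list(
    ha_pos = c("surprised", "excited", "elated"),
    ha_neg = c("upset", "stressed", "nervous", "tense", "alert", "fearful",
               "angry", "disgusted"),
    la_neg = c("sad", "depressed", "lethargic", "fatigued"),
    la_pos = c("happy", "content", "serene", "relaxed", "calm")
  )
}

#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the donor-dataset and PID-trace generators into a
#' validated list. Defaults emulate a sweat-donation study: 36 male donors
#' watching fear-inducing versus calm-neutral film clips in two
#' within-subject sessions, with large fear-vs-neutral separations on tonic
#' skin conductance level (SCL, uS), phasic skin conductance response count
#' (SCR), heart rate (bpm), respiratory rate (breaths/min) and armpit sweat
#' mass (mg per 75 cm2 pad), moderate (~0.5) cross-variable correlations and
#' high (~0.8) correlations among questionnaire items of the same circumplex
#' cluster. A latent per-donor fear intensity scales all fear-condition
#' effects jointly, so stronger responders respond more strongly on every
#' endpoint at once.
#'
#' @param n_donors number of donors (>= 3); each contributes one fear and one
#'   neutral record.
#' @param seed integer master seed; identical config => byte-identical data.
#' @param physio data frame with columns `variable`, `fear_mean`, `fear_sd`,
#'   `neutral_mean`, `neutral_sd` for the five physiological endpoints
#'   `scl_tonic`, `scr_count`, `hr`, `rr`, `sweat_mg`.
#' @param item_clusters data frame with per-cluster rating moments (columns
#'   `cluster`, `fear_mean`, `fear_sd`, `neutral_mean`, `neutral_sd`) for the
#'   four circumplex clusters `ha_pos`, `ha_neg`, `la_neg`, `la_pos`.
#' @param within_cluster_cor latent correlation between items of the same
#'   cluster (default 0.8).
#' @param cross_cor residual latent correlation between any two variables
#'   not in the same item cluster (default 0.3). In the fear condition the
#'   shared intensity factor adds further correlation on top, bringing the
#'   observed cross-variable correlations to the moderate ~0.5 level the
#'   analysis assumes.
#' @param intensity_spread standard deviation of the latent per-donor fear
#'   intensity multiplier (mean 1). 0 switches individual differences off.
#' @param intensity_floor lower bound of the intensity multiplier (default
#'   0.5). Donor studies screen out non-responders at intake and exclude
#'   donors whose fear-condition response resembles calm, so every retained
#'   donor shows at least about half the average fear effect. The multiplier
#'   is `floor + Gamma excess` with overall mean 1 and SD
#'   `intensity_spread`; the gamma excess makes the intensity distribution
#'   right-skewed, matching the wider spread observed in high-intensity
#'   composite-score groups.
#' @param rating_noise_sd residual noise (rating units) on the direct arousal
#'   and valence ratings beyond what the item clusters explain.
#' @param pid list of PID-trace parameters: fast/slow decay amplitudes
#'   `A1`,`A2` (mV) and rate constants `k1`,`k2` (1/min, `k1 > k2 > 0`),
#'   `n_trials`, `mean_iti_s` and `iti_jitter_s` (per-pad inter-trial time,
#'   s), `stim_duration_s`, `sample_rate_hz`, `noise_sd_mv`,
#'   `reference_weight_mg` (pad weight at which the weight multiplier is 1),
#'   `neutral_ratio` and `second_use_ratio` (amplitude multipliers for
#'   neutral emotion and re-used pads), and the optional mid-session break
#'   (`break_after_trial`, `break_duration_s`, `rebound`).
#' @return object of class `generator_config`.
#' @seealso [simulate_donors()], [simulate_pid_trace()]
#' @export
generator_config <- function(n_donors = 36,
                             seed = 1L,
                             physio = default_physio_moments(),
                             item_clusters = default_item_moments(),
                             within_cluster_cor = 0.8,
                             cross_cor = 0.3,
                             intensity_spread = 0.35,
                             intensity_floor = 0.5,
                             rating_noise_sd = 0.3,
                             pid = default_pid_params()) {
  pid_defaults <- default_pid_params()
  pid <- utils::modifyList(pid_defaults, as.list(pid))
  cfg <- structure(
    list(n_donors = as.integer(n_donors), seed = as.integer(seed),
         physio = physio, item_clusters = item_clusters,
         within_cluster_cor = within_cluster_cor, cross_cor = cross_cor,
         intensity_spread = intensity_spread,
         intensity_floor = intensity_floor,
         rating_noise_sd = rating_noise_sd, pid = pid),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

# Fear/neutral moments for the physiological endpoints. The sweat means
# follow the printed study values (fear-condition tertile means averaging
# ~95 mg/75 cm2 vs 28 mg neutral); the remaining endpoints are
# physiologically plausible round numbers: they are configuration, not
# ground truth.
default_physio_moments <- function() {
  data.frame(
    variable     = c("scl_tonic", "scr_count", "hr", "rr", "sweat_mg"),
    fear_mean    = c(4.5, 24, 76, 17, 95),
    fear_sd      = c(0.8,  4,  6, 1.5, 60),
    neutral_mean = c(1.5,  8, 70, 14, 28),
    neutral_sd   = c(0.5, 2.5,  5, 1.2, 15),
    stringsAsFactors = FALSE)
}

default_item_moments <- function() {
  data.frame(
    cluster      = c("ha_pos", "ha_neg", "la_neg", "la_pos"),
    fear_mean    = c(2.0, 3.0, 0.8, 1.0),
    fear_sd      = c(0.7, 0.7, 0.5, 0.6),
    neutral_mean = c(1.0, 0.5, 1.2, 3.5),
    neutral_sd   = c(0.6, 0.4, 0.6, 0.7),
    stringsAsFactors = FALSE)
}

default_pid_params <- function() {
  list(A1 = 25, k1 = 0.35, A2 = 8, k2 = 0.02,
       n_trials = 35L, mean_iti_s = 51, iti_jitter_s = 5,
       stim_duration_s = 5, sample_rate_hz = 10, noise_sd_mv = 0.5,
       reference_weight_mg = 100, neutral_ratio = 0.5,
       second_use_ratio = 0.55,
       break_after_trial = NA_integer_, break_duration_s = 300,
       rebound = 1.5)
}

validate_generator_config <- function(cfg) {
  if (!inherits(cfg, "generator_config")) stop("not a generator_config")
  if (cfg$n_donors < 3) stop("n_donors must be >= 3")
  ph <- cfg$physio
  need <- c("variable", "fear_mean", "fear_sd", "neutral_mean", "neutral_sd")
  if (!all(need %in% names(ph))) stop("physio table misses required columns")
  if (!setequal(ph$variable, default_physio_moments()$variable)) {
    stop("physio table must describe scl_tonic, scr_count, hr, rr, sweat_mg")
  }
  if (any(ph$fear_sd < 0) || any(ph$neutral_sd < 0)) {
    stop("all physiological SDs must be >= 0")
  }
  it <- cfg$item_clusters
  if (!setequal(it$cluster, names(fear_item_clusters()))) {
    stop("item_clusters must describe ha_pos, ha_neg, la_neg, la_pos")
  }
  if (any(it$fear_sd < 0) || any(it$neutral_sd < 0)) {
    stop("all item SDs must be >= 0")
  }
  for (r in c(cfg$within_cluster_cor, cfg$cross_cor)) {
    if (!is.finite(r) || r < -1 || r > 1) stop("correlations must lie in [-1, 1]")
  }
  if (cfg$intensity_spread < 0) stop("intensity_spread must be >= 0")
  if (cfg$intensity_floor < 0 || cfg$intensity_floor > 1) {
    stop("intensity_floor must lie in [0, 1]")
  }
  p <- cfg$pid
  if (any(c(p$k1, p$k2) <= 0)) stop("PID rate constants must be > 0")
  if (p$k1 <= p$k2) stop("fast rate constant k1 must exceed slow constant k2")
  if (any(c(p$A1, p$A2) < 0)) stop("PID amplitudes must be >= 0")
  if (p$noise_sd_mv < 0) stop("PID noise SD must be >= 0")
  invisible(cfg)
}

# Latent correlation matrix over the 5 physiological endpoints and 20 items:
# compound symmetry at `cross_cor`, elevated to `within_cluster_cor` inside
# each item cluster. Positive semi-definiteness is checked per item block and
# for the full assembly.
build_latent_correlation <- function(cfg) {
  clusters <- fear_item_clusters()
  items <- unlist(clusters, use.names = FALSE)
  vars <- c(default_physio_moments()$variable, items)
  p <- length(vars)
  R <- matrix(cfg$cross_cor, p, p)
  for (cl in names(clusters)) {
    idx <- match(clusters[[cl]], vars)
    R[idx, idx] <- cfg$within_cluster_cor
    block <- R[idx, idx]; diag(block) <- 1
    if (min(eigen(block, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop(sprintf("correlation block for item cluster '%s' is not positive semi-definite", cl))
    }
  }
  diag(R) <- 1
  dimnames(R) <- list(vars, vars)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(
      "assembled cross-variable/within-cluster correlation matrix is not positive semi-definite (min eigenvalue %.3g); check cross_cor = %.2f against within_cluster_cor = %.2f",
      min(ev), cfg$cross_cor, cfg$within_cluster_cor))
  }
  R
}

#' Generate a synthetic donor dataset
#'
#' Draws one fear and one neutral record per donor. On a latent scale, all 25
#' variables (5 physiological endpoints + 20 questionnaire items) are jointly
#' multivariate normal with the configured correlation structure. In the fear
#' condition each donor's effect sizes are scaled by a hidden latent
#' intensity multiplier (mean 1, SD `intensity_spread`), so intense
#' responders exceed mild responders on every endpoint jointly. Items are
#' then discretized to the 0-5 rating scale by rounding and clipping;
#' physiological values are clipped at 0. Direct arousal and valence ratings
#' are derived from the item clusters (arousal tracks the high-arousal items,
#' valence the positive-minus-negative contrast), which reproduces the strong
#' multicollinearity these two ratings introduce when entered as predictors
#' next to the cluster scores.
#'
#' @param config a [generator_config()].
#' @return data frame with one row per donor x condition: `donor_id`,
#'   `condition` (`"fear"`/`"neutral"`), `scl_tonic`, `scr_count`, `hr`,
#'   `rr`, `sweat_mg`, twenty `item_*` ratings on 0-5, `arousal`, `valence`
#'   and the hidden `latent_intensity` (emitted for parameter-recovery
#'   checks only; identical on a donor's two rows).
#' @export
simulate_donors <- function(config) {
  validate_generator_config(config)
  R <- build_latent_correlation(config)
  clusters <- fear_item_clusters()
  items <- unlist(clusters, use.names = FALSE)
  vars <- colnames(R)
  n <- config$n_donors

  ph <- config$physio
  it <- config$item_clusters
  item_cluster_of <- rep(names(clusters), lengths(clusters))
  moment <- function(col) {
    m <- numeric(length(vars)); names(m) <- vars
    m[ph$variable] <- ph[[col]]
    m[items] <- it[[col]][match(item_cluster_of, it$cluster)]
    m
  }
  mu_f <- moment("fear_mean");    sd_f <- moment("fear_sd")
  mu_n <- moment("neutral_mean"); sd_n <- moment("neutral_sd")

  local_seed(config$seed, {
    g <- draw_intensity(n, config$intensity_floor, config$intensity_spread)
    zf <- rmvnorm_chol(n, R)
    zn <- rmvnorm_chol(n, R)
    fear <- sweep(zf, 2, sd_f, `*`) +
      outer(g, mu_f - mu_n) + matrix(mu_n, n, length(vars), byrow = TRUE)
    neut <- sweep(zn, 2, sd_n, `*`) + matrix(mu_n, n, length(vars), byrow = TRUE)

    finalize <- function(x) {
      colnames(x) <- vars
      x[, items] <- round(clip(x[, items], 0, 5))
      x[, ph$variable] <- pmax(x[, ph$variable], 0)
      x[, "scr_count"] <- round(x[, "scr_count"])
      x
    }
    fear <- finalize(fear); neut <- finalize(neut)

    # Direct arousal/valence ratings derived from the circumplex clusters.
    derive_av <- function(x) {
      ha <- rowMeans(x[, c(clusters$ha_neg, clusters$ha_pos), drop = FALSE])
      pos <- rowMeans(x[, c(clusters$ha_pos, clusters$la_pos), drop = FALSE])
      neg <- rowMeans(x[, c(clusters$ha_neg, clusters$la_neg), drop = FALSE])
      ar <- round(clip(1.25 * ha + stats::rnorm(nrow(x), 0, config$rating_noise_sd), 0, 5))
      va <- round(clip(2.5 + 0.8 * (pos - neg) +
                         stats::rnorm(nrow(x), 0, config$rating_noise_sd), 0, 5))
      cbind(arousal = ar, valence = va)
    }
    av_f <- derive_av(fear); av_n <- derive_av(neut)

    ids <- sprintf("d%03d", seq_len(n))
    one <- function(x, av, cond) {
      out <- data.frame(donor_id = ids, condition = cond,
                        x[, ph$variable, drop = FALSE],
                        stringsAsFactors = FALSE)
      item_df <- as.data.frame(x[, items, drop = FALSE])
      names(item_df) <- paste0("item_", items)
      cbind(out, item_df, as.data.frame(av), latent_intensity = g)
    }
    out <- rbind(one(fear, av_f, "fear"), one(neut, av_n, "neutral"))
    out <- out[order(out$donor_id, out$condition), ]
    rownames(out) <- NULL
    out
  })
}

# Latent fear-intensity multiplier: screening floor plus a right-skewed
# gamma excess, overall mean 1 and SD `spread`.
draw_intensity <- function(n, floor, spread) {
  if (spread == 0 || floor >= 1) return(rep(1, n))
  excess <- 1 - floor
  shape <- (excess / spread)^2
  floor + stats::rgamma(n, shape = shape, rate = excess / spread^2)
}

pid_envelope <- function(t_min, pid) {
  pid$A1 * exp(-pid$k1 * t_min) + pid$A2 * exp(-pid$k2 * t_min)
}

#' Generate a synthetic PID trace for one sweat pad
#'
#' Simulates a photo-ionization-detector recording (mV versus time) of the
#' headspace above a sweat pad presented repeatedly through an olfactometer.
#' Each stimulus-on window adds a square response whose amplitude follows a
#' bi-exponential decay envelope `A1 * exp(-k1 t) + A2 * exp(-k2 t)` (t in
#' minutes since session start) scaled by pad weight, emotion and freshness
#' multipliers, on top of Gaussian sensor noise. The first trial is the
#' largest in expectation, reflecting volatiles accumulating in the vial's
#' headspace before release. An optional mid-session break reproduces the
#' headspace-rebound artefact: the first post-break trial is amplified and
#' flagged so curve fitting can exclude it.
#'
#' @param config a [generator_config()]; the `pid` element and `seed` are
#'   used.
#' @param pad_meta list with `weight_mg`, `emotion` (`"fear"`/`"neutral"`),
#'   `freshness` (`"first_use"`/`"second_use"`) and `donor_pool_id`.
#' @return object of class `pid_trace`: uniformly sampled `time` (s) and
#'   `signal` (mV), an `events` data frame (`onset_s`, `duration_s`,
#'   `trial`, `post_break`) and the `pad_meta`.
#' @export
simulate_pid_trace <- function(config,
                               pad_meta = list(weight_mg = 100,
                                               emotion = "fear",
                                               freshness = "first_use",
                                               donor_pool_id = "pool1")) {
  validate_generator_config(config)
  p <- config$pid
  if (is.null(p$n_trials) || p$n_trials <= 0) stop("n_trials must be positive")
  if (!pad_meta$emotion %in% c("fear", "neutral")) {
    stop("pad_meta$emotion must be 'fear' or 'neutral'")
  }
  if (!pad_meta$freshness %in% c("first_use", "second_use")) {
    stop("pad_meta$freshness must be 'first_use' or 'second_use'")
  }
  if (!is.numeric(pad_meta$weight_mg) || pad_meta$weight_mg <= 0) {
    stop("pad_meta$weight_mg must be positive")
  }

  mult <- (pad_meta$weight_mg / p$reference_weight_mg) *
    (if (pad_meta$emotion == "neutral") p$neutral_ratio else 1) *
    (if (pad_meta$freshness == "second_use") p$second_use_ratio else 1)

  local_seed(config$seed, {
    n <- as.integer(p$n_trials)
    iti <- p$mean_iti_s + stats::runif(n - 1, -p$iti_jitter_s, p$iti_jitter_s)
    onsets <- 30 + c(0, cumsum(iti))
    post_break <- rep(FALSE, n)
    if (!is.na(p$break_after_trial) && p$break_after_trial >= 1 &&
        p$break_after_trial < n) {
      k <- as.integer(p$break_after_trial)
      onsets[(k + 1):n] <- onsets[(k + 1):n] + p$break_duration_s
      post_break[k + 1] <- TRUE
    }
    span <- ceiling(onsets[n] + p$stim_duration_s + 30)
    time <- seq(0, span, by = 1 / p$sample_rate_hz)
    signal <- stats::rnorm(length(time), 0, p$noise_sd_mv)
    amp <- pid_envelope(onsets / 60, p) * mult
    amp[post_break] <- amp[post_break] * p$rebound
    for (i in seq_len(n)) {
      idx <- time > onsets[i] & time <= onsets[i] + p$stim_duration_s
      signal[idx] <- signal[idx] + amp[i]
    }
    structure(
      list(time = time, signal = signal,
           events = data.frame(onset_s = onsets,
                               duration_s = p$stim_duration_s,
                               trial = seq_len(n), post_break = post_break),
           pad_meta = pad_meta),
      class = "pid_trace")
  })
}

#' @export
print.pid_trace <- function(x, ...) {
  cat(sprintf("PID trace: %d samples over %.1f min, %d trials\n",
              length(x$time), max(x$time) / 60, nrow(x$events)))
  cat(sprintf("pad: %.0f mg, %s, %s\n", x$pad_meta$weight_mg,
              x$pad_meta$emotion, x$pad_meta$freshness))
  invisible(x)
}
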