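# Quantification of sweat volatiles from PID traces and modelling of their
# decay over repeated exposures: per-trial baseline-corrected responses,
# group summaries, a multiple regression of first-exposure responses on pad
# weight/emotion/freshness, and mono- vs bi-exponential decay fits by
# multi-start nonlinear least squares.

#' Extract per-trial responses from a PID trace
#'
#' The response of a trial is the mean signal over the stimulus-on window
#' minus the mean over a pre-onset baseline window — the simplest robust
#' reduction of a square-pulse trace, and invariant to constant offsets.
#'
#' @param trace a `pid_trace` (see [simulate_pid_trace()] /
#'   [read_pid_trace()]).
#' @param baseline_window_s baseline length (s) immediately before onset.
#' @param response_window_s response window length (s) from onset; `NULL`
#'   uses each trial's stimulus duration.
#' @return data frame: `trial`, `onset_s`, `response_mv`, `post_break`,
#'   plus the pad metadata columns `weight_mg`, `emotion`, `freshness`,
#'   `donor_pool_id`.
#' @export
extract_trials <- function(trace, baseline_window_s = 3,
                           response_window_s = NULL) {
  stopifnot(inherits(trace, "pid_trace"))
  ev <- trace$events
  if (is.null(ev) || !nrow(ev)) stop("trace has no stimulus events")
  if (baseline_window_s <= 0) stop("baseline window must be positive")
  t <- trace$time; s <- trace$signal
  resp <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    win <- if (is.null(response_window_s)) ev$duration_s[i] else response_window_s
    if (win <= 0) stop("response window must be positive")
    on <- ev$onset_s[i]
    if (on - baseline_window_s < min(t) || on + win > max(t)) {
      stop(sprintf("trial %d: window exceeds trace span", ev$trial[i]))
    }
    stim <- t > on & t <= on + win
    base <- t > on - baseline_window_s & t <= on
    if (!any(stim) || !any(base)) {
      stop(sprintf("trial %d: empty stimulus or baseline window", ev$trial[i]))
    }
    resp[i] <- mean(s[stim]) - mean(s[base])
  }
  pm <- trace$pad_meta
  out <- data.frame(trial = ev$trial, onset_s = ev$onset_s,
                    response_mv = resp,
                    post_break = if ("post_break" %in% names(ev)) ev$post_break else FALSE,
                    weight_mg = pm$weight_mg, emotion = pm$emotion,
                    freshness = pm$freshness, donor_pool_id = pm$donor_pool_id,
                    stringsAsFactors = FALSE)
  out[order(out$onset_s), ]
}

#' Median and IQR of volatile responses per group
#'
#' Summarizes trial responses by median and interquartile range (25th-75th
#' percentiles, linear-interpolation quantiles, R type 7).
#'
#' @param trials data frame of trial responses (possibly several pads
#'   row-bound), with a `response_mv` column.
#' @param group_by character vector of grouping columns (default
#'   `"emotion"`).
#' @return data frame with the grouping columns plus `n`, `median_mv`,
#'   `q25_mv`, `q75_mv`.
#' @export
summarize_volatiles <- function(trials, group_by = "emotion") {
  if (!all(group_by %in% names(trials))) {
    stop("group_by columns missing from trials")
  }
  key <- interaction(trials[group_by], drop = TRUE, sep = "\r")
  parts <- split(trials, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    q <- stats::quantile(d$response_mv, c(0.25, 0.5, 0.75), type = 7)
    cbind(d[1, group_by, drop = FALSE],
          data.frame(n = nrow(d), median_mv = q[[2]], q25_mv = q[[1]],
                     q75_mv = q[[3]]))
  }))
  rownames(out) <- NULL
  out
}

#' Regression of first-exposure volatile responses on pad properties
#'
#' Ordinary least squares of the first-exposure response (mV) on sweat pad
#' weight (mg), emotion (fear = 1, neutral = 0) and freshness (first use =
#' 1, second use = 0), with intercept.
#'
#' @param responses data frame with columns `response_mv`, `weight_mg`,
#'   `emotion`, `freshness` — one row per pad's first exposure.
#' @return list: `coefficients` table (estimate, std error, t, two-tailed
#'   p), overall `F`, `df` (`(p, n - p - 1)`), `p`, `r2`, the coding used,
#'   and the `lm` fit.
#' @export
volatile_regression <- function(responses) {
  need <- c("response_mv", "weight_mg", "emotion", "freshness")
  if (!all(need %in% names(responses))) {
    stop("responses must have columns response_mv, weight_mg, emotion, freshness")
  }
  d <- data.frame(response_mv = responses$response_mv,
                  weight_mg = responses$weight_mg,
                  emotion = as.numeric(responses$emotion == "fear"),
                  freshness = as.numeric(responses$freshness == "first_use"))
  if (nrow(d) <= ncol(d)) stop("need more observations than predictors + 1")
  fit <- stats::lm(response_mv ~ weight_mg + emotion + freshness, data = d)
  if (any(is.na(stats::coef(fit)))) stop("singular design matrix")
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(coefficients = stats::coef(sm),
       F = unname(fstat[1]), df = unname(fstat[2:3]),
       p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
       r2 = sm$r.squared,
       coding = c(emotion = "fear = 1, neutral = 0",
                  freshness = "first_use = 1, second_use = 0"),
       fit = fit)
}

decay_fun <- function(model) {
  if (model == "mono") {
    function(par, t) exp(par[1]) * exp(-exp(par[2]) * t)
  } else {
    function(par, t) exp(par[1]) * exp(-exp(par[2]) * t) +
      exp(par[3]) * exp(-exp(par[4]) * t)
  }
}

#' Fit a mono- or bi-exponential decay to trial responses
#'
#' Nonlinear least squares of response (mV) against trial onset time
#' (minutes): `A exp(-k t)` or `A1 exp(-k1 t) + A2 exp(-k2 t)` with no
#' offset term. Amplitudes and rate constants are constrained positive by
#' log-parameterization, and local minima are avoided with multi-start
#' Levenberg-Marquardt from a log-spaced grid of rate constants (for the
#' bi-exponential, additionally from perturbations of the mono solution, so
#' the nested bi fit can only improve on the mono fit). For the
#' bi-exponential, `k1 > k2` by convention (fast component first).
#'
#' @param trials data frame with `onset_s` and `response_mv` (as from
#'   [extract_trials()]); rebound trials flagged `post_break` are excluded
#'   by default.
#' @param model `"bi"` (default) or `"mono"`.
#' @param n_starts number of seeded restarts (>= 20 recommended).
#' @param exclude_post_break drop trials flagged as post-break rebound.
#' @return object of class `decay_fit`: `model`, `parameters` (`A`, `k` or
#'   `A1`, `k1`, `A2`, `k2`; mV and 1/min), `r2` on the original scale,
#'   `converged`, `n_restarts_used`, `fitted`, and the data used.
#' @export
fit_decay <- function(trials, model = c("bi", "mono"), n_starts = 20,
                      exclude_post_break = TRUE) {
  model <- match.arg(model)
  d <- trials
  if (exclude_post_break && "post_break" %in% names(d)) {
    d <- d[!d$post_break, ]
  }
  t <- d$onset_s / 60
  y <- d$response_mv
  stopifnot_numeric(t, "onset_s"); stopifnot_numeric(y, "response_mv")
  min_n <- if (model == "mono") 5 else 7
  if (length(y) < min_n) {
    stop(sprintf("need at least %d trials for a %s-exponential fit", min_n, model))
  }

  f <- decay_fun(model)
  sse <- function(par) sum((y - f(par, t))^2)
  y_pos <- max(mean(pmax(y, 0)), 1e-6)
  k_grid <- 10^seq(-2.5, 1, length.out = max(n_starts, 6))

  # Closed-form amplitude for a given rate (least squares through the
  # origin) gives well-placed starts.
  amp_for <- function(k) {
    e <- exp(-k * t)
    max(sum(y * e) / sum(e^2), 1e-6)
  }

  starts <- list()
  if (model == "mono") {
    for (k in k_grid[seq_len(n_starts)]) {
      starts[[length(starts) + 1]] <- c(log(amp_for(k)), log(k))
    }
  } else {
    mono_fit <- fit_decay(trials, model = "mono", n_starts = n_starts,
                          exclude_post_break = exclude_post_break)
    A_m <- mono_fit$parameters[["A"]]; k_m <- mono_fit$parameters[["k"]]
    kg <- 10^seq(-2.5, 1, length.out = 7)
    for (i in seq_along(kg)) for (j in seq_along(kg)) {
      if (kg[i] <= kg[j]) next
      starts[[length(starts) + 1]] <-
        c(log(amp_for(kg[i])), log(kg[i]), log(amp_for(kg[j])), log(kg[j]))
    }
    # embeddings of the mono solution: bi can only do at least as well
    starts[[length(starts) + 1]] <-
      c(log(max(A_m, 1e-6)), log(k_m * 3), log(max(A_m / 3, 1e-6)), log(k_m / 3))
    starts[[length(starts) + 1]] <-
      c(log(max(A_m, 1e-6)), log(k_m), log(max(A_m * 1e-4, 1e-10)), log(k_m / 10))
  }

  best <- NULL; best_sse <- Inf; used <- 0L; converged <- FALSE
  for (st in starts) {
    used <- used + 1L
    res <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = st,
        fn = function(par) y - f(par, t),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(res)) next
    s <- sse(res$par)
    ok <- res$info %in% 1:4
    if (s < best_sse) {
      best_sse <- s; best <- res$par; converged <- ok
    }
  }
  if (is.null(best)) {
    # all restarts errored; report the best grid start as-is
    gs <- vapply(starts, sse, numeric(1))
    best <- starts[[which.min(gs)]]
    best_sse <- min(gs)
    converged <- FALSE
  }

  par <- exp(best)
  if (model == "mono") {
    parameters <- c(A = par[1], k = par[2])
  } else {
    if (par[2] < par[4]) par <- par[c(3, 4, 1, 2)]   # enforce k1 > k2
    parameters <- c(A1 = par[1], k1 = par[2], A2 = par[3], k2 = par[4])
  }
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(model = model, parameters = parameters,
         r2 = 1 - best_sse / ss_tot, sse = best_sse,
         converged = converged, n_restarts_used = used,
         fitted = f(log(par), t),
         data = data.frame(t_min = t, response_mv = y)),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("%s-exponential decay fit (%d restarts, converged: %s)\n",
              x$model, x$n_restarts_used, x$converged))
  print(round(x$parameters, 5))
  cat(sprintf("R2 = %.4f on %d trials\n", x$r2, nrow(x$data)))
  invisible(x)
}

#' @export
predict.decay_fit <- function(object, t_min = NULL, ...) {
  if (is.null(t_min)) return(object$fitted)
  decay_fun(object$model)(log(object$parameters), t_min)
}

#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(x$data$t_min, x$data$response_mv, pch = 19,
                 xlab = "time (min)", ylab = "response (mV)", ...)
  tt <- seq(min(x$data$t_min), max(x$data$t_min), length.out = 200)
  graphics::lines(tt, decay_fun(x$model)(log(x$parameters), tt),
                  col = "firebrick", lwd = 2)
  invisible(x)
}
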