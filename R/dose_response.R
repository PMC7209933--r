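# Univariate fear-vs-neutral contrasts and the fear-intensity -> sweat
# dose-response statistics. The endpoints are generally not normally
# distributed, so paired contrasts use the Wilcoxon signed-rank test and
# correlations are Spearman by default.

contrast_result <- function(statistic, value, df, p, tails, effect = NULL,
                            extra = list()) {
  structure(c(list(statistic = statistic, value = value, df = df, p = p,
                   tails = tails, effect_size = effect), extra),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  dfs <- if (is.null(x$df)) "" else sprintf("(%s) ", paste(x$df, collapse = ","))
  cat(sprintf("%s %s= %.4g, p = %.4g (%s)\n", x$statistic, dfs, x$value,
              x$p, x$tails))
  if (!is.null(x$effect_size)) {
    cat(sprintf("effect size: %.3f\n", x$effect_size))
  }
  invisible(x)
}

#' Paired Wilcoxon signed-rank test with normal approximation
#'
#' Tests a paired fear-vs-neutral difference. Zero differences are
#' discarded, tied absolute differences receive mid-ranks, and the
#' tie-corrected normal approximation yields a Z statistic (positive when
#' the first vector exceeds the second; no continuity correction).
#'
#' @param fear_values,neutral_values equal-length paired vectors (n >= 5).
#' @param alternative `"two.sided"` (default), `"greater"` (fear >
#'   neutral) or `"less"`.
#' @return a `contrast_result` with the `Z` statistic, p value, the number
#'   of pairs used (`n_used`) and discarded zeros (`n_zero`).
#' @export
paired_signed_rank <- function(fear_values, neutral_values,
                               alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot_numeric(fear_values, "fear_values")
  stopifnot_numeric(neutral_values, "neutral_values")
  if (length(fear_values) != length(neutral_values)) {
    stop("paired vectors must have equal length")
  }
  if (length(fear_values) < 5) stop("need at least 5 pairs")
  d <- fear_values - neutral_values
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero")
  n <- length(d)
  r <- rank(abs(d))   # mid-ranks for ties
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w_pos - mu) / sqrt(sigma2)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  contrast_result("Z", z, df = NULL, p = p,
                  tails = if (alternative == "two.sided") "two-tailed" else "one-tailed",
                  extra = list(n_used = n, n_zero = n_zero,
                               alternative = alternative))
}

#' Linear-contrast one-way ANOVA across ordered groups
#'
#' Tests a linear trend over ordered groups (weights `-1, 0, +1` for three
#' groups; equally spaced centred weights in general).
#' `F = SS_contrast / MS_within` on `(1, N - k)` degrees of freedom;
#' `eta2 = SS_contrast / SS_total`.
#'
#' @param values numeric outcome vector.
#' @param ordered_groups ordered factor (or value coercible with a stated
#'   order) of the same length; each group needs >= 2 members.
#' @return a `contrast_result` with the F statistic, df, p (upper tail) and
#'   eta-squared effect size.
#' @export
linear_contrast_anova <- function(values, ordered_groups) {
  stopifnot_numeric(values, "values")
  if (!is.ordered(ordered_groups)) {
    stop("groups must be an ordered factor (the contrast needs an order)")
  }
  g <- droplevels(ordered_groups)
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 groups")
  n_j <- tabulate(g)
  if (any(n_j < 2)) stop("each group needs at least 2 members")
  w <- seq_len(k) - (k + 1) / 2          # -1, 0, +1 for k = 3
  m_j <- tapply(values, g, mean)
  ss_contrast <- sum(w * m_j)^2 / sum(w^2 / n_j)
  ss_within <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  N <- length(values)
  ms_within <- ss_within / (N - k)
  f <- ss_contrast / ms_within
  ss_total <- sum((values - mean(values))^2)
  contrast_result("F", f, df = c(1, N - k),
                  p = stats::pf(f, 1, N - k, lower.tail = FALSE),
                  tails = "upper tail",
                  effect = ss_contrast / ss_total)
}

#' Spearman rank correlation with t-approximation p value
#'
#' Rank correlation with mid-ranks for ties; the p value uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list: `rho`, `p`, `statistic` (t), `df`, `n`.
#' @export
spearman <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot_numeric(x, "x"); stopifnot_numeric(y, "y")
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    t_stat <- sign(rho) * Inf
    p <- if (alternative == "two.sided") 0 else
      if ((alternative == "greater") == (rho > 0)) 0 else 1
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- switch(alternative,
                two.sided = 2 * stats::pt(-abs(t_stat), n - 2),
                greater = stats::pt(t_stat, n - 2, lower.tail = FALSE),
                less = stats::pt(t_stat, n - 2))
  }
  list(rho = rho, p = p, statistic = t_stat, df = n - 2, n = n)
}

#' Pairwise correlation table of the CFS and the predictors
#'
#' Symmetric correlation matrix (unit diagonal) of the composite fear score
#' against the physiological and subjective predictors, Spearman by default
#' (Pearson by flag). The matrix backs a correlation heat map.
#'
#' @param feature_matrix data frame of numeric predictor columns (e.g. the
#'   fear-condition rows of [build_feature_matrix()]).
#' @param cfs optional score vector prepended as the first column `cfs`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param file optional path; when given the matrix is also written as CSV.
#' @return correlation matrix.
#' @export
correlation_heatmap <- function(feature_matrix, cfs = NULL,
                                method = c("spearman", "pearson"),
                                file = NULL) {
  method <- match.arg(method)
  num <- as.data.frame(feature_matrix)
  num <- num[vapply(num, is.numeric, logical(1))]
  if (!is.null(cfs)) num <- cbind(cfs = cfs, num)
  m <- stats::cor(as.matrix(num), method = method)
  if (!is.null(file)) {
    utils::write.csv(round(m, 4), file)
  }
  m
}

#' Plot a correlation heat map
#'
#' Renders the matrix from [correlation_heatmap()] with `pheatmap` when
#' available, otherwise with base graphics.
#'
#' @param m correlation matrix.
#' @param ... passed to the plotting backend.
#' @export
plot_correlation_heatmap <- function(m, ...) {
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       display_numbers = TRUE, ...)
  } else {
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[nrow(m):1, ]),
                    axes = FALSE, xlab = "", ylab = "",
                    zlim = c(-1, 1), ...)
    graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2)
    graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 2)
  }
  invisible(m)
}
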