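# Outlier handling and multicollinearity screening for the predictor matrix
# entering the discriminant model.

#' Winsorize by the MAD rule
#'
#' Replaces values lying more than `threshold` scaled MAD units from the
#' median by the nearest bound. Bounds are `median(x) +/- threshold * MAD`
#' with `MAD = 1.4826 * median(|x - median(x)|)` (the consistency constant
#' for normal data), computed once from the input, so applying the operation
#' to its own output changes nothing. If the MAD is zero on non-constant
#' data the rule is undefined; the vector is returned unmodified with a
#' warning.
#'
#' @param x numeric vector (>= 2 finite values).
#' @param threshold cut-off in scaled MAD units (default 2.5).
#' @param constant MAD scale factor (default 1.4826).
#' @return list: `values` (winsorized vector), `fraction_modified`,
#'   `n_modified`, `lower`, `upper`.
#' @export
winsorize_mad <- function(x, threshold = 2.5, constant = 1.4826) {
  stopifnot_numeric(x, "x")
  if (length(x) < 2) stop("need at least 2 values")
  if (threshold <= 0) stop("threshold must be positive")
  med <- stats::median(x)
  m <- stats::mad(x, constant = constant)
  if (m == 0) {
    if (any(x != med)) {
      warning("MAD is zero on non-constant data; no Winsorization applied")
    }
    return(list(values = x, fraction_modified = 0, n_modified = 0L,
                lower = med, upper = med))
  }
  lower <- med - threshold * m
  upper <- med + threshold * m
  out <- clip(x, lower, upper)
  n_mod <- sum(out != x)
  list(values = out, fraction_modified = n_mod / length(x),
       n_modified = as.integer(n_mod), lower = lower, upper = upper)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)`, with `R2_j` from the least-squares regression
#' of predictor j on all remaining predictors. Perfect collinearity is
#' reported as an infinite VIF rather than an error.
#'
#' @param x numeric matrix or data frame of predictors (rows > columns, no
#'   constant column).
#' @return named numeric vector of VIFs (all >= 1).
#' @export
compute_vif <- function(x) {
  x <- as.matrix(x)
  stopifnot_numeric(x, "x")
  p <- ncol(x)
  if (nrow(x) <= p) stop("need more rows than predictors")
  if (any(apply(x, 2, stats::sd) == 0)) stop("constant predictor column")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  vif <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(x)
  pmax(vif, 1)
}

#' Iteratively drop predictors with excessive VIF
#'
#' Removes the highest-VIF predictor, recomputes, and repeats until every
#' remaining VIF is at or below `threshold`. The removal order is recorded
#' in the `"dropped"` attribute of the result.
#'
#' @param x predictor matrix or data frame.
#' @param threshold maximum acceptable VIF (must be >= 1).
#' @return reduced predictor set (same type as a data frame input is
#'   preserved), with attribute `dropped` (character vector, removal order).
#' @export
drop_high_vif <- function(x, threshold = 5) {
  if (threshold < 1) stop("threshold must be >= 1")
  df <- as.data.frame(x)
  dropped <- character(0)
  repeat {
    if (ncol(df) < 2) break
    vif <- compute_vif(df)
    if (max(vif) <= threshold) break
    worst <- names(vif)[which.max(vif)]
    dropped <- c(dropped, worst)
    df <- df[, setdiff(names(df), worst), drop = FALSE]
  }
  attr(df, "dropped") <- dropped
  df
}

#' Assemble the donors x predictors feature matrix
#'
#' Turns a donor table into the nine-predictor matrix the discriminant model
#' is fit on: the five physiological endpoints plus the four circumplex
#' cluster scores derived from the twenty item ratings. Each predictor is
#' Winsorized by the 2.5-MAD rule separately within the fear and neutral
#' condition (outliers would otherwise underweight in the latent-variable
#' fit).
#'
#' @param donors donor table as produced by [simulate_donors()] or
#'   [read_donor_table()].
#' @param assignment optional item -> cluster assignment; when `NULL` the
#'   items are clustered from the table itself via [cluster_items_mds()].
#' @param winsorize logical; apply the MAD rule (default `TRUE`).
#' @param threshold Winsorization cut-off in scaled MAD units.
#' @param score_method cluster score aggregation, `"mean"` or `"sum"`.
#' @param include_arousal_valence also append the direct `arousal` and
#'   `valence` ratings as predictors (off by default: they duplicate the
#'   cluster scores and inflate VIFs).
#' @return data frame with `donor_id`, `condition` and the ordered predictor
#'   columns `scl_tonic`, `scr_count`, `hr`, `rr`, `sweat_mg`, `ha_neg`,
#'   `ha_pos`, `la_neg`, `la_pos`; attributes `winsorized_fraction` (named,
#'   per condition) and `assignment`.
#' @export
build_feature_matrix <- function(donors, assignment = NULL, winsorize = TRUE,
                                 threshold = 2.5,
                                 score_method = c("mean", "sum"),
                                 include_arousal_valence = FALSE) {
  score_method <- match.arg(score_method)
  item_cols <- grep("^item_", names(donors), value = TRUE)
  if (!length(item_cols)) stop("donor table has no item_* columns")
  if (is.null(assignment)) {
    assignment <- cluster_items_mds(donors[, item_cols])$assignment
  }
  cs <- cluster_scores(donors[, item_cols], assignment, method = score_method)

  pred_cols <- c("scl_tonic", "scr_count", "hr", "rr", "sweat_mg",
                 "ha_neg", "ha_pos", "la_neg", "la_pos")
  out <- data.frame(donor_id = donors$donor_id, condition = donors$condition,
                    donors[, c("scl_tonic", "scr_count", "hr", "rr", "sweat_mg")],
                    stringsAsFactors = FALSE)
  for (cl in c("ha_neg", "ha_pos", "la_neg", "la_pos")) {
    out[[cl]] <- if (cl %in% colnames(cs)) cs[, cl] else
      stop(sprintf("cluster '%s' missing from assignment", cl))
  }
  if (include_arousal_valence) {
    out$arousal <- donors$arousal
    out$valence <- donors$valence
    pred_cols <- c(pred_cols, "arousal", "valence")
  }

  win_frac <- c(fear = 0, neutral = 0)
  if (winsorize) {
    for (cond in c("fear", "neutral")) {
      rows <- out$condition == cond
      n_mod <- 0L; n_cells <- 0L
      for (col in pred_cols) {
        w <- withCallingHandlers(
          winsorize_mad(out[[col]][rows], threshold = threshold),
          warning = function(cnd) invokeRestart("muffleWarning"))
        out[[col]][rows] <- w$values
        n_mod <- n_mod + w$n_modified
        n_cells <- n_cells + sum(rows)
      }
      win_frac[cond] <- n_mod / n_cells
    }
  }
  rownames(out) <- NULL
  attr(out, "winsorized_fraction") <- win_frac
  attr(out, "assignment") <- assignment
  attr(out, "predictors") <- pred_cols
  out
}
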