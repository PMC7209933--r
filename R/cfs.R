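# Composite fear score (CFS): an intercept plus a weighted sum of the nine
# raw predictors (five physiological endpoints and four circumplex cluster
# scores), with the weights being the unstandardized coefficients of the
# fear-vs-neutral PLS-DA classification function. The CFS ranks donors by
# experienced fear intensity; tertiles of the ranking define low/medium/
# high intensity categories, validated by leave-one-out cross-validation
# and exact binomial above-chance tests.

cfs_terms <- function() {
  c("scl_tonic", "scr_count", "hr", "rr", "sweat",
    "ha_neg", "ha_pos", "la_neg", "la_pos")
}

#' Construct a set of CFS weights
#'
#' @param intercept scalar intercept.
#' @param coefficients named numeric vector with exactly the nine terms
#'   `scl_tonic` (per uS), `scr_count` (per response), `hr` (per bpm), `rr`
#'   (per breath/min), `sweat` (per unit pad mass), `ha_neg`, `ha_pos`,
#'   `la_neg`, `la_pos` (per rating unit).
#' @param sweat_unit unit the `sweat` coefficient expects: `"g"` or `"mg"`.
#'   Donor tables carry `sweat_mg`; the conversion is applied when scoring.
#' @return object of class `cfs_weights`.
#' @export
cfs_weights <- function(intercept, coefficients, sweat_unit = c("g", "mg")) {
  sweat_unit <- match.arg(sweat_unit)
  terms <- cfs_terms()
  if (!setequal(names(coefficients), terms)) {
    missing_terms <- setdiff(terms, names(coefficients))
    stop(sprintf("coefficients must be named for all nine terms; missing: %s",
                 paste(missing_terms, collapse = ", ")))
  }
  stopifnot_numeric(unname(coefficients), "coefficients")
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients[terms],
                 sweat_unit = sweat_unit),
            class = "cfs_weights")
}

#' CFS weights from a fitted PLS-DA model
#'
#' Extracts the unstandardized coefficients and intercept of a model fit on
#' the standard nine-predictor feature matrix (whose sweat column is in mg).
#'
#' @param model a [plsda()] fit on the feature-matrix predictors.
#' @return a [cfs_weights()] object with `sweat_unit = "mg"`.
#' @export
cfs_weights_from_plsda <- function(model) {
  co <- model$coefficients
  names(co) <- sub("^sweat_mg$", "sweat", names(co))
  cfs_weights(model$intercept, co, sweat_unit = "mg")
}

#' The reference CFS weight fixture
#'
#' Loads the shipped reference weights of the composite fear score equation
#' (intercept -0.096; SCL 0.053; SCR 0.024; HR 0.002; RR 0.012; sweat pad
#' weight 0.348 per gram; HA- 0.095; HA+ 0.060; LA- -0.071; LA+ -0.080).
#'
#' @return a [cfs_weights()] object.
#' @export
cfs_weights_reference <- function() {
  path <- system.file("extdata", "cfs_weights_reference.json",
                      package = "fearscore", mustWork = TRUE)
  read_cfs_weights(path)
}

#' Read / write CFS weights as JSON
#'
#' @param path file path.
#' @param weights a [cfs_weights()] object.
#' @export
read_cfs_weights <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfs_weights(j$intercept, unlist(j$coefficients), sweat_unit = j$sweat_unit)
}

#' @rdname read_cfs_weights
#' @export
write_cfs_weights <- function(weights, path) {
  stopifnot(inherits(weights, "cfs_weights"))
  jsonlite::write_json(
    list(intercept = weights$intercept,
         coefficients = as.list(weights$coefficients),
         sweat_unit = weights$sweat_unit),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.cfs_weights <- function(x, ...) {
  cat(sprintf("CFS weights (sweat in %s):\n", x$sweat_unit))
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' Compute the composite fear score
#'
#' `CFS = intercept + sum_j coefficient_j * raw_j`, evaluated on
#' fear-condition raw (Winsorized) predictor values. Exactly linear in every
#' argument.
#'
#' @param weights a [cfs_weights()] object.
#' @param newdata data frame (or single named vector) holding the nine
#'   predictors. The sweat mass may be supplied either as `sweat` (already
#'   in the weights' unit) or as `sweat_mg` (converted if the weights expect
#'   grams). A missing predictor is an error naming it.
#' @return numeric vector of scores, one per row.
#' @export
compute_cfs <- function(weights, newdata) {
  stopifnot(inherits(weights, "cfs_weights"))
  if (is.null(dim(newdata))) newdata <- as.data.frame(as.list(newdata))
  newdata <- as.data.frame(newdata)
  if (!"sweat" %in% names(newdata)) {
    if ("sweat_mg" %in% names(newdata)) {
      newdata$sweat <- if (weights$sweat_unit == "g") {
        newdata$sweat_mg / 1000
      } else {
        newdata$sweat_mg
      }
    }
  }
  missing_terms <- setdiff(cfs_terms(), names(newdata))
  if (length(missing_terms)) {
    stop(sprintf("missing predictor(s): %s",
                 paste(missing_terms, collapse = ", ")))
  }
  X <- as.matrix(newdata[, cfs_terms(), drop = FALSE])
  stopifnot_numeric(X, "newdata")
  drop(weights$intercept + X %*% weights$coefficients)
}

#' Assign fear-intensity tertiles from CFS ranks
#'
#' Ranks donors by ascending CFS and splits the ranking into three
#' contiguous groups: lowest third `low`, middle third `medium`, top third
#' `high`. Ties are broken by input order (donor order), so the assignment
#' is invariant to any strictly increasing transform of the scores. When n
#' is not divisible by 3 the group sizes differ by at most one (a remainder
#' of one goes to the middle group; a remainder of two to the outer groups)
#' and a warning is issued.
#'
#' @param cfs numeric scores.
#' @param donor_id optional ids (default `d1..dn` by position).
#' @return data frame `donor_id`, `cfs`, `category` (ordered factor
#'   low < medium < high).
#' @export
assign_tertiles <- function(cfs, donor_id = NULL) {
  stopifnot_numeric(cfs, "cfs")
  n <- length(cfs)
  if (n < 3) stop("need at least 3 donors")
  if (is.null(donor_id)) donor_id <- paste0("d", seq_len(n))
  base <- n %/% 3
  r <- n %% 3
  sizes <- c(low = base, medium = base, high = base)
  if (r == 1) {
    sizes["medium"] <- sizes["medium"] + 1
  } else if (r == 2) {
    sizes["low"] <- sizes["low"] + 1
    sizes["high"] <- sizes["high"] + 1
  }
  if (r != 0) {
    warning(sprintf("n = %d not divisible by 3; group sizes %s",
                    n, paste(sizes, collapse = "/")))
  }
  ord <- order(cfs, seq_len(n))   # ties broken by input (donor) order
  category <- character(n)
  category[ord] <- rep(c("low", "medium", "high"), times = sizes)
  data.frame(donor_id = donor_id, cfs = cfs,
             category = factor(category, levels = c("low", "medium", "high"),
                               ordered = TRUE),
             stringsAsFactors = FALSE)
}

#' One-tailed exact binomial above-chance test
#'
#' Exact upper-tail probability `P(X >= k)` for `X ~ Binomial(n, chance)`;
#' used to test whether a classification accuracy exceeds the chance
#' proportion (one-third for three intensity categories).
#'
#' @param k_correct number of correct classifications (0..n).
#' @param n number of cases.
#' @param chance chance probability, strictly inside (0, 1); default 1/3.
#' @return the exact tail probability.
#' @export
binom_above_chance <- function(k_correct, n, chance = 1 / 3) {
  if (!is.finite(chance) || chance <= 0 || chance >= 1) {
    stop("chance must lie strictly inside (0, 1)")
  }
  if (k_correct < 0 || k_correct > n) stop("k_correct must be in 0..n")
  stats::pbinom(k_correct - 1, size = n, prob = chance, lower.tail = FALSE)
}

#' Leave-one-out cross-validation of the intensity categorization
#'
#' For each donor d the whole scoring chain is repeated without d: the
#' PLS-DA model is refit on the remaining donors' fear and neutral records,
#' its unstandardized coefficients define refit CFS weights, the remaining
#' donors are scored and tertiled, and donor d is then scored with the refit
#' weights and assigned a category. Under the default `"midpoint"` rule the
#' decision boundaries are the midpoints between the adjacent groups'
#' boundary scores (the natural decision boundaries of a rank split); the
#' `"nearest"` rule assigns the category whose group-mean CFS is closest.
#' The held-out assignment is compared with the donor's full-data category.
#'
#' The item -> cluster assignment is derived once from the full table (a
#' single left-out donor does not change it materially) and the component
#' count is fixed from the full-data selection; Winsorization is redone
#' within each training fold, and the held-out donor's raw values are
#' clamped to the training bounds before scoring.
#'
#' @param donors full donor table (both conditions).
#' @param ncomp component count; `NULL` selects by leave-one-out Q2 on the
#'   full data.
#' @param rule held-out categorization rule, `"midpoint"` or `"nearest"`.
#' @param winsorize,threshold,score_method passed to
#'   [build_feature_matrix()].
#' @return object of class `loocv_intensity`: `assignments` (per-donor
#'   `cfs`, `category`, `loocv_category`, `correct`), `overall_accuracy`
#'   (%), `per_category` (k, n, accuracy %, exact binomial p vs chance 1/3),
#'   `ncomp`, and the count of `failed_folds`.
#' @export
loocv_intensity <- function(donors, ncomp = NULL,
                            rule = c("midpoint", "nearest"),
                            winsorize = TRUE, threshold = 2.5,
                            score_method = c("mean", "sum")) {
  rule <- match.arg(rule)
  score_method <- match.arg(score_method)
  item_cols <- grep("^item_", names(donors), value = TRUE)
  assignment <- cluster_items_mds(donors[, item_cols])$assignment

  fm <- build_feature_matrix(donors, assignment = assignment,
                             winsorize = winsorize, threshold = threshold,
                             score_method = score_method)
  preds <- attr(fm, "predictors")
  if (is.null(ncomp)) {
    ncomp <- select_ncomp(fm[, preds], fm$condition)$ncomp
  }
  full_fit <- plsda(fm[, preds], fm$condition, ncomp = ncomp)
  full_w <- cfs_weights_from_plsda(full_fit)
  fear_rows <- fm[fm$condition == "fear", ]
  full_cfs <- compute_cfs(full_w, fear_rows)
  full_cat <- suppressWarnings(assign_tertiles(full_cfs, fear_rows$donor_id))

  ids <- fear_rows$donor_id
  loocv_category <- rep(NA_character_, length(ids))
  failed <- 0L
  for (i in seq_along(ids)) {
    res <- tryCatch(
      loo_fold(donors, ids[i], assignment, ncomp, rule, winsorize,
               threshold, score_method),
      error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else loocv_category[i] <- res
  }

  correct <- loocv_category == as.character(full_cat$category)
  valid <- !is.na(loocv_category)
  overall <- 100 * sum(correct[valid]) / sum(valid)
  per_cat <- do.call(rbind, lapply(c("low", "medium", "high"), function(cc) {
    in_cat <- valid & full_cat$category == cc
    k <- sum(correct[in_cat]); n <- sum(in_cat)
    data.frame(category = cc, k = k, n = n,
               accuracy = if (n) 100 * k / n else NA_real_,
               p = if (n) binom_above_chance(k, n) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(
    list(assignments = data.frame(full_cat,
                                  loocv_category = loocv_category,
                                  correct = correct,
                                  stringsAsFactors = FALSE),
         overall_accuracy = overall, per_category = per_cat,
         ncomp = ncomp, rule = rule, failed_folds = failed),
    class = "loocv_intensity")
}

# One leave-one-out fold: refit without the held-out donor, re-derive
# weights and tertile boundaries, and categorize the held-out donor.
loo_fold <- function(donors, held_id, assignment, ncomp, rule,
                     winsorize, threshold, score_method) {
  train <- donors[donors$donor_id != held_id, ]
  fm <- build_feature_matrix(train, assignment = assignment,
                             winsorize = winsorize, threshold = threshold,
                             score_method = score_method)
  preds <- attr(fm, "predictors")
  rank_t <- qr(base::scale(as.matrix(fm[, preds])))$rank
  fit <- plsda(fm[, preds], fm$condition, ncomp = min(ncomp, rank_t))
  w <- cfs_weights_from_plsda(fit)
  fear_rows <- fm[fm$condition == "fear", ]
  cfs <- compute_cfs(w, fear_rows)
  cat_train <- suppressWarnings(assign_tertiles(cfs, fear_rows$donor_id))

  # Held-out donor: cluster scores from the shared assignment, values
  # clamped to each training predictor's Winsorization bounds.
  held <- donors[donors$donor_id == held_id & donors$condition == "fear", ]
  item_cols <- grep("^item_", names(donors), value = TRUE)
  cs <- cluster_scores(held[, item_cols], assignment, method = score_method)
  hx <- data.frame(held[, c("scl_tonic", "scr_count", "hr", "rr", "sweat_mg")],
                   cs, stringsAsFactors = FALSE)
  if (winsorize) {
    tr_fear <- fm[fm$condition == "fear", preds]
    for (col in preds) {
      b <- withCallingHandlers(
        winsorize_mad(tr_fear[[col]], threshold = threshold),
        warning = function(cnd) invokeRestart("muffleWarning"))
      hx[[col]] <- clip(hx[[col]], b$lower, b$upper)
    }
  }
  held_cfs <- compute_cfs(w, hx)

  by_cat <- split(cat_train$cfs, cat_train$category)
  if (rule == "midpoint") {
    b1 <- (max(by_cat$low) + min(by_cat$medium)) / 2
    b2 <- (max(by_cat$medium) + min(by_cat$high)) / 2
    if (held_cfs < b1) "low" else if (held_cfs < b2) "medium" else "high"
  } else {
    mu <- vapply(by_cat, mean, numeric(1))
    names(mu)[which.min(abs(mu - held_cfs))]
  }
}

#' @export
print.loocv_intensity <- function(x, ...) {
  cat(sprintf("LOO-CV fear-intensity categorization (%s rule, %d component(s))\n",
              x$rule, x$ncomp))
  cat(sprintf("overall accuracy: %.2f%% (%d/%d folds failed)\n",
              x$overall_accuracy, x$failed_folds, nrow(x$assignments)))
  print(transform(x$per_category, accuracy = round(accuracy, 2),
                  p = signif(p, 3)))
  invisible(x)
}
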