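# Two-class partial least-squares discriminant analysis (PLS1 on a
# dummy-coded class label), computed by NIPALS with deflation. The class
# label is coded fear = 1, neutral = 0 and the decision threshold on the
# continuous prediction is 0.5. Predictors are autoscaled internally; the
# reported coefficients are back-transformed to the original predictor
# units so they can be applied directly to raw scores.

#' Fit a two-class PLS-DA model
#'
#' @param x numeric matrix or data frame of predictors (no missing cells).
#' @param y class labels: a factor/character vector containing two classes,
#'   or a numeric 0/1 vector. The `positive` class is coded 1.
#' @param ncomp number of latent components; `NULL` (default) selects the
#'   count maximizing leave-one-out Q2, capped at `max_ncomp`.
#' @param scale autoscale predictors to unit variance (default `TRUE`).
#' @param positive label coded as 1 (default `"fear"`; ignored for numeric
#'   `y`).
#' @param max_ncomp cap for automatic component selection.
#' @return object of class `plsda` with components `weights`, `loadings`,
#'   `scores`, `y_loadings`, `ss_y` (response variance captured per
#'   component), `coefficients` and `intercept` in raw predictor units,
#'   `x_center`/`x_scale`, `fitted_values`, `r2`, `accuracy` (%), class
#'   `levels`, and the training `ncomp` (with the Q2 path in
#'   `ncomp_selection` when selected automatically).
#' @examples
#' cfg <- generator_config(n_donors = 24, seed = 7)
#' donors <- simulate_donors(cfg)
#' fm <- build_feature_matrix(donors)
#' fit <- plsda(fm[, attr(fm, "predictors")], fm$condition, ncomp = 2)
#' summary(fit)
#' @export
plsda <- function(x, y, ncomp = NULL, scale = TRUE, positive = "fear",
                  max_ncomp = 5) {
  x <- as.matrix(x)
  stopifnot_numeric(x, "x")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  yc <- code_classes(y, positive)
  if (length(unique(yc$y)) < 2) stop("both classes must be present")
  if (nrow(x) != length(yc$y)) stop("x and y sizes differ")

  x_center <- colMeans(x)
  x_scale <- if (scale) apply(x, 2, stats::sd) else rep(1, ncol(x))
  if (any(x_scale == 0)) stop("constant predictor column cannot be autoscaled")
  Xs <- sweep(sweep(x, 2, x_center), 2, x_scale, `/`)
  rank_x <- qr(Xs)$rank

  selection <- NULL
  if (is.null(ncomp)) {
    selection <- select_ncomp(x, yc$y, max_ncomp = min(max_ncomp, rank_x),
                              scale = scale)
    ncomp <- selection$ncomp
  }
  ncomp <- as.integer(ncomp)
  if (ncomp < 1) stop("ncomp must be >= 1")
  if (ncomp > rank_x) {
    stop(sprintf("ncomp (%d) exceeds the rank of the predictor matrix (%d)",
                 ncomp, rank_x))
  }

  core <- nipals_pls1(Xs, yc$y, ncomp)
  b_std <- core$coef_std
  coefficients <- drop(b_std) / x_scale
  names(coefficients) <- colnames(x)
  intercept <- mean(yc$y) - sum(coefficients * x_center)
  fitted <- drop(intercept + x %*% coefficients)
  ss_tot <- sum((yc$y - mean(yc$y))^2)
  r2 <- 1 - sum((yc$y - fitted)^2) / ss_tot
  accuracy <- 100 * mean((fitted >= 0.5) == (yc$y == 1))

  structure(
    list(ncomp = ncomp, weights = core$W, loadings = core$P,
         scores = core$Tmat, y_loadings = core$q, ss_y = core$ss_y,
         coefficients = coefficients, intercept = intercept,
         coef_std = drop(b_std), x_center = x_center, x_scale = x_scale,
         y_mean = mean(yc$y), y = yc$y, levels = yc$levels,
         fitted_values = fitted, r2 = r2, accuracy = accuracy,
         ncomp_selection = selection, call = match.call()),
    class = "plsda")
}

# Map labels to 0/1 with the positive class at 1.
code_classes <- function(y, positive) {
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) stop("numeric y must be 0/1")
    return(list(y = as.numeric(y), levels = c("0", "1")))
  }
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("y must contain exactly two classes")
  if (!positive %in% lev) positive <- lev[2]
  negative <- setdiff(lev, positive)
  list(y = as.numeric(y == positive), levels = c(negative, positive))
}

# NIPALS for a single centred response: weights w, scores t, X-loadings p,
# y-loading q per component, with X and y deflation. For a univariate y the
# weight vector has a closed form (w = X'y / ||X'y||), so no inner
# iteration is needed.
nipals_pls1 <- function(Xs, y, ncomp) {
  n <- nrow(Xs); p <- ncol(Xs)
  Xa <- Xs
  ya <- y - mean(y)
  W <- P <- matrix(0, p, ncomp)
  Tmat <- matrix(0, n, ncomp)
  q <- ss_y <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop(sprintf("residual response is orthogonal to X at component %d; reduce ncomp", a))
    }
    w <- w / nw
    tt <- drop(Xa %*% w)
    t2 <- sum(tt^2)
    pp <- crossprod(Xa, tt) / t2
    qq <- sum(ya * tt) / t2
    Xa <- Xa - tcrossprod(tt, pp)
    ya <- ya - qq * tt
    W[, a] <- w; P[, a] <- pp; Tmat[, a] <- tt
    q[a] <- qq; ss_y[a] <- qq^2 * t2
  }
  dimnames(W) <- dimnames(P) <- list(colnames(Xs), paste0("comp", seq_len(ncomp)))
  colnames(Tmat) <- paste0("comp", seq_len(ncomp))
  coef_std <- W %*% solve(crossprod(P, W), q)
  list(W = W, P = P, Tmat = Tmat, q = q, ss_y = ss_y, coef_std = coef_std)
}

#' Predict from a PLS-DA model
#'
#' @param object a [plsda()] fit.
#' @param newdata matrix or data frame whose columns match the training
#'   predictors (order-insensitive; a column mismatch is an error).
#' @param type `"response"` for the continuous prediction
#'   `intercept + X b`, `"class"` for labels at the 0.5 threshold.
#' @param ... unused.
#' @export
predict.plsda <- function(object, newdata,
                          type = c("response", "class"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- as.data.frame(newdata)
  wanted <- names(object$coefficients)
  missing_cols <- setdiff(wanted, names(newdata))
  if (length(missing_cols)) {
    stop(sprintf("newdata lacks predictor column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(newdata[, wanted, drop = FALSE])
  stopifnot_numeric(X, "newdata")
  yhat <- drop(object$intercept + X %*% object$coefficients)
  if (type == "response") return(yhat)
  factor(ifelse(yhat >= 0.5, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' Classify rows and report accuracy
#'
#' Applies the 0.5 decision threshold to the continuous PLS-DA prediction
#' and, when true labels are supplied, reports the percentage correctly
#' classified.
#'
#' @param model a [plsda()] fit.
#' @param x predictor rows.
#' @param y optional true labels.
#' @return list: `labels` (factor) and `accuracy` (% correct, `NA` without
#'   `y`).
#' @export
classify <- function(model, x, y = NULL) {
  labels <- predict(model, x, type = "class")
  acc <- NA_real_
  if (!is.null(y)) {
    truth <- if (is.numeric(y)) object_levels(model)[y + 1] else as.character(y)
    acc <- 100 * mean(as.character(labels) == truth)
  }
  list(labels = labels, accuracy = acc)
}

object_levels <- function(model) model$levels

#' In-sample R2 and leave-one-out Q2 for PLS-DA
#'
#' `R2 = 1 - SS_res / SS_tot` on the full fit. `Q2 = 1 - PRESS / SS_tot`,
#' where PRESS accumulates the squared error of each held-out row predicted
#' by a model refit without it (leave-one-out). Q2 can be negative when the
#' model predicts worse than the response mean.
#'
#' @param x,y as in [plsda()].
#' @param ncomp number of components (fixed across folds).
#' @param scale,positive passed to [plsda()].
#' @return list with `r2`, `q2`, `press`, `ncomp`.
#' @export
q2_r2 <- function(x, y, ncomp, scale = TRUE, positive = "fear") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  yc <- code_classes(y, positive)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 rows for leave-one-out Q2")
  full <- plsda(x, yc$y, ncomp = ncomp, scale = scale)
  ss_tot <- sum((yc$y - mean(yc$y))^2)
  press <- 0
  for (i in seq_len(n)) {
    xi <- x[-i, , drop = FALSE]
    rank_i <- qr(base::scale(xi, scale = scale))$rank
    fit <- plsda(xi, yc$y[-i], ncomp = min(ncomp, rank_i), scale = scale)
    pred <- predict(fit, x[i, , drop = FALSE])
    press <- press + (yc$y[i] - pred)^2
  }
  list(r2 = full$r2, q2 = 1 - press / ss_tot, press = press, ncomp = ncomp)
}

#' Select the number of PLS components by leave-one-out Q2
#'
#' Computes Q2 for 1..`max_ncomp` components and returns the count
#' maximizing it — the standard chemometrics rule when a cross-validated
#' goodness of prediction is the headline diagnostic.
#'
#' @inheritParams q2_r2
#' @param max_ncomp largest candidate count (default 5).
#' @return list: chosen `ncomp` and the `q2` path.
#' @export
select_ncomp <- function(x, y, max_ncomp = 5, scale = TRUE,
                         positive = "fear") {
  x <- as.matrix(x)
  rank_x <- qr(base::scale(x, scale = scale))$rank
  k <- min(max_ncomp, rank_x)
  q2s <- vapply(seq_len(k), function(a) {
    q2_r2(x, y, ncomp = a, scale = scale, positive = positive)$q2
  }, numeric(1))
  list(ncomp = which.max(q2s), q2 = q2s)
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA (%s = 1 vs %s = 0): %d component(s), %d predictors, n = %d\n",
              x$levels[2], x$levels[1], x$ncomp, length(x$coefficients),
              length(x$y)))
  cat(sprintf("R2 = %.3f, training accuracy = %.2f%%\n", x$r2, x$accuracy))
  invisible(x)
}

#' @export
summary.plsda <- function(object, ...) {
  v <- vip(object)
  out <- list(ncomp = object$ncomp, r2 = object$r2,
              accuracy = object$accuracy,
              coefficients = c(`(Intercept)` = object$intercept,
                               object$coefficients),
              vip = v)
  class(out) <- "summary.plsda"
  out
}

#' @export
print.summary.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA summary: %d component(s), R2 = %.3f, accuracy = %.2f%%\n",
              x$ncomp, x$r2, x$accuracy))
  cat("\nUnstandardized coefficients:\n")
  print(round(x$coefficients, 4))
  cat("\nVIP scores:\n")
  print(round(sort(x$vip, decreasing = TRUE), 3))
  invisible(x)
}

#' @export
coef.plsda <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
fitted.plsda <- function(object, ...) object$fitted_values

#' @export
residuals.plsda <- function(object, ...) object$y - object$fitted_values

#' Score plot of a PLS-DA fit
#'
#' Plots the first two latent-component scores (or component values against
#' row index for a one-component model), colour-coded by class.
#'
#' @param x a [plsda()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.plsda <- function(x, ...) {
  cols <- ifelse(x$y == 1, "firebrick", "steelblue")
  if (x$ncomp >= 2) {
    graphics::plot(x$scores[, 1], x$scores[, 2], col = cols, pch = 19,
                   xlab = "component 1 score", ylab = "component 2 score", ...)
  } else {
    graphics::plot(seq_along(x$y), x$scores[, 1], col = cols, pch = 19,
                   xlab = "row", ylab = "component 1 score", ...)
  }
  graphics::legend("topright", legend = rev(x$levels), col = c("firebrick", "steelblue"),
                   pch = 19, bty = "n")
  invisible(x)
}
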