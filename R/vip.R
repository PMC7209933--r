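# Variable importance in projection (VIP) and bootstrap confidence
# intervals. VIP_j summarizes predictor j's contribution across the latent
# components, weighted by the response variance each component captures;
# the mean squared VIP equals 1 (sum VIP^2 = p).

#' VIP scores of a PLS-DA model
#'
#' `VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a )`, where
#' `SS_a` is the response variance captured by component `a` and `w_a` its
#' weight vector.
#'
#' @param model a [plsda()] fit.
#' @return named numeric vector, one VIP per predictor; `sum(vip^2)` equals
#'   the number of predictors.
#' @export
vip <- function(model) {
  W <- model$weights
  ss <- model$ss_y
  p <- nrow(W)
  wn2 <- sweep(W^2, 2, colSums(W^2), `/`)
  v <- sqrt(p * drop(wn2 %*% ss) / sum(ss))
  names(v) <- rownames(W)
  v
}

#' Percentile bootstrap confidence intervals for VIP scores
#'
#' Resamples rows with replacement within each class (preserving the class
#' balance), refits the model with the training component count, and takes
#' percentile intervals of the resulting VIP distribution.
#'
#' @param x,y training predictors and labels.
#' @param ncomp number of components per refit.
#' @param B bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed for the resampling.
#' @param scale,positive passed to [plsda()].
#' @return data frame: `predictor`, `vip` (full-data score), `lower`,
#'   `upper`.
#' @export
vip_ci <- function(x, y, ncomp, B = 1000, level = 0.95, seed = 1L,
                   scale = TRUE, positive = "fear") {
  x <- as.matrix(x)
  yc <- code_classes(y, positive)
  full <- plsda(x, yc$y, ncomp = ncomp, scale = scale)
  idx_by_class <- split(seq_along(yc$y), yc$y)
  boot <- local_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      idx <- unlist(lapply(idx_by_class, function(ii) {
        sample(ii, length(ii), replace = TRUE)
      }), use.names = FALSE)
      fit <- tryCatch(plsda(x[idx, , drop = FALSE], yc$y[idx],
                            ncomp = ncomp, scale = scale),
                      error = function(e) NULL)
      if (is.null(fit)) rep(NA_real_, ncol(x)) else vip(fit)
    }, numeric(ncol(x))))
  })
  alpha <- (1 - level) / 2
  qs <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  data.frame(predictor = names(full$coefficients), vip = unname(vip(full)),
             lower = unname(qs[1, ]), upper = unname(qs[2, ]),
             row.names = NULL, stringsAsFactors = FALSE)
}
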