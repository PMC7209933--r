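# Item clustering, cluster scores, MAD Winsorization and VIF screening.

test_that("MDS clustering recovers a planted 4-block item structure", {
  pl <- planted_items()
  cl <- cluster_items_mds(pl$x)
  # the learned partition matches the planted blocks up to label permutation
  tab <- table(cl$assignment, pl$blocks)
  expect_true(all(apply(tab, 2, function(col) sum(col > 0)) == 1))
  expect_true(all(apply(tab, 1, function(row) sum(row > 0)) == 1))
})

test_that("stress decreases over majorization iterations and stays below 1", {
  pl <- planted_items(seed = 7)
  cl <- cluster_items_mds(pl$x)
  expect_true(all(diff(cl$stress_trace) <= 1e-12))
  expect_lt(cl$stress, 1)
  # embedding distances correlate positively with input dissimilarities
  delta <- 1 - cor(pl$x)
  d_emb <- as.matrix(dist(cl$embedding))
  expect_gt(cor(delta[upper.tri(delta)], d_emb[upper.tri(d_emb)]), 0)
})

test_that("duplicated items land on identical embedding coordinates", {
  pl <- planted_items(seed = 3)
  x <- cbind(pl$x[, 1:6], dup = pl$x[, 1])
  colnames(x)[1] <- "orig"
  cl <- cluster_items_mds(x)
  expect_equal(cl$embedding["orig", ], cl$embedding["dup", ],
               tolerance = 1e-6)
})

test_that("constant-rated items are rejected by name", {
  x <- planted_items(seed = 1)$x[, 1:5]
  x[, 3] <- 2
  expect_error(cluster_items_mds(x), "v3")
})

test_that("canonical affect items co-assign to their circumplex quadrants", {
  d <- simulate_donors(generator_config(seed = 2))
  a <- cluster_items_mds(d[, grep("^item_", names(d))])$assignment
  expect_setequal(unique(a), c("ha_pos", "ha_neg", "la_neg", "la_pos"))
  expect_true(all(a[c("item_fearful", "item_nervous", "item_tense")] == "ha_neg"))
})

test_that("cluster scores are member-item means (sums on request)", {
  x <- matrix(c(1, 2, 3,
                4, 0, 5), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  assignment <- c(a = "g1", b = "g1", c = "g2")
  s <- cluster_scores(x, assignment)
  expect_equal(unname(s[, "g1"]), c(1.5, 2))
  expect_equal(unname(s[, "g2"]), c(3, 5))   # single-item cluster
  s2 <- cluster_scores(x, assignment, method = "sum")
  expect_equal(unname(s2[, "g1"]), c(3, 4))
  expect_equal(cluster_scores(matrix(0, 3, 3,
                                     dimnames = list(NULL, c("a", "b", "c"))),
                              assignment)[, "g1"],
               rep(0, 3))
  expect_error(cluster_scores(x[, 1:2], assignment), "item")
})

test_that("the MAD rule clamps outliers to hand-computed bounds", {
  # with the raw (unscaled) MAD: median 3, MAD 1, upper bound 3 + 2.5
  w <- winsorize_mad(c(1, 2, 3, 4, 100), constant = 1)
  expect_equal(w$values, c(1, 2, 3, 4, 5.5))
  expect_equal(w$fraction_modified, 0.2)
  # default scaled MAD widens the bound accordingly
  w2 <- winsorize_mad(c(1, 2, 3, 4, 100))
  expect_equal(w2$upper, 3 + 2.5 * 1.4826)
  expect_equal(w2$values[5], w2$upper)
})

test_that("winsorization is idempotent, median-preserving and monotone in threshold", {
  set.seed(11)
  for (rep in 1:20) {
    x <- rt(40, df = 2) * 3 + 1
    w <- winsorize_mad(x)
    expect_equal(median(w$values), median(x))
    again <- winsorize_mad(w$values)
    expect_equal(again$values, w$values)
    expect_equal(again$fraction_modified, 0)
    # fraction modified never increases with the threshold
    f <- sapply(c(1.5, 2.5, 3.5), function(th) {
      winsorize_mad(x, threshold = th)$fraction_modified
    })
    expect_true(all(diff(f) <= 0))
    # range confined to the bounds
    expect_true(all(w$values >= w$lower & w$values <= w$upper))
  }
  # symmetric data stay symmetric
  x <- c(-10, -2, -1, 0, 1, 2, 10)
  w <- winsorize_mad(x)
  expect_equal(w$values, -rev(w$values))
  # in-bounds data are untouched
  w0 <- winsorize_mad(c(1, 2, 3, 4, 5))
  expect_equal(w0$fraction_modified, 0)
})

test_that("zero MAD on non-constant data warns and leaves data unchanged", {
  x <- c(1, 1, 1, 1, 100)
  expect_warning(w <- winsorize_mad(x), "MAD is zero")
  expect_equal(w$values, x)
  expect_equal(w$fraction_modified, 0)
})

test_that("VIF matches a per-column regression oracle on random matrices", {
  set.seed(5)
  for (rep in 1:5) {
    x <- matrix(rnorm(120), 20, 6,
                dimnames = list(NULL, paste0("v", 1:6)))
    x[, 2] <- x[, 1] + rnorm(20, sd = 0.5)  # induce some collinearity
    v <- compute_vif(x)
    oracle <- sapply(seq_len(6), function(j) {
      r2 <- summary(lm(x[, j] ~ x[, -j]))$r.squared
      1 / (1 - r2)
    })
    expect_equal(unname(v), oracle, tolerance = 1e-8)
    expect_true(all(v >= 1))
  }
})

test_that("VIF has the closed form 1.5 for three equicorrelated predictors", {
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  L <- chol(S)
  set.seed(1)
  z <- matrix(rnorm(6e4 * 3), ncol = 3) %*% L
  # population value: diag(solve(R)) = 1.5 for pairwise r = 0.5
  expect_equal(unname(compute_vif(z)), rep(1.5, 3), tolerance = 0.05)
})

test_that("near-duplicated predictors produce extreme VIFs and exact duplicates Inf", {
  set.seed(2)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  x <- cbind(x, c = x[, "a"] + rnorm(30, sd = 1e-4))
  v <- compute_vif(x)
  expect_gt(v["a"], 10); expect_gt(v["c"], 10)
  xd <- cbind(x[, c("a", "b")], dup = x[, "a"])
  expect_true(is.infinite(max(compute_vif(xd))))
})

test_that("drop_high_vif removes exactly one of a duplicated pair and is identity when clean", {
  set.seed(3)
  x <- data.frame(a = rnorm(30), b = rnorm(30))
  x$dup <- x$a
  red <- drop_high_vif(x, threshold = 5)
  expect_equal(ncol(red), 2)
  expect_length(attr(red, "dropped"), 1)
  clean <- data.frame(a = rnorm(30), b = rnorm(30))
  expect_equal(ncol(drop_high_vif(clean, threshold = 5)), 2)
  expect_error(drop_high_vif(clean, threshold = 0.5), "threshold")
})

test_that("adding direct arousal/valence ratings inflates the maximum VIF", {
  d <- simulate_donors(generator_config(seed = 2))
  a <- cluster_items_mds(d[, grep("^item_", names(d))])$assignment
  base <- build_feature_matrix(d, assignment = a)
  with_av <- build_feature_matrix(d, assignment = a,
                                  include_arousal_valence = TRUE)
  v0 <- compute_vif(base[, attr(base, "predictors")])
  v1 <- compute_vif(with_av[, attr(with_av, "predictors")])
  expect_gt(max(v1), max(v0))
})

test_that("feature matrix has the fixed column order and per-condition winsorized fractions", {
  d <- simulate_donors(generator_config(seed = 6))
  fm <- build_feature_matrix(d)
  expect_identical(attr(fm, "predictors"),
                   c("scl_tonic", "scr_count", "hr", "rr", "sweat_mg",
                     "ha_neg", "ha_pos", "la_neg", "la_pos"))
  wf <- attr(fm, "winsorized_fraction")
  expect_named(wf, c("fear", "neutral"))
  expect_true(all(wf >= 0 & wf <= 1))
  expect_false(anyNA(fm))
})
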