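# Circumplex clustering of questionnaire items: metric multidimensional
# scaling of the item-item correlation distance, followed by grouping items
# around four cluster centroids (high/low arousal x positive/negative
# affect).

# Metric MDS by stress majorization (SMACOF): classical-scaling start,
# Guttman-transform updates, stop when normalized stress improves by less
# than `tol` or after `max_iter` iterations.
smacof_mds <- function(delta, n_dims = 2, max_iter = 300, tol = 1e-6) {
  n <- nrow(delta)
  X <- suppressWarnings(stats::cmdscale(delta, k = n_dims))
  if (ncol(X) < n_dims) {
    X <- cbind(X, matrix(0, n, n_dims - ncol(X)))
  }
  dist_mat <- function(X) as.matrix(stats::dist(X))
  norm2 <- sum(delta^2) / 2
  stress_of <- function(D) sqrt(sum((delta - D)^2) / 2 / norm2)
  D <- dist_mat(X)
  trace <- stress_of(D)
  for (it in seq_len(max_iter)) {
    B <- ifelse(D > 0, -delta / D, 0)
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
    D <- dist_mat(X)
    s <- stress_of(D)
    trace <- c(trace, s)
    if (trace[length(trace) - 1] - s < tol) break
  }
  list(points = X, stress = trace[length(trace)], stress_trace = trace)
}

#' Cluster questionnaire items into circumplex quadrants
#'
#' Embeds items in a low-dimensional space by metric, stress-minimizing
#' multidimensional scaling of the dissimilarity `d = 1 - r` (r the
#' item-item Pearson correlation of ratings across respondents), partitions
#' the embedding into four groups, then refines the partition so every item
#' sits in the group with whose centroid rating profile it correlates best.
#' When the items are the twenty canonical affect terms, groups are labelled
#' `ha_pos`, `ha_neg`, `la_neg`, `la_pos` (high/low arousal, positive/
#' negative affect) by majority overlap with the canonical membership;
#' otherwise they are labelled `cluster1..4`.
#'
#' @param item_scores numeric matrix or data frame, respondents x items
#'   (>= 3 of each); typically the `item_*` columns of a donor table across
#'   both conditions.
#' @param n_dims embedding dimensionality (default 2).
#' @param n_clusters number of groups (default 4).
#' @param seed seed for the k-means initialization of the partition.
#' @param max_iter,tol majorization iteration cap and stress tolerance.
#' @return object of class `item_clustering`: `embedding` (items x n_dims),
#'   `assignment` (named character vector item -> group), `stress` and the
#'   per-iteration `stress_trace`.
#' @export
cluster_items_mds <- function(item_scores, n_dims = 2, n_clusters = 4,
                              seed = 1L, max_iter = 300, tol = 1e-6) {
  x <- as.matrix(item_scores)
  if (nrow(x) < 3) stop("need at least 3 respondents")
  if (ncol(x) < 3) stop("need at least 3 items")
  stopifnot_numeric(x, "item_scores")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant-rated item(s) with zero variance: %s",
                 paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  r <- stats::cor(x)
  delta <- 1 - r
  emb <- smacof_mds(delta, n_dims = n_dims, max_iter = max_iter, tol = tol)
  rownames(emb$points) <- colnames(x)

  km <- local_seed(seed, stats::kmeans(emb$points, centers = n_clusters,
                                       nstart = 50))
  grp <- km$cluster

  # Refinement: reassign each item to the group whose centroid rating
  # profile (mean of the other member items) it correlates with best.
  for (pass in seq_len(50)) {
    changed <- FALSE
    for (j in seq_len(ncol(x))) {
      best <- NA_integer_; best_r <- -Inf
      for (g in seq_len(n_clusters)) {
        members <- setdiff(which(grp == g), j)
        if (!length(members)) next
        cent <- rowMeans(x[, members, drop = FALSE])
        rj <- stats::cor(x[, j], cent)
        if (is.finite(rj) && rj > best_r) { best_r <- rj; best <- g }
      }
      if (!is.na(best) && best != grp[j]) { grp[j] <- best; changed <- TRUE }
    }
    if (!changed) break
  }

  labels <- label_quadrants(colnames(x), grp, n_clusters)
  assignment <- labels[grp]
  names(assignment) <- colnames(x)
  structure(list(embedding = emb$points, assignment = assignment,
                 stress = emb$stress, stress_trace = emb$stress_trace),
            class = "item_clustering")
}

# Map numeric cluster ids to circumplex quadrant names by overlap with the
# canonical 20-item membership (item_ prefixes tolerated); generic labels
# when the names do not match.
label_quadrants <- function(item_names, grp, n_clusters) {
  canon <- fear_item_clusters()
  bare <- sub("^item_", "", item_names)
  overlap <- sapply(names(canon), function(q) {
    sapply(seq_len(n_clusters), function(g) sum(bare[grp == g] %in% canon[[q]]))
  })
  labels <- paste0("cluster", seq_len(n_clusters))
  if (n_clusters == 4 && sum(overlap) >= length(item_names) / 2) {
    taken_g <- logical(n_clusters); taken_q <- logical(4)
    ord <- order(-as.vector(overlap))
    for (o in ord) {
      g <- (o - 1) %% n_clusters + 1
      q <- (o - 1) %/% n_clusters + 1
      if (!taken_g[g] && !taken_q[q] && overlap[o] > 0) {
        labels[g] <- names(canon)[q]
        taken_g[g] <- TRUE; taken_q[q] <- TRUE
      }
    }
  }
  labels
}

#' @export
print.item_clustering <- function(x, ...) {
  cat(sprintf("item clustering: %d items, stress %.4f (%d majorization steps)\n",
              nrow(x$embedding), x$stress, length(x$stress_trace) - 1))
  for (g in unique(x$assignment)) {
    cat(sprintf("  %s: %s\n", g,
                paste(sub("^item_", "", names(x$assignment)[x$assignment == g]),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Per-respondent cluster scores
#'
#' Collapses item ratings into one score per cluster. The default is the
#' mean of the member items, which keeps scores on the 0-5 rating scale (a
#' sum variant is available).
#'
#' @param item_scores respondents x items matrix or data frame.
#' @param assignment named vector item -> cluster, as returned in
#'   [cluster_items_mds()]`$assignment`.
#' @param method `"mean"` (default) or `"sum"`.
#' @return matrix respondents x clusters.
#' @export
cluster_scores <- function(item_scores, assignment, method = c("mean", "sum")) {
  method <- match.arg(method)
  x <- as.matrix(item_scores)
  if (!all(names(assignment) %in% colnames(x))) {
    stop("assignment names must match item columns")
  }
  if (!all(colnames(x) %in% names(assignment))) {
    stop("assignment must cover all items")
  }
  groups <- split(names(assignment), assignment)
  fun <- if (method == "mean") rowMeans else rowSums
  out <- sapply(groups, function(members) fun(x[, members, drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(groups)))
  out
}
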