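# Readers/writers for the donor-table and PID-trace interchange formats,
# and the umbrella pipeline runner. CSV dialect: comma-separated, UTF-8,
# "." decimal, mandatory header row; missing values are not permitted.

donor_required_cols <- function() {
  c("donor_id", "condition", "scl_tonic", "scr_count", "hr", "rr",
    "sweat_mg")
}

#' Write / read a donor table as CSV
#'
#' One row per donor x condition with the documented header: `donor_id`,
#' `condition` (`fear`/`neutral`), the five physiological endpoints, twenty
#' `item_*` ratings on the 0-5 scale, `arousal`, `valence` and (optionally)
#' `latent_intensity`. Reading validates column presence, numeric cells,
#' rating ranges, non-negative physiology and uniqueness of donor x
#' condition, reporting the offending row/column. A `col_map` renames
#' foreign headers (`c(our_name = "their name")`) so externally exported
#' tables parse without code changes.
#'
#' @param donors donor data frame.
#' @param path CSV path.
#' @param col_map optional named character vector mapping package column
#'   names to the file's native headers.
#' @return `read_donor_table` returns the validated data frame;
#'   `write_donor_table` returns `path` invisibly.
#' @export
write_donor_table <- function(donors, path) {
  utils::write.csv(donors, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_donor_table
#' @export
read_donor_table <- function(path, col_map = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8", check.names = FALSE)
  if (!is.null(col_map)) {
    for (ours in names(col_map)) {
      j <- match(col_map[[ours]], names(d))
      if (!is.na(j)) names(d)[j] <- ours
    }
  }
  miss <- setdiff(donor_required_cols(), names(d))
  if (length(miss)) {
    stop(sprintf("donor table misses column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!all(d$condition %in% c("fear", "neutral"))) {
    bad <- which(!d$condition %in% c("fear", "neutral"))[1]
    stop(sprintf("row %d: condition must be 'fear' or 'neutral'", bad))
  }
  dup <- duplicated(d[, c("donor_id", "condition")])
  if (any(dup)) {
    stop(sprintf("row %d: duplicate donor x condition record", which(dup)[1]))
  }
  num_cols <- setdiff(names(d), c("donor_id", "condition"))
  for (col in num_cols) {
    v <- d[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("row %d, column '%s': non-numeric or missing cell",
                   ifelse(is.na(bad), 1, bad), col))
    }
  }
  for (col in grep("^item_", names(d), value = TRUE)) {
    bad <- which(d[[col]] < 0 | d[[col]] > 5)
    if (length(bad)) {
      stop(sprintf("row %d, column '%s': rating outside [0, 5]", bad[1], col))
    }
  }
  for (col in c("scl_tonic", "scr_count", "hr", "rr", "sweat_mg")) {
    bad <- which(d[[col]] < 0)
    if (length(bad)) {
      stop(sprintf("row %d, column '%s': negative physiological value",
                   bad[1], col))
    }
  }
  d
}

#' Write / read a PID trace (CSV + JSON sidecar)
#'
#' The trace samples go to a two-column CSV (`time_s`, `signal_mv`); the
#' stimulus events and pad metadata go to a JSON sidecar (default: the CSV
#' path with extension `.json`).
#'
#' @param trace a `pid_trace` object.
#' @param path CSV path.
#' @param sidecar JSON path for events and pad metadata.
#' @return `read_pid_trace` returns a validated `pid_trace`;
#'   `write_pid_trace` returns `path` invisibly.
#' @export
write_pid_trace <- function(trace, path,
                            sidecar = sub("\\.csv$", ".json", path)) {
  stopifnot(inherits(trace, "pid_trace"))
  utils::write.csv(data.frame(time_s = trace$time, signal_mv = trace$signal),
                   path, row.names = FALSE)
  jsonlite::write_json(list(events = trace$events, pad_meta = trace$pad_meta),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pid_trace
#' @export
read_pid_trace <- function(path, sidecar = sub("\\.csv$", ".json", path)) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "signal_mv") %in% names(d))) {
    stop("trace CSV must have columns time_s, signal_mv")
  }
  if (is.unsorted(d$time_s, strictly = TRUE)) {
    stop("time must be strictly increasing")
  }
  if (any(!is.finite(d$signal_mv))) stop("signal must be finite")
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  ev <- as.data.frame(side$events)
  span <- range(d$time_s)
  if (any(ev$onset_s < span[1] | ev$onset_s + ev$duration_s > span[2])) {
    stop("events must lie within the trace time span")
  }
  if (nrow(ev) > 1) {
    o <- order(ev$onset_s)
    if (any(ev$onset_s[o][-1] < (ev$onset_s + ev$duration_s)[o][-nrow(ev)])) {
      stop("events must not overlap")
    }
  }
  structure(list(time = d$time_s, signal = d$signal_mv, events = ev,
                 pad_meta = side$pad_meta), class = "pid_trace")
}

#' Run the full encoder-side analysis pipeline
#'
#' Executes, in order: simulate (or load) the donor table, cluster the
#' questionnaire items, assemble and Winsorize the feature matrix, fit
#' PLS-DA (automatic component count), derive CFS weights and scores,
#' tertile the fear-condition donors, leave-one-out cross-validate the
#' categorization, and compute the dose-response statistics (paired
#' signed-rank contrasts per endpoint, linear-contrast ANOVA of sweat over
#' intensity categories, Spearman CFS-sweat correlation, correlation
#' matrix). Any stage failure aborts with the stage name. All randomness
#' flows from the single master seed recorded in the manifest.
#'
#' @param config a [generator_config()]; ignored for the donor simulation
#'   when `donors` is supplied.
#' @param donors optional pre-loaded donor table (e.g. from
#'   [read_donor_table()]); `NULL` simulates from `config`.
#' @param out_dir optional directory; when given, all artifacts (donor
#'   table, feature matrix, model JSON, CFS table, LOO-CV table,
#'   dose-response table, manifest JSON) are written there.
#' @param seed optional master seed overriding `config$seed`.
#' @return a `run_manifest` list: `config`, `seed`, stage `results`,
#'   per-stage `log`, and (when written) output `files` with MD5 digests.
#' @export
run_pipeline <- function(config = generator_config(), donors = NULL,
                         out_dir = NULL, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (is.null(donors)) {
    donors <- stage("simulate", simulate_donors(config))
    note("simulate: %d donors x 2 conditions (seed %d)",
         config$n_donors, config$seed)
  } else {
    note("load: %d rows supplied", nrow(donors))
  }

  item_cols <- grep("^item_", names(donors), value = TRUE)
  clustering <- stage("cluster", cluster_items_mds(donors[, item_cols]))
  note("cluster: stress %.4f", clustering$stress)

  fm <- stage("preprocess",
              build_feature_matrix(donors, assignment = clustering$assignment))
  wf <- attr(fm, "winsorized_fraction")
  note("preprocess: winsorized %.2f%% (fear) / %.2f%% (neutral)",
       100 * wf["fear"], 100 * wf["neutral"])

  preds <- attr(fm, "predictors")
  fit <- stage("fit-plsda", plsda(fm[, preds], fm$condition))
  diag <- stage("fit-plsda", q2_r2(fm[, preds], fm$condition, fit$ncomp))
  note("fit-plsda: %d comp, R2 %.3f, Q2 %.3f, accuracy %.1f%%",
       fit$ncomp, diag$r2, diag$q2, fit$accuracy)

  weights <- cfs_weights_from_plsda(fit)
  fear_rows <- fm[fm$condition == "fear", ]
  cfs <- stage("score", compute_cfs(weights, fear_rows))
  tert <- stage("score", suppressWarnings(
    assign_tertiles(cfs, fear_rows$donor_id)))
  note("score: CFS range [%.3f, %.3f]", min(cfs), max(cfs))

  loocv <- stage("loocv", loocv_intensity(donors, ncomp = fit$ncomp))
  note("loocv: overall accuracy %.2f%%", loocv$overall_accuracy)

  dr <- stage("dose-response", {
    fear_d <- donors[donors$condition == "fear", ]
    neut_d <- donors[donors$condition == "neutral", ]
    fear_d <- fear_d[order(fear_d$donor_id), ]
    neut_d <- neut_d[order(neut_d$donor_id), ]
    endpoints <- c("scl_tonic", "scr_count", "hr", "rr", "sweat_mg")
    contrasts <- lapply(endpoints, function(v) {
      paired_signed_rank(fear_d[[v]], neut_d[[v]])
    })
    names(contrasts) <- endpoints
    sweat_by_id <- fear_rows$sweat_mg[match(tert$donor_id, fear_rows$donor_id)]
    list(
      contrasts = contrasts,
      linear_contrast = linear_contrast_anova(sweat_by_id, tert$category),
      spearman_cfs_sweat = spearman(tert$cfs, sweat_by_id),
      correlations = correlation_heatmap(fear_rows[, preds], cfs = tert$cfs))
  })
  note("dose-response: linear contrast F = %.2f, Spearman rho = %.2f",
       dr$linear_contrast$value, dr$spearman_cfs_sweat$rho)

  manifest <- list(config = config, seed = config$seed,
                   package_version = as.character(utils::packageVersion("fearscore")),
                   results = list(clustering = clustering,
                                  feature_matrix = fm, fit = fit,
                                  diagnostics = diag, weights = weights,
                                  cfs = tert, loocv = loocv,
                                  dose_response = dr),
                   log = log)
  class(manifest) <- "run_manifest"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(donors = file.path(out_dir, "donors.csv"),
               features = file.path(out_dir, "feature_matrix.csv"),
               model = file.path(out_dir, "plsda_model.json"),
               weights = file.path(out_dir, "cfs_weights.json"),
               cfs = file.path(out_dir, "cfs_categories.csv"),
               loocv = file.path(out_dir, "loocv.csv"),
               dose = file.path(out_dir, "dose_response.csv"),
               correlations = file.path(out_dir, "correlations.csv"))
    write_donor_table(donors, paths["donors"])
    utils::write.csv(fm, paths["features"], row.names = FALSE)
    jsonlite::write_json(
      list(ncomp = fit$ncomp, intercept = fit$intercept,
           coefficients = as.list(fit$coefficients),
           x_center = as.list(fit$x_center), x_scale = as.list(fit$x_scale),
           r2 = diag$r2, q2 = diag$q2, accuracy = fit$accuracy),
      paths["model"], auto_unbox = TRUE, digits = NA)
    write_cfs_weights(weights, paths["weights"])
    utils::write.csv(tert, paths["cfs"], row.names = FALSE)
    utils::write.csv(loocv$assignments, paths["loocv"], row.names = FALSE)
    dose_tab <- data.frame(
      test = c(paste0("signed_rank_", names(dr$contrasts)),
               "linear_contrast_sweat", "spearman_cfs_sweat"),
      statistic = c(vapply(dr$contrasts, function(x) x$value, numeric(1)),
                    dr$linear_contrast$value, dr$spearman_cfs_sweat$rho),
      p = c(vapply(dr$contrasts, function(x) x$p, numeric(1)),
            dr$linear_contrast$p, dr$spearman_cfs_sweat$p))
    utils::write.csv(dose_tab, paths["dose"], row.names = FALSE)
    utils::write.csv(round(dr$correlations, 4), paths["correlations"])
    manifest$files <- vapply(paths, function(p) unname(tools::md5sum(p)),
                             character(1))
    jsonlite::write_json(
      list(seed = config$seed, n_donors = config$n_donors,
           package_version = manifest$package_version,
           files = as.list(manifest$files), log = log),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("fearscore pipeline run (seed", x$seed, ")\n")
  for (line in x$log) cat(" -", line, "\n")
  invisible(x)
}
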