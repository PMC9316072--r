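# Cheap FNV-1a hash of a deparsed object, for stamping artifacts with the
# configuration they came from.
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: cohort size, generator and
#' protocol settings, the classifiers to evaluate, bootstrap depth and a
#' master seed from which every stochastic stage derives its own seed
#' (generation, grey zone, cross-validation), so stages are individually
#' reproducible.
#'
#' @param n_subjects cohort size (default 30).
#' @param seed master integer seed.
#' @param generator an [generator_config()]; its own `seed` field is
#'   overridden by the derived stage seed.
#' @param protocol an [lbnp_protocol()].
#' @param models character vector of algorithms to evaluate (subset of
#'   `"knn"`, `"nb"`, `"rf"`, `"svm_linear"`, `"svm_radial"`) or a list of
#'   [model_spec()]s; empty to skip the evaluation stage.
#' @param n_rep outer cross-validation repetitions.
#' @param bootstrap_B bootstrap replicates for the grey-zone stage.
#' @param greyzone_markers ratio-marker columns analysed by the grey-zone
#'   stage.
#' @param cv_markers ratio-marker columns evaluated per repetition in the
#'   cross-validation stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(n_subjects = 30, seed = 7,
                       generator = generator_config(),
                       protocol = lbnp_protocol(),
                       models = "rf", n_rep = 29, bootstrap_B = 1000,
                       greyzone_markers = c("ratio_hr", "ratio_sbp",
                                            "ratio_sv", "ratio_pep",
                                            "ratio_str", "ratio_icon"),
                       cv_markers = c("ratio_hr", "ratio_sbp", "ratio_dbp",
                                      "ratio_map")) {
  stopifnot(n_subjects >= 1, is.numeric(seed), n_rep >= 1, bootstrap_B >= 2)
  if (is.character(models)) {
    models <- lapply(models, model_spec)
  }
  structure(
    list(n_subjects = n_subjects, seed = as.integer(seed),
         generator = generator, protocol = protocol, models = models,
         n_rep = n_rep, bootstrap_B = bootstrap_B,
         greyzone_markers = greyzone_markers, cv_markers = cv_markers),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' simulate -> extract window features -> standardize -> build relational
#' observations -> stage statistics and correlations -> grey-zone ROC per
#' marker -> (optionally) nested cross-validation. Returns a
#' machine-readable report; when `out_dir` is given, all intermediates
#' (CSV), results (JSON) and a human-readable summary are written, each
#' stamped with the configuration hash.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @param verbose print stage progress.
#' @return report list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message("[ecshock] ", ...)
  hash <- .config_hash(unclass(config)[c("n_subjects", "seed", "n_rep",
                                         "bootstrap_B")])
  gen <- config$generator
  gen$seed <- config$seed + 1L

  say("simulate: ", config$n_subjects, " subjects")
  cohort <- generate_cohort(config$n_subjects, gen, config$protocol)

  say("features: extracting windows")
  feats <- cohort_features(cohort)
  scaler <- fit_scaler(feats)
  feats_std <- apply_scaler(scaler, feats)

  say("relate: building relational observations")
  rel <- build_relational(feats_std, raw_features = feats,
                          protocol = config$protocol)
  counts <- list(
    n_subjects = config$n_subjects,
    n_relational = nrow(rel),
    n_valid = sum(rel$valid),
    n_invalid = sum(!rel$valid),
    n_positive = sum(rel$label == 1L, na.rm = TRUE)
  )

  say("stats: stage comparisons and correlations")
  stage_tab <- stage_stats(feats, protocol = config$protocol)
  cor_tab <- correlation_stats(feats, protocol = config$protocol)

  say("greyzone: ", length(config$greyzone_markers), " markers, B = ",
      config$bootstrap_B)
  relv <- rel[rel$valid, , drop = FALSE]
  gz <- list()
  for (mk in intersect(config$greyzone_markers, names(relv))) {
    gz[[mk]] <- grey_zone(relv[[mk]], relv$label, B = config$bootstrap_B,
                          seed = config$seed + 2L)
  }

  cv <- NULL
  if (length(config$models) > 0) {
    say("evaluate: nested cross-validation, ", config$n_rep, " repetitions")
    cv <- run_nested_cv(config$models, feats, protocol = config$protocol,
                        n_rep = config$n_rep, seed = config$seed + 3L,
                        markers = config$cv_markers)
  }

  report <- structure(
    list(config_hash = hash, counts = counts, stage_stats = stage_tab,
         correlations = cor_tab, greyzone = gz, cv = cv,
         config = config),
    class = "pipeline_report"
  )
  if (!is.null(out_dir)) write_report(report, cohort, feats, rel, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report [config ", x$config_hash, "]\n", sep = "")
  cat("  relational observations: ", x$counts$n_relational, " (",
      x$counts$n_valid, " valid, ", x$counts$n_positive, " positive)\n",
      sep = "")
  for (mk in names(x$greyzone)) {
    g <- x$greyzone[[mk]]
    cat(sprintf("  %-12s AUC %.2f (%.2f-%.2f)  grey zone [%.3f, %.3f]\n",
                mk, g$auc_point, g$auc_ci[1], g$auc_ci[2],
                g$grey_zone[1], g$grey_zone[2]))
  }
  if (!is.null(x$cv)) print(x$cv)
  invisible(x)
}

# Serialize report + intermediates to disk.
write_report <- function(report, cohort, feats, rel, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_cohort_csv(cohort, out_dir)
  data.table::fwrite(feats, file.path(out_dir, "features.csv"))
  data.table::fwrite(rel, file.path(out_dir, "relational.csv"))
  data.table::fwrite(report$stage_stats, file.path(out_dir, "stage_stats.csv"))
  data.table::fwrite(report$correlations,
                     file.path(out_dir, "correlations.csv"))
  payload <- list(
    config_hash = report$config_hash,
    counts = report$counts,
    greyzone = lapply(report$greyzone, function(g)
      g[c("auc_point", "auc_mean", "auc_ci", "best_cutoff_mean",
          "grey_zone", "n_bootstrap", "direction")])
  )
  if (!is.null(report$cv)) {
    payload$cv <- list(
      model_auc = lapply(report$cv$models, `[[`, "auc"),
      marker_auc = as.data.frame(report$cv$marker_auc)
    )
  }
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(out_dir, "summary.txt"), "w")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  invisible(out_dir)
}
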