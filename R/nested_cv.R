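#' Subject-based leave-two-out splits
#'
#' Draws `n_rep` outer splits, each holding back a randomly selected pair
#' of subjects as the test set and training on all remaining subjects.
#' Pairs are drawn without duplicates across repetitions while the number
#' of distinct pairs allows; beyond that, pairs recycle (reshuffled).
#'
#' @param subject_ids character vector of subject identifiers (>= 4).
#' @param n_rep number of repetitions (default 29).
#' @param seed optional integer seed.
#' @return list of splits; each has `rep` (index), `test` (2 subjects) and
#'   `train` (the rest).
#' @examples
#' sp <- make_ltocv_splits(sprintf("S%02d", 1:29), n_rep = 29, seed = 1)
#' lengths(sp[[1]][c("test", "train")])  # 2, 27
#' @export
make_ltocv_splits <- function(subject_ids, n_rep = 29, seed = NULL) {
  subject_ids <- unique(subject_ids)
  n <- length(subject_ids)
  if (n < 4) stop("configuration error: need at least 4 subjects")
  if (!is.null(seed)) set.seed(seed)
  all_pairs <- utils::combn(n, 2)
  npairs <- ncol(all_pairs)
  ord <- integer(0)
  while (length(ord) < n_rep) {
    ord <- c(ord, sample.int(npairs))
  }
  ord <- ord[seq_len(n_rep)]
  lapply(seq_len(n_rep), function(r) {
    test <- subject_ids[all_pairs[, ord[r]]]
    list(rep = r, test = test, train = setdiff(subject_ids, test))
  })
}

#' Expand a hyperparameter grid hit at its edge
#'
#' If any chosen axis value sits at the minimum or maximum of its grid,
#' the axis is extended beyond that edge following the grid's own step
#' pattern (multiplicative for near-geometric grids, additive otherwise),
#' bounded by two expansions per axis. Parameters that must stay positive
#' (bandwidths, costs, kernel widths, counts) are kept positive; integer
#' axes stay integer and >= 1.
#'
#' @param spec a [model_spec()] (carries per-axis expansion counters).
#' @param chosen named list of chosen hyperparameter values.
#' @return list: `spec` (possibly enlarged grid, counters updated) and
#'   `rerun` (`TRUE` when the search should be repeated).
#' @export
expand_grid_if_edge <- function(spec, chosen) {
  stopifnot(inherits(spec, "model_spec"))
  rerun <- FALSE
  for (ax in names(spec$grid)) {
    v <- spec$grid[[ax]]
    if (!is.numeric(v) || length(v) < 2) next
    ch <- chosen[[ax]]
    at_max <- isTRUE(all.equal(ch, max(v)))
    at_min <- isTRUE(all.equal(ch, min(v)))
    if (!at_max && !at_min) next
    if (spec$expansions[[ax]] >= 2L) {
      warning("axis '", ax, "' already expanded twice; capped")
      next
    }
    ratios <- v[-1] / v[-length(v)]
    geometric <- all(v > 0) && length(v) >= 3 &&
      stats::sd(ratios) < 1e-8 * mean(ratios)
    new_vals <- if (at_max) {
      if (geometric) max(v) * ratios[length(ratios)]^(1:2)
      else max(v) + diff(utils::tail(v, 2)) * (1:2)
    } else {
      if (geometric) min(v) / ratios[1]^(1:2)
      else min(v) - diff(utils::head(v, 2)) * (1:2)
    }
    if (ax %in% c("k", "mtry")) new_vals <- pmax(1, round(new_vals))
    if (ax %in% c("adjust", "sigma", "cost")) {
      new_vals <- new_vals[new_vals > 0]
    }
    if (ax == "fL") new_vals <- new_vals[new_vals >= 0]
    new_vals <- setdiff(new_vals, v)
    if (length(new_vals) == 0) next
    spec$grid[[ax]] <- sort(c(v, new_vals))
    spec$expansions[[ax]] <- spec$expansions[[ax]] + 1L
    rerun <- TRUE
  }
  list(spec = spec, rerun = rerun)
}

#' Hyperparameter grid search by inner cross-validated AUC
#'
#' Evaluates every grid point by stratified `inner_folds`-fold
#' cross-validated AUC on the training observations and returns the
#' maximizer; ties break toward the first point in ascending grid order
#' (the least complex setting). When the optimum lies on a grid edge the
#' grid is expanded (see [expand_grid_if_edge()]) and the search repeated.
#'
#' @inheritParams select_features
#' @param expand whether to apply the edge-expansion rule (default `TRUE`).
#' @return list: `pars` (chosen setting), `auc` (its inner-CV AUC), `spec`
#'   (with any grid expansions), `expanded` (number of expansion rounds).
#' @export
grid_search <- function(spec, X, y, expand = TRUE) {
  stopifnot(inherits(spec, "model_spec"), length(spec$grid) > 0)
  folds <- .stratified_folds(y, spec$inner_folds)
  rounds <- 0L
  repeat {
    grid <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE)
    aucs <- vapply(seq_len(nrow(grid)), function(i) {
      .inner_cv_auc(spec, X, y, as.list(grid[i, , drop = FALSE]), folds)
    }, numeric(1))
    if (all(is.na(aucs))) stop("training error: every grid setting failed")
    best <- which.max(aucs)  # first maximum = least complex by grid order
    pars <- as.list(grid[best, , drop = FALSE])
    if (!expand) break
    ex <- expand_grid_if_edge(spec, pars)
    if (!ex$rerun) break
    spec <- ex$spec
    rounds <- rounds + 1L
  }
  list(pars = pars, auc = aucs[best], spec = spec, expanded = rounds)
}

#' Compare two AUC distributions
#'
#' Two-sided unpaired rank-sum test between the per-repetition AUC values
#' of a model and those of a single-marker reference on the same held-out
#' observations. Identical degenerate samples yield p = 1 with a flag.
#'
#' @param model_aucs,marker_aucs numeric AUC samples (length >= 2 each,
#'   NAs dropped).
#' @return p-value with attribute `degenerate`.
#' @export
compare_auc <- function(model_aucs, marker_aucs) {
  a <- model_aucs[!is.na(model_aucs)]
  b <- marker_aucs[!is.na(marker_aucs)]
  if (length(a) < 2 || length(b) < 2) {
    stop("evaluation error: need at least 2 AUC values per group")
  }
  if (length(unique(c(a, b))) == 1) {
    return(structure(1, degenerate = TRUE))
  }
  p <- suppressWarnings(stats::wilcox.test(a, b,
                                           alternative = "two.sided"))$p.value
  structure(min(p, 1), degenerate = FALSE)
}

# Relational model matrix: EC-feature difference columns only (cuff vitals
# and echo are reference channels, not model inputs).
.model_feature_cols <- function(rel) {
  cols <- grep("^d_", names(rel), value = TRUE)
  vital <- grep("^d_(sbp|dbp|map)_", cols, value = TRUE)
  setdiff(cols, vital)
}

#' Subject-grouped nested cross-validation
#'
#' Runs the full evaluation scheme: for each outer leave-two-subjects-out
#' repetition, the feature scaler, the feature selection and the
#' hyperparameter grid search are fitted on the training subjects only;
#' the tuned model is then scored on the held-out subjects' relational
#' observations. Single-marker reference AUCs (ratio markers, orientation
#' learned on the training split) are computed per repetition on the same
#' held-out observations.
#'
#' @param models list of [model_spec()]s (a single spec is accepted).
#' @param features unstandardized feature table from [cohort_features()].
#' @param protocol an [lbnp_protocol()].
#' @param n_rep outer repetitions (default 29).
#' @param seed integer seed governing splits, folds and model randomness.
#' @param markers ratio-marker columns to evaluate alongside the models
#'   (default: heart rate and the three cuff pressures).
#' @param permute_labels permutation-null diagnostic: when `TRUE`, the
#'   outcome labels of the relational observations are randomly permuted
#'   within each subject (train and test alike) before any selection or
#'   tuning, so test AUCs should concentrate around 0.5.
#' @return object of class `cv_result`: per model the vector of `n_rep`
#'   test AUCs (NA when a held-out split is single-class), selected
#'   features, chosen hyperparameters and expansion rounds per repetition;
#'   plus the marker AUC matrix and the splits.
#' @export
run_nested_cv <- function(models, features, protocol = lbnp_protocol(),
                          n_rep = 29, seed = NULL,
                          markers = c("ratio_hr", "ratio_sbp", "ratio_dbp",
                                      "ratio_map"),
                          permute_labels = FALSE) {
  if (inherits(models, "model_spec")) models <- list(models)
  stopifnot(all(vapply(models, inherits, logical(1), "model_spec")))
  names(models) <- vapply(models, `[[`, character(1), "algorithm")
  if (!is.null(seed)) set.seed(seed)
  splits <- make_ltocv_splits(unique(features$subject_id), n_rep)

  res <- lapply(models, function(m) list(
    auc = rep(NA_real_, n_rep), features = vector("list", n_rep),
    pars = vector("list", n_rep), expanded = integer(n_rep)))
  marker_auc <- matrix(NA_real_, n_rep, length(markers),
                       dimnames = list(NULL, markers))

  for (r in seq_len(n_rep)) {
    sp <- splits[[r]]
    tr_rows <- features$subject_id %in% sp$train
    f_train <- features[tr_rows, , drop = FALSE]
    f_test <- features[!tr_rows, , drop = FALSE]
    scaler <- fit_scaler(f_train)
    rel_train <- build_relational(apply_scaler(scaler, f_train),
                                  raw_features = f_train,
                                  protocol = protocol)
    rel_test <- build_relational(apply_scaler(scaler, f_test),
                                 raw_features = f_test,
                                 protocol = protocol)
    rel_train <- rel_train[rel_train$valid, , drop = FALSE]
    rel_test <- rel_test[rel_test$valid, , drop = FALSE]
    if (permute_labels) {
      for (rl in c("rel_train", "rel_test")) {
        tab <- get(rl)
        for (sid in unique(tab$subject_id)) {
          i <- which(tab$subject_id == sid)
          tab$label[i] <- tab$label[sample(i)]
        }
        assign(rl, tab)
      }
    }
    if (nrow(rel_train) == 0 || length(unique(rel_train$label)) < 2) next
    fcols <- .model_feature_cols(rel_train)
    Xtr <- as.matrix(rel_train[, fcols, drop = FALSE])
    ytr <- factor(ifelse(rel_train$label == 1L, "pos", "neg"),
                  levels = c("neg", "pos"))
    Xte <- as.matrix(rel_test[, fcols, drop = FALSE])
    yte <- rel_test$label
    test_two_class <- length(unique(yte)) == 2

    for (mk in intersect(markers, names(rel_train))) {
      if (!test_two_class) next
      dir_train <- if (.rank_auc(rel_train[[mk]],
                                 rel_train$label) >= 0.5) ">" else "<"
      s <- rel_test[[mk]]
      if (dir_train == "<") s <- -s
      marker_auc[r, mk] <- .rank_auc(s, yte)
    }

    for (mn in names(models)) {
      m <- models[[mn]]
      sel <- select_features(m, Xtr, ytr)
      gs <- grid_search(m, Xtr[, sel, drop = FALSE], ytr)
      res[[mn]]$features[[r]] <- sel
      res[[mn]]$pars[[r]] <- gs$pars
      res[[mn]]$expanded[r] <- gs$expanded
      if (!test_two_class) next
      fit <- .model_fit(gs$spec, Xtr[, sel, drop = FALSE], ytr, gs$pars)
      sc <- .model_scores(fit, Xte[, sel, drop = FALSE])
      res[[mn]]$auc[r] <- .rank_auc(sc, yte)
    }
  }
  structure(
    list(models = res, marker_auc = marker_auc, splits = splits,
         n_rep = n_rep, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Nested cross-validation (", x$n_rep, " leave-two-subjects-out",
      " repetitions)\n", sep = "")
  for (mn in names(x$models)) {
    a <- x$models[[mn]]$auc
    cat(sprintf("  %-10s median test AUC %.3f (IQR %.3f-%.3f, %d valid)\n",
                mn, stats::median(a, na.rm = TRUE),
                stats::quantile(a, 0.25, na.rm = TRUE),
                stats::quantile(a, 0.75, na.rm = TRUE), sum(!is.na(a))))
  }
  for (mk in colnames(x$marker_auc)) {
    a <- x$marker_auc[, mk]
    cat(sprintf("  %-10s median test AUC %.3f\n", mk,
                stats::median(a, na.rm = TRUE)))
  }
  invisible(x)
}
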