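#' Default feature parameter roster
#'
#' Beat parameters entering the descriptive-statistic feature grid. The
#' development-only cardiac cycle counter (`ccc`) is excluded by default;
#' cuff vitals are retained as reference markers but can be dropped from
#' model features downstream.
#'
#' @return character vector of parameter names.
#' @export
feature_parameters <- function() setdiff(ec_parameters(), "ccc")

#' Extract end-of-stage analysis windows
#'
#' Slices, for every (subject, stage) present in the beat table, the beats
#' falling in the last `window_length_s` seconds of the stage
#' (`time_s` in `[duration - window, duration)`). The protocol guarantees
#' the window never overlaps the excluded settling interval at the stage
#' start. Windows with fewer than 10 beats are flagged degenerate and
#' excluded.
#'
#' @param cohort an `lbnp_cohort` (or a list with a `beats` data.table).
#' @param protocol an [lbnp_protocol()]; defaults to the cohort's.
#' @return data.table of window beats, with attribute `degenerate`
#'   (data.frame of excluded subject/stage pairs, possibly empty).
#' @export
extract_windows <- function(cohort, protocol = cohort$protocol) {
  stopifnot(inherits(protocol, "lbnp_protocol"))
  beats <- data.table::as.data.table(cohort$beats)
  wb <- window_bounds(protocol)
  idx <- match(beats$stage, wb$stage)
  if (anyNA(idx)) stop("unknown stage label(s) in beat table")
  inside <- beats$time_s >= wb$window_start_s[idx] &
    beats$time_s < wb$window_end_s[idx]
  win <- beats[inside]
  counts <- win[, list(n = .N), by = c("subject_id", "stage")]
  degen <- counts[counts$n < 10, c("subject_id", "stage")]
  if (nrow(degen) > 0) {
    key <- paste(win$subject_id, win$stage)
    win <- win[!(key %in% paste(degen$subject_id, degen$stage))]
    warning(nrow(degen), " degenerate window(s) (<10 beats) excluded")
  }
  data.table::setorderv(win, c("subject_id", "stage", "time_s"))
  attr(win, "degenerate") <- as.data.frame(degen)
  win
}

#' Descriptive statistics of one window
#'
#' The seven window descriptors: mean, median, standard deviation (n-1),
#' variance, moment skewness g1, excess kurtosis g2 and interquartile range
#' (linear-interpolation quantiles, type 7). Zero-variance input yields
#' skew = kurt = 0 by convention so that constant channels do not propagate
#' NaN into the models.
#'
#' @param x numeric vector of beat values.
#' @return named numeric vector of length 7.
#' @examples
#' descriptor_stats(c(1, 2, 3, 4))
#' @export
descriptor_stats <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) stop("domain error: empty window")
  m <- mean(x)
  v <- if (n > 1) stats::var(x) else 0
  s <- sqrt(v)
  if (v > 0) {
    m2 <- mean((x - m)^2)
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  c(mean = m, median = stats::median(x), sd = s, var = v,
    skew = skew, kurt = kurt,
    iqr = unname(stats::quantile(x, 0.75, type = 7) -
                   stats::quantile(x, 0.25, type = 7)))
}

#' Window feature grid
#'
#' Computes the 7-statistic descriptor grid for every parameter in every
#' (subject, stage) analysis window. Column names follow
#' `<parameter>_<statistic>`.
#'
#' @param windows window beat table from [extract_windows()].
#' @param parameters parameter columns to describe; defaults to
#'   [feature_parameters()].
#' @return data.frame, one row per (subject, stage), columns `subject_id`,
#'   `stage`, `n_beats`, then the feature grid.
#' @export
compute_descriptors <- function(windows, parameters = feature_parameters()) {
  stopifnot(all(parameters %in% names(windows)))
  stats_names <- c("mean", "median", "sd", "var", "skew", "kurt", "iqr")
  dt <- data.table::as.data.table(windows)
  res <- dt[, {
    vals <- lapply(.SD, descriptor_stats)
    out <- as.list(unlist(vals))
    names(out) <- as.vector(outer(stats_names, parameters,
                                  function(s, p) paste(p, s, sep = "_")))
    c(list(n_beats = .N), out)
  }, by = c("subject_id", "stage"), .SDcols = parameters]
  as.data.frame(res)
}

#' Fit / apply a z-score feature scaler
#'
#' Learns per-feature location (mean) and scale (n-1 standard deviation)
#' from a reference feature table; zero-variance features are recorded and
#' dropped consistently when the scaler is applied. Applying the scaler to
#' its own reference set yields per-feature mean 0 and sd 1.
#'
#' @param features data.frame of feature vectors (from
#'   [compute_descriptors()]).
#' @param feature_cols columns to scale; default: all numeric columns
#'   except bookkeeping (`subject_id`, `stage`, `n_beats`).
#' @return `fit_scaler`: object of class `feature_scaler` with `center`,
#'   `scale` (named vectors over retained features) and `dropped`.
#' @examples
#' f <- data.frame(subject_id = c("a", "b"), stage = c("s", "s"),
#'                 x_mean = c(0, 10))
#' sc <- fit_scaler(f, "x_mean")
#' apply_scaler(sc, f)$x_mean  # -0.7071, +0.7071
#' @export
fit_scaler <- function(features, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                                   logical(1))],
                            c("n_beats", "sv_tte_ml"))
  }
  if (nrow(features) < 2) stop("need >= 2 feature vectors to fit a scaler")
  X <- as.matrix(features[, feature_cols, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  dropped <- feature_cols[!is.finite(scl) | scl <= 0]
  keep <- setdiff(feature_cols, dropped)
  structure(
    list(center = ctr[keep], scale = scl[keep], dropped = dropped),
    class = "feature_scaler"
  )
}

#' @rdname fit_scaler
#' @param scaler a fitted `feature_scaler`.
#' @return `apply_scaler`: the feature table with retained features
#'   standardized and dropped features removed.
#' @export
apply_scaler <- function(scaler, features) {
  stopifnot(inherits(scaler, "feature_scaler"))
  keep <- names(scaler$center)
  missing_cols <- setdiff(keep, names(features))
  if (length(missing_cols) > 0) {
    stop("schema error: feature(s) absent at apply time: ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  out <- features[, setdiff(names(features), scaler$dropped), drop = FALSE]
  for (cn in keep) {
    out[[cn]] <- (out[[cn]] - scaler$center[[cn]]) / scaler$scale[[cn]]
  }
  out
}

#' Full feature pipeline for a cohort
#'
#' Extract windows, compute the descriptor grid, and attach the echo
#' reference stroke volume per (subject, stage).
#'
#' @param cohort an `lbnp_cohort`.
#' @param parameters parameter roster, default [feature_parameters()].
#' @return data.frame: one row per (subject, stage) with features and
#'   `sv_tte_ml` (NA where echo is missing).
#' @export
cohort_features <- function(cohort, parameters = feature_parameters()) {
  win <- extract_windows(cohort)
  feats <- compute_descriptors(win, parameters)
  key <- paste(feats$subject_id, feats$stage)
  ekey <- paste(cohort$echo$subject_id, cohort$echo$stage)
  feats$sv_tte_ml <- cohort$echo$sv_tte_ml[match(key, ekey)]
  feats
}
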