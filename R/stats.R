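#' Cohen strength class of a correlation coefficient
#'
#' Pure step function of the absolute coefficient with inclusive lower
#' edges: |rho| < 0.1 "below-small", 0.1 <= |rho| < 0.3 "small",
#' 0.3 <= |rho| < 0.5 "medium", |rho| >= 0.5 "large".
#'
#' @param rho numeric vector of correlation coefficients in [-1, 1].
#' @return character vector of classes.
#' @examples
#' cohen_class(c(0.05, 0.1, 0.3, 0.5, -0.9))
#' @export
cohen_class <- function(rho) {
  stopifnot(all(abs(rho[!is.na(rho)]) <= 1 + 1e-12))
  cut(abs(rho), breaks = c(-Inf, 0.1, 0.3, 0.5, Inf), right = FALSE,
      labels = c("below-small", "small", "medium", "large")) |>
    as.character()
}

#' Relative change of stage values versus subject baseline
#'
#' Divides every subject's per-stage value by that subject's baseline
#' value. Baseline rows are exactly 1; subjects with a zero or missing
#' baseline are excluded with a warning.
#'
#' @param df data.frame with `subject_id`, `stage` and the value column.
#' @param value_col name of the numeric value column.
#' @param protocol an [lbnp_protocol()] (first stage = baseline).
#' @return `df` with an added `rel_change` column, baseline-less subjects
#'   removed.
#' @export
relative_changes <- function(df, value_col, protocol = lbnp_protocol()) {
  stopifnot(all(c("subject_id", "stage", value_col) %in% names(df)))
  baseline_stage <- protocol$stages$stage[1]
  base <- df[df$stage == baseline_stage, c("subject_id", value_col)]
  basev <- stats::setNames(base[[value_col]], base$subject_id)
  b <- basev[df$subject_id]
  bad_subj <- unique(df$subject_id[is.na(b) | b == 0])
  if (length(bad_subj) > 0) {
    warning("excluding ", length(bad_subj),
            " subject(s) with missing/zero baseline")
    keep <- !(df$subject_id %in% bad_subj)
    df <- df[keep, , drop = FALSE]
    b <- b[keep]
  }
  df$rel_change <- df[[value_col]] / b
  df$rel_change[df$stage == baseline_stage] <- 1
  df
}

#' Paired Wilcoxon signed-rank test against baseline
#'
#' Two-sided paired signed-rank test (zero differences dropped; exact null
#' distribution for small samples without ties, normal approximation with
#' continuity correction otherwise). When every difference is zero the
#' test is degenerate and p = 1 is returned with a `degenerate` attribute.
#'
#' @param x,y paired numeric vectors (stage values and baseline values).
#' @return p-value with attribute `degenerate`.
#' @export
wilcoxon_vs_baseline <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  d <- x - y
  if (all(d == 0)) {
    return(structure(1, degenerate = TRUE))
  }
  p <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                           alternative = "two.sided"))$p.value
  structure(min(p, 1), degenerate = FALSE)
}

#' Pearson and Spearman correlation with Cohen class
#'
#' Population scope: one coefficient pair over all points. Per-subject
#' scope: coefficients per subject (requiring at least 3 paired points
#' each) and their distribution (median, quartiles). Spearman uses average
#' ranks for ties. Zero-variance input is flagged undefined (NA).
#'
#' @param x,y paired numeric vectors.
#' @param subject_id subject identifier per point (required for
#'   `scope = "per-subject"`).
#' @param scope `"population"` or `"per-subject"`.
#' @return list with `scope`, `pearson`, `spearman`, `cohen_class`
#'   (population) or the per-subject coefficient vectors plus their
#'   `median`/`q25`/`q75` and the class of the median (per-subject).
#' @export
correlations <- function(x, y, subject_id = NULL,
                         scope = c("population", "per-subject")) {
  scope <- match.arg(scope)
  one <- function(x, y) {
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(c(pearson = NA_real_, spearman = NA_real_))
    }
    c(pearson = stats::cor(x, y, method = "pearson"),
      spearman = stats::cor(x, y, method = "spearman"))
  }
  if (scope == "population") {
    r <- one(x, y)
    return(list(scope = scope, pearson = r[["pearson"]],
                spearman = r[["spearman"]],
                cohen_class = cohen_class(r[["pearson"]])))
  }
  stopifnot(!is.null(subject_id), length(subject_id) == length(x))
  per <- vapply(split(seq_along(x), subject_id),
                function(i) one(x[i], y[i]), numeric(2))
  pe <- per["pearson", ]; sp <- per["spearman", ]
  med <- stats::median(pe, na.rm = TRUE)
  list(
    scope = scope,
    pearson = pe, spearman = sp,
    median = med,
    q25 = unname(stats::quantile(pe, 0.25, na.rm = TRUE, type = 7)),
    q75 = unname(stats::quantile(pe, 0.75, na.rm = TRUE, type = 7)),
    spearman_median = stats::median(sp, na.rm = TRUE),
    cohen_class = cohen_class(med)
  )
}

#' Stage-wise comparison table
#'
#' For every parameter's window mean: median relative change versus
#' baseline with quartiles, and the paired Wilcoxon signed-rank p-value of
#' the stage values against the baseline values.
#'
#' @param features feature table from [cohort_features()] (unstandardized).
#' @param parameters parameters to summarize (window `_mean` columns used);
#'   `"sv_tte"` is included via the `sv_tte_ml` column when present.
#' @param protocol an [lbnp_protocol()].
#' @return data.frame: parameter, stage, n, median_rel, q25, q75, p_value.
#' @export
stage_stats <- function(features,
                        parameters = c("sv_tte", "sv", "hr", "co", "icon",
                                       "pep", "str", "svv", "hrv",
                                       "sbp", "dbp", "map"),
                        protocol = lbnp_protocol()) {
  baseline_stage <- protocol$stages$stage[1]
  other_stages <- setdiff(protocol$stages$stage, baseline_stage)
  out <- list()
  for (p in parameters) {
    col <- if (p == "sv_tte") "sv_tte_ml" else paste0(p, "_mean")
    if (!col %in% names(features)) next
    df <- features[, c("subject_id", "stage", col)]
    rel <- relative_changes(df, col, protocol)
    base <- df[df$stage == baseline_stage, ]
    basev <- stats::setNames(base[[col]], base$subject_id)
    for (s in other_stages) {
      rs <- rel[rel$stage == s & !is.na(rel$rel_change), ]
      st <- df[df$stage == s, ]
      pairs <- cbind(st[[col]], basev[st$subject_id])
      pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
      pv <- if (nrow(pairs) >= 5) {
        as.numeric(wilcoxon_vs_baseline(pairs[, 1], pairs[, 2]))
      } else NA_real_
      out[[length(out) + 1]] <- data.frame(
        parameter = p, stage = s, n = nrow(rs),
        median_rel = stats::median(rs$rel_change),
        q25 = unname(stats::quantile(rs$rel_change, 0.25, type = 7)),
        q75 = unname(stats::quantile(rs$rel_change, 0.75, type = 7)),
        p_value = pv,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Intra-subject correlation of each parameter with SV-TTE
#'
#' Per-subject Pearson/Spearman correlations between each parameter's
#' window mean and the echo reference stroke volume across protocol
#' stages, summarized by the cohort median and quartiles with the Cohen
#' strength class of the median.
#'
#' @inheritParams stage_stats
#' @return data.frame: parameter, n_subjects, pearson_median, pearson_q25,
#'   pearson_q75, spearman_median, cohen_class.
#' @export
correlation_stats <- function(features,
                              parameters = c("sv", "icon", "pep", "str",
                                             "svv", "hrv", "sbp", "hr",
                                             "dbp", "map"),
                              protocol = lbnp_protocol()) {
  out <- list()
  for (p in parameters) {
    col <- paste0(p, "_mean")
    if (!col %in% names(features)) next
    cr <- correlations(features[[col]], features$sv_tte_ml,
                       subject_id = features$subject_id,
                       scope = "per-subject")
    out[[length(out) + 1]] <- data.frame(
      parameter = p,
      n_subjects = sum(!is.na(cr$pearson)),
      pearson_median = cr$median,
      pearson_q25 = cr$q25,
      pearson_q75 = cr$q75,
      spearman_median = cr$spearman_median,
      cohen_class = cr$cohen_class,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
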