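#' Label a relational observation by stroke-volume decrease
#'
#' Positive (compensated-shock) label when the target stroke volume has
#' fallen by 20% or more relative to the reference timepoint:
#' `sv_target <= 0.8 * sv_ref`. The boundary (exactly 20%) is positive.
#'
#' @param sv_ref,sv_target reference and target stroke volume (mL), both
#'   strictly positive. Vectorized.
#' @return integer vector: 1 = decrease of 20% or more, 0 otherwise.
#' @examples
#' label_observation(100, c(79, 80, 81))  # 1 1 0
#' @export
label_observation <- function(sv_ref, sv_target) {
  if (any(sv_ref <= 0, na.rm = TRUE) || any(sv_target <= 0, na.rm = TRUE)) {
    stop("domain error: stroke volumes must be strictly positive")
  }
  as.integer(sv_target <= 0.8 * sv_ref)
}

#' Number of relational observations
#'
#' A subject observed at `T` timepoints yields every (earlier, later) pair
#' plus the baseline singleton: `1 + T (T - 1) / 2` observations.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_timepoints timepoints per subject (>= 1).
#' @return total count across the cohort.
#' @examples
#' count_relational(30, 5)  # 330
#' count_relational(29, 5)  # 319
#' @export
count_relational <- function(n_subjects, n_timepoints) {
  stopifnot(n_subjects >= 1, n_timepoints >= 1)
  n_subjects * (1 + n_timepoints * (n_timepoints - 1) / 2)
}

#' Build within-subject relational observations
#'
#' Relates each observed timepoint to every earlier timepoint of the same
#' subject. The relational features are element-wise differences of the
#' (standardized) window features, target minus reference; the baseline
#' measurement enters once as a self-relation with an all-zero feature
#' vector and a negative label. When a raw (unstandardized) feature table
#' is supplied, ratio markers `ratio_<parameter>` (target window mean over
#' reference window mean) are attached for single-feature diagnostics.
#'
#' An observation is `valid` only when the echo reference stroke volume is
#' available at both compared timepoints; invalid observations are emitted
#' (for accounting) with `label = NA`.
#'
#' @param features feature table (one row per subject x stage) carrying
#'   `subject_id`, `stage`, `sv_tte_ml` and feature columns -- typically
#'   standardized via [apply_scaler()].
#' @param raw_features optional unstandardized feature table (same rows)
#'   whose `<parameter>_mean` columns provide the ratio markers.
#' @param protocol an [lbnp_protocol()] giving the stage order.
#' @param feature_cols relational feature columns; default: all numeric
#'   columns except bookkeeping and `sv_tte_ml`.
#' @param marker_params parameters for which ratio markers are computed
#'   (those with a `<parameter>_mean` column in `raw_features`).
#' @return data.frame of class `relational_table`: `subject_id`,
#'   `ref_stage`, `target_stage`, `label`, `valid`, marker columns, and
#'   `d_<feature>` difference columns.
#' @export
build_relational <- function(features,
                             raw_features = NULL,
                             protocol = lbnp_protocol(),
                             feature_cols = NULL,
                             marker_params = c("hr", "sbp", "dbp", "map",
                                               "sv", "pep", "str", "icon",
                                               "svv", "hrv")) {
  stopifnot(all(c("subject_id", "stage", "sv_tte_ml") %in% names(features)))
  if (anyDuplicated(features[c("subject_id", "stage")]) > 0) {
    stop("data error: duplicate (subject, stage) rows")
  }
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(
      names(features)[vapply(features, is.numeric, logical(1))],
      c("n_beats", "sv_tte_ml"))
  }
  rank <- stage_rank(features$stage, protocol)
  baseline_stage <- protocol$stages$stage[1]

  if (!is.null(raw_features)) {
    mcols <- paste0(marker_params, "_mean")
    have <- mcols %in% names(raw_features)
    marker_params <- marker_params[have]
    mcols <- mcols[have]
    rk <- paste(raw_features$subject_id, raw_features$stage)
    fk <- paste(features$subject_id, features$stage)
    raw_means <- as.matrix(raw_features[match(fk, rk), mcols, drop = FALSE])
  } else {
    marker_params <- character(0)
    raw_means <- NULL
  }

  X <- as.matrix(features[, feature_cols, drop = FALSE])
  out <- vector("list", length(unique(features$subject_id)))
  oi <- 0L
  for (sid in unique(features$subject_id)) {
    rows <- which(features$subject_id == sid)
    rows <- rows[order(rank[rows])]
    pairs <- list()
    if (features$stage[rows[1]] == baseline_stage) {
      pairs[[1]] <- c(rows[1], rows[1])  # baseline singleton
    }
    if (length(rows) >= 2) {
      for (j in 2:length(rows)) {
        for (i in 1:(j - 1)) {
          pairs[[length(pairs) + 1]] <- c(rows[i], rows[j])
        }
      }
    }
    if (length(pairs) == 0) next
    ref <- vapply(pairs, `[`, integer(1), 1)
    tgt <- vapply(pairs, `[`, integer(1), 2)
    singleton <- ref == tgt
    sv_r <- features$sv_tte_ml[ref]
    sv_t <- features$sv_tte_ml[tgt]
    valid <- !is.na(sv_r) & !is.na(sv_t)
    label <- rep(NA_integer_, length(ref))
    label[valid] <- label_observation(sv_r[valid], sv_t[valid])
    label[singleton & valid] <- 0L  # baseline singleton: negative by construction
    d <- X[tgt, , drop = FALSE] - X[ref, , drop = FALSE]
    colnames(d) <- paste0("d_", feature_cols)
    block <- data.frame(
      subject_id = sid,
      ref_stage = features$stage[ref],
      target_stage = features$stage[tgt],
      label = label,
      valid = valid,
      stringsAsFactors = FALSE
    )
    if (!is.null(raw_means) && length(marker_params) > 0) {
      ratio <- raw_means[tgt, , drop = FALSE] / raw_means[ref, , drop = FALSE]
      colnames(ratio) <- paste0("ratio_", marker_params)
      block <- cbind(block, as.data.frame(ratio))
    }
    oi <- oi + 1L
    out[[oi]] <- cbind(block, as.data.frame(d))
  }
  res <- do.call(rbind, out[seq_len(oi)])
  rownames(res) <- NULL
  class(res) <- c("relational_table", "data.frame")
  res
}

#' @export
print.relational_table <- function(x, ...) {
  cat("Relational observations: ", nrow(x), " rows (",
      sum(x$valid), " valid, ", sum(x$label[x$valid] == 1L),
      " positive), ", length(grep("^d_", names(x))), " features\n", sep = "")
  invisible(as.data.frame(x))
}
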