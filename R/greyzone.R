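# Internal: per-unique-value positive/negative counts, sorted ascending.
.score_counts <- function(scores, labels) {
  if (anyNA(scores) || anyNA(labels)) {
    keep <- !is.na(scores) & !is.na(labels)
    scores <- scores[keep]; labels <- labels[keep]
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("evaluation error: both classes must be present")
  }
  o <- order(scores)
  s <- scores[o]; l <- labels[o]
  n <- length(s)
  newgrp <- c(TRUE, s[-1] != s[-n])
  gid <- cumsum(newgrp)
  pos <- as.vector(rowsum(as.numeric(l), gid))
  neg <- as.vector(rowsum(1 - as.numeric(l), gid))
  list(u = s[newgrp], pos = pos, neg = neg, n1 = n1, n0 = n0)
}

# Internal: fast AUC by the rank statistic (ties counted 1/2), direction
# "larger score indicates positive".
.rank_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and trapezoidal AUC
#'
#' Builds the full ROC curve of a scalar marker against a binary outcome
#' and computes the area under it by the trapezoidal rule (equal, with ties
#' counted one half, to the Mann-Whitney rank statistic).
#'
#' @param scores numeric marker values.
#' @param labels binary outcome (0/1), both classes present.
#' @param direction `">"` if larger scores indicate the positive class,
#'   `"<"` for the opposite, `"auto"` (default) to pick the direction with
#'   AUC >= 0.5 (recorded in the result).
#' @return object of class `roc_curve`: `thresholds` (candidate cutoffs,
#'   "positive if score > threshold" after orientation), `sensitivity`,
#'   `specificity`, `auc`, `direction`.
#' @examples
#' r <- roc_auc(c(0, 1, 2, 3), c(0, 0, 1, 1), direction = ">")
#' r$auc  # 1
#' @export
roc_auc <- function(scores, labels, direction = c("auto", ">", "<")) {
  direction <- match.arg(direction)
  cc <- .score_counts(scores, labels)
  if (direction == "auto") {
    direction <- if (.rank_auc(scores, labels) >= 0.5) ">" else "<"
  }
  s <- if (direction == "<") -scores else scores
  cc <- .score_counts(s, labels)
  k <- length(cc$u)
  # candidate cutoffs: -Inf, midpoints of adjacent unique values, +Inf
  thr <- c(-Inf, if (k > 1) (cc$u[-k] + cc$u[-1]) / 2, Inf)
  cumpos <- c(0, cumsum(cc$pos))[c(1, if (k > 1) 2:k, k + 1)]
  cumneg <- c(0, cumsum(cc$neg))[c(1, if (k > 1) 2:k, k + 1)]
  sens <- (cc$n1 - cumpos) / cc$n1
  spec <- cumneg / cc$n0
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(o)]) / 2)
  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         auc = auc, direction = direction),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve: AUC =", format(x$auc, digits = 4),
      "| direction", x$direction,
      "|", length(x$thresholds), "thresholds\n")
  invisible(x)
}

# Internal Youden maximizer over oriented scores; returns c(cutoff, j).
# Ties broken toward the smaller threshold.
.youden <- function(scores, labels) {
  cc <- .score_counts(scores, labels)
  k <- length(cc$u)
  if (k == 1) return(c(cutoff = cc$u, j = 0))
  thr <- c(-Inf, (cc$u[-k] + cc$u[-1]) / 2, Inf)
  cumpos <- c(0, cumsum(cc$pos))
  cumneg <- c(0, cumsum(cc$neg))
  sens <- (cc$n1 - cumpos) / cc$n1
  spec <- cumneg / cc$n0
  j <- sens + spec - 1
  # first maximum (tolerant to floating noise) = smallest threshold
  best <- which(j > max(j) - 1e-12)[1]
  c(cutoff = thr[best], j = j[best])
}

#' Youden-optimal cutoff
#'
#' Cutoff maximizing the Youden index J = sensitivity + specificity - 1
#' over all candidate thresholds (midpoints between adjacent sorted unique
#' scores, plus the two infinite extremes). Ties break toward the smaller
#' threshold. An observation is called positive when its (oriented) score
#' exceeds the cutoff.
#'
#' @inheritParams roc_auc
#' @return numeric cutoff (on the original score scale) with attributes
#'   `youden_j` and `direction`.
#' @examples
#' youden_best_cutoff(c(0, 1, 2, 3), c(0, 0, 1, 1), direction = ">")  # 1.5
#' @export
youden_best_cutoff <- function(scores, labels, direction = c("auto", ">", "<")) {
  direction <- match.arg(direction)
  if (direction == "auto") {
    .score_counts(scores, labels)  # class check
    direction <- if (.rank_auc(scores, labels) >= 0.5) ">" else "<"
  }
  s <- if (direction == "<") -scores else scores
  res <- .youden(s, labels)
  cut <- if (direction == "<") -res[["cutoff"]] else res[["cutoff"]]
  structure(cut, youden_j = res[["j"]], direction = direction)
}

#' Bootstrap AUC with percentile confidence interval
#'
#' Resamples observations with replacement `B` times, recomputes the AUC on
#' every replicate (replicates degenerating to a single class are skipped),
#' and returns the bootstrap mean with percentile 2.5%/97.5% bounds.
#'
#' @inheritParams roc_auc
#' @param B number of bootstrap replicates (>= 2), default 1000.
#' @param seed optional integer seed.
#' @param stratified resample within outcome classes, preserving class
#'   counts (default `FALSE`).
#' @return list: `auc_point`, `auc_mean`, `ci_low`, `ci_high`, `B_valid`.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 1000, seed = NULL,
                             direction = c("auto", ">", "<"),
                             stratified = FALSE) {
  direction <- match.arg(direction)
  if (!is.numeric(B) || B < 2) stop("evaluation error: B must be >= 2")
  B <- as.integer(B)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  .score_counts(scores, labels)
  if (direction == "auto") {
    direction <- if (.rank_auc(scores, labels) >= 0.5) ">" else "<"
  }
  s <- if (direction == "<") -scores else scores
  if (!is.null(seed)) set.seed(seed)
  n <- length(s)
  idx_pos <- which(labels == 1L); idx_neg <- which(labels == 0L)
  aucs <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- if (stratified) {
      c(sample(idx_pos, length(idx_pos), replace = TRUE),
        sample(idx_neg, length(idx_neg), replace = TRUE))
    } else {
      sample.int(n, n, replace = TRUE)
    }
    aucs[b] <- .rank_auc(s[idx], labels[idx])
  }
  valid <- aucs[!is.na(aucs)]
  if (length(valid) == 0) {
    stop("evaluation error: all bootstrap replicates were single-class")
  }
  list(
    auc_point = .rank_auc(s, labels),
    auc_mean = mean(valid),
    ci_low = unname(stats::quantile(valid, 0.025, type = 7)),
    ci_high = unname(stats::quantile(valid, 0.975, type = 7)),
    B_valid = length(valid),
    direction = direction
  )
}

#' Grey-zone analysis of a scalar marker
#'
#' Full diagnostic evaluation: point AUC with bootstrap 95% CI, and the
#' distribution of the Youden-optimal cutoff over `B` bootstrap replicates.
#' The grey zone is the percentile 95% CI of the best cutoff -- the
#' interval of marker values within which the condition can be neither
#' ruled in nor ruled out; its lower bound rules the stroke-volume decrease
#' out, its upper bound rules it in (after orientation).
#'
#' @inheritParams bootstrap_auc_ci
#' @return object of class `greyzone_result`: `auc_point`, `auc_mean`,
#'   `auc_ci` (length-2), `best_cutoff_mean`, `grey_zone` (length-2,
#'   ordered), `youden_point`, `n_bootstrap` (valid replicates),
#'   `direction`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(50, 0, 0.5), rnorm(50, 1, 0.5))
#' y <- rep(0:1, each = 50)
#' grey_zone(x, y, B = 200, seed = 7)
#' @export
grey_zone <- function(scores, labels, B = 1000, seed = NULL,
                      direction = c("auto", ">", "<"),
                      stratified = FALSE) {
  direction <- match.arg(direction)
  if (!is.numeric(B) || B < 2) stop("evaluation error: B must be >= 2")
  B <- as.integer(B)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  .score_counts(scores, labels)
  if (direction == "auto") {
    direction <- if (.rank_auc(scores, labels) >= 0.5) ">" else "<"
  }
  s <- if (direction == "<") -scores else scores
  if (!is.null(seed)) set.seed(seed)
  n <- length(s)
  idx_pos <- which(labels == 1L); idx_neg <- which(labels == 0L)
  aucs <- rep(NA_real_, B)
  cuts <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- if (stratified) {
      c(sample(idx_pos, length(idx_pos), replace = TRUE),
        sample(idx_neg, length(idx_neg), replace = TRUE))
    } else {
      sample.int(n, n, replace = TRUE)
    }
    lb <- labels[idx]
    if (all(lb == 1L) || all(lb == 0L)) next
    sb <- s[idx]
    aucs[b] <- .rank_auc(sb, lb)
    cuts[b] <- .youden(sb, lb)[["cutoff"]]
  }
  aucs <- aucs[!is.na(aucs)]
  cuts <- cuts[is.finite(cuts)]
  if (length(cuts) == 0) {
    stop("evaluation error: no valid bootstrap replicate")
  }
  flip <- function(v) if (direction == "<") -v else v
  zone <- sort(flip(unname(stats::quantile(cuts, c(0.025, 0.975), type = 7))))
  point <- .youden(s, labels)
  structure(
    list(
      auc_point = .rank_auc(s, labels),
      auc_mean = mean(aucs),
      auc_ci = c(unname(stats::quantile(aucs, 0.025, type = 7)),
                 unname(stats::quantile(aucs, 0.975, type = 7))),
      best_cutoff_mean = flip(mean(cuts)),
      grey_zone = zone,
      youden_point = flip(point[["cutoff"]]),
      n_bootstrap = length(cuts),
      direction = direction
    ),
    class = "greyzone_result"
  )
}

#' @export
print.greyzone_result <- function(x, ...) {
  cat("Grey-zone analysis (direction ", x$direction, ")\n",
      "  AUC = ", format(x$auc_point, digits = 3),
      " (95% CI ", format(x$auc_ci[1], digits = 3), "-",
      format(x$auc_ci[2], digits = 3), ", ", x$n_bootstrap,
      " bootstrap replicates)\n",
      "  best cutoff mean = ", format(x$best_cutoff_mean, digits = 4),
      ", grey zone = [", format(x$grey_zone[1], digits = 4), ", ",
      format(x$grey_zone[2], digits = 4), "]\n", sep = "")
  invisible(x)
}
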