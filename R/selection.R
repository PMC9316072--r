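# Equal-frequency discretization into at most `bins` bins.
.discretize <- function(x, bins = 5) {
  u <- unique(x)
  if (length(u) <= bins) return(factor(x))  # already (near-)discrete
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 7, na.rm = TRUE))
  if (length(br) < 2) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

.entropy <- function(f) {
  p <- table(f) / length(f)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy-based feature filter scores
#'
#' Information gain, gain ratio and symmetrical uncertainty of each
#' feature with respect to a binary label, after equal-frequency
#' discretization of continuous features into `bins` bins:
#' `IG = H(Y) - H(Y|X)`, `GR = IG / H(X)`, `SU = 2 IG / (H(X) + H(Y))`.
#' Constant features score 0 on all three.
#'
#' @param X numeric matrix or data.frame of features.
#' @param y binary labels (0/1 or a 2-level factor), both classes present.
#' @param bins number of discretization bins (default 5).
#' @return data.frame: feature, info_gain, gain_ratio, sym_uncert
#'   (all nonnegative).
#' @export
entropy_filters <- function(X, y, bins = 5) {
  X <- as.data.frame(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) {
    stop("selection error: labels must contain both classes")
  }
  hy <- .entropy(y)
  res <- lapply(names(X), function(fn) {
    xf <- if (is.numeric(X[[fn]])) .discretize(X[[fn]], bins)
          else as.factor(X[[fn]])
    hx <- .entropy(xf)
    if (hx == 0) {
      return(data.frame(feature = fn, info_gain = 0, gain_ratio = 0,
                        sym_uncert = 0))
    }
    # H(Y|X) = sum_x p(x) H(Y|X=x)
    hyx <- sum(vapply(split(y, xf), function(ys) {
      if (length(ys) == 0) 0 else length(ys) / length(y) * .entropy(ys)
    }, numeric(1)))
    ig <- max(hy - hyx, 0)
    data.frame(feature = fn, info_gain = ig, gain_ratio = ig / hx,
               sym_uncert = 2 * ig / (hx + hy))
  })
  do.call(rbind, res)
}

# Forward greedy wrapper: adds the feature maximizing inner-CV AUC until
# no candidate improves by more than `tol`; the best single feature is
# always kept.
.forward_wrapper <- function(spec, X, y, pars, folds) {
  p <- ncol(X)
  remaining <- seq_len(p)
  chosen <- integer(0)
  best_auc <- -Inf
  while (length(remaining) > 0 && length(chosen) < spec$wrapper_max) {
    cand_auc <- vapply(remaining, function(j) {
      .inner_cv_auc(spec, X[, c(chosen, j), drop = FALSE], y, pars, folds)
    }, numeric(1))
    jbest <- which.max(cand_auc)
    improvement <- cand_auc[jbest] - best_auc
    if (length(chosen) > 0 && improvement <= spec$wrapper_tol) break
    best_auc <- cand_auc[jbest]
    chosen <- c(chosen, remaining[jbest])
    remaining <- remaining[-jbest]
  }
  colnames(X)[chosen]
}

# Recursive elimination over subset sizes: features ranked by symmetrical
# uncertainty; nested subsets of decreasing size evaluated by inner-CV
# AUC; the best-performing size wins.
.recursive_elimination <- function(spec, X, y, pars, folds) {
  sc <- entropy_filters(X, y)
  ord <- order(sc$sym_uncert, decreasing = TRUE)
  p <- ncol(X)
  sizes <- unique(pmin(p, c(2, 4, 8, 16, 32, 64, p)))
  sizes <- sizes[sizes >= 1]
  aucs <- vapply(sizes, function(k) {
    .inner_cv_auc(spec, X[, ord[seq_len(k)], drop = FALSE], y, pars, folds)
  }, numeric(1))
  k <- sizes[which.max(aucs)]
  colnames(X)[ord[seq_len(k)]]
}

#' Select model features
#'
#' Dispatches the feature-selection method of a [model_spec()]: all
#' features, union of the three entropy filters (features scored positive
#' by any of information gain, gain ratio or symmetrical uncertainty),
#' the gain-ratio filter alone, recursive elimination over ranked subset
#' sizes, or the forward wrapper evaluated by inner-CV AUC.
#'
#' @param spec a [model_spec()].
#' @param X feature matrix (training observations only).
#' @param y factor labels with levels `c("neg", "pos")`.
#' @param pars hyperparameters used by wrapper/elimination evaluation
#'   (defaults to the grid midpoint).
#' @return character vector of selected feature names (never empty).
#' @export
select_features <- function(spec, X, y, pars = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(pars)) {
    pars <- lapply(spec$grid, function(v) v[[ceiling(length(v) / 2)]])
  }
  sel <- switch(spec$selection,
    all = colnames(X),
    entropy_union = {
      sc <- entropy_filters(X, y)
      sc$feature[sc$info_gain > 0 | sc$gain_ratio > 0 | sc$sym_uncert > 0]
    },
    gain_ratio = {
      sc <- entropy_filters(X, y)
      sc$feature[sc$gain_ratio > 0]
    },
    recursive_elimination = {
      folds <- .stratified_folds(y, spec$inner_folds)
      .recursive_elimination(spec, X, y, pars, folds)
    },
    forward_wrapper = {
      folds <- .stratified_folds(y, spec$inner_folds)
      .forward_wrapper(spec, X, y, pars, folds)
    }
  )
  if (length(sel) == 0) {
    # guard: a filter rejecting everything falls back to the best-scoring
    # single feature
    sc <- entropy_filters(X, y)
    sel <- sc$feature[which.max(sc$sym_uncert)]
  }
  sel
}
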