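#' Classifier specification with hyperparameter grid
#'
#' Defines one of the five supported algorithms together with its
#' hyperparameter grid axes, feature-selection method and inner
#' cross-validation depth. Default grids follow the package's standard
#' search ranges; each axis can be overridden.
#'
#' Axes by algorithm: `k` (neighbour count) for KNN; `adjust`
#' (kernel-bandwidth multiplier), `kernel` (use kernel densities instead
#' of Gaussians) and `fL` (Laplace-style prior smoothing count) for naive
#' Bayes; `sigma` (radial-kernel width) and `cost` for the radial SVM;
#' `cost` (margin-violation penalty) for the linear SVM; `mtry` (features
#' sampled per split) for the random forest.
#'
#' @param algorithm one of `"knn"`, `"nb"`, `"rf"`, `"svm_linear"`,
#'   `"svm_radial"`.
#' @param grid named list of axis value vectors; `NULL` for the default.
#' @param selection feature-selection method: `"all"`,
#'   `"recursive_elimination"`, `"gain_ratio"`, `"entropy_union"` or
#'   `"forward_wrapper"`; `NULL` for the algorithm default (KNN uses all
#'   features; NB recursive elimination; radial SVM the gain-ratio filter;
#'   linear SVM and RF the union of the three entropy filters).
#' @param inner_folds folds of the inner stratified cross-validation
#'   (default 10).
#' @param ntree trees per random forest (ignored otherwise).
#' @param wrapper_tol minimum inner-CV AUC improvement for the forward
#'   wrapper to continue.
#' @param wrapper_max maximum features the forward wrapper may add.
#' @return object of class `model_spec`.
#' @examples
#' model_spec("rf", grid = list(mtry = c(2, 5, 8)))
#' @export
model_spec <- function(algorithm = c("knn", "nb", "rf", "svm_linear",
                                     "svm_radial"),
                       grid = NULL, selection = NULL, inner_folds = 10,
                       ntree = 300, wrapper_tol = 0.01, wrapper_max = 15) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    knn = list(grid = list(k = seq(1, 105, by = 2)), selection = "all"),
    nb = list(grid = list(adjust = c(0.5, 1, 1.5), kernel = c(FALSE, TRUE),
                          fL = c(0, 1)),
              selection = "recursive_elimination"),
    svm_radial = list(grid = list(sigma = 2^c(-9, -8, -7, -6, -5, -3),
                                  cost = c(0.4, 0.6, 0.8, 1, 2, 4, 8)),
                      selection = "gain_ratio"),
    svm_linear = list(grid = list(cost = c(0.001, 0.01, 0.2, 0.4, 0.6,
                                           0.8, 1, 2, 4)),
                      selection = "entropy_union"),
    rf = list(grid = list(mtry = 1:15), selection = "entropy_union")
  )
  if (is.null(grid)) grid <- defaults$grid
  if (is.null(selection)) selection <- defaults$selection
  selection <- match.arg(selection,
                         c("all", "recursive_elimination", "gain_ratio",
                           "entropy_union", "forward_wrapper"))
  allowed_axes <- switch(algorithm,
    knn = "k", nb = c("adjust", "kernel", "fL"),
    svm_radial = c("sigma", "cost"), svm_linear = "cost", rf = "mtry")
  if (!setequal(names(grid), allowed_axes)) {
    stop("grid axes for ", algorithm, " must be: ",
         paste(allowed_axes, collapse = ", "))
  }
  grid <- lapply(grid, sort)
  structure(
    list(algorithm = algorithm, grid = grid, selection = selection,
         inner_folds = inner_folds, ntree = ntree,
         wrapper_tol = wrapper_tol, wrapper_max = wrapper_max,
         expansions = stats::setNames(rep(0L, length(grid)), names(grid))),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec:", x$algorithm, "| selection:", x$selection,
      "| grid:", paste(vapply(names(x$grid), function(a)
        paste0(a, "[", length(x$grid[[a]]), "]"), character(1)),
        collapse = " x "), "\n")
  invisible(x)
}

# --- naive Bayes for continuous features (Gaussian or kernel density) ----

.nb_fit <- function(X, y, adjust = 1, kernel = FALSE, fL = 0) {
  stopifnot(adjust > 0, fL >= 0)
  classes <- levels(y)
  n <- length(y)
  prior <- (table(y) + fL) / (n + fL * length(classes))
  cond <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    lapply(seq_len(ncol(X)), function(j) {
      x <- Xi[, j]
      if (!kernel) {
        list(type = "gauss", mean = mean(x), sd = max(stats::sd(x), 1e-6))
      } else {
        bw <- tryCatch(stats::bw.nrd0(x), error = function(e) 1e-3)
        list(type = "kde", d = stats::density(x, adjust = adjust,
                                              bw = max(bw, 1e-6),
                                              n = 256, cut = 3))
      }
    })
  })
  names(cond) <- classes
  structure(list(prior = prior, cond = cond, classes = classes,
                 p = ncol(X)), class = "ecshock_nb")
}

.nb_scores <- function(fit, X) {
  logpost <- vapply(fit$classes, function(cl) {
    lp <- rep(log(as.numeric(fit$prior[[cl]])), nrow(X))
    for (j in seq_len(fit$p)) {
      cj <- fit$cond[[cl]][[j]]
      dens <- if (cj$type == "gauss") {
        stats::dnorm(X[, j], cj$mean, cj$sd)
      } else {
        stats::approx(cj$d$x, cj$d$y, xout = X[, j], rule = 2)$y
      }
      lp <- lp + log(pmax(dens, 1e-12))
    }
    lp
  }, numeric(nrow(X)))
  if (nrow(X) == 1) logpost <- matrix(logpost, nrow = 1,
                                      dimnames = list(NULL, fit$classes))
  m <- apply(logpost, 1, max)
  post <- exp(logpost - m)
  post <- post / rowSums(post)
  post[, "pos"]
}

# --- unified fit / score interface ---------------------------------------

# y: factor with levels c("neg", "pos"). Returns an object for
# .model_scores(); scores are P(positive) or a monotone surrogate.
.model_fit <- function(spec, X, y, pars) {
  switch(spec$algorithm,
    knn = list(kind = "knn", X = X, y = y,
               k = min(pars$k, nrow(X) - 1L)),
    nb = c(.nb_fit(X, y, adjust = pars$adjust, kernel = pars$kernel,
                   fL = pars$fL), kind = "nb"),
    rf = list(kind = "rf",
              fit = randomForest::randomForest(
                x = X, y = y, ntree = spec$ntree,
                mtry = max(1L, min(pars$mtry, ncol(X))))),
    svm_linear = list(kind = "svm",
                      fit = e1071::svm(x = X, y = y, kernel = "linear",
                                       cost = pars$cost, scale = FALSE,
                                       probability = TRUE)),
    svm_radial = list(kind = "svm",
                      fit = e1071::svm(x = X, y = y, kernel = "radial",
                                       cost = pars$cost, gamma = pars$sigma,
                                       scale = FALSE, probability = TRUE))
  )
}

.model_scores <- function(fit, X) {
  switch(fit$kind,
    knn = {
      pr <- class::knn(train = fit$X, test = X, cl = fit$y,
                       k = fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "pos", p, 1 - p)
    },
    nb = .nb_scores(fit, X),
    rf = stats::predict(fit$fit, X, type = "prob")[, "pos"],
    svm = {
      pr <- stats::predict(fit$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "pos"]
    }
  )
}

# Stratified fold assignment: every fold gets both classes whenever class
# counts allow. Returns an integer fold id per observation.
.stratified_folds <- function(y, k) {
  k <- max(2L, min(k, sum(y == "pos"), sum(y == "neg")))
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Inner-CV AUC of one hyperparameter setting on (X, y).
.inner_cv_auc <- function(spec, X, y, pars, folds) {
  aucs <- rep(NA_real_, max(folds))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
    fit <- .model_fit(spec, X[tr, , drop = FALSE], y[tr], pars)
    sc <- .model_scores(fit, X[!tr, , drop = FALSE])
    aucs[f] <- .rank_auc(sc, as.integer(y[!tr] == "pos"))
  }
  mean(aucs, na.rm = TRUE)
}
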