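# Class balancing, data splitting, and the grid-searched classifiers.
#
# kcr_fit() is the modelling core: it grid-searches a classifier by
# stratified k-fold cross-validation on the (balanced) training matrix,
# refits the best point on the full training matrix, and returns a
# classed object with predict / print / summary methods.  All
# randomness is controlled by explicit seeds and scoped so the caller's
# RNG state is untouched.

#' Randomly undersample the majority class to a 1:1 ratio
#'
#' Every minority-class sample is retained; the majority class is
#' sampled without replacement down to the minority size.  Applied to
#' the training split only -- the test split stays imbalanced for
#' validation.
#'
#' @param fm A `kcr_features` object with both classes present.
#' @param seed Integer seed making the draw reproducible.
#' @return A `kcr_features` with an exact 1:1 class ratio, original row
#'   order preserved.
#' @export
undersample_balance <- function(fm, seed = 1L) {
  stopifnot(inherits(fm, "kcr_features"))
  npos <- sum(fm$label == "positive")
  nneg <- sum(fm$label == "negative")
  if (npos == 0L || nneg == 0L) stop("both classes must be present")
  if (npos == nneg) return(fm)
  minority <- if (npos < nneg) "positive" else "negative"
  keep_min <- which(fm$label == minority)
  maj <- which(fm$label != minority)
  keep_maj <- with_seed(seed, sample(maj, length(keep_min)))
  fm[sort(c(keep_min, keep_maj)), ]
}

#' Stratified train/test split
#'
#' Splits samples into disjoint, exhaustive train and test sets,
#' stratified by class so each split's class proportion is within one
#' sample of the input's.  The test side is left imbalanced.
#'
#' @param fm A `kcr_features` object.
#' @param fraction Training fraction in `(0, 1)` (default 0.8).
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (`kcr_features`).
#' @export
train_test_split <- function(fm, fraction = 0.8, seed = 1L) {
  stopifnot(inherits(fm, "kcr_features"), fraction > 0, fraction < 1)
  idx_tr <- integer(0)
  for (cl in levels(fm$label)) {
    rows <- which(fm$label == cl)
    if (length(rows) < 2L)
      stop("class '", cl, "' has fewer than 2 samples")
    ntr <- round(fraction * length(rows))
    ntr <- min(max(ntr, 1L), length(rows) - 1L)  # both splits non-empty
    idx_tr <- c(idx_tr, with_seed(seed + match(cl, levels(fm$label)),
                                  sample(rows, ntr)))
  }
  idx_tr <- sort(idx_tr)
  list(train = fm[idx_tr, ],
       test = fm[setdiff(seq_along(fm$label), idx_tr), ])
}

#' k-fold cross-validation indices
#'
#' Randomly partitions `1:n_samples` into `k` validation folds whose
#' sizes differ by at most one; each index appears in exactly one fold.
#'
#' @param n_samples Number of samples.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of `k` integer vectors.
#' @export
kfold_indices <- function(n_samples, k = 5L, seed = 1L) {
  stopifnot(k >= 2L)
  if (k > n_samples) stop("k = ", k, " exceeds n_samples = ", n_samples)
  idx <- with_seed(seed, sample.int(n_samples))
  unname(split(idx, rep(seq_len(k), length.out = n_samples)))
}

default_grid <- function(classifier) {
  switch(classifier,
    svm = {
      g <- expand.grid(gamma = 2^(-10:0), C = 2^(0:10),
                       KEEP.OUT.ATTRS = FALSE)
      g[, c("C", "gamma")]          # C ascending (outer), gamma ascending
    },
    rf = data.frame(num_trees = seq(1400L, 2400L, by = 200L)),
    lr = data.frame(lr = 0.1))
}

# --- per-classifier fit/score backends -------------------------------

fit_backend <- function(classifier, x, y, point, seed) {
  switch(classifier,
    svm = e1071::svm(x, y, type = "C-classification", kernel = "radial",
                     cost = point$C, gamma = point$gamma,
                     scale = FALSE, probability = FALSE),
    rf = ranger::ranger(x = x, y = y, num.trees = point$num_trees,
                        probability = TRUE, seed = seed,
                        num.threads = 1L),
    lr = sgd_logistic(x, y, lr0 = point$lr, seed = seed))
}

score_backend <- function(classifier, model, x) {
  switch(classifier,
    svm = {
      pr <- predict(model, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # orient the decision value toward the positive class
      sgn <- if (grepl("^positive", colnames(dv)[1L])) 1 else -1
      stats::plogis(sgn * dv[, 1L])
    },
    rf = predict(model, data = x, num.threads = 1L)$predictions[, "positive"],
    lr = stats::plogis(cbind(1, x) %*% model$w)[, 1L])
}

# Logistic regression trained by minibatch stochastic gradient descent
# on the cross-entropy loss.  Stops when the epoch-mean loss changes by
# less than `tol` or after `max_epochs`.
sgd_logistic <- function(x, y, lr0 = 0.1, batch = 32L, tol = 1e-4,
                         max_epochs = 1000L, seed = 1L) {
  yy <- as.numeric(y == "positive")
  xb <- cbind(1, x)
  w <- numeric(ncol(xb))
  n <- nrow(xb)
  prev <- Inf
  with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      eta <- lr0 / (1 + 0.01 * (epoch - 1))
      for (start in seq(1L, n, by = batch)) {
        rows <- ord[start:min(start + batch - 1L, n)]
        xi <- xb[rows, , drop = FALSE]
        p <- stats::plogis(xi %*% w)[, 1L]
        w <- w - eta * crossprod(xi, p - yy[rows])[, 1L] / length(rows)
      }
      p <- stats::plogis(xb %*% w)[, 1L]
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      loss <- -mean(yy * log(p) + (1 - yy) * log(1 - p))
      if (abs(prev - loss) < tol) break
      prev <- loss
    }
  })
  list(w = w, loss = prev)
}

#' Fit a grid-searched Kcr classifier
#'
#' Evaluates every hyperparameter grid point by stratified k-fold
#' cross-validation on the training matrix, picks the point with the
#' best mean validation objective (AUC by default; ties broken toward
#' the first point in iteration order -- `C` ascending then `gamma`
#' ascending for the SVM, tree count ascending for the random forest),
#' and refits it on the full training matrix.
#'
#' The default grids follow the reference protocol: SVM with an RBF
#' kernel, `C` in `2^(0:10)` and `gamma` in `2^(-10:0)`; random forest
#' with tree counts `{1400, 1600, ..., 2400}`; logistic regression
#' trained by minibatch SGD on the cross-entropy loss with no grid.
#' Features are z-standardized (fit on the training matrix) for the SVM
#' and logistic regression, not for the random forest.
#'
#' @param fm Training `kcr_features`, normally balanced beforehand with
#'   [undersample_balance()].
#' @param classifier One of `"svm"`, `"rf"`, `"lr"`.
#' @param grid Optional `data.frame` of grid points overriding the
#'   default (columns `C`/`gamma`, `num_trees`, or `lr`).
#' @param k Cross-validation folds (default 5).
#' @param seed Integer seed controlling fold assignment and classifier
#'   initialization.
#' @param objective `"auc"` (default) or `"accuracy"` at `cutoff`.
#' @param cutoff Decision cutoff in `(0, 1)` (default 0.5); scores at or
#'   above it are called positive.
#' @return A `kcr_fit` object with elements `classifier`, `grid`, `cv`
#'   (mean validation objective per point), `best` (chosen point),
#'   `model`, `center`/`scale` (standardization, if used), `columns`,
#'   `cutoff` and `seed`.
#' @seealso [predict.kcr_fit()], [kcr_evaluate()]
#' @export
kcr_fit <- function(fm, classifier = c("svm", "rf", "lr"), grid = NULL,
                    k = 5L, seed = 1L, objective = c("auc", "accuracy"),
                    cutoff = 0.5) {
  stopifnot(inherits(fm, "kcr_features"), cutoff > 0, cutoff < 1)
  classifier <- match.arg(classifier)
  objective <- match.arg(objective)
  if (is.null(grid)) grid <- default_grid(classifier)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  if (nlevels(droplevels(fm$label)) < 2L) stop("both classes must be present")

  x <- fm$x
  center <- scl <- NULL
  if (classifier %in% c("svm", "lr")) {
    center <- colMeans(x)
    scl <- apply(x, 2L, sd)
    scl[scl == 0] <- 1
    x <- scale(x, center = center, scale = scl)
  }
  y <- droplevels(fm$label)
  y <- factor(as.character(y), levels = c("negative", "positive"))

  folds <- kfold_indices(nrow(x), k = k, seed = seed)
  cv <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    point <- grid[g, , drop = FALSE]
    perf <- numeric(length(folds))
    for (f in seq_along(folds)) {
      val <- folds[[f]]
      ytr <- y[-val]; yval <- y[val]
      if (nlevels(droplevels(ytr)) < 2L || nlevels(droplevels(yval)) < 2L)
        stop("single-class fold encountered; use more data or smaller k")
      m <- fit_backend(classifier, x[-val, , drop = FALSE], ytr, point,
                       seed = seed + f)
      s <- score_backend(classifier, m, x[val, , drop = FALSE])
      perf[f] <- if (objective == "auc") roc_auc(s, yval)$auc
                 else mean((s >= cutoff) == (yval == "positive"))
    }
    cv[g] <- mean(perf)
  }
  best <- which.max(cv)                         # first point wins ties
  model <- fit_backend(classifier, x, y, grid[best, , drop = FALSE],
                       seed = seed)
  structure(list(classifier = classifier, grid = grid, cv = cv,
                 best = grid[best, , drop = FALSE], best_index = best,
                 model = model, center = center, scale = scl,
                 columns = colnames(fm$x), cutoff = cutoff, seed = seed,
                 k = k, objective = objective,
                 n_train = nrow(x),
                 class_counts = table(y)),
            class = "kcr_fit")
}

#' Predict scores or labels from a fitted Kcr classifier
#'
#' @param object A `kcr_fit`.
#' @param newdata A `kcr_features` or numeric matrix whose columns match
#'   the training columns (order-insensitive; mismatches are an error
#'   listing the missing/extra names).
#' @param type `"score"` for probabilities in `[0, 1]`, `"label"` for
#'   hard calls (`score >= cutoff` is positive).
#' @param ... Unused.
#' @return Numeric score vector, or factor of labels.
#' @export
predict.kcr_fit <- function(object, newdata, type = c("score", "label"),
                            ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "kcr_features")) newdata$x else as.matrix(newdata)
  missing_ <- setdiff(object$columns, colnames(x))
  extra <- setdiff(colnames(x), object$columns)
  if (length(missing_) || length(extra))
    stop("feature columns do not match training columns",
         if (length(missing_)) paste0("; missing: ",
           paste(head(missing_, 5L), collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
           paste(head(extra, 5L), collapse = ", ")))
  x <- x[, object$columns, drop = FALSE]
  if (!is.null(object$center))
    x <- scale(x, center = object$center, scale = object$scale)
  s <- as.numeric(score_backend(object$classifier, object$model, x))
  if (type == "score") s
  else factor(ifelse(s >= object$cutoff, "positive", "negative"),
              levels = c("negative", "positive"))
}

#' @export
print.kcr_fit <- function(x, ...) {
  cat("<kcr_fit> ", x$classifier, " trained on ", x$n_train,
      " samples x ", length(x$columns), " dimensions\n", sep = "")
  cat("  best point: ",
      paste(names(x$best), unlist(x$best), sep = "=", collapse = ", "),
      "  (mean CV ", x$objective, " = ",
      formatC(x$cv[x$best_index], digits = 4, format = "f"), ")\n",
      sep = "")
  invisible(x)
}

#' @export
summary.kcr_fit <- function(object, ...) {
  print(object)
  tab <- cbind(object$grid, cv = object$cv)
  tab <- tab[order(-tab$cv), , drop = FALSE]
  cat("  grid (top 5 by CV ", object$objective, "):\n", sep = "")
  print(utils::head(tab, 5L), row.names = FALSE)
  invisible(object)
}
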