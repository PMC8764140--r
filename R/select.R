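# Feature selection: chi-square filtering and information-gain ranking.
# Both are fitted on the training split only; applying a stored result
# to new data is a pure column subset (no recomputation, no leakage).

#' Chi-square feature selection
#'
#' For each dimension the observed quantities are the class-wise sums of
#' the (nonnegative) feature values; the expected quantities are the
#' class priors times the total sum.  The statistic
#' `chi2 = sum((observed - expected)^2 / expected)` is referred to a
#' chi-square distribution with one degree of freedom fewer than the
#' number of classes (here 1), and dimensions with `p > alpha` are
#' dropped.
#'
#' @param fm A `kcr_features` object with nonnegative values and both
#'   classes present.
#' @param alpha Retention significance level (default 0.05): kept
#'   `<=>` `p <= alpha`.  No multiple-testing correction is applied.
#' @return A `kcr_selection`: list with `method`, `names`, `score`
#'   (chi-square values), `p_value`, `kept` (logical mask) and `params`.
#' @export
chi_square_select <- function(fm, alpha = 0.05) {
  stopifnot(inherits(fm, "kcr_features"))
  if (any(fm$x < 0)) stop("chi-square selection needs nonnegative features")
  if (nlevels(droplevels(fm$label)) < 2L) stop("both classes must be present")
  obs <- rowsum(fm$x, fm$label)                 # 2 x p class-wise sums
  prior <- as.vector(table(fm$label)) / length(fm$label)
  tot <- colSums(obs)
  expd <- outer(prior, tot)
  dev <- (obs - expd)^2 / expd
  dev[expd == 0] <- 0                           # dimension identically 0
  chi2 <- colSums(dev)
  p <- pchisq(chi2, df = 1L, lower.tail = FALSE)
  structure(list(method = "chi2", names = colnames(fm$x),
                 score = unname(chi2), p_value = unname(p),
                 kept = unname(p <= alpha),
                 params = list(alpha = alpha)),
            class = "kcr_selection")
}

#' Information-gain feature selection
#'
#' Each dimension is discretized into equal-frequency bins (quantile
#' breaks fitted on the data given); the gain is
#' `H(class) - H(class | binned feature)` in bits.  Dimensions are
#' ranked by descending gain; by default those with gain `> 0` are kept,
#' or the top `top_k` when given.
#'
#' @param fm A `kcr_features` object with both classes present.
#' @param bins Number of equal-frequency bins (default 2: split at the
#'   median).
#' @param top_k Optional: keep the `top_k` highest-gain dimensions
#'   instead of the gain `> 0` rule.
#' @return A `kcr_selection` with `score` = information gain in bits
#'   (`p_value` is `NA`).
#' @export
information_gain_select <- function(fm, bins = 2L, top_k = NULL) {
  stopifnot(inherits(fm, "kcr_features"), bins >= 2L)
  if (nlevels(droplevels(fm$label)) < 2L) stop("both classes must be present")
  y <- fm$label
  n <- length(y)
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  hy <- ent(table(y))
  gain <- apply(fm$x, 2L, function(v) {
    br <- unique(quantile(v, probs = seq(0, 1, length.out = bins + 1L),
                          names = FALSE))
    if (length(br) < 2L) return(0)              # constant feature
    b <- cut(v, breaks = br, include.lowest = TRUE)
    tab <- table(b, y)
    hcond <- sum(vapply(seq_len(nrow(tab)), function(r) {
      (sum(tab[r, ]) / n) * ent(tab[r, ])
    }, numeric(1L)))
    hy - hcond
  })
  gain <- pmax(gain, 0)                         # guard tiny negatives
  kept <- if (is.null(top_k)) gain > 0
          else rank(-gain, ties.method = "first") <= top_k
  structure(list(method = "ig", names = colnames(fm$x),
                 score = unname(gain), p_value = rep(NA_real_, ncol(fm$x)),
                 kept = unname(kept),
                 params = list(bins = bins, top_k = top_k)),
            class = "kcr_selection")
}

#' Apply a stored selection to a feature matrix
#'
#' Subsets columns by the stored mask; scores are never recomputed, so a
#' selection fitted on the training split can be applied to the test
#' split without information leakage.
#'
#' @param fm A `kcr_features` object whose columns match the selection.
#' @param sel A `kcr_selection`.
#' @return `fm` restricted to the kept dimensions.
#' @export
apply_selection <- function(fm, sel) {
  stopifnot(inherits(fm, "kcr_features"), inherits(sel, "kcr_selection"))
  if (!identical(colnames(fm$x), sel$names))
    stop("feature columns do not match the selection")
  if (!any(sel$kept)) stop("selection keeps no dimension")
  fm[, sel$kept]
}

#' @export
print.kcr_selection <- function(x, ...) {
  cat("<kcr_selection> method=", x$method, ": ", sum(x$kept), " of ",
      length(x$kept), " dimensions kept\n", sep = "")
  invisible(x)
}
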