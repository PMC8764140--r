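# Confusion-matrix metrics, ROC curve and AUC.
#
# The metric panel follows the standard Kcr-prediction conventions:
#   Sn  = TP / (TP + FN)                  (= Recall)
#   Sp  = TN / (TN + FP)
#   Acc = (TP + TN) / (TP + FP + TN + FN)
#   MCC = (TP*TN - FN*FP) /
#         sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))
#   Precision = 1 - FP / (TP + FP)        (identically TP / (TP + FP))
#   F1 = 1 - (FP + FN) / (2*TP + FP + FN) (identically 2TP/(2TP+FP+FN))
# Any metric whose denominator is zero is reported as 0 and flagged.

#' Confusion counts at a decision cutoff
#'
#' A sample is called positive when its score is greater than or equal
#' to the cutoff (boundary inclusive).
#'
#' @param scores Numeric score vector.
#' @param labels True labels (any standard positive/negative encoding).
#' @param cutoff Decision cutoff (default 0.5).
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff = 0.5) {
  if (length(scores) == 0L) stop("empty input")
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  pos <- as_positive(labels)
  call_pos <- scores >= cutoff
  c(TP = sum(call_pos & pos), FP = sum(call_pos & !pos),
    TN = sum(!call_pos & !pos), FN = sum(!call_pos & pos))
}

#' Compute the seven-metric panel from confusion counts
#'
#' @param counts Named vector or list with `TP`, `FP`, `TN`, `FN`.
#' @return List with `Sn`, `Sp`, `Acc`, `MCC`, `Recall`, `Precision`,
#'   `F1`, the `counts`, and `zero_denominator` naming any metric whose
#'   denominator was zero (reported as 0).
#' @examples
#' compute_metrics(c(TP = 50, FP = 10, TN = 90, FN = 50))
#' @export
compute_metrics <- function(counts) {
  TP <- as.numeric(counts[["TP"]]); FP <- as.numeric(counts[["FP"]])
  TN <- as.numeric(counts[["TN"]]); FN <- as.numeric(counts[["FN"]])
  if (any(c(TP, FP, TN, FN) < 0) || TP + FP + TN + FN < 1)
    stop("invalid confusion counts")
  flagged <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { flagged <<- c(flagged, name); 0 } else num / den
  }
  mcc_den <- sqrt((TP + FN) * (TN + FP)) * sqrt((TP + FP) * (TN + FN))
  out <- list(
    Sn = safe(TP, TP + FN, "Sn"),
    Sp = safe(TN, TN + FP, "Sp"),
    Acc = (TP + TN) / (TP + FP + TN + FN),
    MCC = safe(TP * TN - FN * FP, mcc_den, "MCC"),
    Recall = safe(TP, TP + FN, "Recall"),
    Precision = if (TP + FP == 0) { flagged <- c(flagged, "Precision"); 0 }
                else 1 - FP / (TP + FP),
    F1 = if (2 * TP + FP + FN == 0) { flagged <- c(flagged, "F1"); 0 }
         else 1 - (FP + FN) / (2 * TP + FP + FN)
  )
  out$counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  out$zero_denominator <- unique(flagged)
  out
}

#' ROC curve and AUC
#'
#' The ROC is traced by sweeping the unique scores as thresholds in
#' descending order.  The AUC is computed from the rank statistic (ties
#' contribute half), so it equals the Mann-Whitney probability that a
#' random positive outscores a random negative, and coincides with the
#' trapezoid area under the tied ROC.
#'
#' @param scores Numeric score vector.
#' @param labels True labels; both classes must be present.
#' @return List with `roc` (`data.frame` of `fpr`, `tpr` including the
#'   (0,0) and (1,1) endpoints) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0L || nneg == 0L) stop("both classes must be present")
  r <- rank(scores)                              # ties averaged
  auc <- (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  s <- scores[ord]
  keep <- c(s[-length(s)] != s[-1L], TRUE)  # last point of each tie run
  roc <- data.frame(fpr = c(0, fp[keep] / nneg),
                    tpr = c(0, tp[keep] / npos))
  list(roc = roc, auc = auc)
}

#' Full evaluation report for a scored test set
#'
#' Combines [confusion_at_cutoff()], [compute_metrics()] and
#' [roc_auc()] into one report object with print and plot methods.
#'
#' @param scores Numeric score vector.
#' @param labels True labels.
#' @param cutoff Decision cutoff (default 0.5).
#' @return A `kcr_eval`: list with the seven metrics, `AUC`, `counts`,
#'   `roc`, `cutoff` and `zero_denominator`.
#' @export
kcr_evaluate <- function(scores, labels, cutoff = 0.5) {
  counts <- confusion_at_cutoff(scores, labels, cutoff)
  m <- compute_metrics(counts)
  ra <- roc_auc(scores, labels)
  structure(c(m[c("Sn", "Sp", "Acc", "MCC", "Recall", "Precision", "F1")],
              list(AUC = ra$auc, counts = m$counts, roc = ra$roc,
                   cutoff = cutoff, zero_denominator = m$zero_denominator)),
            class = "kcr_eval")
}

#' @export
print.kcr_eval <- function(x, digits = 4L, ...) {
  cat("<kcr_eval>  cutoff =", x$cutoff, "\n")
  cat("  counts: TP=", x$counts[["TP"]], " FP=", x$counts[["FP"]],
      " TN=", x$counts[["TN"]], " FN=", x$counts[["FN"]], "\n", sep = "")
  for (nm in c("Sn", "Sp", "Acc", "MCC", "Recall", "Precision", "F1",
               "AUC")) {
    cat(sprintf("  %-9s %.*f\n", nm, digits, x[[nm]]))
  }
  if (length(x$zero_denominator))
    cat("  (zero denominator, reported as 0: ",
        paste(x$zero_denominator, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Plot the ROC curve of an evaluation report
#'
#' @param x A `kcr_eval`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.kcr_eval <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l",
                 xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$AUC), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param x A `kcr_eval`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
eval_report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "kcr_eval"))
  obj <- list(metrics = x[c("Sn", "Sp", "Acc", "MCC", "Recall",
                            "Precision", "F1", "AUC")],
              counts = as.list(x$counts), cutoff = x$cutoff,
              zero_denominator = x$zero_denominator)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
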