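#' One-vs-rest confusion counts
#'
#' For each CMS class, samples are split into true/false positives/negatives
#' by treating that class as positive and the other three as negative.
#'
#' @param true_labels,predicted_labels Character vectors of equal length with
#'   values in `cms_levels()`.
#' @return A `ConfusionCounts` data frame with columns `class`, `TP`, `TN`,
#'   `FP`, `FN` (one row per class, `TP + TN + FP + FN = n` in each).
#' @export
confusion_counts <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  lv <- cms_levels()
  tr <- factor(as.character(true_labels), levels = lv)
  pr <- factor(as.character(predicted_labels), levels = lv)
  if (anyNA(tr) || anyNA(pr))
    stop("unknown label(s): ",
         paste(unique(c(as.character(true_labels)[is.na(tr)],
                        as.character(predicted_labels)[is.na(pr)])),
               collapse = ", "))
  n <- length(tr)
  cm <- table(tr, pr)                          # true x predicted
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  structure(
    data.frame(class = lv, TP = as.integer(tp), TN = as.integer(n - tp -
                 fn - fp), FP = as.integer(fp), FN = as.integer(fn),
               stringsAsFactors = FALSE),
    class = c("ConfusionCounts", "data.frame")
  )
}

ratio_pct <- function(num, den) ifelse(den > 0, num / den * 100, NA_real_)

#' Per-class and macro-averaged classification metrics
#'
#' Per class (one-vs-rest, all in percent): sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)` and per-class accuracy
#' `(TP+TN)/n`. Macro values are the arithmetic means over classes; a
#' per-class ratio with zero denominator (e.g. precision of a class never
#' predicted) is undefined, excluded from the macro mean and counted in
#' `n_undefined` — scoring it 0 would silently reward degenerate predictors.
#' Overall accuracy is the fraction of correctly classified samples.
#'
#' @param cc A `ConfusionCounts` data frame.
#' @return A `MetricsReport` list: `per_class` data frame, `macro` named
#'   vector (`sensitivity`, `specificity`, `precision`, `class_accuracy`),
#'   `overall_accuracy`, and `n_undefined` per macro metric.
#' @export
classification_metrics <- function(cc) {
  stopifnot(inherits(cc, "ConfusionCounts"))
  n <- cc$TP[1] + cc$TN[1] + cc$FP[1] + cc$FN[1]
  per_class <- data.frame(
    class = cc$class,
    sensitivity = ratio_pct(cc$TP, cc$TP + cc$FN),
    specificity = ratio_pct(cc$TN, cc$TN + cc$FP),
    precision = ratio_pct(cc$TP, cc$TP + cc$FP),
    class_accuracy = (cc$TP + cc$TN) / n * 100,
    stringsAsFactors = FALSE
  )
  macro_of <- function(x) mean(x, na.rm = TRUE)
  metrics <- c("sensitivity", "specificity", "precision", "class_accuracy")
  macro <- vapply(metrics, function(m) macro_of(per_class[[m]]), numeric(1))
  n_undefined <- vapply(metrics, function(m) sum(is.na(per_class[[m]])),
                        integer(1))
  structure(
    list(per_class = per_class, macro = macro,
         overall_accuracy = sum(cc$TP) / n * 100,
         n_undefined = n_undefined),
    class = "MetricsReport"
  )
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat("MetricsReport (percent)\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat("macro:",
      paste(names(x$macro), sprintf("%.2f", x$macro), sep = "=",
            collapse = " "), "\n")
  cat(sprintf("overall accuracy: %.2f\n", x$overall_accuracy))
  if (any(x$n_undefined > 0))
    cat("undefined per-class values excluded from macro means:",
        paste(names(x$n_undefined)[x$n_undefined > 0],
              x$n_undefined[x$n_undefined > 0], sep = "=",
              collapse = " "), "\n")
  invisible(x)
}
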