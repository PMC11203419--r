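# Confusion matrices, the four standard metric formulas, weighted averages,
# normalised confusion views and per-patient LSC recall.

#' Confusion matrix between true and predicted labels
#'
#' Counts are exact; per-class positive views (TP/TN/FP/FN with class c as
#' positive) are derivable via [metric_report()].
#'
#' @param truth,predicted Equal-length label vectors over `labels`.
#' @param labels Class labels (order fixes the matrix layout).
#' @return An `ifc_confusion`: integer matrix, rows = true, cols =
#'   predicted.
#' @export
confusion <- function(truth, predicted, labels = c("HSC", "LSC")) {
  if (length(truth) != length(predicted))
    stop("label vectors differ in length", call. = FALSE)
  bad <- setdiff(unique(c(truth, predicted)), labels)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cm <- table(factor(truth, levels = labels),
              factor(predicted, levels = labels))
  cm <- matrix(as.integer(cm), length(labels), length(labels),
               dimnames = list(true = labels, predicted = labels))
  structure(cm, class = "ifc_confusion")
}

#' @export
print.ifc_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted)\n")
  print(unclass(x))
  invisible(x)
}

.class_counts <- function(cm, cl) {
  labels <- rownames(cm)
  tp <- cm[cl, cl]
  fn <- sum(cm[cl, ]) - tp
  fp <- sum(cm[, cl]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Per-class and weighted performance metrics
#'
#' Applies the four standard formulas per class, with class c as positive:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), recall = TP/(TP+FN), precision =
#' TP/(TP+FP), F1 = 2*precision*recall/(precision+recall). All reported as
#' percentages; a zero denominator yields `NaN` (undefined), never a
#' silent 0. Weighted averages are support-weighted
#' (sum support*metric / sum support).
#'
#' @param cm An `ifc_confusion`.
#' @param supports Optional named per-class supports; defaults to the
#'   true-label row sums.
#' @return An `ifc_metrics`: list with `per_class` (data.frame),
#'   `accuracy`, `weighted` (named vector) and `supports`.
#' @export
metric_report <- function(cm, supports = NULL) {
  labels <- rownames(cm)
  if (is.null(supports)) supports <- rowSums(cm)
  per <- lapply(labels, function(cl) {
    k <- .class_counts(cm, cl)
    prec <- if (k[["TP"]] + k[["FP"]] == 0) NaN else
      100 * k[["TP"]] / (k[["TP"]] + k[["FP"]])
    rec <- if (k[["TP"]] + k[["FN"]] == 0) NaN else
      100 * k[["TP"]] / (k[["TP"]] + k[["FN"]])
    f1 <- if (!is.finite(prec) || !is.finite(rec) || prec + rec == 0) NaN
    else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, support = supports[[cl]], precision = prec,
               recall = rec, f1 = f1, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  acc <- 100 * sum(diag(unclass(cm))) / sum(cm)
  w <- supports[per$class] / sum(supports)
  weighted <- c(precision = sum(w * per$precision),
                recall = sum(w * per$recall),
                f1 = sum(w * per$f1))
  structure(list(per_class = per, accuracy = acc, weighted = weighted,
                 supports = supports),
            class = "ifc_metrics")
}

#' @export
print.ifc_metrics <- function(x, digits = 2, ...) {
  cat("Performance metrics (%)\n")
  pc <- x$per_class
  pc[, c("precision", "recall", "f1")] <-
    round(pc[, c("precision", "recall", "f1")], digits)
  print(pc, row.names = FALSE)
  cat(sprintf("  accuracy: %.*f | weighted precision %.*f, recall %.*f, F1 %.*f\n",
              digits, x$accuracy, digits, x$weighted[["precision"]],
              digits, x$weighted[["recall"]], digits, x$weighted[["f1"]]))
  invisible(x)
}

#' Row- or column-normalised confusion matrix
#'
#' Row normalisation puts each class's recall on the diagonal; column
#' normalisation its precision. Empty rows/columns yield `NaN` entries.
#'
#' @param cm An `ifc_confusion`.
#' @param axis `"row"` or `"column"`.
#' @return Numeric matrix of fractions.
#' @export
normalize_confusion <- function(cm, axis = c("row", "column")) {
  axis <- match.arg(axis)
  m <- unclass(cm)
  if (axis == "row") {
    sw <- rowSums(m)
    out <- sweep(m, 1, sw, "/")
    out[sw == 0, ] <- NaN
  } else {
    sw <- colSums(m)
    out <- sweep(m, 2, sw, "/")
    out[, sw == 0] <- NaN
  }
  out
}

#' Per-patient and pooled LSC recall on a holdout set
#'
#' The holdout is all-LSC by construction, so the fraction predicted LSC
#' is the LSC recall. The pooled value is count-weighted
#' (total correct / total n), not the mean of the percentages.
#'
#' @param predicted Predicted labels (`"HSC"`/`"LSC"`).
#' @param patient_ids Patient id per prediction.
#' @return A list with `per_patient` (data.frame `patient`, `n`,
#'   `recall_pct`) and `pooled_pct`.
#' @export
patient_recall <- function(predicted, patient_ids) {
  keep <- !is.na(patient_ids)
  if (any(!keep))
    warning("dropping predictions without a patient id", call. = FALSE)
  predicted <- predicted[keep]
  patient_ids <- patient_ids[keep]
  tab <- split(predicted == "LSC", patient_ids)
  tab <- tab[vapply(tab, length, 1L) > 0]
  per <- data.frame(
    patient = names(tab),
    n = vapply(tab, length, 1L),
    recall_pct = vapply(tab, function(v) 100 * mean(v), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(per) <- NULL
  pooled <- 100 * sum(predicted == "LSC") / length(predicted)
  list(per_patient = per, pooled_pct = pooled)
}
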