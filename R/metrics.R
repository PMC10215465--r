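#' Precision, recall and F1 from counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and F1 their
#' harmonic mean. Any quantity with a zero denominator is reported as 0
#' (matching the convention of reporting F1 = 0 for classes with no
#' correct predictions).
#'
#' @param tp,fp,fn Nonnegative counts.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
prf1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Aggregate per-class metrics
#'
#' `macro` is the unweighted mean over classes; `weighted` the
#' support-weighted mean; `micro` pools the TP/FP/FN counts and recomputes
#' the metrics (for single-label classification over the full class set,
#' micro precision, recall and F1 all equal accuracy).
#'
#' @param rows Data frame with columns `precision`, `recall`, `f1`,
#'   `support` and, for `mode = "micro"`, `tp`, `fp`, `fn`.
#' @param mode `"macro"`, `"micro"` or `"weighted"`.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
aggregate_metrics <- function(rows, mode = c("macro", "micro", "weighted")) {
  mode <- match.arg(mode)
  if (nrow(rows) == 0L) stop("cannot aggregate an empty set of per-class rows")
  switch(mode,
    macro = c(
      precision = mean(rows$precision), recall = mean(rows$recall), f1 = mean(rows$f1)
    ),
    weighted = {
      w <- rows$support / sum(rows$support)
      c(precision = sum(w * rows$precision), recall = sum(w * rows$recall),
        f1 = sum(w * rows$f1))
    },
    micro = {
      if (!all(c("tp", "fp", "fn") %in% names(rows))) {
        stop("micro aggregation needs per-class tp/fp/fn counts")
      }
      prf1(sum(rows$tp), sum(rows$fp), sum(rows$fn))
    }
  )
}

#' Confusion matrix over a label scheme
#'
#' @param gold,predicted Equal-length character vectors of labels from the
#'   scheme.
#' @param scheme A [label_scheme()] fixing row/column order.
#' @return Integer matrix `counts[gold, predicted]`; its trace is the
#'   number of correct predictions.
#' @export
confusion_matrix <- function(gold, predicted, scheme) {
  stopifnot(length(gold) == length(predicted))
  bad <- setdiff(c(gold, predicted), scheme$labels)
  if (length(bad)) stop("label(s) outside scheme '", scheme$name, "': ",
                        paste(bad, collapse = ", "))
  g <- factor(gold, levels = scheme$labels)
  p <- factor(predicted, levels = scheme$labels)
  unclass(table(gold = g, predicted = p))
}

#' Full evaluation report
#'
#' Per-class precision/recall/F1/support, accuracy, macro/micro/weighted
#' aggregates and the confusion matrix. When the scheme has a negative
#' label and `exclude_negative_accuracy` is set, an additional accuracy is
#' computed on the subset where the gold label is positive (the DDI
#' `-false` evaluation mode).
#'
#' @param gold,predicted Equal-length character vectors of labels.
#' @param scheme A [label_scheme()].
#' @param exclude_negative_accuracy Also report accuracy over instances
#'   whose gold label is not the scheme's negative label.
#' @return An `evaluation_report` list with elements `per_class` (data
#'   frame), `accuracy`, `macro`, `micro`, `weighted`, `confusion`, and
#'   optionally `accuracy_excluding_negative`.
#' @export
evaluate <- function(gold, predicted, scheme, exclude_negative_accuracy = FALSE) {
  cm <- confusion_matrix(gold, predicted, scheme)
  labs <- scheme$labels
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  per_class <- do.call(rbind, lapply(seq_along(labs), function(i) {
    m <- prf1(tp[i], fp[i], fn[i])
    data.frame(
      label = labs[i], precision = m["precision"], recall = m["recall"],
      f1 = m["f1"], support = unname(rowSums(cm)[i]),
      tp = unname(tp[i]), fp = unname(fp[i]), fn = unname(fn[i]),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }))
  acc <- sum(tp) / length(gold)
  rep <- list(
    per_class = per_class,
    accuracy = acc,
    macro = aggregate_metrics(per_class, "macro"),
    micro = aggregate_metrics(per_class, "micro"),
    weighted = aggregate_metrics(per_class, "weighted"),
    confusion = cm,
    n = length(gold)
  )
  if (exclude_negative_accuracy) {
    if (is.na(scheme$negative_label)) {
      stop("scheme '", scheme$name, "' has no negative label to exclude")
    }
    keep <- gold != scheme$negative_label
    rep$accuracy_excluding_negative <-
      if (any(keep)) mean(gold[keep] == predicted[keep]) else NA_real_
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  pc <- x$per_class
  pc$precision <- round(pc$precision, digits)
  pc$recall <- round(pc$recall, digits)
  pc$f1 <- round(pc$f1, digits)
  print(pc[, c("label", "precision", "recall", "f1", "support")], row.names = FALSE)
  cat(sprintf("accuracy     %.*f  (n = %d)\n", digits, x$accuracy, x$n))
  for (m in c("macro", "micro", "weighted")) {
    v <- x[[m]]
    cat(sprintf("%-8s avg. P %.*f  R %.*f  F1 %.*f\n", m,
                digits, v["precision"], digits, v["recall"], digits, v["f1"]))
  }
  if (!is.null(x$accuracy_excluding_negative)) {
    cat(sprintf("accuracy (-%s) %.*f\n",
                "false", digits, x$accuracy_excluding_negative))
  }
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' Emits the per-class table in (Precision, Recall, F1-Score, Support)
#' column order followed by accuracy and the three aggregate rows, plus the
#' confusion matrix to a companion `*.confusion.tsv` file.
#'
#' @param report An [evaluate()] report.
#' @param path Output TSV path.
#' @param digits Rounding for the report (full precision is retained in the
#'   report object itself).
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path, digits = 4) {
  pc <- report$per_class
  lines <- c(
    "Relation Type\tPrecision\tRecall\tF1-Score\tSupport",
    vapply(seq_len(nrow(pc)), function(i) {
      sprintf("%s\t%.*f\t%.*f\t%.*f\t%d", pc$label[i],
              digits, pc$precision[i], digits, pc$recall[i],
              digits, pc$f1[i], pc$support[i])
    }, character(1)),
    sprintf("Accuracy\t\t\t%.*f\t%d", digits, report$accuracy, report$n),
    vapply(c("macro", "micro", "weighted"), function(m) {
      v <- report[[m]]
      sprintf("%s avg.\t%.*f\t%.*f\t%.*f\t%d", tools::toTitleCase(m),
              digits, v["precision"], digits, v["recall"], digits, v["f1"], report$n)
    }, character(1))
  )
  writeLines(lines, path)
  cm_path <- sub("\\.tsv$", ".confusion.tsv", path)
  utils::write.table(report$confusion, cm_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
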