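#' Cross-tabulate true vs predicted classes
#'
#' @param results data.frame with `true_class` and `predicted_class` (e.g.
#'   from [classify_seeds()]); every row must carry a true class.
#' @param classes class labels defining the table axes (default 1:5).
#' @return integer matrix, entry `(t, p)` = number of seeds of true class `t`
#'   predicted as class `p`.
#' @export
confusion_counts <- function(results, classes = 1:5) {
  stopifnot(all(c("true_class", "predicted_class") %in% names(results)))
  if (any(is.na(results$true_class))) stop("every result must carry a true class")
  counts <- table(factor(results$true_class, levels = classes),
                  factor(results$predicted_class, levels = classes))
  matrix(as.integer(counts), length(classes), length(classes),
         dimnames = list(true = classes, predicted = classes))
}

#' Overall classification accuracy (percent)
#'
#' `100 * correct / n_total` — seeds correctly classified by the model over
#' the total number of evaluated seeds.
#'
#' @param counts square confusion matrix.
#' @param n_total total seed count (default `sum(counts)`).
#' @return percent.
#' @export
classification_accuracy <- function(counts, n_total = sum(counts)) {
  if (n_total <= 0) stop("n_total must be positive")
  100 * sum(diag(counts)) / n_total
}

#' Per-class classification accuracy (percent)
#'
#' Diagonal over true-class row total, i.e. the overall-accuracy formula
#' restricted to each true class. Classes with no seeds give `NA`.
#'
#' @param counts square confusion matrix.
#' @return named numeric vector, one entry per class.
#' @export
per_class_accuracy <- function(counts) {
  rs <- rowSums(counts)
  out <- ifelse(rs > 0, 100 * diag(counts) / rs, NA_real_)
  stats::setNames(out, rownames(counts))
}

#' False-negative percentage of one class
#'
#' Seeds that belong to class `class` but were not assigned to it, as a
#' percentage of all evaluated seeds:
#' `100 * (row_sum(class) - counts[class, class]) / n_total`.
#'
#' @param counts square confusion matrix.
#' @param class class label (matched against the row names).
#' @param n_total total evaluated seeds (default `sum(counts)`).
#' @return percent.
#' @export
false_negative_pct <- function(counts, class, n_total = sum(counts)) {
  if (n_total <= 0) stop("n_total must be positive")
  i <- match(as.character(class), rownames(counts))
  if (is.na(i)) stop("unknown class: ", class)
  100 * (sum(counts[i, ]) - counts[i, i]) / n_total
}

#' False-positive percentage of one class
#'
#' Seeds the model assigned to class `class` that do not belong to it, as a
#' percentage of all evaluated seeds:
#' `100 * (col_sum(class) - counts[class, class]) / n_total`.
#'
#' @inheritParams false_negative_pct
#' @return percent.
#' @export
false_positive_pct <- function(counts, class, n_total = sum(counts)) {
  if (n_total <= 0) stop("n_total must be positive")
  i <- match(as.character(class), colnames(counts))
  if (is.na(i)) stop("unknown class: ", class)
  100 * (sum(counts[, i]) - counts[i, i]) / n_total
}

#' Per-variety overall accuracy
#'
#' @param results data.frame with `variety_id`, `true_class`,
#'   `predicted_class`.
#' @return named numeric vector, percent correct per variety.
#' @export
per_variety_accuracy <- function(results) {
  stopifnot("variety_id" %in% names(results))
  vs <- sort(unique(results$variety_id))
  out <- vapply(vs, function(v) {
    r <- results[results$variety_id == v, ]
    100 * sum(r$true_class == r$predicted_class) / nrow(r)
  }, 0)
  stats::setNames(out, vs)
}

#' Build the full evaluation report
#'
#' Misclassification table plus per-class accuracy, false-negative and
#' false-positive percentages, overall accuracy, and per-variety accuracy.
#' Percentages are carried at full precision; the print method rounds to one
#' decimal.
#'
#' @param results data.frame with `true_class`, `predicted_class` and
#'   optionally `variety_id`.
#' @param classes class labels (default 1:5).
#' @return an `evaluation_report`: `counts`, `n_total`, `overall_accuracy`,
#'   `per_class` (data.frame class/accuracy/fn_pct/fp_pct/fn_count/fp_count),
#'   `per_variety_accuracy`.
#' @export
evaluation_report <- function(results, classes = 1:5) {
  counts <- confusion_counts(results, classes)
  n <- sum(counts)
  per_class <- data.frame(
    damage_class = classes,
    accuracy = unname(per_class_accuracy(counts)),
    fn_pct = vapply(classes, function(k) false_negative_pct(counts, k, n), 0),
    fp_pct = vapply(classes, function(k) false_positive_pct(counts, k, n), 0),
    fn_count = as.integer(rowSums(counts) - diag(counts)),
    fp_count = as.integer(colSums(counts) - diag(counts)))
  pv <- if ("variety_id" %in% names(results) &&
            !all(is.na(results$variety_id))) {
    per_variety_accuracy(results)
  } else NULL
  structure(list(counts = counts, n_total = n,
                 overall_accuracy = classification_accuracy(counts, n),
                 per_class = per_class, per_variety_accuracy = pv),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Misclassification table (rows: true class; columns: predicted class)\n")
  tab <- cbind(x$counts,
               `accuracy%` = round(x$per_class$accuracy, 1),
               `FN%` = round(x$per_class$fn_pct, 1),
               `FP%` = round(x$per_class$fp_pct, 1))
  print(tab)
  cat(sprintf("n = %d seeds, overall accuracy = %.1f%%\n",
              x$n_total, x$overall_accuracy))
  if (!is.null(x$per_variety_accuracy)) {
    cat("per-variety accuracy (%):",
        paste(names(x$per_variety_accuracy),
              round(x$per_variety_accuracy, 1), sep = ":", collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Write an evaluation report as delimited text
#' @param report an `evaluation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("n_total\t%d", report$n_total), con)
  writeLines(sprintf("overall_accuracy\t%s",
                     format(report$overall_accuracy, digits = 17)), con)
  writeLines("counts:", con)
  utils::write.table(report$counts, con, sep = "\t", quote = FALSE)
  writeLines("per_class:", con)
  utils::write.table(report$per_class, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(report$per_variety_accuracy)) {
    writeLines("per_variety_accuracy:", con)
    utils::write.table(
      data.frame(variety_id = names(report$per_variety_accuracy),
                 accuracy = report$per_variety_accuracy),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
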