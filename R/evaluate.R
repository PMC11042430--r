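#' Confusion matrix for seizure-vs-background classification
#'
#' Seizure is the positive class: TP = seizure called seizure, FN = seizure
#' called background, TN = background called background, FP = background
#' called seizure.
#'
#' @param true_labels,predicted_labels equal-length vectors with values in
#'   `{background, seizure}`.
#' @return A `confusion_matrix` list with counts `TP`, `FN`, `TN`, `FP`.
#' @export
confusion <- function(true_labels, predicted_labels) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop_with("cfcdetect_validation", "label vectors differ in length")
  }
  ok <- c("background", "seizure")
  if (!all(true_labels %in% ok) || !all(predicted_labels %in% ok)) {
    stop_with("cfcdetect_validation",
              "labels must be 'background' or 'seizure'")
  }
  structure(list(
    TP = sum(true_labels == "seizure" & predicted_labels == "seizure"),
    FN = sum(true_labels == "seizure" & predicted_labels == "background"),
    TN = sum(true_labels == "background" & predicted_labels == "background"),
    FP = sum(true_labels == "background" & predicted_labels == "seizure")
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(predicted = c("seizure", "background"),
                              true = c("seizure", "background")))
  print(m)
  invisible(x)
}

#' Detection metrics from a confusion matrix
#'
#' Percentages: sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/total, positive predictive value per class, and the
#' false-positive *fraction* FP/total. Two quantities are reported for the
#' false-positive behaviour because their denominators differ: the
#' false-positive rate among background items is `100 - specificity`, while
#' `fp_fraction` uses all items. When the total analysed background duration
#' is supplied, FP is also converted to false alarms per hour. A zero
#' denominator yields `NA` (undefined), never 0.
#'
#' @param cm a [confusion()] result.
#' @param total_background_hours total hours of background data analysed, or
#'   `NULL` to omit the false-alarm rate.
#' @return A `metrics_report` list of named numbers (percent scale except
#'   `false_alarms_per_hour`).
#' @export
metrics <- function(cm, total_background_hours = NULL) {
  div <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  total <- cm$TP + cm$FN + cm$TN + cm$FP
  rep <- list(
    sensitivity = div(cm$TP, cm$TP + cm$FN),
    specificity = div(cm$TN, cm$TN + cm$FP),
    accuracy = div(cm$TP + cm$TN, total),
    ppv_seizure = div(cm$TP, cm$TP + cm$FP),
    ppv_background = div(cm$TN, cm$TN + cm$FN),
    fp_fraction = div(cm$FP, total)
  )
  if (!is.null(total_background_hours)) {
    rep$false_alarms_per_hour <-
      if (total_background_hours > 0) cm$FP / total_background_hours
      else NA_real_
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.list(v)) {
      cat(sprintf("%-22s %6.2f +/- %.2f\n", nm, v$mean, v$sd))
    } else {
      cat(sprintf("%-22s %6.2f\n", nm, v))
    }
  }
  invisible(x)
}

#' Aggregate metrics over repeated train/test splits
#'
#' Per metric, the mean and sample standard deviation over runs (undefined
#' entries are dropped per metric).
#'
#' @param reports a list of at least two [metrics()] reports.
#' @return A `metrics_report` whose entries are `list(mean =, sd =)`.
#' @export
aggregate_runs <- function(reports) {
  if (length(reports) < 2) {
    stop_with("cfcdetect_aggregation", "need >= 2 reports to aggregate")
  }
  nms <- names(reports[[1]])
  out <- lapply(nms, function(nm) {
    vals <- vapply(reports, function(r) {
      v <- r[[nm]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    list(mean = mean(vals), sd = stats::sd(vals))
  })
  names(out) <- nms
  structure(out, class = "metrics_report")
}

#' Write predictions and a metrics report to disk
#'
#' @param predictions data.frame with columns `segment_id`, `true_label`,
#'   `predicted_label`, `p_seizure`.
#' @param report a [metrics()] or [aggregate_runs()] result.
#' @param dir output directory.
#' @export
write_evaluation <- function(predictions, report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "metrics.txt"))
  invisible(dir)
}
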