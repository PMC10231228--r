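# Confusion-matrix construction and the standard binary metrics.

#' Confusion counts for binary predictions
#'
#' Counts follow the usual 2x2 convention with the disease class (`AD`) as
#' positive unless overridden: `tp` = predicted and true positive, `fp` =
#' predicted positive but true negative, `fn` = predicted negative but true
#' positive, `tn` = both negative.
#'
#' @param predictions,truths Equal-length label vectors.
#' @param positive_class Label treated as positive, default `"AD"`.
#' @return Object of class `confusion_matrix` with fields `tp`, `fp`, `fn`,
#'   `tn`, `positive_class`.
#' @export
confusion_counts <- function(predictions, truths, positive_class = "AD") {
  if (length(predictions) != length(truths)) {
    stop("input error: predictions and truths differ in length",
         call. = FALSE)
  }
  if (length(predictions) == 0L) {
    stop("input error: empty label sequences", call. = FALSE)
  }
  p <- predictions == positive_class
  t <- truths == positive_class
  structure(
    list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t),
         tn = sum(!p & !t), positive_class = positive_class),
    class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(paste("pred", c("pos", "neg")),
                              paste("true", c("pos", "neg"))))
  print(m)
  invisible(x)
}

#' Compute accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy = (TN+TP)/(TN+FP+FN+TP); Precision = TP/(TP+FP);
#' Recall = TP/(TP+FN); F1 = 2TP/(2TP+FP+FN). A metric whose denominator is
#' zero is reported as `NA` with the reason listed in the `undefined` field
#' rather than being coerced to 0, so degenerate folds cannot silently
#' inflate or deflate aggregate scores.
#'
#' @param cm A [confusion_counts()] result.
#' @return Object of class `metric_report` with fields `accuracy`,
#'   `precision`, `recall`, `f1`, `confusion`, `n`, `undefined`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n == 0L) stop("input error: all-zero confusion matrix", call. = FALSE)
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, sprintf("%s: denominator 0", name))
      return(NA_real_)
    }
    num / den
  }
  structure(
    list(accuracy = (cm$tn + cm$tp) / n,
         precision = ratio(cm$tp, cm$tp + cm$fp, "precision"),
         recall = ratio(cm$tp, cm$tp + cm$fn, "recall"),
         f1 = ratio(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn, "f1"),
         confusion = cm, n = n, undefined = undefined),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("<metric_report> n=%d  accuracy %.4f  precision %s  ",
                     "recall %s  F1 %s\n"),
              x$n, x$accuracy, format(x$precision, digits = 4),
              format(x$recall, digits = 4), format(x$f1, digits = 4)))
  if (length(x$undefined)) {
    cat("  undefined:", paste(x$undefined, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Aggregate per-fold metric reports
#'
#' The headline aggregate is the unweighted mean of per-fold metrics
#' (undefined fold metrics are dropped from their mean with a note); the
#' pooled-confusion aggregate (summed counts, then one metric computation)
#' is also emitted for transparency.
#'
#' @param reports List of [compute_metrics()] results.
#' @return List with `mean` (per-metric means plus `n_folds`) and `pooled`
#'   (a `metric_report` over summed counts).
#' @export
aggregate_metric_reports <- function(reports) {
  stopifnot(length(reports) > 0)
  pick <- function(f) vapply(reports, `[[`, 0, f)
  pooled_cm <- structure(
    list(tp = sum(vapply(reports, function(r) r$confusion$tp, 0)),
         fp = sum(vapply(reports, function(r) r$confusion$fp, 0)),
         fn = sum(vapply(reports, function(r) r$confusion$fn, 0)),
         tn = sum(vapply(reports, function(r) r$confusion$tn, 0)),
         positive_class = reports[[1]]$confusion$positive_class),
    class = "confusion_matrix")
  list(mean = list(accuracy = mean(pick("accuracy"), na.rm = TRUE),
                   precision = mean(pick("precision"), na.rm = TRUE),
                   recall = mean(pick("recall"), na.rm = TRUE),
                   f1 = mean(pick("f1"), na.rm = TRUE),
                   n_folds = length(reports)),
       pooled = compute_metrics(pooled_cm))
}

#' Write a metric report (or CV aggregate) as JSON and a text table
#'
#' @param x A `metric_report`, or the result of [cross_validate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `metrics.json`, `metrics.txt` and
#'   `confusion.csv`.
#' @export
write_metrics <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  as_plain <- function(r) {
    list(accuracy = r$accuracy, precision = r$precision, recall = r$recall,
         f1 = r$f1, n = r$n,
         confusion = r$confusion[c("tp", "fp", "fn", "tn")],
         undefined = r$undefined)
  }
  payload <- if (inherits(x, "han_cv")) {
    list(folds = lapply(x$folds, function(f) as_plain(f$metrics)),
         mean = x$aggregate$mean, pooled = as_plain(x$aggregate$pooled))
  } else {
    as_plain(x)
  }
  jsonlite::write_json(payload, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cm <- if (inherits(x, "han_cv")) x$aggregate$pooled$confusion else
    x$confusion
  utils::write.csv(
    data.frame(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn),
    file.path(dir, "confusion.csv"), row.names = FALSE)
  rep <- if (inherits(x, "han_cv")) x$aggregate$pooled else x
  writeLines(utils::capture.output(print(rep)),
             file.path(dir, "metrics.txt"))
  invisible(dir)
}
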