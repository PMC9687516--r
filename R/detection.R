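#' Specify a detection threshold rule
#'
#' Threshold-based detection of severe disease (EOTRH 3, the positive class)
#' against normal teeth (EOTRH 0). The threshold is the mean, mean + SD or
#' mean + 2 SD (sample SD) of a reference population of measure values; by
#' default the pooled grade-0 and grade-3 values. For a measure that
#' increases with disease severity the positive call is made strictly above
#' the threshold (ties go to the negative class); `direction =
#' "positive_below"` flips the rule for decreasing measures.
#'
#' @param kind One of `"mean"`, `"mean_plus_sd"`, `"mean_plus_2sd"`.
#' @param reference Reference population for the threshold statistics:
#'   `"pooled_0_and_3"` (default), `"grade0_only"`, or `"all_grades"`.
#' @param direction `"positive_above"` (default) or `"positive_below"`.
#' @return A `threshold_rule` object.
#' @export
threshold_rule <- function(kind = c("mean", "mean_plus_sd", "mean_plus_2sd"),
                           reference = c("pooled_0_and_3", "grade0_only",
                                         "all_grades"),
                           direction = c("positive_above",
                                         "positive_below")) {
  structure(list(kind = match.arg(kind), reference = match.arg(reference),
                 direction = match.arg(direction)),
            class = "threshold_rule")
}

#' Compute a threshold value from reference measurements
#'
#' @param values Numeric vector of reference measure values.
#' @param rule A [threshold_rule()] (only `kind` is used here).
#' @return The threshold: mean plus 0, 1 or 2 sample standard deviations.
#' @export
compute_threshold <- function(values, rule = threshold_rule()) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("empty reference population for threshold")
  k <- switch(rule$kind, mean = 0, mean_plus_sd = 1, mean_plus_2sd = 2)
  s <- if (length(values) > 1) sd(values) else 0
  mean(values) + k * s
}

#' Classify positives and negatives against a threshold
#'
#' @param values_pos Measure values of the positive class (EOTRH 3).
#' @param values_neg Measure values of the negative class (EOTRH 0).
#' @param threshold Numeric threshold.
#' @param direction `"positive_above"`: a value strictly above the threshold
#'   is called positive, ties and below are negative; `"positive_below"`
#'   mirrors this.
#' @return Named integer vector `c(TP, FP, FN, TN)`.
#' @export
classify_by_threshold <- function(values_pos, values_neg, threshold,
                                  direction = "positive_above") {
  stopifnot(length(values_pos) > 0, length(values_neg) > 0)
  called_pos <- function(v) {
    if (direction == "positive_above") v > threshold else v < threshold
  }
  tp <- sum(called_pos(values_pos))
  fp <- sum(called_pos(values_neg))
  c(TP = tp, FP = fp,
    FN = length(values_pos) - tp, TN = length(values_neg) - fp)
}

#' Diagnostic accuracy metrics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive
#' value `TP/(TP+FP)` and negative predictive value `TN/(TN+FN)`. Ratios with
#' a zero denominator are undefined and reported as `NA` (rendered `"-"` in
#' formatted tables). Full precision is kept in `value`; `value_2dp` is the
#' conventional half-up 2-decimal reporting form.
#'
#' @param cm Named vector or list with `TP`, `FP`, `FN`, `TN`.
#' @return Tibble with columns `metric`, `value`, `value_2dp`.
#' @export
accuracy_metrics <- function(cm) {
  cm <- as.list(cm)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  v <- c(Se = ratio(cm$TP, cm$TP + cm$FN),
         Sp = ratio(cm$TN, cm$TN + cm$FP),
         PPV = ratio(cm$TP, cm$TP + cm$FP),
         NPV = ratio(cm$TN, cm$TN + cm$FN))
  tibble::tibble(metric = names(v), value = unname(v),
                 value_2dp = round_half_up(unname(v), 2))
}

#' Threshold detection report for one measure
#'
#' Computes, for each threshold kind, the threshold from the configured
#' reference population, the confusion matrix of grade-3 (positive) versus
#' grade-0 (negative) calls, and the four accuracy metrics.
#'
#' @param features Feature tibble with columns `grade`, `filter`, `measure`,
#'   `value` (long format, as produced by [extract_features()]).
#' @param measure,filter Which measure/filter combination to evaluate.
#' @param rules List of [threshold_rule()]s; default all three kinds.
#' @param reference,direction Override the rules' reference population and
#'   call direction in one place.
#' @return Tibble with one row per rule and metric: `rule`, `threshold`,
#'   `TP`, `FP`, `FN`, `TN`, `metric`, `value`, `value_2dp`.
#' @export
detect_grades <- function(features, measure, filter,
                          rules = lapply(c("mean", "mean_plus_sd",
                                           "mean_plus_2sd"), threshold_rule),
                          reference = "pooled_0_and_3",
                          direction = "positive_above") {
  sub <- features[features$measure == measure &
                    features$filter == filter &
                    is.finite(features$value), ]
  pos <- sub$value[sub$grade == 3]
  neg <- sub$value[sub$grade == 0]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("detection needs measurements for both grade 0 and grade 3")
  }
  all_vals <- sub$value
  purrr::map_dfr(rules, function(rule) {
    rule$reference <- reference
    rule$direction <- direction
    ref <- switch(rule$reference,
                  pooled_0_and_3 = c(pos, neg),
                  grade0_only = neg,
                  all_grades = all_vals)
    thr <- compute_threshold(ref, rule)
    cm <- classify_by_threshold(pos, neg, thr, rule$direction)
    met <- accuracy_metrics(cm)
    tibble::tibble(rule = rule$kind, threshold = thr,
                   TP = cm[["TP"]], FP = cm[["FP"]],
                   FN = cm[["FN"]], TN = cm[["TN"]],
                   metric = met$metric, value = met$value,
                   value_2dp = met$value_2dp)
  })
}

#' Format a detection report as a printed accuracy table
#'
#' Reshapes a [detect_grades()] result into the conventional wide layout
#' (rows Se/Sp/PPV/NPV per threshold kind), with undefined values rendered
#' as `"-"`.
#'
#' @param report Tibble from [detect_grades()] (possibly for several
#'   measures, bound with a `measure` column).
#' @return Tibble with columns `rule`, `metric`, and one column per measure
#'   (or a single `value` column when no `measure` column is present).
#' @export
format_detection_table <- function(report) {
  fmt <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", x))
  if ("measure" %in% names(report)) {
    report |>
      dplyr::mutate(shown = fmt(.data$value_2dp)) |>
      dplyr::select("rule", "metric", "measure", "shown") |>
      tidyr::pivot_wider(names_from = "measure", values_from = "shown")
  } else {
    report |>
      dplyr::mutate(shown = fmt(.data$value_2dp)) |>
      dplyr::select("rule", "metric", "shown")
  }
}
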