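#' Decision-rule cutoffs
#'
#' The default thresholds parameterizing the PET/CT, elastography, and
#' combined decision rules: SUVmax 7.02, TLG 12.53, mean hue 132.73,
#' grading score 3 (equivalent to a 3.5 threshold on an integer scale).
#' All rules use strict `>` comparisons, so boundary values are negative
#' calls.
#'
#' @param suvmax_cut,tlg_cut,hue_cut Numeric cutoffs.
#' @param grade_cut Integer in 1-4.
#' @return Object of class `rule_cutoffs`.
#' @export
rule_cutoffs <- function(suvmax_cut = 7.02, tlg_cut = 12.53,
                         hue_cut = 132.73, grade_cut = 3L) {
  vals <- c(suvmax_cut, tlg_cut, hue_cut, grade_cut)
  if (!all(is.finite(vals))) stop("all cutoffs must be finite")
  if (grade_cut != round(grade_cut) || grade_cut < 1 || grade_cut > 4)
    stop("grade_cut must be an integer in 1-4")
  structure(list(suvmax_cut = suvmax_cut, tlg_cut = tlg_cut,
                 hue_cut = hue_cut, grade_cut = as.integer(grade_cut)),
            class = "rule_cutoffs")
}

check_feature <- function(x, name) {
  if (is.null(x) || anyNA(x))
    stop("missing feature value(s) for '", name, "'")
  x
}

#' PET/CT decision rule
#'
#' Positive iff SUVmax > cutoff OR TLG > cutoff (strict inequalities).
#'
#' @param suv_max,tlg Numeric feature vectors.
#' @param cutoffs A [rule_cutoffs()].
#' @return Logical vector; `TRUE` = PET/CT positive.
#' @export
petct_rule <- function(suv_max, tlg, cutoffs = rule_cutoffs()) {
  check_feature(suv_max, "suv_max"); check_feature(tlg, "tlg")
  suv_max > cutoffs$suvmax_cut | tlg > cutoffs$tlg_cut
}

#' Elastography decision rule
#'
#' Positive iff mean hue > cutoff OR grading score > cutoff (strict).
#'
#' @param mean_hue,grade Numeric feature vectors.
#' @param cutoffs A [rule_cutoffs()].
#' @return Logical vector; `TRUE` = elastography positive.
#' @export
elasto_rule <- function(mean_hue, grade, cutoffs = rule_cutoffs()) {
  check_feature(mean_hue, "mean_hue"); check_feature(grade, "grade")
  mean_hue > cutoffs$hue_cut | grade > cutoffs$grade_cut
}

#' Combined (AND-fusion) decision rule
#'
#' The combined method is positive only when both PET/CT and
#' elastography are positive; either component negative makes the
#' combined call negative.
#'
#' @param petct_call,elasto_call Logical vectors.
#' @return Logical vector.
#' @export
combined_rule <- function(petct_call, elasto_call) {
  stopifnot(length(petct_call) == length(elasto_call))
  petct_call & elasto_call
}

#' Apply all three decision rules to a feature table
#'
#' @param features `data.frame` with columns `suv_max`, `tlg`,
#'   `mean_hue`, `grade` (and optionally `node_id`).
#' @param cutoffs A [rule_cutoffs()].
#' @return `data.frame` with `petct_call`, `elasto_call`,
#'   `combined_call` (and `node_id` when present).
#' @export
classify_nodes <- function(features, cutoffs = rule_cutoffs()) {
  p <- petct_rule(features$suv_max, features$tlg, cutoffs)
  e <- elasto_rule(features$mean_hue, features$grade, cutoffs)
  out <- data.frame(petct_call = p, elasto_call = e,
                    combined_call = combined_rule(p, e))
  if (!is.null(features$node_id))
    out <- cbind(node_id = features$node_id, out,
                 stringsAsFactors = FALSE)
  out
}

#' Confusion matrix (malignant = positive class)
#'
#' @param calls Logical predictions (`TRUE` = called malignant).
#' @param truth Truth labels (`"malignant"`/`"benign"`, logical or 0/1).
#' @return Object of class `confusion_matrix`: list with `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(calls, truth) {
  y <- as_binary_labels(truth)
  stopifnot(length(calls) == length(y))
  calls <- as.logical(calls)
  if (anyNA(calls) || anyNA(y)) stop("calls and truth must be complete")
  structure(list(tp = sum(calls & y), fp = sum(calls & !y),
                 fn = sum(!calls & y), tn = sum(!calls & !y)),
            class = "confusion_matrix")
}

#' Build a confusion matrix from counts
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion: TP %d  FP %d  FN %d  TN %d  (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Diagnostic-performance metrics
#'
#' The seven standard metrics, as percentages: sensitivity
#' 100 TP/(TP+FN), specificity 100 TN/(TN+FP), positive and negative
#' predictive values, accuracy, and the false-positive / false-negative
#' rates (complements of specificity / sensitivity). Both classes must be
#' present; an undefined predictive value (empty call margin) is reported
#' as `NA` with a message.
#'
#' @param cm A `confusion_matrix`.
#' @return Object of class `diagnostic_report`: list of percentages
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`, `fpr`,
#'   `fnr`, plus the confusion counts.
#' @export
diagnostic_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  pos <- cm$tp + cm$fn; neg <- cm$tn + cm$fp
  if (pos == 0 || neg == 0)
    stop("both classes must be present to compute diagnostic metrics")
  total <- pos + neg
  ppv <- if (cm$tp + cm$fp == 0) {
    message("diagnostic_metrics: no positive calls; PPV undefined")
    NA_real_
  } else 100 * cm$tp / (cm$tp + cm$fp)
  npv <- if (cm$tn + cm$fn == 0) {
    message("diagnostic_metrics: no negative calls; NPV undefined")
    NA_real_
  } else 100 * cm$tn / (cm$tn + cm$fn)
  sens <- 100 * cm$tp / pos
  spec <- 100 * cm$tn / neg
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv,
                 npv = npv, accuracy = 100 * (cm$tp + cm$tn) / total,
                 fpr = 100 - spec, fnr = 100 - sens, confusion = cm),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(format_metrics_line(x), "\n")
  invisible(x)
}

metric_names <- c("sensitivity", "specificity", "ppv", "npv",
                  "accuracy", "fpr", "fnr")

format_metrics_line <- function(report) {
  paste(vapply(metric_names, function(m)
    if (is.na(report[[m]])) "   NA " else sprintf("%6.2f%%", report[[m]]),
    character(1)), collapse = "  ")
}

#' Evaluate the three diagnostic methods on a cohort
#'
#' Applies the PET/CT, elastography and combined rules and computes a
#' confusion matrix and the seven performance metrics for each.
#'
#' @param features Feature table with `suv_max`, `tlg`, `mean_hue`,
#'   `grade` and a truth column.
#' @param cutoffs A [rule_cutoffs()].
#' @param truth_col Name of the truth column (default `"true_class"`).
#' @return Object of class `ln_evaluation`: named list with elements
#'   `petct`, `elastography`, `combined`, each a `diagnostic_report`.
#' @export
evaluate_cohort <- function(features, cutoffs = rule_cutoffs(),
                            truth_col = "true_class") {
  truth <- features[[truth_col]]
  if (is.null(truth)) stop("truth column '", truth_col, "' not found")
  calls <- classify_nodes(features, cutoffs)
  structure(list(
    petct = diagnostic_metrics(confusion(calls$petct_call, truth)),
    elastography = diagnostic_metrics(confusion(calls$elasto_call, truth)),
    combined = diagnostic_metrics(confusion(calls$combined_call, truth))
  ), class = "ln_evaluation")
}

#' @export
print.ln_evaluation <- function(x, ...) {
  hdr <- paste(vapply(c("Sens", "Spec", "PPV", "NPV", "Acc", "FPR", "FNR"),
                      function(s) sprintf("%7s", s), character(1)),
               collapse = " ")
  cat(sprintf("%-22s%s\n", "Method", hdr))
  for (m in names(x))
    cat(sprintf("%-22s%s\n", m, format_metrics_line(x[[m]])))
  invisible(x)
}
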