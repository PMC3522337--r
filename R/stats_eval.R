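#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value, used to assess whether the class means of a
#' feature differ.  (The fractional degrees of freedom printed by this test
#' are the signature of the Welch form.)
#'
#' @param group_a,group_b numeric vectors, each with >= 2 values; at least
#'   one group must have nonzero variance.
#' @return an object of class `welch_ttest`: list with `t_value`,
#'   `degrees_of_freedom`, `p_value`.
#' @export
welch_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    abort("each group needs at least 2 values", "airtrapcad_input_error")
  if (var(group_a) == 0 && var(group_b) == 0)
    abort("both groups have zero variance", "airtrapcad_degenerate_error")
  res <- t.test(group_a, group_b, var.equal = FALSE)
  structure(list(t_value = unname(res$statistic),
                 degrees_of_freedom = unname(res$parameter),
                 p_value = res$p.value),
            class = "welch_ttest")
}

#' @export
print.welch_ttest <- function(x, ...) {
  cat(sprintf("Welch t-test: t = %.4f, df = %.4f, p = %.3e\n",
              x$t_value, x$degrees_of_freedom, x$p_value))
  invisible(x)
}

#' Confusion matrix
#'
#' Counts with the patient class as positive.
#'
#' @param tp,fp,fn,tn non-negative integer counts (total >= 1).
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    abort("counts must be non-negative integers", "airtrapcad_input_error")
  if (sum(counts) < 1)
    abort("confusion matrix must contain at least one subject",
          "airtrapcad_input_error")
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("patient", "normal"),
                              truth = c("patient", "normal")))
  print(m)
  invisible(x)
}

#' Diagnostic accuracy metrics
#'
#' Sensitivity, specificity, positive and negative predictive value, and
#' accuracy, each as a fraction and as a percentage rounded (half away from
#' zero) to one decimal.  A metric with zero denominator is reported as `NA`
#' (undefined), never as 0.
#'
#' @param cm a [confusion_matrix()].
#' @return a data frame with columns `metric`, `fraction`, `percent`.
#' @export
confusion_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix"))
    abort("cm must be a confusion_matrix", "airtrapcad_input_error")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  frac <- c(sensitivity = safe(cm$tp, cm$tp + cm$fn),
            specificity = safe(cm$tn, cm$tn + cm$fp),
            ppv = safe(cm$tp, cm$tp + cm$fp),
            npv = safe(cm$tn, cm$tn + cm$fn),
            accuracy = safe(cm$tp + cm$tn, cm$tp + cm$fp + cm$fn + cm$tn))
  data.frame(metric = names(frac),
             fraction = unname(frac),
             percent = round_half_up(100 * unname(frac), 1),
             row.names = NULL)
}

#' Tabulate predictions against truth and score them
#'
#' @param predicted,truth equal-length label vectors with values `"normal"`
#'   / `"patient"` (patient = positive).
#' @return list with `confusion` (a [confusion_matrix()]) and `metrics`
#'   (a [confusion_metrics()] table).
#' @export
evaluate_predictions <- function(predicted, truth) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth) || length(truth) == 0L)
    abort("predicted and truth must be non-empty and of equal length",
          "airtrapcad_input_error")
  bad <- setdiff(unique(c(predicted, truth)), c("normal", "patient"))
  if (length(bad))
    abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")),
          "airtrapcad_input_error")
  cm <- confusion_matrix(tp = sum(predicted == "patient" & truth == "patient"),
                         fp = sum(predicted == "patient" & truth == "normal"),
                         fn = sum(predicted == "normal" & truth == "patient"),
                         tn = sum(predicted == "normal" & truth == "normal"))
  list(confusion = cm, metrics = confusion_metrics(cm))
}
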