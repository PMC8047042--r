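#' Confusion matrix for binary LL classification
#'
#' Positive class is the low-language outcome (label 1).
#'
#' @param truth,pred equal-length 0/1 vectors
#' @return object of class `ll_confusion`: named list TP, FP, TN, FN
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred differ in length")
  if (!all(truth %in% c(0, 1)) || !all(pred %in% c(0, 1))) {
    stop("labels must be 0/1")
  }
  structure(list(
    TP = sum(truth == 1 & pred == 1), FP = sum(truth == 0 & pred == 1),
    TN = sum(truth == 0 & pred == 0), FN = sum(truth == 1 & pred == 0)
  ), class = "ll_confusion")
}

#' @export
print.ll_confusion <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(pred = c("LL", "TD"), truth = c("LL", "TD")))
  print(m)
  invisible(x)
}

#' Clinical screening metric suite
#'
#' Sensitivity, specificity, balanced accuracy (their mean), positive and
#' negative predictive values, and positive/negative likelihood ratios:
#' LR+ = sens / (1 - spec), LR- = (1 - sens) / spec.
#'
#' Degenerate denominators follow clinical reading rather than returning 0:
#' spec = 1 gives LR+ = Inf, spec = 0 gives LR- = Inf, and PPV/NPV with an
#' empty margin are NA (never 0). Sensitivity (specificity) is NA when no
#' true positives (negatives) exist.
#'
#' @param cm an [confusion()] matrix, or sensitivity when `spec` is given
#' @param spec optional: call as `screening_metrics(sens, spec)` to compute
#'   the ratio metrics directly from printed sensitivity/specificity
#' @return list of class `screening_metrics`: sensitivity, specificity,
#'   balanced_accuracy, PPV, NPV, LR_plus, LR_minus (plus counts when built
#'   from a confusion matrix)
#' @examples
#' screening_metrics(0.99, 0.82)$LR_plus  # 5.5
#' @export
screening_metrics <- function(cm, spec = NULL) {
  if (!is.null(spec)) {
    sens <- cm
    cm <- NULL
  } else {
    stopifnot(inherits(cm, "ll_confusion"))
    sens <- ratio_or_na(cm$TP, cm$TP + cm$FN)
    spec <- ratio_or_na(cm$TN, cm$TN + cm$FP)
  }
  out <- list(
    sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2,
    PPV = if (is.null(cm)) NA_real_ else ratio_or_na(cm$TP, cm$TP + cm$FP),
    NPV = if (is.null(cm)) NA_real_ else ratio_or_na(cm$TN, cm$TN + cm$FN),
    LR_plus = if (isTRUE(spec == 1)) Inf else sens / (1 - spec),
    LR_minus = if (isTRUE(spec == 0)) Inf else (1 - sens) / spec
  )
  if (!is.null(cm)) out <- c(out, unclass(cm))
  class(out) <- "screening_metrics"
  out
}

ratio_or_na <- function(num, den) if (den == 0) NA_real_ else num / den

#' @export
print.screening_metrics <- function(x, ...) {
  v <- unlist(x[c("balanced_accuracy", "sensitivity", "specificity",
                  "PPV", "NPV", "LR_plus", "LR_minus")])
  print(round_half_up(v, 2))
  invisible(x)
}

#' One-sided t-test of balanced accuracies against a chance baseline
#'
#' Tests whether the mean per-run balanced accuracy exceeds the 0.5 achieved
#' by any single-class classifier (H1: mean > baseline). Constant inputs are
#' reported as degenerate rather than producing a silent p-value.
#'
#' @param balacc numeric vector of per-run balanced accuracies (length >= 2)
#' @param baseline chance level (default 0.5)
#' @return list: n, mean, t, df, p, degenerate
#' @export
balanced_accuracy_test <- function(balacc, baseline = 0.5) {
  if (length(balacc) < 2) stop("need >= 2 balanced accuracies for a t-test")
  if (stats::sd(balacc) == 0) {
    return(list(n = length(balacc), mean = mean(balacc), t = NA_real_,
                df = length(balacc) - 1, p = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(balacc, mu = baseline, alternative = "greater")
  list(n = length(balacc), mean = mean(balacc),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

# footnote convention: *** p < .0001, ** p < .001, * p < .01
significance_stars <- function(p) {
  if (is.na(p)) "" else if (p < 1e-4) "***" else if (p < 1e-3) "**"
  else if (p < 1e-2) "*" else ""
}

#' Performance report table
#'
#' One row per train/test pair in the layout of the study's performance
#' tables: balanced accuracy (with significance stars from the per-run
#' t-test against 0.5 where run-level accuracies are available), sensitivity,
#' specificity, PPV, NPV, LR+ and LR-. Display values are rounded half-up to
#' 2 decimals; the returned data.frame keeps full precision alongside.
#'
#' @param results named list; each element is either an `ll_fit` (internal
#'   validation) or a prediction data.frame with `label`/`pred` columns
#'   (e.g. from [external_validate()])
#' @param file optional CSV path to write the display table
#' @return data.frame with one row per result
#' @export
screening_report <- function(results, file = NULL) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    if (inherits(r, "ll_fit")) {
      pr <- r$predictions
      star <- significance_stars(balanced_accuracy_test(r$run_balacc)$p)
    } else {
      pr <- r
      star <- ""
    }
    m <- screening_metrics(confusion(pr$label, pr$pred))
    data.frame(
      model = nm, BalAcc = m$balanced_accuracy, stars = star,
      Sens = m$sensitivity, Spec = m$specificity, PPV = m$PPV, NPV = m$NPV,
      LR_plus = m$LR_plus, LR_minus = m$LR_minus, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    disp <- out
    for (v in c("BalAcc", "Sens", "Spec", "PPV", "NPV", "LR_plus",
                "LR_minus")) {
      disp[[v]] <- ifelse(is.infinite(out[[v]]), "Inf",
                          sprintf("%.2f", round_half_up(out[[v]], 2)))
    }
    utils::write.csv(disp, file, row.names = FALSE)
  }
  out
}

#' Bar plot of a feature-importance ranking
#'
#' @param imp an `importance_report` (or a named list of them, averaged by
#'   mean rank is not attempted — pass one report)
#' @param main plot title
#' @return invisibly, the report; skipped with a warning when empty
#' @export
plot_importance <- function(imp, main = "Drop-one feature importance") {
  if (is.null(imp) || nrow(imp) == 0) {
    warning("empty importance report; plot skipped")
    return(invisible(imp))
  }
  op <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(op))
  o <- order(imp$importance)
  graphics::barplot(imp$importance[o], names.arg = imp$feature[o],
                    horiz = TRUE, las = 1, main = main,
                    xlab = "accuracy change (percentage points)")
  invisible(imp)
}
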