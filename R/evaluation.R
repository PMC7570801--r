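# Agreement and classification statistics: Bland-Altman limits, paired
# t-test, R^2, mean absolute percentage error, confusion matrices.

#' Method-agreement statistics for paired measurements
#'
#' Compares an estimated series against a reference series (typically
#' water-displacement volumes).  Differences are
#' \eqn{d_i = est_i - ref_i}; the report carries their mean and SD
#' (n - 1 denominator), the Bland-Altman 95% limits of agreement
#' (mean +/- 1.96 SD), the mean absolute percentage error, the squared
#' Pearson correlation between the two series (the scatter-plot R^2), and
#' a two-tailed paired t-test with its 95% confidence interval
#' \eqn{m \pm t_{0.975, n-1} \cdot SD/\sqrt{n}}.
#'
#' @param estimated numeric vector (mL or g).
#' @param reference numeric vector, same length and units.
#' @return Object of class `"agreement_report"`: list with
#'   `mean_abs_pct_error`, `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `r_squared`, `t_stat`, `p_value`, `ci_low`, `ci_high`, `n`.
#' @export
agreement <- function(estimated, reference) {
  if (length(estimated) != length(reference)) stop("agreement(): length mismatch")
  n <- length(estimated)
  if (n < 2) stop("agreement(): need at least 2 pairs")
  if (anyNA(estimated) || anyNA(reference)) stop("agreement(): missing values")
  d <- estimated - reference
  m <- mean(d)
  s <- stats::sd(d)
  nz <- reference != 0
  if (!all(nz)) warning("agreement(): zero reference values excluded from MAPE")
  mape <- mean(100 * abs(d[nz]) / abs(reference[nz]))
  r2 <- if (stats::sd(estimated) == 0 || stats::sd(reference) == 0) {
    if (all(d == 0)) 1 else 0
  } else {
    stats::cor(estimated, reference)^2
  }
  if (s == 0) {
    tt <- list(statistic = c(t = if (m == 0) 0 else sign(m) * Inf),
               p.value = if (m == 0) 1 else 0, conf.int = c(m, m))
  } else {
    tt <- stats::t.test(estimated, reference, paired = TRUE)
  }
  structure(list(mean_abs_pct_error = mape,
                 mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 r_squared = r2,
                 t_stat = unname(tt$statistic), p_value = tt$p.value,
                 ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                 n = n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement over %d pairs\n", x$n))
  cat(sprintf("  mean |error|      : %.3f %%\n", x$mean_abs_pct_error))
  cat(sprintf("  mean difference   : %.4f (SD %.4f)\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  limits of agreement: [%.4f, %.4f]\n", x$loa_low, x$loa_high))
  cat(sprintf("  R^2               : %.4f\n", x$r_squared))
  cat(sprintf("  paired t          : t = %.4f, p = %.4g, 95%% CI [%.4f, %.4f]\n",
              x$t_stat, x$p_value, x$ci_low, x$ci_high))
  invisible(x)
}

#' Build a confusion matrix from predicted and true class labels
#'
#' @param predicted character vector of predicted labels.
#' @param truth character vector of true labels, same length.
#' @param labels class label order; defaults to the sorted union.
#' @return Square integer matrix (class `"table"`), rows = truth,
#'   columns = predicted.
#' @export
confusion_matrix <- function(predicted, truth, labels = NULL) {
  if (length(predicted) != length(truth)) stop("confusion_matrix(): length mismatch")
  if (is.null(labels)) labels <- sort(unique(c(predicted, truth)))
  table(truth = factor(truth, levels = labels),
        predicted = factor(predicted, levels = labels))
}

#' Accuracy and error of a confusion matrix
#'
#' Accuracy is the trace over the grand total (per cent); error is its
#' complement.
#'
#' @param cm square numeric matrix of counts.
#' @return list with `accuracy` and `error` (per cent) and `n`.
#' @export
confusion_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion_accuracy(): matrix must be square")
  total <- sum(cm)
  if (total == 0) stop("confusion_accuracy(): empty matrix")
  acc <- 100 * sum(diag(cm)) / total
  list(accuracy = acc, error = 100 - acc, n = total)
}

#' Compare estimation methods against a common reference
#'
#' Produces the per-method summary table (mean absolute percentage error,
#' R^2, SD of the differences) for any number of estimators evaluated on
#' the same reference series.
#'
#' @param estimates named list of numeric vectors, one per method.
#' @param reference reference volumes (mL), common to all methods.
#' @return data frame with columns `method`, `mean_error_pct`, `r_squared`,
#'   `sd_ml`.
#' @export
method_comparison <- function(estimates, reference) {
  if (length(estimates) == 0) stop("method_comparison(): no methods given")
  if (is.null(names(estimates)) || any(names(estimates) == "")) {
    stop("method_comparison(): estimates must be a named list")
  }
  bad <- vapply(estimates, function(e) length(e) != length(reference), TRUE)
  if (any(bad)) stop("method_comparison(): sample sets do not match the reference")
  rows <- lapply(names(estimates), function(nm) {
    a <- agreement(estimates[[nm]], reference)
    data.frame(method = nm, mean_error_pct = a$mean_abs_pct_error,
               r_squared = a$r_squared, sd_ml = a$sd_diff)
  })
  do.call(rbind, rows)
}
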