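#' Build the 2x2 confusion table against chart review
#'
#' Cross-tabulates computed classifications against gold-standard chart
#' review. Cell `a` counts computed+/chart+, `b` computed+/chart-,
#' `c` computed-/chart+, `d` computed-/chart-. Every label must refer to a
#' classified order and appear at most once; labels for unknown orders are
#' an error, never a silent drop. Classified orders with no label are an
#' error too, so the table is always built on the full paired cohort.
#'
#' @param classifications Tibble with `order_id` and `computed_pe_positive`.
#' @param labels Tibble with `order_id` and `chart_review_pe_positive`.
#' @return An object of class `confusion_2x2` with fields `a`, `b`, `c`,
#'   `d`, `n`.
#' @export
build_confusion <- function(classifications, labels) {
  if (anyDuplicated(labels$order_id)) {
    abort_integrity("Duplicate gold-standard labels for order(s): " %+%
                      paste(unique(labels$order_id[duplicated(labels$order_id)]),
                            collapse = ", "))
  }
  idx <- match(labels$order_id, classifications$order_id)
  if (anyNA(idx)) {
    abort_integrity("Gold-standard label(s) for unclassified order(s): " %+%
                      paste(utils::head(labels$order_id[is.na(idx)], 5),
                            collapse = ", "))
  }
  unlabeled <- setdiff(classifications$order_id, labels$order_id)
  if (length(unlabeled) > 0) {
    abort_integrity("Classified order(s) lacking a gold-standard label: " %+%
                      paste(utils::head(unlabeled, 5), collapse = ", "))
  }
  comp <- classifications$computed_pe_positive[idx]
  chart <- labels$chart_review_pe_positive
  confusion_2x2(
    a = sum(comp & chart),
    b = sum(comp & !chart),
    c = sum(!comp & chart),
    d = sum(!comp & !chart)
  )
}

`%+%` <- function(x, y) paste0(x, y)

#' Construct a 2x2 confusion table from cell counts
#'
#' @param a Computed-positive / chart-positive count.
#' @param b Computed-positive / chart-negative count.
#' @param c Computed-negative / chart-positive count.
#' @param d Computed-negative / chart-negative count.
#' @return A `confusion_2x2` object.
#' @export
confusion_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    abort_validation("Confusion cells must be non-negative integers.")
  }
  structure(as.list(c(cells, n = sum(cells))), class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(chart = c("PE+", "PE-"),
                              computed = c("PE+", "PE-")))
  cat("<confusion_2x2> n =", x$n, "\n")
  print(m)
  invisible(x)
}

#' Cohen's kappa with asymptotic 95% confidence interval
#'
#' Chance-corrected agreement between the computed classification and chart
#' review: `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (a+d)/n` and chance agreement
#' `p_e = ((a+b)(a+c) + (c+d)(b+d)) / n^2`. The standard error is the
#' large-sample form `se = sqrt(p_o (1-p_o) / (n (1-p_e)^2))` and the 95%
#' interval `kappa +/- 1.96 se` is truncated to `[-1, 1]`.
#'
#' @param table A [confusion_2x2()].
#' @return A list with `kappa`, `se`, `ci95` (length-2 vector), `p_o`,
#'   `p_e`.
#' @examples
#' cohens_kappa(confusion_2x2(27, 0, 1, 321))
#' @export
cohens_kappa <- function(table) {
  stopifnot(inherits(table, "confusion_2x2"))
  n <- table$n
  if (n == 0) abort_validation("Kappa is undefined on an empty table.")
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (p_e >= 1) {
    abort_validation(
      "Kappa is undefined: degenerate marginals give chance agreement of 1.")
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  ci <- pmin(1, pmax(-1, kappa + c(-1, 1) * 1.96 * se))
  list(kappa = kappa, se = se, ci95 = ci, p_o = p_o, p_e = p_e)
}

#' McNemar's test for paired yields
#'
#' Tests marginal homogeneity of the paired computed vs chart-review
#' classifications, driven by the discordant cells `b` and `c`.
#' Variants: `"uncorrected"` uses `chi2 = (b-c)^2/(b+c)` against a 1-df
#' chi-square; `"continuity_corrected"` uses `(|b-c|-1)^2/(b+c)` floored at
#' zero; `"exact_binomial"` is the two-sided binomial test of `b` successes
#' in `b+c` trials at probability 1/2 (no chi-square statistic). With no
#' discordant pairs (`b+c = 0`) the p-value is 1 by convention for all
#' variants. The uncorrected variant is the default.
#'
#' @param table A [confusion_2x2()].
#' @param variant One of `"uncorrected"`, `"continuity_corrected"`,
#'   `"exact_binomial"`.
#' @return A list with `statistic` (`NA` for the exact variant), `p_value`,
#'   and `variant`.
#' @examples
#' mcnemar_test(confusion_2x2(27, 0, 1, 321))  # chi2 = 1, p ~ 0.317
#' @export
mcnemar_test <- function(table,
                         variant = c("uncorrected", "continuity_corrected",
                                     "exact_binomial")) {
  stopifnot(inherits(table, "confusion_2x2"))
  variant <- match.arg(variant)
  b <- table$b; c <- table$c
  nd <- b + c
  if (nd == 0) {
    stat <- if (variant == "exact_binomial") NA_real_ else 0
    return(list(statistic = stat, p_value = 1, variant = variant))
  }
  if (variant == "uncorrected") {
    stat <- (b - c)^2 / nd
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else if (variant == "continuity_corrected") {
    stat <- max(0, (abs(b - c) - 1))^2 / nd
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stat <- NA_real_
    p <- stats::binom.test(b, nd, p = 0.5)$p.value
    p <- min(1, p)
  }
  list(statistic = stat, p_value = p, variant = variant)
}

#' Capture accuracy of the computerized method
#'
#' The fraction of chart-review-positive scans that the computerized method
#' identifies: `a / (a + c)`. Operationally this is a sensitivity; the name
#' "capture accuracy" follows how the measure is reported in imaging-yield
#' validation. Undefined (an explicit error, not `NaN`) when there are no
#' chart-positive scans.
#'
#' @param table A [confusion_2x2()].
#' @return A fraction in `[0, 1]`.
#' @examples
#' capture_accuracy(confusion_2x2(27, 0, 1, 321))  # 27/28
#' @export
capture_accuracy <- function(table) {
  stopifnot(inherits(table, "confusion_2x2"))
  pos <- table$a + table$c
  if (pos == 0) {
    abort_validation(
      "Capture accuracy is undefined: no chart-review-positive scans.")
  }
  table$a / pos
}

#' Observed agreement
#'
#' The raw fraction of orders on which the computed classification and
#' chart review agree: `(a + d) / n`. Reported separately from capture
#' accuracy to keep the two denominators distinct.
#'
#' @param table A [confusion_2x2()].
#' @return A fraction in `[0, 1]`.
#' @export
observed_agreement <- function(table) {
  stopifnot(inherits(table, "confusion_2x2"))
  if (table$n == 0) abort_validation("Observed agreement is undefined on an empty table.")
  (table$a + table$d) / table$n
}

#' Validate computed classifications against chart review
#'
#' Convenience wrapper producing the full validation panel: the 2x2
#' confusion table, Cohen's kappa with its asymptotic 95% CI, McNemar's
#' test, capture accuracy, and observed agreement.
#'
#' @param classifications Tibble with `order_id`, `computed_pe_positive`
#'   (e.g. the `classifications` element of a `ctpa_yield_result`).
#' @param labels Gold-standard label table.
#' @param mcnemar_variant Passed to [mcnemar_test()].
#' @return An object of class `agreement_stats`.
#' @export
validate_against_chart <- function(classifications, labels,
                                   mcnemar_variant = "uncorrected") {
  tab <- build_confusion(classifications, labels)
  kap <- cohens_kappa(tab)
  mcn <- mcnemar_test(tab, mcnemar_variant)
  structure(
    list(
      table = tab,
      kappa = kap$kappa,
      kappa_se = kap$se,
      kappa_ci95 = kap$ci95,
      mcnemar_statistic = mcn$statistic,
      mcnemar_p = mcn$p_value,
      mcnemar_variant = mcn$variant,
      capture_accuracy = capture_accuracy(tab),
      observed_agreement = observed_agreement(tab)
    ),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  t <- x$table
  cat("<agreement_stats> computed vs chart review, n =", t$n, "\n")
  cat(sprintf("  confusion (a,b,c,d):  (%d, %d, %d, %d)\n", t$a, t$b, t$c, t$d))
  cat(sprintf("  kappa:                %.2f  95%% CI (%.2f, %.2f)\n",
              x$kappa, x$kappa_ci95[1], x$kappa_ci95[2]))
  cat(sprintf("  McNemar (%s):  %s p = %.2f\n", x$mcnemar_variant,
              if (is.na(x$mcnemar_statistic)) "" else
                sprintf("chi2 = %.2f,", x$mcnemar_statistic), x$mcnemar_p))
  cat(sprintf("  capture accuracy:     %.1f%% (%d/%d)\n",
              100 * x$capture_accuracy, t$a, t$a + t$c))
  cat(sprintf("  observed agreement:   %.1f%%\n", 100 * x$observed_agreement))
  invisible(x)
}
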