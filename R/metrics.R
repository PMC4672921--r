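# 2x2 contingency metrics, net reclassification indices, distribution
# comparisons and the binomial cohort-balance check.

#' Contingency metrics at a fixed cutoff
#'
#' Summarises binary calls against case/control labels: counts (TP, FP,
#' FN, TN), accuracy, sensitivity, specificity, PPV and NPV with Wilson
#' score intervals, and the diagnostic likelihood ratios LR+ =
#' sensitivity / (1 - specificity) and LR- = (1 - sensitivity) /
#' specificity with log-method (Simel) intervals. Point estimates use
#' the raw counts (so LR- is exactly 0 when there are no false
#' negatives); for the LR intervals only, 0.5 is added to every cell when
#' some cell is zero.
#'
#' @param calls Character vector of `"positive"` / `"negative"` calls
#'   (named, or aligned with `labels`).
#' @param labels Cohort labels (case/control only).
#' @param conf.level Confidence level (default 0.95).
#' @return An object of class `contingency_metrics`.
#' @export
contingency_metrics <- function(calls, labels, conf.level = 0.95) {
  cls <- .align_labels(labels, names(calls) %||% seq_along(calls))
  .check_class_labels(cls, allow_possible = FALSE)
  if (!all(calls %in% c("positive", "negative"))) {
    .stopf("calls must be 'positive' or 'negative'")
  }
  is_case <- cls == "case"
  pos <- calls == "positive"
  if (!any(is_case) || !any(!is_case)) .stopf("both classes must be non-empty")
  tp <- sum(pos & is_case); fn <- sum(!pos & is_case)
  fp <- sum(pos & !is_case); tn <- sum(!pos & !is_case)
  n1 <- tp + fn; n0 <- fp + tn
  sens <- tp / n1; spec <- tn / n0

  prop <- function(x, n) list(est = x / n, ci = .wilson_ci(x, n, conf.level))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  lr_ci <- function(lr, a, m, b, n) {
    # log-method CI for a ratio of proportions a/m over b/n
    if (any(c(a, m - a, b, n - b) == 0)) {
      a <- a + 0.5; b <- b + 0.5; m <- m + 1; n <- n + 1
      lr_c <- (a / m) / (b / n)
    } else lr_c <- lr
    se <- sqrt(1 / a - 1 / m + 1 / b - 1 / n)
    exp(log(lr_c) + c(-1, 1) * z * se)
  }
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    n_cases = n1, n_controls = n0,
    accuracy = prop(tp + tn, n1 + n0),
    sensitivity = prop(tp, n1),
    specificity = prop(tn, n0),
    ppv = prop(tp, tp + fp),
    npv = prop(tn, tn + fn),
    lr_pos = list(est = sens / (1 - spec),
                  ci = lr_ci(sens / (1 - spec), tp, n1, fp, n0)),
    lr_neg = list(est = (1 - sens) / spec,
                  ci = lr_ci((1 - sens) / spec, fn, n1, tn, n0)),
    conf.level = conf.level
  ), class = "contingency_metrics")
}

#' @export
print.contingency_metrics <- function(x, ...) {
  cat(sprintf("2x2 table: TP %d, FP %d, FN %d, TN %d\n", x$tp, x$fp, x$fn, x$tn))
  fmt <- function(nm, v) {
    cat(sprintf("  %-12s %.3f (%.3f, %.3f)\n", nm, v$est, v$ci[1L], v$ci[2L]))
  }
  fmt("accuracy", x$accuracy); fmt("sensitivity", x$sensitivity)
  fmt("specificity", x$specificity); fmt("PPV", x$ppv); fmt("NPV", x$npv)
  fmt("LR+", x$lr_pos); fmt("LR-", x$lr_neg)
  invisible(x)
}

#' Net reclassification indices for paired binary tests
#'
#' For two binary tests on the same samples, NRI+ is the gain in
#' sensitivity (new minus old, among cases) and NRI- the gain in
#' specificity (among controls). Confidence intervals and p-values use
#' the paired-proportion variance of the reclassification differences:
#' with discordant fractions p10 (new correct, old wrong) and p01 (new
#' wrong, old correct) in a class of size n,
#' `var = (p10 + p01 - (p10 - p01)^2) / n`.
#'
#' @param calls_new,calls_old Paired `"positive"`/`"negative"` call
#'   vectors on identical samples.
#' @param labels Cohort labels (case/control only).
#' @param conf.level Confidence level (default 0.95).
#' @return A `comparison_result` with `nri_pos`, `nri_neg`, their CIs and
#'   p-values.
#' @export
nri <- function(calls_new, calls_old, labels, conf.level = 0.95) {
  if (length(calls_new) != length(calls_old)) {
    .stopf("NRI requires paired calls on identical samples")
  }
  cls <- .align_labels(labels, names(calls_new) %||% seq_along(calls_new))
  .check_class_labels(cls, allow_possible = FALSE)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  one_class <- function(keep, correct) {
    n <- sum(keep)
    new_ok <- calls_new[keep] == correct
    old_ok <- calls_old[keep] == correct
    p10 <- mean(new_ok & !old_ok)
    p01 <- mean(!new_ok & old_ok)
    est <- p10 - p01
    v <- (p10 + p01 - est^2) / n
    se <- sqrt(max(v, 0))
    p <- if (se == 0) as.numeric(est == 0) else 2 * stats::pnorm(-abs(est) / se)
    list(est = est, ci = est + c(-1, 1) * z * se, p = p)
  }
  pos <- one_class(cls == "case", "positive")
  neg <- one_class(cls == "control", "negative")
  structure(list(method = "nri", paired = TRUE,
                 nri_pos = pos$est, nri_pos_ci = pos$ci, nri_pos_p = pos$p,
                 nri_neg = neg$est, nri_neg_ci = neg$ci, nri_neg_p = neg$p),
            class = "comparison_result")
}

#' Compare two statistical distributions
#'
#' Dispatches the distribution comparisons used in cohort QC: the
#' Kolmogorov-Smirnov test for cumulative distributions, and for
#' frequency distributions a Welch t-test if both samples pass a Shapiro
#' normality screen (alpha = 0.05) or a Wilcoxon rank-sum test otherwise
#' (`mode = "auto"`). All tests are two-sided.
#'
#' @param sample_x,sample_y Numeric vectors (>= 2 values each; auto mode
#'   needs >= 3 for the normality screen).
#' @param mode One of `"auto"`, `"t"`, `"wilcoxon"`, `"ks"`.
#' @return A `comparison_result` with `statistic`, `p_value` and the
#'   `method` actually used.
#' @export
compare_distributions <- function(sample_x, sample_y,
                                  mode = c("auto", "t", "wilcoxon", "ks")) {
  mode <- match.arg(mode)
  if (length(sample_x) < 2L || length(sample_y) < 2L) {
    .stopf("both samples must have at least 2 values")
  }
  if (mode == "auto") {
    if (length(sample_x) < 3L || length(sample_y) < 3L) {
      .stopf("auto mode needs >= 3 values per sample for the normality screen")
    }
    normal <- stats::shapiro.test(sample_x)$p.value > 0.05 &&
      stats::shapiro.test(sample_y)$p.value > 0.05
    mode <- if (normal) "t" else "wilcoxon"
  }
  res <- switch(mode,
    t = stats::t.test(sample_x, sample_y),
    wilcoxon = suppressWarnings(stats::wilcox.test(sample_x, sample_y)),
    ks = suppressWarnings(stats::ks.test(sample_x, sample_y))
  )
  structure(list(method = mode, statistic = unname(res$statistic),
                 p_value = res$p.value, paired = FALSE),
            class = "comparison_result")
}

#' Binomial balance check for two group sizes
#'
#' Flags a (case, control) split as unbalanced when the observed count
#' falls outside the central 95% acceptance region of a
#' Binomial(n1 + n2, 1/2) distribution centred on (n1 + n2) / 2, i.e.
#' outside `[qbinom(.025, N, .5), qbinom(.975, N, .5)]`. The exact
#' two-sided binomial test p-value is reported alongside.
#'
#' @param n_group1,n_group2 Non-negative counts, sum >= 1.
#' @param conf.level Confidence level (default 0.95).
#' @return List with `balanced` (logical), the acceptance interval
#'   `ci_low`/`ci_high` (counts), and `p_value`.
#' @export
binomial_balance_check <- function(n_group1, n_group2, conf.level = 0.95) {
  stopifnot(n_group1 >= 0, n_group2 >= 0, n_group1 + n_group2 >= 1)
  n <- n_group1 + n_group2
  alpha <- (1 - conf.level) / 2
  lo <- stats::qbinom(alpha, n, 0.5)
  hi <- stats::qbinom(1 - alpha, n, 0.5)
  p <- stats::binom.test(n_group1, n, 0.5)$p.value
  structure(list(balanced = n_group1 >= lo && n_group1 <= hi,
                 ci_low = lo, ci_high = hi, n = n,
                 observed = n_group1, p_value = p),
            class = "balance_check")
}

#' @export
print.balance_check <- function(x, ...) {
  cat(sprintf("balance check: %s (observed %d of %d; acceptance region [%d, %d]; exact p = %.3g)\n",
              if (x$balanced) "balanced" else "unbalanced",
              x$observed, x$n, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}
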