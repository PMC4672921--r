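# ROC curves, AUC estimation and AUC comparison tests.
#
# AUC is always the Mann-Whitney probability P(case score > control score)
# with midrank handling of ties. The comparison tests are the two used to
# benchmark diagnostic classifiers on these data: DeLong's
# placement-value test for differences in AUC, and Venkatraman's
# permutation test for equality of the entire ROC curves.

.roc_points <- function(cases, controls) {
  thr <- sort(unique(c(cases, controls)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(cases >= t), numeric(1L))
  fpr <- vapply(thr, function(t) mean(controls >= t), numeric(1L))
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

.roc_summary <- function(auc, ci_low, ci_high, method, n_cases, n_controls, curve) {
  structure(list(auc = auc, ci_low = ci_low, ci_high = ci_high,
                 method = method, n_cases = n_cases, n_controls = n_controls,
                 curve = curve),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else sprintf(" (95%% CI %.3f-%.3f)", x$ci_low, x$ci_high)
  cat(sprintf("%s ROC: AUC %.3f%s  [%d cases, %d controls]\n",
              x$method, x$auc, ci, x$n_cases, x$n_controls))
  invisible(x)
}

#' Empirical ROC curve and AUC
#'
#' @param case_scores,control_scores Numeric score vectors for the two
#'   classes; both must be non-empty.
#' @return A `roc_summary` with the Mann-Whitney AUC and the empirical
#'   curve (FPR, TPR) obtained by thresholding at every distinct score.
#' @export
empirical_auc <- function(case_scores, control_scores) {
  .roc_summary(.auc(case_scores, control_scores), NA_real_, NA_real_,
               "empirical", length(case_scores), length(control_scores),
               .roc_points(case_scores, control_scores))
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples cases and controls independently (within class), recomputes
#' the empirical AUC per replicate, and reports the percentile 2.5/97.5
#' interval. Degenerate replicates (a class resampled to a constant) are
#' retained; the midrank AUC remains defined. Deterministic given `seed`.
#'
#' @inheritParams empirical_auc
#' @param reps Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param conf.level Confidence level (default 0.95).
#' @return A `roc_summary` with `ci_low`/`ci_high`; replicate AUCs are
#'   attached as attribute `"replicates"`.
#' @export
bootstrap_auc_ci <- function(case_scores, control_scores, reps = 2000L,
                             seed = 1L, conf.level = 0.95) {
  if (reps < 100L) .stopf("reps must be >= 100")
  n1 <- length(case_scores); n0 <- length(control_scores)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      .auc(case_scores[sample.int(n1, n1, replace = TRUE)],
           control_scores[sample.int(n0, n0, replace = TRUE)])
    }, numeric(1L))
  })
  alpha <- (1 - conf.level) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  out <- .roc_summary(.auc(case_scores, control_scores), ci[1L], ci[2L],
                      "empirical", n1, n0,
                      .roc_points(case_scores, control_scores))
  attr(out, "replicates") <- boot
  attr(out, "seed") <- seed
  out
}

#' Binormal smoothed ROC curve and AUC
#'
#' Fits the binormal ROC model by method of moments on the raw scores:
#' with `a = (mean_case - mean_control) / sd_case` and
#' `b = sd_control / sd_case`, the smooth curve is
#' `TPR = Phi(a + b * Phi^-1(FPR))` and `AUC = Phi(a / sqrt(1 + b^2))`.
#'
#' @inheritParams empirical_auc
#' @return A `roc_summary` with the smooth curve evaluated on an FPR
#'   grid; the binormal parameters are attached as attribute `"ab"`.
#' @export
binormal_auc <- function(case_scores, control_scores) {
  if (length(unique(case_scores)) < 2L || length(unique(control_scores)) < 2L) {
    .stopf("binormal fit needs >= 2 distinct values per group; use the empirical method")
  }
  s1 <- stats::sd(case_scores); s0 <- stats::sd(control_scores)
  if (s1 == 0 || s0 == 0) .stopf("zero variance in a group; use the empirical method")
  a <- (mean(case_scores) - mean(control_scores)) / s1
  b <- s0 / s1
  fpr <- seq(0, 1, length.out = 201L)
  tpr <- c(0, stats::pnorm(a + b * stats::qnorm(fpr[-c(1L, 201L)])), 1)
  out <- .roc_summary(stats::pnorm(a / sqrt(1 + b^2)), NA_real_, NA_real_,
                      "binormal", length(case_scores), length(control_scores),
                      data.frame(fpr = fpr, tpr = tpr))
  attr(out, "ab") <- c(a = a, b = b)
  out
}

# DeLong placement values: v10[i] = P-hat(case_i > random control),
# v01[j] = P-hat(random case > control_j); midrank ties count 1/2.
.placements <- function(cases, controls) {
  m <- length(cases); n <- length(controls)
  r <- rank(c(cases, controls), ties.method = "average")
  v10 <- (r[seq_len(m)] - rank(cases, ties.method = "average")) / n
  v01 <- 1 - (r[m + seq_len(n)] - rank(controls, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's test for a difference in AUC
#'
#' Nonparametric comparison of two AUCs via the covariance of placement
#' values. In the paired form both markers are measured on the same
#' samples and the covariance between markers is subtracted; in the
#' unpaired form the two markers come from independent cohorts (then
#' `labels_b`/`scores_b` describe the second cohort) and the variances
#' add. The p-value is two-sided normal.
#'
#' @param scores_a,scores_b Numeric score vectors for the two markers.
#' @param labels Class labels aligned with `scores_a` (and with
#'   `scores_b` when paired).
#' @param paired Logical; paired requires identical sample sets.
#' @param labels_b Labels for `scores_b` in the unpaired case (defaults
#'   to `labels`).
#' @return A `comparison_result` with `delta_auc`, the z `statistic` and
#'   `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels, paired = TRUE,
                        labels_b = NULL) {
  ga <- .split_scores(scores_a, labels, names(scores_a) %||% seq_along(scores_a))
  if (paired) {
    if (length(scores_a) != length(scores_b)) {
      .stopf("paired DeLong test requires identical sample sets")
    }
    gb <- .split_scores(scores_b, labels, names(scores_b) %||% seq_along(scores_b))
  } else {
    gb <- .split_scores(scores_b, labels_b %||% labels,
                        names(scores_b) %||% seq_along(scores_b))
  }
  pa <- .placements(ga$cases, ga$controls)
  pb <- .placements(gb$cases, gb$controls)
  delta <- pa$auc - pb$auc
  if (paired) {
    s10 <- stats::cov(cbind(pa$v10, pb$v10))
    s01 <- stats::cov(cbind(pa$v01, pb$v01))
    S <- s10 / length(pa$v10) + s01 / length(pa$v01)
    v <- S[1L, 1L] + S[2L, 2L] - 2 * S[1L, 2L]
  } else {
    v <- stats::var(pa$v10) / length(pa$v10) + stats::var(pa$v01) / length(pa$v01) +
      stats::var(pb$v10) / length(pb$v10) + stats::var(pb$v01) / length(pb$v01)
  }
  if (abs(delta) < 1e-15) {
    z <- 0; p <- 1
  } else if (v <= 0) {
    z <- sign(delta) * Inf; p <- 0
  } else {
    z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(method = "delong", statistic = z, p_value = p,
                 delta_auc = delta, auc_a = pa$auc, auc_b = pb$auc,
                 variance = v, paired = paired),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s test (%s)\n", x$method,
              if (isTRUE(x$paired)) "paired" else "unpaired"))
  if (!is.null(x$delta_auc)) cat(sprintf("  delta AUC: %.4f\n", x$delta_auc))
  if (!is.null(x$nri_pos)) {
    cat(sprintf("  NRI+: %.3f (%.3f, %.3f), p = %.3g\n",
                x$nri_pos, x$nri_pos_ci[1L], x$nri_pos_ci[2L], x$nri_pos_p))
    cat(sprintf("  NRI-: %.3f (%.3f, %.3f), p = %.3g\n",
                x$nri_neg, x$nri_neg_ci[1L], x$nri_neg_ci[2L], x$nri_neg_p))
    return(invisible(x))
  }
  cat(sprintf("  statistic: %.4f, p = %.4g\n", x$statistic, x$p_value))
  if (!is.null(x$reps)) cat(sprintf("  reps: %d, seed: %d\n", x$reps, x$seed))
  invisible(x)
}

# Venkatraman error statistic on the rank scale: for each cut k of the
# joint ranks, e(k) = (#cases ranked <= k) + (#controls ranked > k);
# the statistic sums |e_x(k) - e_y(k)| over k = 1..n-1. Ties are broken
# by first occurrence so ranks are a permutation of 1..n.
.venkatraman_errors <- function(scores, is_case) {
  n <- length(scores)
  z <- integer(n)
  z[rank(scores, ties.method = "first")] <- as.integer(is_case)
  cumsum(z) + (sum(!is_case) - cumsum(1L - z))
}

.venkatraman_stat_paired <- function(x, y, is_case) {
  ex <- .venkatraman_errors(x, is_case)
  ey <- .venkatraman_errors(y, is_case)
  n <- length(x)
  sum(abs(ex - ey)[seq_len(n - 1L)])
}

# Unpaired statistic: integrated absolute difference between the two
# empirical ROC step curves over FPR.
.venkatraman_stat_unpaired <- function(ca, co_a, cb, co_b) {
  curve_a <- .roc_points(ca, co_a)
  curve_b <- .roc_points(cb, co_b)
  grid <- sort(unique(c(curve_a$fpr, curve_b$fpr)))
  ta <- stats::approx(curve_a$fpr, curve_a$tpr, xout = grid, method = "constant",
                      f = 1, ties = max, rule = 2L)$y
  tb <- stats::approx(curve_b$fpr, curve_b$tpr, xout = grid, method = "constant",
                      f = 1, ties = max, rule = 2L)$y
  sum(abs(ta - tb)[-length(grid)] * diff(grid))
}

#' Venkatraman's permutation test for equality of ROC curves
#'
#' Tests whether two markers have the same ROC curve (not merely the same
#' AUC). Paired form: the statistic is the integrated absolute difference
#' between the rank-scale error curves, and the null is generated by
#' randomly exchanging the two markers' values within each subject.
#' Unpaired form: the statistic integrates the absolute TPR difference of
#' the two empirical ROC curves over FPR, and the null permutes marker
#' membership separately within the case pool and the control pool.
#' The p-value is `(exceedances + 1) / (reps + 1)`.
#'
#' @inheritParams delong_test
#' @param reps Number of permutations (>= 100).
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @return A `comparison_result` with the observed `statistic`, `p_value`,
#'   `reps` and `seed`.
#' @export
venkatraman_test <- function(scores_a, scores_b, labels, reps = 2000L,
                             seed = 1L, paired = TRUE, labels_b = NULL) {
  if (reps < 100L) .stopf("reps must be >= 100")
  reps <- as.integer(reps)
  if (paired) {
    if (length(scores_a) != length(scores_b)) {
      .stopf("paired test requires identical sample sets")
    }
    cls <- .align_labels(labels, names(scores_a) %||% seq_along(scores_a))
    .check_class_labels(cls, allow_possible = FALSE)
    is_case <- cls == "case"
    obs <- .venkatraman_stat_paired(scores_a, scores_b, is_case)
    n <- length(scores_a)
    exceed <- withr::with_seed(seed, {
      sum(vapply(seq_len(reps), function(i) {
        swap <- stats::runif(n) < 0.5
        xs <- ifelse(swap, scores_b, scores_a)
        ys <- ifelse(swap, scores_a, scores_b)
        .venkatraman_stat_paired(xs, ys, is_case)
      }, numeric(1L)) >= obs - 1e-12)
    })
  } else {
    ga <- .split_scores(scores_a, labels, names(scores_a) %||% seq_along(scores_a))
    gb <- .split_scores(scores_b, labels_b %||% labels,
                        names(scores_b) %||% seq_along(scores_b))
    obs <- .venkatraman_stat_unpaired(ga$cases, ga$controls, gb$cases, gb$controls)
    case_pool <- c(ga$cases, gb$cases)
    ctrl_pool <- c(ga$controls, gb$controls)
    m_a <- length(ga$cases); n_a <- length(ga$controls)
    exceed <- withr::with_seed(seed, {
      sum(vapply(seq_len(reps), function(i) {
        ci <- sample.int(length(case_pool))
        ki <- sample.int(length(ctrl_pool))
        .venkatraman_stat_unpaired(case_pool[ci[seq_len(m_a)]],
                                   ctrl_pool[ki[seq_len(n_a)]],
                                   case_pool[ci[-seq_len(m_a)]],
                                   ctrl_pool[ki[-seq_len(n_a)]])
      }, numeric(1L)) >= obs - 1e-12)
    })
  }
  structure(list(method = "venkatraman", statistic = obs,
                 p_value = (exceed + 1) / (reps + 1),
                 reps = reps, seed = as.integer(seed), paired = paired),
            class = "comparison_result")
}
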