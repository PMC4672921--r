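test_that("empirical AUC equals exhaustive pair counting, ties included", {
  expect_equal(empirical_auc(c(2, 3), c(0, 1))$auc, 1.0)
  expect_equal(empirical_auc(c(0, 1), c(2, 3))$auc, 0.0)
  expect_equal(empirical_auc(c(1, 2), c(1, 3))$auc, 0.375)
  for (s in 1:200) {
    g <- withr::with_seed(s, {
      n1 <- sample(2:12, 1); n0 <- sample(2:12, 1)
      list(cases = sample(0:5, n1, replace = TRUE),   # heavy ties on purpose
           controls = sample(0:5, n0, replace = TRUE))
    })
    expect_equal(empirical_auc(g$cases, g$controls)$auc,
                 pair_count_auc(g$cases, g$controls))
  }
})

test_that("AUC complement and monotone-transform invariances hold exactly", {
  g <- make_scores(15, 12, d = 0.8, seed = 3)
  a <- empirical_auc(g$cases, g$controls)$auc
  expect_equal(a + empirical_auc(-g$cases, -g$controls)$auc, 1)
  expect_equal(empirical_auc(exp(g$cases), exp(g$controls))$auc, a)
  expect_equal(empirical_auc(g$cases * 10 + 2, g$controls * 10 + 2)$auc, a)
})

test_that("ROC curve runs monotonically from (0,0) to (1,1)", {
  g <- make_scores(20, 20, d = 1, seed = 4)
  cv <- empirical_auc(g$cases, g$controls)$curve
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)
  expect_true(all(diff(cv$fpr) >= 0))
  expect_true(all(diff(cv$tpr) >= 0))
})

test_that("bootstrap CI is seed-deterministic and covers the point estimate", {
  g <- make_scores(30, 30, d = 1, seed = 5)
  b1 <- bootstrap_auc_ci(g$cases, g$controls, reps = 500, seed = 7)
  b2 <- bootstrap_auc_ci(g$cases, g$controls, reps = 500, seed = 7)
  expect_identical(attr(b1, "replicates"), attr(b2, "replicates"))
  for (s in 1:4) {
    b <- bootstrap_auc_ci(g$cases, g$controls, reps = 500, seed = s)
    expect_gte(b$auc, b$ci_low)
    expect_lte(b$auc, b$ci_high)
  }
  # perfect separation survives within-class resampling
  sep <- make_scores(200, 200, d = 0, seed = 6)
  b <- bootstrap_auc_ci(sep$cases + 100, sep$controls, reps = 500, seed = 1)
  expect_equal(b$ci_high, 1.0)
  expect_gt(b$ci_low, 0.95)
  expect_error(bootstrap_auc_ci(1:3, 4:6, reps = 10), ">= 100")
})

test_that("binormal AUC matches its closed form and is affine-invariant", {
  g <- make_scores(40, 40, d = 0, seed = 9)
  expect_equal(binormal_auc(g$cases, g$cases)$auc, 0.5)  # equal moments
  # method of moments: a and b from the sample moments exactly
  bn <- binormal_auc(g$cases + 1, g$controls)
  ab <- attr(bn, "ab")
  a_exp <- (mean(g$cases + 1) - mean(g$controls)) / sd(g$cases)
  expect_equal(unname(ab["a"]), a_exp)
  expect_equal(bn$auc, pnorm(a_exp / sqrt(1 + (sd(g$controls) / sd(g$cases))^2)))
  # population check: 1 SD shift, equal variances -> Phi(1/sqrt(2))
  big <- make_scores(20000, 20000, d = 1, seed = 10)
  expect_equal(binormal_auc(big$cases, big$controls)$auc, pnorm(1 / sqrt(2)),
               tolerance = 0.01)
  expect_equal(binormal_auc(g$cases * 10, g$controls * 10)$auc,
               binormal_auc(g$cases, g$controls)$auc)
  expect_error(binormal_auc(rep(1, 5), g$controls), "distinct")
})

test_that("DeLong test is null on identical scores and matches pROC", {
  g <- make_scores(20, 25, d = 1, seed = 12)
  scores <- c(g$cases, g$controls)
  labels <- cc_labels(20, 25)
  id <- delong_test(scores, scores, labels)
  expect_equal(id$delta_auc, 0)
  expect_equal(id$p_value, 1)
  for (s in 1:5) {
    h <- withr::with_seed(s, list(a = scores + rnorm(45, 0, 0.5),
                                  b = scores + rnorm(45, 0, 1.5)))
    mine <- delong_test(h$a, h$b, labels, paired = TRUE)
    ra <- pROC::roc(labels, h$a, levels = c("control", "case"),
                    direction = "<", quiet = TRUE)
    rb <- pROC::roc(labels, h$b, levels = c("control", "case"),
                    direction = "<", quiet = TRUE)
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("DeLong variance equals the grouped delete-one jackknife", {
  m <- 50; n <- 50
  labels <- cc_labels(m, n)
  h <- withr::with_seed(13, list(a = c(rnorm(m, 1), rnorm(n)),
                                 b = c(rnorm(m, 0.8), rnorm(n))))
  dl <- delong_test(h$a, h$b, labels, paired = TRUE)
  d_auc <- function(keep) {
    ic <- labels[keep] == "case"
    empirical_auc(h$a[keep][ic], h$a[keep][!ic])$auc -
      empirical_auc(h$b[keep][ic], h$b[keep][!ic])$auc
  }
  idx <- seq_along(labels)
  dc <- vapply(which(labels == "case"), function(i) d_auc(idx[-i]), numeric(1))
  dk <- vapply(which(labels == "control"), function(i) d_auc(idx[-i]), numeric(1))
  vj <- (m - 1) / m * sum((dc - mean(dc))^2) + (n - 1) / n * sum((dk - mean(dk))^2)
  expect_lt(abs(dl$variance / vj - 1), 0.10)
  expect_gt(dl$variance, 0)
})

test_that("unpaired DeLong accepts cohorts of different sizes", {
  ga <- make_scores(20, 30, d = 1.0, seed = 14)
  gb <- make_scores(25, 25, d = 0.9, seed = 15)
  res <- delong_test(c(ga$cases, ga$controls), c(gb$cases, gb$controls),
                     cc_labels(20, 30), paired = FALSE,
                     labels_b = cc_labels(25, 25))
  expect_false(res$paired)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_error(delong_test(1:10, 1:12, cc_labels(5, 5), paired = TRUE), "identical")
})

test_that("Venkatraman test is null on identical curves and seed-stable", {
  g <- make_scores(15, 15, d = 1, seed = 16)
  scores <- c(g$cases, g$controls)
  labels <- cc_labels(15, 15)
  id <- venkatraman_test(scores, scores, labels, reps = 200, seed = 1)
  expect_equal(id$statistic, 0)
  expect_equal(id$p_value, 1)
  h <- withr::with_seed(17, list(a = scores + rnorm(30, 0, 0.4),
                                 b = scores + rnorm(30, 0, 1.2)))
  v1 <- venkatraman_test(h$a, h$b, labels, reps = 300, seed = 5)
  v2 <- venkatraman_test(h$a, h$b, labels, reps = 300, seed = 5)
  expect_identical(v1$p_value, v2$p_value)
})

test_that("Venkatraman rank-error statistic matches the pROC reference", {
  labels <- cc_labels(25, 25)
  h <- withr::with_seed(5, list(a = c(rnorm(25, 1.2), rnorm(25)),
                                b = c(rnorm(25, 0.4), rnorm(25))))
  mine <- venkatraman_test(h$a, h$b, labels, reps = 500, seed = 9)
  ra <- pROC::roc(labels, h$a, levels = c("control", "case"),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(labels, h$b, levels = c("control", "case"),
                  direction = "<", quiet = TRUE)
  ref <- withr::with_seed(9,
    pROC::roc.test(ra, rb, method = "venkatraman", paired = TRUE, boot.n = 500))
  expect_equal(unname(mine$statistic), unname(ref$statistic))
  expect_lt(abs(mine$p_value - ref$p.value), 0.08)  # Monte-Carlo noise only
})

test_that("unpaired Venkatraman integrates the ROC difference over FPR", {
  ga <- make_scores(18, 22, d = 1.2, seed = 18)
  gb <- make_scores(20, 20, d = 1.2, seed = 19)
  same <- venkatraman_test(c(ga$cases, ga$controls), c(gb$cases, gb$controls),
                           cc_labels(18, 22), reps = 300, seed = 2,
                           paired = FALSE, labels_b = cc_labels(20, 20))
  expect_gt(same$p_value, 0.05)  # same generative model: curves equal
  gc <- make_scores(20, 20, d = 3, seed = 20)
  diff <- venkatraman_test(c(ga$cases, ga$controls), c(gc$cases, gc$controls),
                           cc_labels(18, 22), reps = 300, seed = 2,
                           paired = FALSE, labels_b = cc_labels(20, 20))
  expect_gt(diff$statistic, same$statistic)
})
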