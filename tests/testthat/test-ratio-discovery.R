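test_that("ratio features are log differences with exact antisymmetry", {
  m <- toy_matrix(c(10, 12, 9, 9), c("A", "B"), c("s1", "s2"))
  expect_equal(unname(compute_ratio_feature(m, "A", "B")), c(1, 3))
  expect_equal(unname(compute_ratio_feature(m, "A", "A")), c(0, 0))
  expect_equal(compute_ratio_feature(m, "B", "A"),
               -compute_ratio_feature(m, "A", "B"))
  expect_error(compute_ratio_feature(m, "A", "ZZZ"), "ZZZ")
})

test_that("prefilter ranks a planted informative gene first", {
  spec <- sim_spec(n_cases = 30, n_controls = 30, n_genes = 51,
                   signature = c(UP1 = 2, UP2 = 2, DN1 = -2, DN2 = -2),
                   seed = 101)
  coh <- generate_expression_cohort(spec)
  # keep one informative gene among 47 nulls
  keep <- c("UP1", grep("^G", rownames(coh$matrix), value = TRUE))
  top <- prefilter_genes(coh$matrix[keep, ], coh$labels, top_n = 10)
  expect_equal(top[1], "UP1")
  # top_n equal to the gene count is the identity set
  all_genes <- prefilter_genes(coh$matrix[keep, ], coh$labels, top_n = length(keep))
  expect_setequal(all_genes, keep)
  expect_warning(prefilter_genes(coh$matrix[keep, ], coh$labels,
                                 top_n = length(keep) + 5), "exceeds")
})

test_that("prefilter tie-break on a constant matrix is deterministic", {
  m <- toy_matrix(rep(1, 30), sprintf("g%02d", c(3, 1, 2)), sprintf("s%d", 1:10))
  labs <- cc_labels(5, 5)
  top <- prefilter_genes(m, labs, top_n = 3)
  expect_equal(top, c("g01", "g02", "g03"))  # all AUC 0.5; lexicographic
})

test_that("ratio screen enumerates each unordered pair once, oriented", {
  spec <- sim_spec(n_genes = 10, seed = 11)
  coh <- generate_expression_cohort(spec)
  ranked <- screen_all_ratios(coh$matrix, coh$labels, rownames(coh$matrix))
  expect_equal(nrow(ranked), choose(10, 2))
  expect_true(all(ranked$auc >= 0.5))
  expect_false(is.unsorted(rev(ranked$auc)))
  # planted up/down pair outranks everything at the default effect size
  expect_true(all(c(ranked$gene_a[1], ranked$gene_b[1]) %in%
                    c("PLAC8", "LAMP1", "PLA2G7", "CEACAM4")))
  expect_true(ranked$gene_a[1] %in% c("PLAC8", "LAMP1"))  # oriented up-gene first
  expect_error(screen_all_ratios(coh$matrix, coh$labels, "PLAC8"), "at least 2")
})

test_that("screen top AUC under label permutation is consistent with null", {
  spec <- sim_spec(n_cases = 30, n_controls = 30, n_genes = 20,
                   signature = numeric(0), seed = 21)
  coh <- generate_expression_cohort(spec)
  tops <- withr::with_seed(99, {
    vapply(1:20, function(i) {
      labs <- sample(coh$labels$class_label)
      screen_all_ratios(coh$matrix, labs, rownames(coh$matrix))$auc[1]
    }, numeric(1))
  })
  expect_gte(median(tops), 0.5)
  expect_lte(median(tops), 0.75)
})

test_that("greedy search matches exhaustive enumeration on a small pool", {
  spec <- sim_spec(n_cases = 40, n_controls = 40, n_genes = 8,
                   signature = c(U1 = 1, U2 = 1, D1 = -1, D2 = -1), seed = 31)
  coh <- generate_expression_cohort(spec)
  labs <- coh$labels
  ranked <- screen_all_ratios(coh$matrix, labs, rownames(coh$matrix))
  clf <- greedy_pair_search(coh$matrix, labs, ranked, pool_k = nrow(ranked))

  # brute force: best gene-disjoint partner for the top-ranked seed
  is_case <- labs$class_label == "case"
  seed_f <- coh$matrix[ranked$gene_a[1], ] - coh$matrix[ranked$gene_b[1], ]
  best <- -Inf
  for (k in 2:nrow(ranked)) {
    if (length(intersect(unlist(ranked[1, 1:2]), unlist(ranked[k, 1:2])))) next
    f <- seed_f + coh$matrix[ranked$gene_a[k], ] - coh$matrix[ranked$gene_b[k], ]
    a <- septikit::empirical_auc(f[is_case], f[!is_case])$auc
    if (a > best) best <- a
  }
  expect_equal(clf$training_auc, best)
  expect_gte(clf$training_auc, ranked$auc[1])
  expect_length(unique(clf$gene_set), 4)
})

test_that("greedy search degrades to a single ratio when no partner is admissible", {
  spec <- sim_spec(n_cases = 20, n_controls = 20, n_genes = 6,
                   signature = c(U1 = 1.5, U2 = 1.5, D1 = -1.5, D2 = -1.5),
                   seed = 41)
  coh <- generate_expression_cohort(spec)
  ranked <- screen_all_ratios(coh$matrix, coh$labels, rownames(coh$matrix))
  expect_warning(clf <- greedy_pair_search(coh$matrix, coh$labels, ranked, pool_k = 1),
                 "single-ratio")
  expect_null(clf$ratio_2)
  expect_equal(clf$training_auc, ranked$auc[1])
})

test_that("classifier scores sum the two ratios and ignore per-sample shifts", {
  m <- toy_matrix(c(12, 12, 10, 10, 11, 11, 9, 9),
                  c("PLAC8", "PLA2G7", "LAMP1", "CEACAM4"), c("s1", "s2"))
  clf <- structure(list(
    ratio_1 = list(gene_a = "PLAC8", gene_b = "PLA2G7", auc = 1),
    ratio_2 = list(gene_a = "LAMP1", gene_b = "CEACAM4", auc = 1),
    training_auc = 1, gene_set = rownames(m)), class = "ratio_classifier")
  expect_equal(unname(apply_classifier(clf, m)), c(4, 4))
  m_eq <- toy_matrix(rep(7, 4), rownames(m), "s1")
  expect_equal(unname(apply_classifier(clf, m_eq)), 0)
  m_shift <- m; m_shift[, "s1"] <- m[, "s1"] + 3.7
  expect_equal(apply_classifier(clf, m_shift), apply_classifier(clf, m))
})

test_that("ratio AUC ranking is invariant under the log base", {
  spec <- sim_spec(n_genes = 12, seed = 51)
  coh <- generate_expression_cohort(spec)
  r2 <- screen_all_ratios(coh$matrix, coh$labels, rownames(coh$matrix))
  r10 <- screen_all_ratios(coh$matrix * log10(2), coh$labels, rownames(coh$matrix))
  expect_equal(r10$auc, r2$auc)
  expect_equal(r10$gene_a, r2$gene_a)
})

test_that("swapping case and control labels preserves oriented AUCs", {
  spec <- sim_spec(n_genes = 8, seed = 61)
  coh <- generate_expression_cohort(spec)
  flipped <- coh$labels
  flipped$class_label <- ifelse(flipped$class_label == "case", "control", "case")
  a <- screen_all_ratios(coh$matrix, coh$labels, rownames(coh$matrix))
  b <- screen_all_ratios(coh$matrix, flipped, rownames(coh$matrix))
  expect_equal(sort(a$auc), sort(b$auc))
})

test_that("selection optimism on null data shrinks with sample size", {
  top_auc <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      coh <- generate_expression_cohort(
        sim_spec(n_cases = n, n_controls = n, n_genes = 15,
                 signature = numeric(0), seed = s))
      ranked <- screen_all_ratios(coh$matrix, coh$labels, rownames(coh$matrix))
      greedy_pair_search(coh$matrix, coh$labels, ranked,
                         pool_k = nrow(ranked))$training_auc
    }, numeric(1)))
  }
  small <- top_auc(15, 1:8)
  large <- top_auc(120, 1:8)
  expect_gt(small, 0.5)
  expect_gt(large, 0.5)
  expect_lt(large, small)  # optimism gap narrows as n grows
})

test_that("two-sample differential expression needs signal and fold change", {
  m <- toy_matrix(log2(c(150, 400, 90, 400, 200, 200)),
                  c("g1", "g2", "g3"), c("sx", "sy"))
  hits <- differential_expression_filter(m, "sx", "sy")
  expect_equal(hits, "g1")            # 150 vs 400: fold 2.67, both > 100
  # same matrix supplied on linear scale
  lin <- 2^m; attr(lin, "scale") <- NULL
  expect_equal(differential_expression_filter(lin, "sx", "sy", scale = "linear"), "g1")
  expect_error(differential_expression_filter(m, "sx", "nope"), "nope")
})
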