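# Discovery of additive two-ratio classifiers from a labelled log2
# expression matrix. The central transform replaces per-gene intensities
# with log-ratios between gene pairs,
#     ratio[a,b](s) = log2 I[a,s] - log2 I[b,s],
# screens all pairs by Mann-Whitney AUC, and greedily adds a second,
# gene-disjoint ratio to form a four-gene additive classifier
#     comb[a,b,c,d](s) = ratio[a,b](s) + ratio[c,d](s).

#' Log-ratio feature for a gene pair
#'
#' Computes the per-sample difference of log2 intensities between two
#' genes. On log2 scale this is the log fold-change between the genes
#' within each sample, so the feature is invariant to any per-sample
#' constant shift (e.g. global normalisation offsets).
#'
#' @param matrix Numeric log2 matrix, genes in rows, samples in columns.
#' @param gene_a,gene_b Gene identifiers (rows of `matrix`).
#' @return Named numeric vector, one value per sample; NA where either
#'   gene's value is missing.
#' @export
compute_ratio_feature <- function(matrix, gene_a, gene_b) {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(matrix)) .stopf("gene not in matrix: %s", g)
  }
  matrix[gene_a, ] - matrix[gene_b, ]
}

#' Rank genes by oriented univariate AUC
#'
#' Generic univariate prefilter that stands in front of the ratio screen:
#' each gene is scored by its case-vs-control Mann-Whitney AUC, oriented
#' so AUC >= 0.5, and the top `top_n` genes are returned. Ties are broken
#' by the absolute standardised mean difference, then lexicographic gene
#' id, so the ranking is deterministic.
#'
#' @inheritParams compute_ratio_feature
#' @param labels Cohort labels (data frame with `sample_id` and
#'   `class_label`, or an aligned vector); only case/control samples are
#'   admitted.
#' @param top_n Number of genes to retain; if larger than the gene count,
#'   all genes are returned with a warning.
#' @return Character vector of gene ids, best first.
#' @export
prefilter_genes <- function(matrix, labels, top_n) {
  cls <- .align_labels(labels, colnames(matrix))
  .check_class_labels(cls, allow_possible = FALSE)
  is_case <- cls == "case"
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    .stopf("need at least 2 samples per class")
  }
  stats_df <- .gene_stats(matrix, is_case)
  ord <- order(-stats_df$auc, -stats_df$smd, stats_df$gene)
  if (top_n > nrow(stats_df)) {
    .warnf("top_n (%d) exceeds gene count (%d); returning all genes",
           top_n, nrow(stats_df))
    top_n <- nrow(stats_df)
  }
  stats_df$gene[ord][seq_len(top_n)]
}

.gene_stats <- function(matrix, is_case) {
  auc <- apply(matrix, 1L, function(v) .auc(v[is_case], v[!is_case]))
  auc <- pmax(auc, 1 - auc)  # orientation
  m1 <- rowMeans(matrix[, is_case, drop = FALSE])
  m0 <- rowMeans(matrix[, !is_case, drop = FALSE])
  sdp <- apply(matrix, 1L, stats::sd)
  smd <- ifelse(sdp > 0, abs(m1 - m0) / sdp, 0)
  data.frame(gene = rownames(matrix), auc = auc, smd = smd,
             stringsAsFactors = FALSE)
}

#' Screen all two-gene ratios by AUC
#'
#' Evaluates every unordered gene pair in `gene_pool` once, orients each
#' ratio so that higher values associate with the case class (AUC >=
#' 0.5), and returns the ranked table. With a pool of p genes the table
#' has p(p-1)/2 rows. Ranking is by AUC descending with deterministic
#' tie-breaks (larger absolute standardised mean difference of the
#' oriented feature, then lexicographic gene ids). AUC is the empirical
#' Mann-Whitney estimate with midrank ties, which makes the ranking
#' invariant to the log base of the input.
#'
#' @inheritParams prefilter_genes
#' @param gene_pool Character vector of genes (subset of the matrix rows).
#' @return Data frame with columns `gene_a`, `gene_b` (oriented so the
#'   feature `gene_a - gene_b` has AUC >= 0.5), `auc` and `smd`, sorted
#'   best first.
#' @export
screen_all_ratios <- function(matrix, labels, gene_pool) {
  if (length(gene_pool) < 2L) .stopf("gene pool must contain at least 2 genes")
  missing <- setdiff(gene_pool, rownames(matrix))
  if (length(missing)) .stopf("genes not in matrix: %s", paste(utils::head(missing, 5L), collapse = ", "))
  cls <- .align_labels(labels, colnames(matrix))
  .check_class_labels(cls, allow_possible = FALSE)
  is_case <- cls == "case"
  if (!any(is_case) || !any(!is_case)) .stopf("both classes must be non-empty")

  pairs <- utils::combn(sort(gene_pool), 2L)
  n_pairs <- ncol(pairs)
  gene_a <- character(n_pairs); gene_b <- character(n_pairs)
  auc <- numeric(n_pairs); smd <- numeric(n_pairs)
  sub <- matrix[sort(gene_pool), , drop = FALSE]
  for (k in seq_len(n_pairs)) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    f <- sub[a, ] - sub[b, ]
    v <- .auc(f[is_case], f[!is_case])
    if (v < 0.5) { tmp <- a; a <- b; b <- tmp; f <- -f; v <- 1 - v }
    s <- stats::sd(f)
    gene_a[k] <- a; gene_b[k] <- b; auc[k] <- v
    smd[k] <- if (s > 0) abs(mean(f[is_case]) - mean(f[!is_case])) / s else 0
  }
  out <- data.frame(gene_a = gene_a, gene_b = gene_b, auc = auc, smd = smd,
                    stringsAsFactors = FALSE)
  out[order(-out$auc, -out$smd, out$gene_a, out$gene_b), , drop = FALSE]
}

#' Greedy search for the best additive ratio pair
#'
#' Seeds with the top-ranked ratio, then scans the top `pool_k` ranked
#' ratios for the partner whose addition maximises the AUC of the summed
#' score, under the constraint that the two ratios use four distinct
#' genes. If no admissible partner exists, or no partner improves on the
#' seed, a single-ratio classifier is returned with a warning.
#'
#' @inheritParams prefilter_genes
#' @param ranked_ratios Ranked ratio table from [screen_all_ratios()].
#' @param pool_k Number of top-ranked ratios scanned as candidate
#'   partners (default 100).
#' @return An object of class `ratio_classifier` with elements `ratio_1`,
#'   `ratio_2` (possibly NULL), `training_auc` and `gene_set`.
#' @export
greedy_pair_search <- function(matrix, labels, ranked_ratios, pool_k = 100L) {
  if (!nrow(ranked_ratios)) .stopf("ranked_ratios is empty")
  pool_k <- min(as.integer(pool_k), nrow(ranked_ratios))
  cls <- .align_labels(labels, colnames(matrix))
  .check_class_labels(cls, allow_possible = FALSE)
  is_case <- cls == "case"

  seed <- ranked_ratios[1L, ]
  f1 <- matrix[seed$gene_a, ] - matrix[seed$gene_b, ]
  best_auc <- seed$auc
  best_row <- NULL
  for (k in seq_len(pool_k)[-1L]) {
    cand <- ranked_ratios[k, ]
    if (length(intersect(c(seed$gene_a, seed$gene_b),
                         c(cand$gene_a, cand$gene_b)))) next
    f2 <- matrix[cand$gene_a, ] - matrix[cand$gene_b, ]
    a <- .auc((f1 + f2)[is_case], (f1 + f2)[!is_case])
    if (a > best_auc) { best_auc <- a; best_row <- cand }
  }
  ratio_1 <- list(gene_a = seed$gene_a, gene_b = seed$gene_b, auc = seed$auc)
  if (is.null(best_row)) {
    .warnf("no admissible partner ratio improved on the seed; returning a single-ratio classifier")
    return(structure(list(ratio_1 = ratio_1, ratio_2 = NULL,
                          training_auc = seed$auc,
                          gene_set = c(seed$gene_a, seed$gene_b)),
                     class = "ratio_classifier"))
  }
  structure(list(ratio_1 = ratio_1,
                 ratio_2 = list(gene_a = best_row$gene_a, gene_b = best_row$gene_b,
                                auc = best_row$auc),
                 training_auc = best_auc,
                 gene_set = c(seed$gene_a, seed$gene_b,
                              best_row$gene_a, best_row$gene_b)),
            class = "ratio_classifier")
}

#' @export
print.ratio_classifier <- function(x, ...) {
  cat("Additive ratio classifier\n")
  cat(sprintf("  ratio 1: %s - %s (AUC %.3f)\n",
              x$ratio_1$gene_a, x$ratio_1$gene_b, x$ratio_1$auc))
  if (!is.null(x$ratio_2)) {
    cat(sprintf("  ratio 2: %s - %s (AUC %.3f)\n",
                x$ratio_2$gene_a, x$ratio_2$gene_b, x$ratio_2$auc))
  }
  cat(sprintf("  training AUC: %.3f\n", x$training_auc))
  cat("  (training AUC is the greedy objective; it is not an unbiased\n")
  cat("   estimate of performance on independent samples)\n")
  invisible(x)
}

#' Score samples with a fitted ratio classifier
#'
#' The score of a sample is the sum of its oriented log-ratio features.
#' For the canonical four-gene panel this equals
#' `log2(PLAC8) - log2(PLA2G7) + log2(LAMP1) - log2(CEACAM4)`.
#'
#' @param classifier A `ratio_classifier`.
#' @inheritParams compute_ratio_feature
#' @return Named numeric score vector, one value per sample.
#' @export
apply_classifier <- function(classifier, matrix) {
  stopifnot(inherits(classifier, "ratio_classifier"))
  s <- compute_ratio_feature(matrix, classifier$ratio_1$gene_a, classifier$ratio_1$gene_b)
  if (!is.null(classifier$ratio_2)) {
    s <- s + compute_ratio_feature(matrix, classifier$ratio_2$gene_a, classifier$ratio_2$gene_b)
  }
  s
}

#' One-call discovery pipeline
#'
#' Convenience wrapper: univariate prefilter, exhaustive ratio screen over
#' the retained genes, then greedy pair search.
#'
#' @inheritParams prefilter_genes
#' @param top_n Genes kept by the prefilter (default 25).
#' @param pool_k Candidate-partner pool for the greedy step (default 100).
#' @return A `ratio_classifier`; the ranked ratio table is attached as
#'   attribute `"ranked_ratios"`.
#' @export
discover_classifier <- function(matrix, labels, top_n = 25L, pool_k = 100L) {
  pool <- prefilter_genes(matrix, labels, top_n)
  ranked <- screen_all_ratios(matrix, labels, pool)
  clf <- greedy_pair_search(matrix, labels, ranked, pool_k)
  attr(clf, "ranked_ratios") <- ranked
  clf
}

#' Two-sample differential-expression filter
#'
#' Flags genes differentially expressed between two individual samples:
#' both linear-scale intensities must exceed 100 units and the fold
#' change must exceed 2.0 in either direction.
#'
#' @inheritParams compute_ratio_feature
#' @param sample_x,sample_y Sample identifiers (columns of `matrix`).
#' @param scale `"log2"` (default; intensities are 2^value) or
#'   `"linear"`.
#' @return Character vector of gene ids passing both rules.
#' @export
differential_expression_filter <- function(matrix, sample_x, sample_y,
                                           scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  for (s in c(sample_x, sample_y)) {
    if (!s %in% colnames(matrix)) .stopf("sample not in matrix: %s", s)
  }
  x <- matrix[, sample_x]
  y <- matrix[, sample_y]
  if (scale == "log2") { x <- 2^x; y <- 2^y }
  keep <- x > 100 & y > 100 & pmax(x / y, y / x) > 2.0
  rownames(matrix)[which(keep)]
}
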