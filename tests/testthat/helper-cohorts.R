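# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no stored data.

# Two-class score vectors with a Gaussian location shift of `d` SD.
make_scores <- function(n1, n0, d = 0, seed = 1) {
  withr::with_seed(seed, {
    list(cases = stats::rnorm(n1, d), controls = stats::rnorm(n0))
  })
}

# Labels vector helper.
cc_labels <- function(n1, n0) rep(c("case", "control"), c(n1, n0))

# Exhaustive pair-counting AUC oracle: concordant pairs + half ties.
pair_count_auc <- function(cases, controls) {
  conc <- 0
  for (x in cases) for (y in controls) {
    conc <- conc + (x > y) + 0.5 * (x == y)
  }
  conc / (length(cases) * length(controls))
}

# Small expression matrix with named genes/samples.
toy_matrix <- function(values, genes, samples) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  attr(m, "scale") <- "log2"
  m
}

# Ct table row(s) in canonical column order.
make_ct <- function(plac8, pla2g7, lamp1, ceacam4,
                    sample_id = sprintf("s%d", seq_along(plac8)),
                    platform_id = NA_character_) {
  data.frame(sample_id = sample_id, ct_plac8 = plac8, ct_pla2g7 = pla2g7,
             ct_lamp1 = lamp1, ct_ceacam4 = ceacam4,
             platform_id = platform_id, stringsAsFactors = FALSE)
}

# Binary-call vectors realising exact 2x2 counts.
make_calls <- function(tp, fn, fp, tn) {
  list(calls = c(rep("positive", tp), rep("negative", fn),
                 rep("positive", fp), rep("negative", tn)),
       labels = cc_labels(tp + fn, fp + tn))
}

# Score/label pair realising exact per-band counts for the default edges;
# band i gets all its samples at `at[i]`.
banded_cohort <- function(case_counts, ctrl_counts, at = c(2, 5, 7, 10)) {
  scores <- c(rep(at, case_counts), rep(at, ctrl_counts))
  labels <- cc_labels(sum(case_counts), sum(ctrl_counts))
  list(scores = scores, labels = labels)
}
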