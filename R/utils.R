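# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
# Mann-Whitney AUC with midrank tie handling: P(case > control) + 0.5 P(tie).
.auc <- function(cases, controls) {
  n1 <- length(cases)
  n0 <- length(controls)
  if (n1 == 0L || n0 == 0L) .stopf("AUC needs at least one score in each class")
  r <- rank(c(cases, controls), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Normalise a labels argument into a character vector of class labels aligned
# to `sample_ids`. Accepts a data frame with sample_id/class_label columns or
# a plain vector already aligned to the samples.
.align_labels <- function(labels, sample_ids) {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "class_label") %in% names(labels))) {
      .stopf("a labels data frame needs 'sample_id' and 'class_label' columns")
    }
    idx <- match(sample_ids, labels$sample_id)
    if (anyNA(idx)) {
      .stopf(
        "samples missing from labels: %s",
        paste(utils::head(sample_ids[is.na(idx)], 5L), collapse = ", ")
      )
    }
    return(as.character(labels$class_label[idx]))
  }
  labels <- as.character(labels)
  if (length(labels) != length(sample_ids)) {
    .stopf("labels length (%d) does not match sample count (%d)",
           length(labels), length(sample_ids))
  }
  labels
}

.check_class_labels <- function(cls, allow_possible = TRUE) {
  allowed <- c("case", "control", if (allow_possible) "possible")
  bad <- setdiff(unique(cls), allowed)
  if (length(bad)) {
    .stopf("unknown class labels: %s (allowed: %s)",
           paste(bad, collapse = ", "), paste(allowed, collapse = ", "))
  }
  invisible(cls)
}

# Split a score vector into case / control groups, refusing "possible".
.split_scores <- function(scores, labels, sample_ids = names(scores)) {
  cls <- .align_labels(labels, sample_ids %||% seq_along(scores))
  .check_class_labels(cls, allow_possible = FALSE)
  if (!any(cls == "case") || !any(cls == "control")) {
    .stopf("both classes must be non-empty (got %d cases, %d controls)",
           sum(cls == "case"), sum(cls == "control"))
  }
  list(cases = scores[cls == "case"], controls = scores[cls == "control"])
}

# Wilson score interval for a binomial proportion.
.wilson_ci <- function(x, n, conf.level = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}
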