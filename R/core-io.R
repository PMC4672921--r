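#' Read a log2 expression matrix from delimited text
#'
#' Reads a genes x samples (or samples x genes) table of log2-scale
#' intensities. The delimiter is auto-detected between tab and comma, and
#' identifiers are treated case-sensitively. Duplicate gene or sample
#' identifiers and non-numeric cells are hard errors, because downstream
#' ratio features index the matrix by name.
#'
#' @param path Path to a TSV/CSV file whose first column holds gene
#'   identifiers (or sample identifiers when `genes_in_rows = FALSE`) and
#'   whose header row holds the other dimension's identifiers.
#' @param genes_in_rows Logical; `TRUE` (default) when genes are rows.
#' @param input_scale Either `"log2"` (default; values stored as-is) or
#'   `"linear"`, in which case strictly positive intensities are converted
#'   to log2 on read. Ratio features require log-scale intensities.
#' @return A numeric matrix, genes in rows, with a `"scale"` attribute of
#'   `"log2"`.
#' @seealso [write_expression_matrix()], [compute_ratio_feature()]
#' @export
read_expression_matrix <- function(path, genes_in_rows = TRUE,
                                   input_scale = c("log2", "linear")) {
  input_scale <- match.arg(input_scale)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  sep <- .detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (ncol(raw) < 2L) .stopf("expected an identifier column plus a numeric body in %s", path)
  ids <- as.character(raw[[1L]])
  other <- colnames(raw)[-1L]
  .check_unique(ids, "row identifier")
  .check_unique(other, "column identifier")
  body <- raw[, -1L, drop = FALSE]
  mat <- matrix(NA_real_, nrow(body), ncol(body), dimnames = list(ids, other))
  for (j in seq_len(ncol(body))) {
    col <- body[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & trimws(as.character(col)) != "")
    if (length(bad)) {
      .stopf("non-numeric value '%s' at row '%s', column '%s' in %s",
             col[bad[1L]], ids[bad[1L]], other[j], path)
    }
    mat[, j] <- num
  }
  if (!genes_in_rows) mat <- t(mat)
  if (input_scale == "linear") {
    if (any(mat <= 0, na.rm = TRUE)) {
      .stopf("linear-scale input must be strictly positive for log2 conversion")
    }
    mat <- log2(mat)
  }
  attr(mat, "scale") <- "log2"
  message(sprintf("read expression matrix: %d genes x %d samples", nrow(mat), ncol(mat)))
  mat
}

#' Write an expression matrix to tab-delimited text
#'
#' Inverse of [read_expression_matrix()]; values round-trip to within
#' formatting precision (re-parse error below 1e-12).
#'
#' @param x Numeric matrix, genes in rows, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    .stopf("matrix must carry gene (row) and sample (column) names")
  }
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a four-gene Ct table
#'
#' Reads per-sample threshold-cycle (Ct) values for the PLAC8, PLA2G7,
#' LAMP1 and CEACAM4 assays. Ct values must lie in (0, 50]; missing cells
#' are permitted and flag the panel incomplete (they are never imputed).
#'
#' @param path Delimited text with columns `sample_id`, `ct_plac8`,
#'   `ct_pla2g7`, `ct_lamp1`, `ct_ceacam4` and optionally `platform_id`.
#' @return A data frame, one row per sample, with the five required
#'   columns plus `platform_id` (NA when absent) and a logical `complete`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  sep <- .detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  names(raw) <- tolower(names(raw))
  required <- c("sample_id", "ct_plac8", "ct_pla2g7", "ct_lamp1", "ct_ceacam4")
  missing <- setdiff(required, names(raw))
  if (length(missing)) .stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  ct <- raw[, required, drop = FALSE]
  ct$sample_id <- as.character(ct$sample_id)
  .check_unique(ct$sample_id, "sample_id")
  for (col in required[-1L]) {
    v <- suppressWarnings(as.numeric(ct[[col]]))
    out <- which(!is.na(v) & (v <= 0 | v > 50))
    if (length(out)) {
      .stopf("Ct value %s out of admissible range (0, 50] in column %s, sample %s",
             v[out[1L]], col, ct$sample_id[out[1L]])
    }
    ct[[col]] <- v
  }
  ct$platform_id <- if ("platform_id" %in% names(raw)) as.character(raw$platform_id) else NA_character_
  ct$complete <- stats::complete.cases(ct[, required[-1L]])
  if (any(!ct$complete)) {
    message(sprintf("%d of %d Ct panels incomplete (missing Ct values flagged, not imputed)",
                    sum(!ct$complete), nrow(ct)))
  }
  ct
}

#' Read cohort labels and clinical covariates
#'
#' @param path Delimited text with columns `sample_id`, `class_label`
#'   (one of case / control / possible) and any number of additional
#'   covariate columns (numeric covariates are converted; others kept as
#'   character).
#' @return Data frame with `sample_id`, `class_label`, covariates.
#' @export
read_cohort_labels <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (!all(c("sample_id", "class_label") %in% names(df))) {
    .stopf("labels file needs 'sample_id' and 'class_label' columns")
  }
  df$sample_id <- as.character(df$sample_id)
  .check_unique(df$sample_id, "sample_id")
  df$class_label <- as.character(df$class_label)
  .check_class_labels(df$class_label)
  tab <- table(df$class_label)
  message(sprintf("read labels: %s", paste(names(tab), tab, sep = "=", collapse = ", ")))
  df
}

#' RNA quality-control gate
#'
#' Partitions RNA extraction records into pass/fail using the acceptance
#' rules of the assay workflow: for RT-qPCR, yield >= 2 ng/ul (boundary
#' inclusive); for microarray profiling, A260/A280 ratio > 1.6 and RNA
#' integrity score > 5 (both strict). Records lacking a field needed by
#' the chosen mode fail with reason "insufficient QC data".
#'
#' @param records Data frame with `sample_id` plus `yield_ng_per_ul`
#'   (rtqpcr mode) or `a260_a280_ratio` and `integrity_score` (microarray
#'   mode). Values must be non-negative.
#' @param mode `"rtqpcr"` or `"microarray"`.
#' @return List with data frames `pass` and `fail`; `fail` carries a
#'   `reason` column naming the violated rule. The partition is exhaustive
#'   and disjoint.
#' @export
qc_filter_rna <- function(records, mode = c("rtqpcr", "microarray")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records), "sample_id" %in% names(records))
  num_cols <- intersect(c("yield_ng_per_ul", "a260_a280_ratio", "integrity_score"),
                        names(records))
  for (col in num_cols) {
    if (any(records[[col]] < 0, na.rm = TRUE)) .stopf("negative value in %s", col)
  }
  reason <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    if (mode == "rtqpcr") {
      y <- if ("yield_ng_per_ul" %in% names(records)) records$yield_ng_per_ul[i] else NA_real_
      reason[i] <- if (is.na(y)) "insufficient QC data"
        else if (y >= 2) "" else "yield < 2 ng/ul"
    } else {
      r <- if ("a260_a280_ratio" %in% names(records)) records$a260_a280_ratio[i] else NA_real_
      q <- if ("integrity_score" %in% names(records)) records$integrity_score[i] else NA_real_
      reason[i] <- if (is.na(r) || is.na(q)) "insufficient QC data"
        else if (!(r > 1.6)) "A260/A280 ratio not > 1.6"
        else if (!(q > 5)) "RNA integrity not > 5"
        else ""
    }
  }
  fail <- records[reason != "", , drop = FALSE]
  fail$reason <- reason[reason != ""]
  list(pass = records[reason == "", , drop = FALSE], fail = fail)
}

#' Assay configuration
#'
#' Holds the tunable constants of the scoring and evaluation pipeline:
#' the binary cutoff (default 3.100 score units, boundary assigned to the
#' positive class), the band edges (default 4, 6, 9), the pre-test sepsis
#' probability (default 0.30, the ICU prevalence the banding was
#' calibrated against), per-platform affine shifts onto the reference
#' RT-qPCR chemistry, and resampling controls.
#'
#' @param cutoff Score cutoff for the binary call; `score >= cutoff` is
#'   positive.
#' @param band_edges Strictly increasing numeric vector of band edges.
#' @param pretest_probability Pre-test probability in (0, 1).
#' @param platform_shifts Named list of `c(offset, slope)` pairs mapping a
#'   platform's scores onto the reference platform (`"asuragen"` and
#'   `"identity"` are implicitly the identity map).
#' @param bootstrap_reps,permutation_reps Resampling replicate counts
#'   (>= 1).
#' @param global_seed Integer seed driving all randomised procedures.
#' @return An object of class `assay_config`.
#' @export
assay_config <- function(cutoff = 3.100, band_edges = c(4, 6, 9),
                         pretest_probability = 0.30,
                         platform_shifts = list(),
                         bootstrap_reps = 2000L, permutation_reps = 2000L,
                         global_seed = 1L) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  if (length(band_edges) < 1L || any(diff(band_edges) <= 0)) {
    .stopf("band_edges must be strictly increasing")
  }
  if (!(pretest_probability > 0 && pretest_probability < 1)) {
    .stopf("pretest_probability must lie in (0, 1)")
  }
  if (bootstrap_reps < 1L || permutation_reps < 1L) .stopf("replicate counts must be >= 1")
  for (p in platform_shifts) {
    if (length(p) != 2L || !is.numeric(p)) .stopf("each platform shift is c(offset, slope)")
  }
  structure(
    list(cutoff = cutoff, band_edges = as.numeric(band_edges),
         pretest_probability = pretest_probability,
         platform_shifts = platform_shifts,
         bootstrap_reps = as.integer(bootstrap_reps),
         permutation_reps = as.integer(permutation_reps),
         global_seed = as.integer(global_seed)),
    class = "assay_config"
  )
}

#' @export
print.assay_config <- function(x, ...) {
  cat("Assay configuration\n")
  cat(sprintf("  cutoff: %.3f (score >= cutoff is positive)\n", x$cutoff))
  cat(sprintf("  band edges: %s\n", paste(x$band_edges, collapse = ", ")))
  cat(sprintf("  pre-test probability: %.2f\n", x$pretest_probability))
  cat(sprintf("  platform shifts: %s\n",
              if (length(x$platform_shifts)) paste(names(x$platform_shifts), collapse = ", ")
              else "(identity only)"))
  cat(sprintf("  bootstrap reps: %d, permutation reps: %d, seed: %d\n",
              x$bootstrap_reps, x$permutation_reps, x$global_seed))
  invisible(x)
}

#' Read an assay configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys match
#'   the arguments of [assay_config()].
#' @return An `assay_config` object.
#' @export
read_assay_config <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$platform_shifts)) {
    cfg$platform_shifts <- lapply(cfg$platform_shifts, function(p) as.numeric(unlist(p)))
  }
  do.call(assay_config, cfg[intersect(names(cfg), names(formals(assay_config)))])
}

#' Cohort accounting summary
#'
#' Counts samples per class and reports the sepsis prevalence among
#' samples of known status, i.e. cases / (cases + controls) after
#' excluding the diagnostically ambiguous "possible" group. This is the
#' accounting used when a banding table's pre-test probability is equated
#' to the observed prevalence.
#'
#' @param labels Data frame with `class_label`, or a character vector.
#' @return List with `n_case`, `n_control`, `n_possible`, `n_known` and
#'   `prevalence`.
#' @export
cohort_summary <- function(labels) {
  cls <- if (is.data.frame(labels)) as.character(labels$class_label) else as.character(labels)
  .check_class_labels(cls)
  n_case <- sum(cls == "case")
  n_control <- sum(cls == "control")
  n_possible <- sum(cls == "possible")
  n_known <- n_case + n_control
  if (n_known == 0L) .stopf("no samples with known status")
  structure(list(n_case = n_case, n_control = n_control,
                 n_possible = n_possible, n_known = n_known,
                 prevalence = n_case / n_known),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort: %d cases, %d controls (%d 'possible' excluded)\n",
              x$n_case, x$n_control, x$n_possible))
  cat(sprintf("prevalence among known status: %.1f%%\n", 100 * x$prevalence))
  invisible(x)
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

.check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    .stopf("duplicate %ss: %s", what, paste(utils::head(dup, 5L), collapse = ", "))
  }
  invisible(ids)
}
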