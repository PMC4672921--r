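# Ct-based scoring of the four-gene panel. RT-qPCR threshold cycles are
# inversely related to log2 transcript abundance, so the RT-qPCR score is
# the sign-flipped analogue of the expression-ratio classifier:
#     score = -Ct(PLAC8) + Ct(PLA2G7) - Ct(LAMP1) + Ct(CEACAM4)
# with all coefficients fixed at +/-1. Higher scores indicate a higher
# probability of sepsis.

#' Compute the quantitative score from Ct values
#'
#' @param ct Data frame as returned by [read_ct_table()] (columns
#'   `sample_id`, `ct_plac8`, `ct_pla2g7`, `ct_lamp1`, `ct_ceacam4`).
#' @return Named numeric vector of scores; NA for any sample with a
#'   missing Ct value (samples are flagged, never imputed).
#' @export
compute_septiscore <- function(ct) {
  required <- c("ct_plac8", "ct_pla2g7", "ct_lamp1", "ct_ceacam4")
  missing <- setdiff(required, names(ct))
  if (length(missing)) .stopf("missing Ct column(s): %s", paste(missing, collapse = ", "))
  s <- -ct$ct_plac8 + ct$ct_pla2g7 - ct$ct_lamp1 + ct$ct_ceacam4
  names(s) <- if ("sample_id" %in% names(ct)) ct$sample_id else NULL
  if (anyNA(s)) {
    message(sprintf("%d sample(s) without a score (missing Ct values)", sum(is.na(s))))
  }
  s
}

#' Harmonise a score across RT-qPCR platforms
#'
#' Applies the affine shift `offset + slope * score` registered for
#' `platform_id` in the configuration, mapping scores onto the reference
#' chemistry ("asuragen"). Platforms `"asuragen"` and `"identity"`, and a
#' missing platform id, are the identity map; any other unregistered
#' platform is an error listing the registered platforms.
#'
#' @param score Numeric score(s).
#' @param platform_id Platform identifier (scalar).
#' @param config An [assay_config()].
#' @return Adjusted score(s).
#' @export
adjust_platform <- function(score, platform_id, config = assay_config()) {
  if (is.null(platform_id) || is.na(platform_id) ||
      platform_id %in% c("asuragen", "identity")) {
    return(score)
  }
  shift <- config$platform_shifts[[platform_id]]
  if (is.null(shift)) {
    .stopf("unknown platform '%s'; registered: %s", platform_id,
           paste(c("asuragen", "identity", names(config$platform_shifts)),
                 collapse = ", "))
  }
  shift[1L] + shift[2L] * score
}

#' Band labels for a set of edges
#' @param band_edges Strictly increasing numeric vector.
#' @return Character vector of length `length(band_edges) + 1`.
#' @export
band_labels <- function(band_edges = c(4, 6, 9)) {
  k <- length(band_edges)
  c(paste0("<", band_edges[1L]),
    if (k > 1L) paste0(band_edges[-k], "-", band_edges[-1L]),
    paste0(">", band_edges[k]))
}

#' Assign a score to its band
#'
#' Bands are half-open on the right: with the default edges the bands are
#' (-Inf, 4), \[4, 6), \[6, 9) and \[9, Inf), labelled `<4`, `4-6`, `6-9`
#' and `>9`. The half-open convention makes the bands a partition; a
#' score exactly at an edge falls in the upper band (so 6.0 is `6-9` and
#' 9.0 is `>9`).
#'
#' @param score Numeric score(s); must be finite.
#' @inheritParams band_labels
#' @return Factor of band labels with levels in band order.
#' @export
assign_band <- function(score, band_edges = c(4, 6, 9)) {
  if (any(diff(band_edges) <= 0)) .stopf("band_edges must be strictly increasing")
  if (any(!is.finite(score))) .stopf("cannot band a non-finite score")
  labs <- band_labels(band_edges)
  factor(labs[findInterval(score, band_edges) + 1L], levels = labs)
}

#' Binary call at a score cutoff
#'
#' The boundary is assigned to the positive class (`score >= cutoff` is
#' positive): the cutoff is chosen to bias toward sensitivity, so ties go
#' to the call that avoids false negatives.
#'
#' @param score Finite numeric score(s).
#' @param cutoff Score cutoff (default 3.100).
#' @return Character vector, `"positive"` / `"negative"`.
#' @export
binary_call <- function(score, cutoff = 3.100) {
  if (any(!is.finite(score))) .stopf("cannot call a non-finite score")
  ifelse(score >= cutoff, "positive", "negative")
}

#' Post-test probability from a likelihood ratio
#'
#' Bayes on the odds scale: posterior odds = pre-test odds x LR, then
#' converted back to a probability. An infinite LR returns 1 and LR = 0
#' returns 0.
#'
#' @param pretest Pre-test probability in (0, 1).
#' @param lr Non-negative likelihood ratio(s); `Inf` allowed.
#' @return Post-test probability in \[0, 1\].
#' @export
post_test_probability <- function(pretest, lr) {
  if (!(pretest > 0 && pretest < 1)) .stopf("pretest must lie in (0, 1)")
  if (any(lr < 0, na.rm = TRUE)) .stopf("likelihood ratios must be non-negative")
  odds <- pretest / (1 - pretest) * lr
  ifelse(is.infinite(lr), 1, odds / (1 + odds))
}

#' Score-band likelihood-ratio table
#'
#' Cross-tabulates case and control scores over the score bands and
#' derives, per band: the per-class fractions, the fraction of all
#' patients, the diagnostic likelihood ratio
#' `LR = (cases in band / total cases) / (controls in band / total controls)`,
#' and the post-test probability at the supplied pre-test probability.
#' Point estimates use the raw per-class fractions with no continuity
#' correction, so a band with cases but no controls has LR `Inf`
#' (post-test probability 1) and a band with controls but no cases has
#' LR 0.
#'
#' @param scores Numeric score vector (named, or aligned with `labels`).
#' @param labels Cohort labels (case/control only).
#' @inheritParams band_labels
#' @param pretest Pre-test probability (default 0.30).
#' @return Data frame of class `score_band_table` with one row per band;
#'   totals are attached as attributes `n_cases` / `n_controls`.
#' @export
band_table <- function(scores, labels, band_edges = c(4, 6, 9), pretest = 0.30) {
  grp <- .split_scores(scores, labels)
  n1 <- length(grp$cases); n0 <- length(grp$controls)
  bands <- band_labels(band_edges)
  case_n <- table(assign_band(grp$cases, band_edges))
  ctrl_n <- table(assign_band(grp$controls, band_edges))
  fc <- as.numeric(case_n) / n1
  f0 <- as.numeric(ctrl_n) / n0
  lr <- fc / f0
  out <- data.frame(
    band = bands,
    n_controls = as.integer(ctrl_n),
    n_cases = as.integer(case_n),
    fraction_of_all = (as.numeric(ctrl_n) + as.numeric(case_n)) / (n0 + n1),
    fraction_of_controls = f0,
    fraction_of_cases = fc,
    likelihood_ratio = lr,
    post_test_probability = post_test_probability(pretest, ifelse(is.nan(lr), NA_real_, lr)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_cases") <- n1
  attr(out, "n_controls") <- n0
  attr(out, "pretest") <- pretest
  class(out) <- c("score_band_table", "data.frame")
  out
}

#' @export
print.score_band_table <- function(x, digits = 3L, ...) {
  cat(sprintf("Score band table (%d cases, %d controls; pre-test %.2f)\n",
              attr(x, "n_cases"), attr(x, "n_controls"), attr(x, "pretest")))
  print.data.frame(cbind(x[1:3],
                         round(x[4:8], digits)), row.names = FALSE)
  invisible(x)
}

#' Score, band and call a cohort of Ct panels
#'
#' Full per-sample scoring pipeline: compute the score from the four Ct
#' values, apply the platform shift onto the reference chemistry, assign
#' the band and make the binary call. Samples with missing Ct values get
#' NA score and no call. Scores are reported to 3 decimal places,
#' matching the precision of the cutoff.
#'
#' @param ct Ct table from [read_ct_table()].
#' @param config An [assay_config()].
#' @return Data frame with `sample_id`, `septiscore`, `band`,
#'   `binary_call`, `platform_adjusted`.
#' @export
score_samples <- function(ct, config = assay_config()) {
  s <- compute_septiscore(ct)
  platform <- if ("platform_id" %in% names(ct)) ct$platform_id else rep(NA_character_, nrow(ct))
  adjusted <- logical(nrow(ct))
  for (i in seq_len(nrow(ct))) {
    if (!is.na(s[i])) {
      s[i] <- adjust_platform(s[[i]], platform[i], config)
      adjusted[i] <- !(is.na(platform[i]) || platform[i] %in% c("asuragen", "identity"))
    }
  }
  ok <- !is.na(s)
  band <- rep(NA_character_, nrow(ct))
  call <- rep(NA_character_, nrow(ct))
  band[ok] <- as.character(assign_band(s[ok], config$band_edges))
  call[ok] <- binary_call(s[ok], config$cutoff)
  data.frame(sample_id = ct$sample_id,
             septiscore = round(as.numeric(s), 3L),
             band = band, binary_call = call,
             platform_adjusted = adjusted,
             stringsAsFactors = FALSE)
}
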