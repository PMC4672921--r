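# Seeded generators for discovery-like expression cohorts, validation-like
# Ct cohorts and clinical covariates. The generative model is the simplest
# one consistent with what the ratio-classifier method assumes: Gaussian
# log2 expression with a four-gene signature (two genes shifted up in
# cases, two shifted down) on a null background, and threshold cycles
# inversely related to log2 expression, Ct = alpha - beta * log2(I).

#' Simulation specification
#'
#' Bundles the parameters of the synthetic cohort generators. Defaults
#' mirror a discovery-style cohort: 74 cases vs 31 controls, a four-gene
#' signature named after the canonical panel with effects of +/-1.5
#' noise-SD on log2 scale (PLAC8 and LAMP1 up-regulated in cases, PLA2G7
#' and CEACAM4 down-regulated), and a Ct map with alpha = 30, beta = 1
#' and Ct noise 0.25 cycles.
#'
#' @param n_cases,n_controls,n_possible Sample counts per class.
#' @param n_genes Total gene count (signature plus null background).
#' @param signature Named numeric vector of four per-gene effect sizes in
#'   log2 units (positive = up in cases); names are gene ids.
#' @param noise_sd Log2-scale noise SD shared by all genes (>= 0).
#' @param baseline Background mean log2 intensity.
#' @param ct_alpha,ct_beta Parameters of the inverse map
#'   `Ct = ct_alpha - ct_beta * log2(I)`; `ct_beta > 0`.
#' @param ct_noise_sd Ct measurement noise SD in cycles (>= 0).
#' @param possible_case_weight Probability that a "possible" sample is
#'   drawn from the case score distribution. The default (`NULL`) uses
#'   the case prevalence among known-status samples, which makes the
#'   "possible" score distribution coincide with the pooled known-status
#'   distribution by construction.
#' @param covariate_effects Named numeric vector of covariate effect
#'   sizes in SD units (case minus control mean, standardised scale).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_cases = 74L, n_controls = 31L, n_possible = 0L,
                     n_genes = 200L,
                     signature = c(PLAC8 = 1.5, LAMP1 = 1.5,
                                   PLA2G7 = -1.5, CEACAM4 = -1.5),
                     noise_sd = 1, baseline = 8,
                     ct_alpha = 30, ct_beta = 1, ct_noise_sd = 0.25,
                     possible_case_weight = NULL,
                     covariate_effects = c(pct = 1.2, apache_iv = 0.4),
                     seed = 1L) {
  stopifnot(n_cases >= 1L, n_controls >= 1L, n_possible >= 0L,
            noise_sd >= 0, ct_noise_sd >= 0, ct_beta > 0)
  if (length(signature)) {
    if (length(signature) != 4L || is.null(names(signature))) {
      .stopf("signature must be four named per-gene effect sizes")
    }
    if (n_genes < 4L) .stopf("n_genes must be >= 4 when a signature is requested")
    if (sum(signature > 0) != 2L || sum(signature < 0) != 2L) {
      .stopf("signature needs two up-regulated and two down-regulated genes")
    }
  }
  if (!is.null(possible_case_weight)) {
    stopifnot(possible_case_weight >= 0, possible_case_weight <= 1)
  }
  structure(list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 n_possible = as.integer(n_possible), n_genes = as.integer(n_genes),
                 signature = signature, noise_sd = noise_sd, baseline = baseline,
                 ct_alpha = ct_alpha, ct_beta = ct_beta, ct_noise_sd = ct_noise_sd,
                 possible_case_weight = possible_case_weight,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

.sim_expression <- function(spec, is_case, sample_ids) {
  n <- length(is_case)
  sig_genes <- names(spec$signature)
  bg <- max(spec$n_genes - length(sig_genes), 0L)
  genes <- c(sig_genes, if (bg) sprintf("G%04d", seq_len(bg)))
  mat <- matrix(stats::rnorm(length(genes) * n, spec$baseline, spec$noise_sd),
                nrow = length(genes), dimnames = list(genes, sample_ids))
  for (g in sig_genes) {
    mat[g, is_case] <- mat[g, is_case] + spec$signature[[g]]
  }
  attr(mat, "scale") <- "log2"
  mat
}

#' Generate a discovery-like labelled expression cohort
#'
#' Background genes are Normal(baseline, noise_sd) identically in both
#' classes; signature genes are additionally shifted by their effect
#' sizes in cases. Deterministic given `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @return List with `matrix` (log2, genes x samples) and `labels`
#'   (data frame with `sample_id`, `class_label`).
#' @export
generate_expression_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  is_case <- rep(c(TRUE, FALSE), c(spec$n_cases, spec$n_controls))
  ids <- c(sprintf("case_%03d", seq_len(spec$n_cases)),
           sprintf("ctrl_%03d", seq_len(spec$n_controls)))
  mat <- withr::with_seed(spec$seed, .sim_expression(spec, is_case, ids))
  list(matrix = mat,
       labels = data.frame(sample_id = ids,
                           class_label = ifelse(is_case, "case", "control"),
                           stringsAsFactors = FALSE))
}

#' Convert log2 expression of the four panel genes to Ct values
#'
#' Applies the inverse relationship between microarray intensity and
#' threshold cycle, `Ct = alpha - beta * log2(I) + Normal(0, ct_noise_sd)`,
#' to the four canonical panel genes and clips the result to (0, 50]
#' (clipping is reported). Noise is seeded from `spec$seed + 1` so the
#' expression draw and the Ct noise are independent streams.
#'
#' @param matrix Log2 expression matrix containing rows PLAC8, PLA2G7,
#'   LAMP1, CEACAM4.
#' @param spec A [sim_spec()].
#' @return A Ct table data frame matching [read_ct_table()] output.
#' @export
expression_to_ct <- function(matrix, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  panel <- c("PLAC8", "PLA2G7", "LAMP1", "CEACAM4")
  missing <- setdiff(panel, rownames(matrix))
  if (length(missing)) .stopf("matrix lacks panel gene(s): %s", paste(missing, collapse = ", "))
  n <- ncol(matrix)
  ct <- withr::with_seed(spec$seed + 1L, {
    vapply(panel, function(g) {
      spec$ct_alpha - spec$ct_beta * matrix[g, ] +
        stats::rnorm(n, 0, spec$ct_noise_sd)
    }, numeric(n))
  })
  if (n == 1L) ct <- matrix(ct, nrow = 1L, dimnames = list(NULL, panel))
  clipped <- sum(ct <= 0 | ct > 50)
  if (clipped) {
    message(sprintf("%d Ct value(s) clipped into (0, 50]", clipped))
    ct <- pmin(pmax(ct, 0.01), 50)
  }
  out <- data.frame(sample_id = colnames(matrix),
                    ct_plac8 = ct[, "PLAC8"], ct_pla2g7 = ct[, "PLA2G7"],
                    ct_lamp1 = ct[, "LAMP1"], ct_ceacam4 = ct[, "CEACAM4"],
                    platform_id = "asuragen",
                    stringsAsFactors = FALSE)
  out$complete <- stats::complete.cases(out[, 2:5])
  out
}

#' Generate a validation-like Ct cohort with "possible" samples
#'
#' Draws case, control and diagnostically ambiguous "possible" samples;
#' each "possible" sample is generated from the case model with
#' probability `possible_case_weight` (default: the case prevalence
#' among known-status samples, so the "possible" score distribution
#' matches the pooled known-status distribution) and from the control
#' model otherwise. Expression is converted to Ct values via the inverse
#' map, and clinical covariates (a procalcitonin-like marker and a
#' severity-score-like covariate by default) are generated on a
#' standardised scale with the configured class effects.
#'
#' @param spec A [sim_spec()].
#' @return List with `ct` (Ct table), `labels` (including "possible") and
#'   `covariates` (data frame, rows aligned with `labels`).
#' @export
generate_validation_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n_known <- spec$n_cases + spec$n_controls
  w <- spec$possible_case_weight %||% (spec$n_cases / n_known)
  cls <- rep(c("case", "control", "possible"),
             c(spec$n_cases, spec$n_controls, spec$n_possible))
  ids <- sprintf("v_%03d", seq_along(cls))
  out <- withr::with_seed(spec$seed, {
    latent_case <- cls == "case"
    if (spec$n_possible) {
      latent_case[cls == "possible"] <- stats::runif(spec$n_possible) < w
    }
    mat <- .sim_expression(spec, latent_case, ids)
    covs <- lapply(spec$covariate_effects, function(eff) {
      stats::rnorm(length(cls)) + eff * latent_case
    })
    list(mat = mat, covs = covs)
  })
  ct <- expression_to_ct(out$mat, spec)
  covariates <- data.frame(sample_id = ids, out$covs, stringsAsFactors = FALSE)
  list(ct = ct,
       labels = data.frame(sample_id = ids, class_label = cls,
                           stringsAsFactors = FALSE),
       covariates = covariates)
}
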