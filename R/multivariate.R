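# Forward greedy logistic combination of clinical parameters with
# repeated (default 50 x 2) cross-validated AUC as the selection
# objective. Logistic fits carry a tiny fixed ridge penalty purely to
# stay defined under separation, which is frequent in half-splits of
# small cohorts.

.labels_to_y <- function(labels, ids) {
  cls <- .align_labels(labels, ids)
  .check_class_labels(cls, allow_possible = FALSE)
  as.integer(cls == "case")
}

# IRLS for ridge-penalised logistic regression; X already standardized,
# intercept unpenalised.
.fit_logistic_ridge <- function(X, y, lambda = 1e-6, maxit = 100L, tol = 1e-8) {
  p <- ncol(X)
  Xd <- cbind(1, X)
  beta <- numeric(p + 1L)
  pen <- diag(c(0, rep(lambda, p)), p + 1L)
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    zz <- eta + (y - mu) / w
    bnew <- drop(solve(crossprod(Xd * w, Xd) + pen, crossprod(Xd * w, zz)))
    done <- max(abs(bnew - beta)) < tol
    beta <- bnew
    if (done) break
  }
  beta
}

# Train on a covariate data frame: median-impute and z-score using
# training statistics only; returns a linear-predictor function.
.train_logistic <- function(covariates, y, params, lambda = 1e-6) {
  X <- as.matrix(covariates[, params, drop = FALSE])
  med <- apply(X, 2L, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- med[j]
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  beta <- .fit_logistic_ridge(Xs, y, lambda)
  function(newdata) {
    Xn <- as.matrix(newdata[, params, drop = FALSE])
    for (j in seq_len(ncol(Xn))) Xn[is.na(Xn[, j]), j] <- med[j]
    Xn <- sweep(sweep(Xn, 2L, mu), 2L, sdv, "/")
    drop(cbind(1, Xn) %*% beta)
  }
}

# Stratified 1:1 train/test splits, one list element per repeat.
.make_splits <- function(y, n_repeats, seed) {
  idx1 <- which(y == 1L)
  idx0 <- which(y == 0L)
  if (length(idx1) < 2L || length(idx0) < 2L) .stopf("need >= 2 samples per class")
  withr::with_seed(seed, {
    lapply(seq_len(n_repeats), function(i) {
      sort(c(sample(idx1, ceiling(length(idx1) / 2)),
             sample(idx0, ceiling(length(idx0) / 2))))
    })
  })
}

.cv_auc_splits <- function(params, covariates, y, splits) {
  vapply(splits, function(train) {
    fit <- .train_logistic(covariates[train, , drop = FALSE], y[train], params)
    pred <- fit(covariates[-train, , drop = FALSE])
    .auc(pred[y[-train] == 1L], pred[y[-train] == 0L])
  }, numeric(1L))
}

#' Cross-validated AUC of a logistic model
#'
#' Per repeat: a seeded, stratified 1:1 train/test split; a
#' ridge-stabilised logistic fit on the training half (covariates
#' z-scored and median-imputed with training-fold statistics); and the
#' Mann-Whitney AUC of the linear predictor on the held-out half.
#' Returns the mean test AUC with the 2.5/97.5 percentile interval
#' across repeats.
#'
#' @param params Character vector of covariate names (>= 1).
#' @param covariates Data frame of numeric covariates, rows aligned with
#'   `labels`.
#' @param labels Cohort labels (case/control only).
#' @param n_repeats Number of random splits (default 50).
#' @param seed Integer seed.
#' @return List with `mean_auc`, `ci` and the per-repeat `aucs`.
#' @export
cv_auc <- function(params, covariates, labels, n_repeats = 50L, seed = 1L) {
  if (!length(params)) .stopf("model must list at least one parameter")
  missing <- setdiff(params, names(covariates))
  if (length(missing)) .stopf("unknown covariate(s): %s", paste(missing, collapse = ", "))
  y <- .labels_to_y(labels, rownames(covariates) %||% seq_len(nrow(covariates)))
  splits <- .make_splits(y, n_repeats, seed)
  aucs <- .cv_auc_splits(params, covariates, y, splits)
  list(mean_auc = mean(aucs),
       ci = unname(stats::quantile(aucs, c(0.025, 0.975))),
       aucs = aucs)
}

#' Univariate significance screen for clinical covariates
#'
#' Tests each covariate individually in a single-predictor logistic
#' model (Wald test) and retains those with p <= alpha. Constant or
#' all-missing covariates are excluded with a warning.
#'
#' @inheritParams cv_auc
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector of retained covariate names; per-covariate
#'   p-values attached as attribute `"p_values"`.
#' @export
univariate_screen <- function(covariates, labels, alpha = 0.05) {
  y <- .labels_to_y(labels, rownames(covariates) %||% seq_len(nrow(covariates)))
  pvals <- vapply(names(covariates), function(nm) {
    x <- covariates[[nm]]
    ok <- !is.na(x)
    if (!any(ok) || stats::sd(x[ok]) == 0 || length(unique(y[ok])) < 2L) {
      .warnf("covariate '%s' excluded (constant or all-missing)", nm)
      return(NA_real_)
    }
    fit <- suppressWarnings(stats::glm(y[ok] ~ x[ok], family = stats::binomial()))
    cf <- stats::coef(summary(fit))
    if (nrow(cf) < 2L) NA_real_ else cf[2L, "Pr(>|z|)"]
  }, numeric(1L))
  keep <- names(pvals)[!is.na(pvals) & pvals <= alpha]
  attr(keep, "p_values") <- pvals
  keep
}

#' Forward greedy logistic model selection under cross-validated AUC
#'
#' Starting from the `forced_in` set (added first, in order, regardless
#' of rank), repeatedly adds the candidate covariate that maximises the
#' mean cross-validated test AUC of the logistic model, stopping when no
#' addition improves the mean AUC or when `max_k` parameters have been
#' accepted. The same seeded splits are reused for every candidate
#' evaluation so models are compared on common resamples. `forced_out`
#' parameters never enter.
#'
#' @inheritParams cv_auc
#' @param max_k Maximum number of accepted parameters (>= 1).
#' @param forced_in,forced_out Character vectors of parameter names.
#' @param candidates Optional candidate set; defaults to all covariate
#'   columns not forced out. Callers typically pass the result of
#'   [univariate_screen()].
#' @return A data frame of class `selection_trace`: one row per accepted
#'   step with `parameter`, `cv_mean_auc`, `ci_low`, `ci_high`, `forced`.
#' @export
forward_greedy_select <- function(covariates, labels, max_k = 5L,
                                  forced_in = character(), forced_out = character(),
                                  n_repeats = 50L, seed = 1L, candidates = NULL) {
  if (max_k < 1L) .stopf("max_k must be >= 1")
  y <- .labels_to_y(labels, rownames(covariates) %||% seq_len(nrow(covariates)))
  candidates <- setdiff(candidates %||% names(covariates), c(forced_in, forced_out))
  splits <- .make_splits(y, n_repeats, seed)

  model <- character()
  rows <- list()
  add_row <- function(param, aucs, forced) {
    rows[[length(rows) + 1L]] <<- data.frame(
      step = length(rows) + 1L, parameter = param,
      cv_mean_auc = mean(aucs),
      ci_low = unname(stats::quantile(aucs, 0.025)),
      ci_high = unname(stats::quantile(aucs, 0.975)),
      forced = forced, stringsAsFactors = FALSE)
  }
  for (p in forced_in) {
    model <- c(model, p)
    add_row(p, .cv_auc_splits(model, covariates, y, splits), TRUE)
  }
  best_auc <- if (length(rows)) rows[[length(rows)]]$cv_mean_auc else -Inf
  while (length(model) < max_k && length(candidates)) {
    cand_auc <- vapply(candidates, function(p) {
      mean(.cv_auc_splits(c(model, p), covariates, y, splits))
    }, numeric(1L))
    top <- which.max(cand_auc)
    if (cand_auc[top] <= best_auc) break
    p <- candidates[top]
    model <- c(model, p)
    candidates <- candidates[-top]
    add_row(p, .cv_auc_splits(model, covariates, y, splits), FALSE)
    best_auc <- rows[[length(rows)]]$cv_mean_auc
  }
  if (!length(rows)) .stopf("no parameters could be evaluated")
  out <- do.call(rbind, rows)
  attr(out, "n_splits") <- as.integer(n_repeats)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "forced_in") <- forced_in
  attr(out, "forced_out") <- forced_out
  class(out) <- c("selection_trace", "data.frame")
  out
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("Forward greedy selection (%d x 2 CV, seed %d)\n",
              attr(x, "n_splits"), attr(x, "seed")))
  print.data.frame(x, row.names = FALSE, digits = 4L)
  invisible(x)
}
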