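#' Scale a vector to mean zero and unit standard deviation
#'
#' Standardization (n - 1 denominator) applied to exposures and outcomes so
#' mediation effect estimates are comparable across exposures.
#'
#' @param v Numeric vector with positive sample SD.
#' @return Standardized numeric vector.
#' @export
standardize <- function(v) {
  s <- stats::sd(v, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant (zero-variance) vector", call. = FALSE)
  (v - mean(v, na.rm = TRUE)) / s
}

#' Linear structural-equation mediation decomposition
#'
#' Fits the two-regression Baron-Kenny system on complete cases:
#' \enumerate{
#'   \item `mediator ~ exposure + covariates` (path `a`);
#'   \item `outcome ~ exposure + mediator + covariates` (paths `b` and the
#'     direct effect `c'`).
#' }
#' Point estimates are closed-form: ACME `= a * b`, direct `= c'`, total
#' `= c' + a * b`, so additivity holds exactly. Confidence intervals come
#' from quasi-Bayesian simulation: coefficient vectors are drawn from normal
#' distributions centered at the estimates with the heteroscedasticity-robust
#' covariance of each fit, the estimands are formed per draw, and percentile
#' intervals are taken. With continuous exposure and outcome this is the
#' linear reduction of the standard causal-mediation framework.
#'
#' The exposure and outcome are standardized internally; the mediator enters
#' on its own scale (ACME and total are therefore in outcome-SD units per
#' exposure SD).
#'
#' @param exposure,mediator,outcome Aligned numeric vectors.
#' @param covariates Optional data.frame or matrix of covariates (categorical
#'   columns are expanded via [expand_covariates()]).
#' @param n_draws Number of quasi-Bayesian draws (default 20, the convention
#'   this implementation mirrors; >= 1000 is recommended for stable
#'   percentile intervals and a message is emitted below 100).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed for the draws.
#' @param se_type Robust covariance flavor (default `"HC0"`).
#' @param total_tol `prop_mediated` is reported only when
#'   `|total| > total_tol` (it is unstable near a null total effect).
#' @return An object of class `gxe_mediation`: `total_effect`, `acme`,
#'   `direct_effect`, `prop_mediated`, `ci` (matrix of per-estimand limits),
#'   `n_draws`, `level`, `n_used`, `inconsistent`, and the path coefficients
#'   `paths = c(a, b, c_prime)`.
#' @export
fit_mediation <- function(exposure, mediator, outcome, covariates = NULL,
                          n_draws = 20, level = 0.95, seed = NULL,
                          se_type = "HC0", total_tol = 1e-8) {
  if (n_draws < 2) stop("`n_draws` must be at least 2", call. = FALSE)
  if (n_draws < 100)
    message("n_draws = ", n_draws,
            " gives unstable percentile intervals; >= 1000 is recommended")
  cv <- if (!is.null(covariates)) {
    if (is.data.frame(covariates)) expand_covariates(covariates)
    else as.matrix(covariates)
  }
  keep <- stats::complete.cases(exposure, mediator, outcome,
                                if (is.null(cv)) rep(TRUE, length(exposure)) else cv)
  x <- standardize(exposure[keep])
  m <- mediator[keep]
  y <- standardize(outcome[keep])
  cvk <- if (!is.null(cv)) cv[keep, , drop = FALSE]
  Xa <- cbind(`(Intercept)` = 1, exposure = x)
  Xb <- cbind(`(Intercept)` = 1, exposure = x, mediator = m)
  if (!is.null(cvk)) { Xa <- cbind(Xa, cvk); Xb <- cbind(Xb, cvk) }
  fit_a <- fit_ols_robust(Xa, m, se_type = se_type)
  fit_b <- fit_ols_robust(Xb, y, se_type = se_type)
  a <- unname(fit_a$beta["exposure"])
  b <- unname(fit_b$beta["mediator"])
  cp <- unname(fit_b$beta["exposure"])
  acme <- a * b
  total <- cp + acme
  if (!is.null(seed)) set.seed(seed)
  a_draw <- stats::rnorm(n_draws, a, fit_a$se_robust["exposure"])
  bc <- MASS::mvrnorm(n_draws,
                      mu = fit_b$beta[c("mediator", "exposure")],
                      Sigma = fit_b$cov_robust[c("mediator", "exposure"),
                                              c("mediator", "exposure")])
  acme_d <- a_draw * bc[, 1]
  dir_d <- bc[, 2]
  tot_d <- acme_d + dir_d
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- rbind(total_effect = stats::quantile(tot_d, qs, names = FALSE),
              acme = stats::quantile(acme_d, qs, names = FALSE),
              direct_effect = stats::quantile(dir_d, qs, names = FALSE))
  colnames(ci) <- c("ci_low", "ci_high")
  res <- structure(
    list(total_effect = total, acme = acme, direct_effect = cp,
         prop_mediated = if (abs(total) > total_tol) acme / total else NA_real_,
         ci = ci, n_draws = n_draws, level = level,
         n_used = fit_a$n_used, paths = c(a = a, b = b, c_prime = cp),
         inconsistent = NA),
    class = "gxe_mediation")
  res$inconsistent <- flag_inconsistent_mediation(res)
  res
}

#' @export
print.gxe_mediation <- function(x, ...) {
  cat(sprintf("<gxe_mediation> n=%d, %d draws, level %.2f\n",
              x$n_used, x$n_draws, x$level))
  est <- c(x$total_effect, x$acme, x$direct_effect)
  print(data.frame(estimate = est, ci_low = x$ci[, 1], ci_high = x$ci[, 2],
                   row.names = rownames(x$ci)))
  if (!is.na(x$prop_mediated))
    cat(sprintf("proportion mediated: %.3f\n", x$prop_mediated))
  if (isTRUE(x$inconsistent))
    cat("note: |ACME| exceeds |total| (inconsistent mediation)\n")
  invisible(x)
}

#' Flag inconsistent mediation
#'
#' Inconsistent mediation — a mediated effect larger in magnitude than the
#' total effect — indicates offsetting direct/indirect paths or residual
#' confounding in the opposite direction of the mediated effect.
#'
#' @param result A `gxe_mediation` (or any list with elements `acme` and
#'   `total_effect`).
#' @param tol Slack on the comparison (default `1e-6`).
#' @return `TRUE` iff `|acme| > |total_effect| + tol`.
#' @export
flag_inconsistent_mediation <- function(result, tol = 1e-6) {
  if (is.null(result$acme) || is.null(result$total_effect))
    stop("`result` must carry `acme` and `total_effect`", call. = FALSE)
  abs(result$acme) > abs(result$total_effect) + tol
}

#' Compare mediation across mediator components
#'
#' Runs [fit_mediation()] independently for each named mediator component
#' (e.g. a total plasma fraction and its subspecies), sharing the exposure,
#' outcome, covariates and draw seed. A derived remainder component can be
#' formed upstream by subtracting one component from a total.
#'
#' @param exposure,outcome Aligned numeric vectors.
#' @param mediator_components Named list (or data.frame) of aligned mediator
#'   vectors; names must be unique.
#' @param covariates Optional covariates as in [fit_mediation()].
#' @param ... Further arguments passed to [fit_mediation()] (`n_draws`,
#'   `seed`, ...).
#' @return Data.frame with one row per component: estimates, CI limits,
#'   `prop_mediated`, `inconsistent`.
#' @export
compare_mediators <- function(exposure, mediator_components, outcome,
                              covariates = NULL, ...) {
  comps <- as.list(mediator_components)
  nms <- names(comps)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("mediator components must be named", call. = FALSE)
  if (anyDuplicated(nms))
    stop("duplicate mediator component name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  rows <- lapply(nms, function(nm) {
    r <- fit_mediation(exposure, comps[[nm]], outcome,
                       covariates = covariates, ...)
    data.frame(component = nm, total_effect = r$total_effect, acme = r$acme,
               direct_effect = r$direct_effect,
               acme_ci_low = r$ci["acme", 1], acme_ci_high = r$ci["acme", 2],
               prop_mediated = r$prop_mediated, inconsistent = r$inconsistent,
               n_used = r$n_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
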