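#' Define a simulation scenario for decomposed interaction testing
#'
#' A scenario fully parameterizes the data-generating process for one cell of
#' a power study over the exposure (E) -> mediator (M) -> outcome (Y) pathway
#' with a biallelic genotype G. In an \emph{upstream} scenario the genetic
#' interaction acts on the E-to-M leg (M carries a G x E product term and Y a
#' main effect of M); in a \emph{downstream} scenario it acts on the M-to-Y
#' leg (M carries an E main effect and Y a G x M product term).
#'
#' Variance fractions are interpreted on the marginal scale: the coefficient
#' b of the product term satisfies b^2 * Var(G * modifier) = `v_interaction`,
#' with G kept as the uncentered dosage in \{0, 1, 2\} unless
#' `product_centering = "centered"` is requested. Every generated trait is
#' scaled to unit total variance so fractions are directly comparable.
#'
#' @param kind `"upstream"` or `"downstream"`.
#' @param n Sample size per simulated dataset.
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param v_interaction Fraction of variance of the interaction-bearing trait
#'   (M for upstream, Y for downstream) explained by the product term, in
#'   \[0, 1).
#' @param v_transmit Fraction of variance explained along the mediating
#'   main-effect path (M -> Y for upstream, E -> M for downstream), in \[0, 1\].
#' @param icc_m Intraclass correlation of the measured mediator, in (0, 1];
#'   1 means the mediator is measured without error.
#' @param beta_g_main,beta_e_main Optional variance fractions for genotype and
#'   exposure main effects in the interaction-bearing trait equation
#'   (default 0, matching the minimal generating model).
#' @param product_centering `"none"` (default) keeps the raw dosage in the
#'   generating product term; `"centered"` uses G - 2*maf.
#' @return An object of class `gxe_scenario`.
#' @seealso [simulate_dataset()], [estimate_power()], [scenario_ncp()]
#' @export
sim_scenario <- function(kind = c("upstream", "downstream"),
                         n = 1000, maf = 0.25,
                         v_interaction = 0.005, v_transmit = 0.10,
                         icc_m = 1, beta_g_main = 0, beta_e_main = 0,
                         product_centering = c("none", "centered")) {
  kind <- match.arg(kind)
  product_centering <- match.arg(product_centering)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive sample count", call. = FALSE)
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5)
    stop("`maf` must lie in (0, 0.5]", call. = FALSE)
  if (v_interaction < 0 || v_interaction >= 1)
    stop("`v_interaction` must lie in [0, 1)", call. = FALSE)
  if (v_transmit < 0 || v_transmit > 1)
    stop("`v_transmit` must lie in [0, 1]", call. = FALSE)
  if (icc_m <= 0 || icc_m > 1)
    stop("`icc_m` must lie in (0, 1]: the measurement-noise variance is undefined otherwise",
         call. = FALSE)
  if (beta_g_main < 0 || beta_e_main < 0)
    stop("main-effect variance fractions must be non-negative", call. = FALSE)
  sc <- structure(
    list(kind = kind, n = as.integer(n), maf = maf,
         v_interaction = v_interaction, v_transmit = v_transmit,
         icc_m = icc_m, beta_g_main = beta_g_main, beta_e_main = beta_e_main,
         product_centering = product_centering),
    class = "gxe_scenario")
  # fail early if the requested fractions cannot fit in a unit-variance trait
  invisible(scenario_coefficients(sc))
  sc
}

#' @export
print.gxe_scenario <- function(x, ...) {
  cat(sprintf("<gxe_scenario> %s: n=%d, maf=%.3g, v_int=%.4g, v_transmit=%.4g, icc_m=%.3g\n",
              x$kind, x$n, x$maf, x$v_interaction, x$v_transmit, x$icc_m))
  invisible(x)
}

# Second moments of G and of the product term under the scenario's centering.
product_moments <- function(maf, centering = "none") {
  var_g <- 2 * maf * (1 - maf)
  eg2 <- var_g + (2 * maf)^2            # E[G^2] for uncentered dosage
  if (centering == "none") {
    # P = G * X with X ~ (0,1) independent of G: Var(P) = E[G^2],
    # Cov(P, X) = E[G], Cov(P, G) = 0
    list(var_g = var_g, var_p = eg2, cov_px = 2 * maf, var_p_partial = var_g)
  } else {
    list(var_g = var_g, var_p = var_g, cov_px = 0, var_p_partial = var_g)
  }
}

# Resolve the generating coefficients implied by the variance fractions.
# Errors if the implied residual variance of any trait equation is negative.
scenario_coefficients <- function(sc) {
  mom <- product_moments(sc$maf, sc$product_centering)
  b_p <- sqrt(sc$v_interaction / mom$var_p)
  b_g <- sqrt(sc$beta_g_main / mom$var_g)
  b_t <- sqrt(sc$v_transmit)            # modifier/main path: unit-variance regressor
  if (sc$kind == "upstream") {
    # M = b_p*(G*E) + b_g*G + b_e*E + eps_m;  Y = b_t*M + eps_y
    b_e <- sqrt(sc$beta_e_main)
    sig_m <- sc$v_interaction + sc$beta_g_main + sc$beta_e_main +
      2 * b_p * b_e * mom$cov_px
    sig_y <- sc$v_transmit
  } else {
    # M = b_t*E + eps_m;  Y = b_p*(G*M) + b_g*G + b_e*E + eps_y
    b_e <- sqrt(sc$beta_e_main)
    # Cov(G*M, E) = E[G] * Cov(M, E) = E[G] * b_t (uncentered only)
    cov_pe <- if (sc$product_centering == "none") 2 * sc$maf * b_t else 0
    sig_y <- sc$v_interaction + sc$beta_g_main + sc$beta_e_main +
      2 * b_p * b_e * cov_pe
    sig_m <- sc$v_transmit
  }
  if (sig_m > 1 + 1e-12 || sig_y > 1 + 1e-12)
    stop("variance fractions imply negative residual variance in a trait equation",
         call. = FALSE)
  list(b_p = b_p, b_g = b_g, b_e = b_e, b_t = b_t,
       resid_m = sqrt(pmax(1 - sig_m, 0)), resid_y = sqrt(pmax(1 - sig_y, 0)),
       mom = mom)
}

#' Simulate biallelic genotype dosages
#'
#' Hard-call genotypes drawn as Binomial(2, maf), the Hardy-Weinberg model
#' used throughout the simulation study.
#'
#' @param n Number of samples.
#' @param maf Minor allele frequency, in (0, 0.5].
#' @return Integer vector in \{0, 1, 2\} of length `n`.
#' @export
simulate_genotypes <- function(n, maf) {
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5)
    stop("`maf` must lie in (0, 0.5]", call. = FALSE)
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  stats::rbinom(n, 2L, maf)
}

#' Add measurement error to a mediator at a target intraclass correlation
#'
#' Returns `m_true + e` with `e ~ Normal(0, var(m_true) * (1 - icc_m) / icc_m)`,
#' so that the fraction of measured-mediator variance attributable to the true
#' mediator equals `icc_m`. The noise variance is anchored to the \emph{sample}
#' variance of the realized `m_true`, so the ICC holds conditionally on the
#' data at hand. `icc_m = 1` returns the input unchanged.
#'
#' @param m_true Numeric vector of true mediator values.
#' @param icc_m Target intraclass correlation, in (0, 1].
#' @return Numeric vector of the same length.
#' @export
add_measurement_noise <- function(m_true, icc_m) {
  if (!is.numeric(icc_m) || length(icc_m) != 1L || icc_m <= 0 || icc_m > 1)
    stop("`icc_m` must lie in (0, 1]: the noise variance is undefined otherwise",
         call. = FALSE)
  if (icc_m == 1) return(m_true)
  v <- stats::var(m_true)
  m_true + stats::rnorm(length(m_true), sd = sqrt(v * (1 - icc_m) / icc_m))
}

#' Simulate one dataset under an upstream-interaction scenario
#'
#' G ~ Binomial(2, maf), E ~ Normal(0, 1); the mediator carries the G x E
#' product term (plus optional main effects) and is scaled to unit variance;
#' the outcome carries a main effect of the true mediator transmitting
#' `v_transmit` of its variance. The measured mediator adds noise per
#' [add_measurement_noise()].
#'
#' @param scenario A `gxe_scenario` with `kind = "upstream"`.
#' @return A data.frame of class `gxe_simdata` with columns
#'   `g, e, m_true, m_measured, y`.
#' @export
simulate_upstream <- function(scenario) {
  stopifnot(inherits(scenario, "gxe_scenario"))
  if (scenario$kind != "upstream")
    stop("scenario kind must be 'upstream'", call. = FALSE)
  cf <- scenario_coefficients(scenario)
  n <- scenario$n
  g <- simulate_genotypes(n, scenario$maf)
  e <- stats::rnorm(n)
  gp <- if (scenario$product_centering == "centered") g - 2 * scenario$maf else g
  m <- cf$b_p * gp * e + cf$b_g * g + cf$b_e * e +
    stats::rnorm(n, sd = cf$resid_m)
  mm <- add_measurement_noise(m, scenario$icc_m)
  y <- cf$b_t * m + stats::rnorm(n, sd = cf$resid_y)
  new_simdata(g, e, m, mm, y)
}

#' Simulate one dataset under a downstream-interaction scenario
#'
#' The mediator carries an E main effect transmitting `v_transmit` of its
#' variance; the outcome carries a G x M product term on the \emph{true}
#' mediator. The measured mediator adds noise per [add_measurement_noise()].
#'
#' @param scenario A `gxe_scenario` with `kind = "downstream"`.
#' @return A data.frame of class `gxe_simdata` with columns
#'   `g, e, m_true, m_measured, y`.
#' @export
simulate_downstream <- function(scenario) {
  stopifnot(inherits(scenario, "gxe_scenario"))
  if (scenario$kind != "downstream")
    stop("scenario kind must be 'downstream'", call. = FALSE)
  cf <- scenario_coefficients(scenario)
  n <- scenario$n
  g <- simulate_genotypes(n, scenario$maf)
  e <- stats::rnorm(n)
  m <- cf$b_t * e + stats::rnorm(n, sd = cf$resid_m)
  mm <- add_measurement_noise(m, scenario$icc_m)
  gp <- if (scenario$product_centering == "centered") g - 2 * scenario$maf else g
  y <- cf$b_p * gp * m + cf$b_g * g + cf$b_e * e +
    stats::rnorm(n, sd = cf$resid_y)
  new_simdata(g, e, m, mm, y)
}

#' Simulate one dataset under a scenario of either kind
#' @param scenario A `gxe_scenario`.
#' @return A `gxe_simdata` data.frame; see [simulate_upstream()].
#' @export
simulate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "gxe_scenario"))
  switch(scenario$kind,
         upstream = simulate_upstream(scenario),
         downstream = simulate_downstream(scenario))
}

new_simdata <- function(g, e, m, mm, y) {
  structure(data.frame(g = g, e = e, m_true = m, m_measured = mm, y = y),
            class = c("gxe_simdata", "data.frame"))
}
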