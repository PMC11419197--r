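#' Monte-Carlo configuration for power estimation
#'
#' Defaults mirror the primary simulation protocol: 500 replicates per
#' scenario at a 0.05 significance threshold.
#'
#' @param n_reps Number of simulation replicates (>= 1).
#' @param alpha Significance threshold in (0, 1).
#' @param seed Optional master seed; per-replicate seeds are derived from it
#'   deterministically so grids are reproducible and order-invariant.
#' @return An object of class `gxe_power_config`.
#' @export
power_config <- function(n_reps = 500, alpha = 0.05, seed = NULL) {
  if (n_reps < 1) stop("`n_reps` must be at least 1", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]", call. = FALSE)
  structure(list(n_reps = as.integer(n_reps), alpha = alpha, seed = seed),
            class = "gxe_power_config")
}

# Deterministic per-replicate seed streams derived from a master seed.
replicate_seeds <- function(n_reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_reps)
}

default_pathways <- function(kind) {
  switch(kind,
         upstream = c("standard", "upstream"),
         downstream = c("standard", "downstream"))
}

#' Estimate rejection rates of the pathway interaction tests by simulation
#'
#' For each replicate one dataset is drawn from the scenario and the
#' interaction term is Wald-tested (robust SEs) in each requested pathway
#' regression; power is the fraction of replicates with `p < alpha`. All
#' pathways are evaluated on the same replicates, as in the simulation
#' protocol ("tested for significance in two of three regressions").
#'
#' @param scenario A `gxe_scenario`.
#' @param pathways Character vector of pathways to test; defaults to
#'   `c("standard", "upstream")` for upstream scenarios and
#'   `c("standard", "downstream")` for downstream scenarios. Requesting the
#'   decomposed test of the other leg is an error (its generating signal is
#'   not defined under the scenario).
#' @param config A `gxe_power_config`.
#' @param se_type Robust covariance flavor passed to [fit_ols_robust()].
#' @return A data.frame with one row per pathway: scenario parameters,
#'   `pathway`, `power`, `mc_se` (binomial standard error), `n_reps`, `alpha`.
#' @export
estimate_power <- function(scenario, pathways = NULL, config = power_config(),
                           se_type = "HC0") {
  stopifnot(inherits(scenario, "gxe_scenario"),
            inherits(config, "gxe_power_config"))
  allowed <- c("standard", default_pathways(scenario$kind))
  if (is.null(pathways)) pathways <- default_pathways(scenario$kind)
  bad <- setdiff(pathways, allowed)
  if (length(bad))
    stop(sprintf("pathway(s) %s are not admissible for a %s scenario",
                 paste(bad, collapse = ", "), scenario$kind), call. = FALSE)
  seeds <- replicate_seeds(config$n_reps, config$seed)
  rej <- matrix(0L, nrow = config$n_reps, ncol = length(pathways),
                dimnames = list(NULL, pathways))
  for (i in seq_len(config$n_reps)) {
    set.seed(seeds[i])
    d <- simulate_dataset(scenario)
    for (pw in pathways) {
      fit <- fit_pathway(d, pw, se_type = se_type)
      p <- interaction_wald_test(fit, fit$interaction_term)$p
      rej[i, pw] <- as.integer(p < config$alpha)
    }
  }
  pow <- colMeans(rej)
  data.frame(
    scenario_kind = scenario$kind, n = scenario$n, maf = scenario$maf,
    v_interaction = scenario$v_interaction, v_transmit = scenario$v_transmit,
    icc_m = scenario$icc_m, pathway = pathways, power = unname(pow),
    mc_se = unname(sqrt(pow * (1 - pow) / config$n_reps)),
    n_reps = config$n_reps, alpha = config$alpha,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Analytic power of a 1-df (or df-df) chi-square Wald test
#'
#' `P(chisq_df(ncp) > q_{1-alpha}(chisq_df))` — the non-central chi-square
#' oracle against which the Monte-Carlo engine is validated.
#'
#' @param ncp Non-centrality parameter (>= 0).
#' @param alpha Significance threshold.
#' @param df Degrees of freedom (default 1, a single product term).
#' @return Power fraction in \[alpha, 1\].
#' @export
analytic_power <- function(ncp, alpha, df = 1) {
  if (any(ncp < 0)) stop("`ncp` must be non-negative", call. = FALSE)
  if (df < 1) stop("`df` must be at least 1", call. = FALSE)
  stats::pchisq(stats::qchisq(1 - alpha, df), df, ncp = ncp,
                lower.tail = FALSE)
}

#' Non-centrality parameter of a pathway interaction test under a scenario
#'
#' Closed-form approximation `ncp = n * v_partial / residual variance`, where
#' `v_partial` is the variance fraction of the product term orthogonalized
#' against the intercept, genotype and modifier columns (for the uncentered
#' dosage product at MAF q this multiplies the marginal fraction by
#' `Var(G) / E[G^2]`), attenuated by the transmission fraction for the
#' standard test and by `icc_m` for terms involving the measured mediator.
#'
#' @param scenario A `gxe_scenario`.
#' @param pathway One of `"standard"`, `"upstream"`, `"downstream"` (the
#'   decomposed pathway must match the scenario kind).
#' @return Non-negative scalar NCP.
#' @export
scenario_ncp <- function(scenario, pathway) {
  stopifnot(inherits(scenario, "gxe_scenario"))
  allowed <- c("standard", scenario$kind)
  if (!pathway %in% allowed)
    stop(sprintf("pathway '%s' is not admissible for a %s scenario",
                 pathway, scenario$kind), call. = FALSE)
  mom <- product_moments(scenario$maf, scenario$product_centering)
  f <- mom$var_p_partial / mom$var_p   # orthogonalization factor (1 if centered)
  v <- scenario$v_interaction
  icc <- scenario$icc_m
  vt <- scenario$v_transmit
  mains <- scenario$beta_g_main + scenario$beta_e_main
  if (pathway == scenario$kind) {
    # decomposed test: product coefficient attenuated by icc on the measured
    # side (outcome noise for upstream, regressor noise for downstream)
    num <- v * f * icc
    den <- 1 - (v + mains) * icc
  } else {
    # standard test: interaction signal transmitted through the mediating leg
    num <- v * vt * f
    den <- 1 - v * vt
  }
  scenario$n * num / den
}

#' Run a grid of power scenarios
#'
#' Evaluates [estimate_power()] over a list of scenarios; a failing cell is
#' recorded in the `status` column rather than aborting the grid. Replicate
#' seed streams are spawned per cell from the master seed, so results do not
#' depend on grid order.
#'
#' @param scenarios List of `gxe_scenario` objects (see [scenario_grid()]).
#' @param config A `gxe_power_config`; its seed is the master seed.
#' @param se_type Robust covariance flavor.
#' @return Long-format data.frame: scenario parameters, `pathway`, `power`,
#'   `mc_se`, `n_reps`, `alpha`, `seed`, `status`.
#' @export
run_power_grid <- function(scenarios, config = power_config(), se_type = "HC0") {
  if (!length(scenarios)) stop("empty scenario grid", call. = FALSE)
  if (inherits(scenarios, "gxe_scenario")) scenarios <- list(scenarios)
  cell_seeds <- replicate_seeds(length(scenarios), config$seed)
  rows <- lapply(seq_along(scenarios), function(i) {
    sc <- scenarios[[i]]
    cell_cfg <- power_config(config$n_reps, config$alpha, seed = cell_seeds[i])
    out <- tryCatch(estimate_power(sc, config = cell_cfg, se_type = se_type),
                    error = function(e) {
                      data.frame(scenario_kind = sc$kind, n = sc$n, maf = sc$maf,
                                 v_interaction = sc$v_interaction,
                                 v_transmit = sc$v_transmit, icc_m = sc$icc_m,
                                 pathway = NA_character_, power = NA_real_,
                                 mc_se = NA_real_, n_reps = config$n_reps,
                                 alpha = config$alpha,
                                 stringsAsFactors = FALSE,
                                 status = conditionMessage(e))
                    })
    if (is.null(out$status)) out$status <- "ok"
    out$seed <- cell_seeds[i]
    out
  })
  do.call(rbind, rows)
}

#' Expand parameter lists into a Cartesian grid of scenarios
#'
#' Each argument may be a vector; the grid is the Cartesian product of all
#' supplied values, mirroring a faceted power-plot layout.
#'
#' @inheritParams sim_scenario
#' @return List of `gxe_scenario` objects.
#' @export
scenario_grid <- function(kind, n = 1000, maf = 0.25,
                          v_interaction = 0.005, v_transmit = 0.10,
                          icc_m = 1, product_centering = "none") {
  grid <- expand.grid(kind = kind, n = n, maf = maf,
                      v_interaction = v_interaction, v_transmit = v_transmit,
                      icc_m = icc_m, product_centering = product_centering,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    sim_scenario(kind = grid$kind[i], n = grid$n[i], maf = grid$maf[i],
                 v_interaction = grid$v_interaction[i],
                 v_transmit = grid$v_transmit[i], icc_m = grid$icc_m[i],
                 product_centering = grid$product_centering[i]))
}
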