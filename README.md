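# gxedecomp

Decomposed gene-environment interaction (GxE) testing along mediated
pathways, for statistical geneticists and epidemiologists studying
exposure → mediator → outcome systems (the motivating example: dietary
omega-3 intake → plasma omega-3 fraction → hsCRP inflammation).

## The idea

A standard GxE scan fits, per variant,

    Y ~ G + E + G:E + covariates

and Wald-tests the product term with heteroscedasticity-robust (sandwich)
standard errors. When the exposure acts through a measured mediator M, that
single end-to-end test dilutes any genetic modification specific to one leg
of the pathway. The decomposed approach runs three scans and tests the
product term in each:

| pathway    | model                | question                                   |
|------------|----------------------|--------------------------------------------|
| standard   | `Y ~ G + E + G:E`    | does G modify the E→Y association?         |
| upstream   | `M ~ G + E + G:E`    | does G modify the E→M association?         |
| downstream | `Y ~ G + M + G:M`    | does G modify the M→Y association?         |

If the interaction lives on one leg and that leg transmits only a fraction
`v` of its variance onward, the standard test's non-centrality is attenuated
by `v` while the matching decomposed test keeps it in full — at `v = 0.10`
the decomposed test is several-fold more powerful.

The package provides: a parameterized simulation engine with an analytic
non-central chi-square power oracle; linear structural-equation mediation
decomposition (total effect, ACME, direct effect) with quasi-Bayesian
intervals; a synthetic cohort + LD-aware variant panel generator; and a
miniature GWIS pipeline (phenotype preparation, derived dietary exposure,
three-pathway scan, greedy LD clumping, strand-aware gene windows, Brown's
method gene-level combination, per-pathway BH FDR, stratified summaries,
sensitivity models). A thin CLI (`inst/scripts/gxedecomp`) exposes the
subcommands `power-grid`, `mediate`, `synth-cohort`, `gwis`, `clump`,
`gene-test`, `stratify`.

## Worked example

Power of the decomposed vs standard test when a G×M interaction explains
0.5% of Var(Y) and E explains 10% of Var(M) (N = 1,000, MAF 0.25):

```r
library(gxedecomp)
sc <- sim_scenario("downstream", n = 1000, maf = 0.25,
                   v_interaction = 0.005, v_transmit = 0.10)
estimate_power(sc, config = power_config(n_reps = 2000, seed = 42))
#>      pathway power   mc_se n_reps
#> 1   standard 0.082 0.00613   2000
#> 2 downstream 0.403 0.01097   2000
analytic_power(scenario_ncp(sc, "downstream"), 0.05)  #> 0.412
analytic_power(scenario_ncp(sc, "standard"),  0.05)   #> 0.085
```

The downstream test rejects ~40% of the time, the standard test ~8% — the
roughly five-fold advantage that motivates decomposition.

End-to-end on a synthetic cohort with an upstream-only causal interaction
at one variant:

```r
set.seed(42)
panel <- generate_variant_panel(n_samples = 5000, n_variants = 100, seed = 1)
gen   <- generate_cohort(panel, cohort_truth(gamma_gxd = 0.15), seed = 2)
co    <- gen$cohort

# derived dietary exposure: mediator regressed on the four intake sources
dw <- derive_weighted_exposure(
  co[c("oily_fish", "nonoily_fish", "fishoil_touchscreen",
       "fishoil_interview")], co$mediator_pct)
round(dw$weights, 3)
#>   oily_fish  nonoily_fish  fishoil_touchscreen  fishoil_interview
#>       1.712         0.696                0.889              0.713

po <- prepare_outcome(co$outcome_raw)      # log + 5-SD outlier filter
co$dn3fa <- dw$exposure
co$log_crp <- NA; co$log_crp[po$kept] <- po$values

rec <- run_gwis(panel, co, "dn3fa", "mediator_pct", "log_crp",
                covariates = c("age", "sex", "smoking"))
rec[rec$variant_id == gen$truth$causal_variant,
    c("pathway", "beta_int", "p_int")]
#>        pathway     beta_int        p_int
#> 235   standard -0.094561057 1.098548e-05
#> 236   upstream  0.306242091 9.898445e-24
#> 237 downstream  0.002978607 7.853124e-01
```

The upstream scan nails the causal variant at genome-wide significance; the
standard scan would not reach 5e-8 there, and the downstream scan is null —
the qualitative signature of an interaction on the diet→plasma leg.

Mediation of the exposure-outcome effect through the plasma mediator
(exposure and outcome standardized; ACME = a·b):

```r
fit_mediation(co$dn3fa, co$mediator_pct, co$log_crp,
              covariates = co[c("age", "sex", "smoking", "income")],
              n_draws = 1000, seed = 3)
#> <gxe_mediation> n=5000, 1000 draws, level 0.95
#>                 estimate     ci_low    ci_high
#> total_effect  -0.4079000 -0.4313624 -0.3848582
#> acme          -0.2403305 -0.2574318 -0.2247306
#> direct_effect -0.1675694 -0.1944564 -0.1429612
#> proportion mediated: 0.589
```

See `vignettes/decomposed-gxe-methods.Rmd` for the generating model,
parameter conventions, and numerical choices.

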