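test_that("sandwich covariance matches an elementwise brute-force evaluation", {
  x <- 0:5
  y <- c(0, 1, 2, 3, 4, 10)
  X <- cbind(`(Intercept)` = 1, x = x)
  for (type in c("HC0", "HC1", "HC3")) {
    fit <- fit_ols_robust(X, y, se_type = type)
    V <- brute_force_sandwich(X, y, type)
    expect_equal(unname(fit$cov_robust), unname(V), tolerance = 1e-10)
    expect_equal(unname(fit$se_robust), unname(sqrt(diag(V))),
                 tolerance = 1e-10)
  }
})

test_that("sandwich covariance agrees with the sandwich package", {
  skip_if_not_installed("sandwich")
  set.seed(201)
  n <- 200
  x1 <- rnorm(n); x2 <- rbinom(n, 2, 0.3)
  y <- 1 + 0.5 * x1 - 0.2 * x2 + rnorm(n) * (1 + abs(x1))
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)
  lmfit <- lm(y ~ x1 + x2)
  for (type in c("HC0", "HC1", "HC3")) {
    fit <- fit_ols_robust(X, y, se_type = type)
    expect_equal(unname(fit$cov_robust),
                 unname(sandwich::vcovHC(lmfit, type = type)),
                 tolerance = 1e-8)
  }
})

test_that("a perfect fit yields zero robust SEs and exact fitted values", {
  x <- 1:10
  y <- 2 + 3 * x
  fit <- fit_ols_robust(cbind(1, x), y)
  expect_equal(fit$fitted, y, tolerance = 1e-10)
  expect_true(all(fit$se_robust < 1e-10))
})

test_that("HC flavors converge and match model-based SEs under homoscedasticity", {
  set.seed(202)
  n <- 1e5
  x <- rnorm(n)
  y <- 1 + 0.3 * x + rnorm(n)
  X <- cbind(`(Intercept)` = 1, x = x)
  f0 <- fit_ols_robust(X, y, "HC0")
  f1 <- fit_ols_robust(X, y, "HC1")
  f3 <- fit_ols_robust(X, y, "HC3")
  classical <- summary(lm(y ~ x))$coefficients[, "Std. Error"]
  expect_lt(max(abs(f0$se_robust / classical - 1)), 0.02)
  expect_lt(max(abs(f1$se_robust / f0$se_robust - 1)), 0.01)
  expect_lt(max(abs(f3$se_robust / f0$se_robust - 1)), 0.01)
})

test_that("degenerate designs raise informative errors", {
  set.seed(203)
  x <- rnorm(50)
  X <- cbind(`(Intercept)` = 1, a = x, dup = x)
  expect_error(fit_ols_robust(X, rnorm(50)), "collinear.*dup")
  expect_error(fit_ols_robust(cbind(1, rnorm(3), rnorm(3), rnorm(3)),
                              rnorm(3)),
               "insufficient data")
  # zero-variance covariate duplicates the intercept
  d <- data.frame(g = rbinom(50, 2, 0.3), e = rnorm(50), y = rnorm(50))
  expect_error(
    fit_pathway(d, "standard", covariates = cbind(flat = rep(1, 50))),
    "collinear")
})

test_that("Wald p-values follow the two-sided normal reference", {
  set.seed(204)
  d <- data.frame(g = rbinom(300, 2, 0.25), e = rnorm(300))
  d$y <- 0.5 * d$g * d$e + rnorm(300)
  d$m_measured <- rnorm(300)
  fit <- fit_pathway(d, "standard")
  expect_equal(unname(fit$p), unname(2 * pnorm(-abs(fit$z))), tolerance = 1e-12)
  iw <- interaction_wald_test(fit, "g:e")
  expect_identical(iw$p, unname(fit$p["g:e"]))
  expect_error(interaction_wald_test(fit, "nope"), "not found")
  # genome-wide boundary: p < 5e-8 iff |z| > 5.4513
  expect_lt(2 * pnorm(-5.4514), 5e-8)
  expect_gt(2 * pnorm(-5.4512), 5e-8)
})

test_that("pathway designs carry the documented term labels", {
  d <- data.frame(g = c(0, 1, 2, 1), e = rnorm(4), m_measured = rnorm(4),
                  m_true = rnorm(4), y = rnorm(4))
  expect_identical(colnames(build_pathway_design(d, "standard")$design),
                   c("(Intercept)", "g", "e", "g:e"))
  expect_identical(colnames(build_pathway_design(d, "upstream")$design),
                   c("(Intercept)", "g", "e", "g:e"))
  bd <- build_pathway_design(d, "downstream")
  expect_identical(colnames(bd$design),
                   c("(Intercept)", "g", "m_measured", "g:m_measured"))
  expect_identical(bd$y, d$y)
  # literal-reading switch: main-effect slot holds the true mediator
  bd_true <- build_pathway_design(d, "downstream", mediator_main = "true")
  expect_identical(unname(bd_true$design[, "m_measured"]), d$m_true)
  expect_identical(unname(bd_true$design[, "g:m_measured"]),
                   d$g * d$m_measured)
  expect_error(build_pathway_design(d[, c("g", "e")], "standard"),
               "missing required column")
})

test_that("interaction p-values are uniform under the global null", {
  set.seed(205)
  n <- 300
  p <- replicate(1500, {
    d <- data.frame(g = rbinom(n, 2, 0.25), e = rnorm(n), y = rnorm(n))
    fit <- fit_pathway(d, "standard")
    unname(fit$p["g:e"])
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("coefficients rescale inversely to covariate scaling", {
  set.seed(206)
  n <- 500
  d <- data.frame(g = rbinom(n, 2, 0.25), e = rnorm(n))
  d$y <- 0.2 * d$g + 0.1 * d$e + rnorm(n)
  cv <- cbind(z = rnorm(n))
  f1 <- fit_pathway(d, "standard", covariates = cv)
  f2 <- fit_pathway(d, "standard", covariates = cv * 100)
  expect_equal(unname(f2$beta["z"]), unname(f1$beta["z"]) / 100,
               tolerance = 1e-10)
  expect_equal(unname(f2$beta["g:e"]), unname(f1$beta["g:e"]),
               tolerance = 1e-10)
})

test_that("categorical covariates expand with the modal level as reference", {
  cv <- data.frame(smoke = c("never", "never", "past", "current", "never",
                             "do not know"),
                   age = 1:6)
  m <- expand_covariates(cv)
  expect_true(all(c("smoke.past", "smoke.current", "smoke.do not know",
                    "age") %in% colnames(m)))
  expect_false("smoke.never" %in% colnames(m))
  expect_equal(unname(m[, "age"]), 1:6)
})
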