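test_that("outcome preparation applies the 5-SD log-scale filter", {
  # degenerate SD: nothing removed
  po <- prepare_outcome(rep(2.5, 10))
  expect_equal(sum(po$kept), 10)
  expect_equal(nrow(po$report), 0)

  # one constructed extreme value is exactly the removal
  set.seed(601)
  v <- exp(rnorm(100))
  v[101] <- exp(8)
  lv <- log(v)
  stopifnot(abs(lv[101] - mean(lv)) > 5 * sd(lv))   # construction is valid
  po <- prepare_outcome(v)
  expect_identical(which(!po$kept), 101L)
  expect_match(po$report$reason, "5 SD")

  # no-removal case round-trips through exp
  set.seed(602)
  w <- exp(rnorm(50, sd = 0.3))
  po2 <- prepare_outcome(w)
  expect_equal(exp(po2$values), w[po2$kept], tolerance = 1e-12)

  # nonpositive values excluded before the log, with report
  po3 <- prepare_outcome(c(-1, 0, exp(rnorm(20))))
  expect_equal(sum(!po3$kept), 2)
  expect_error(prepare_outcome(c(1, 2)), "fewer than 3")
})

test_that("derived exposure weights follow the mediator regression", {
  set.seed(603)
  n <- 5000
  src <- data.frame(s1 = rpois(n, 2), s2 = rpois(n, 1),
                    s3 = rbinom(n, 1, 0.3), s4 = rbinom(n, 1, 0.2))
  med <- 0.8 * src$s1 + rnorm(n)
  dw <- derive_weighted_exposure(src, med)
  expect_equal(unname(dw$weights["s1"]), 0.8, tolerance = 0.05)
  expect_lt(max(abs(dw$weights[c("s2", "s3", "s4")])), 0.1)
  expect_equal(cor(dw$exposure, as.matrix(src) %*% dw$weights)[1], 1,
               tolerance = 1e-12)

  # missing fish-oil style values impute to zero before the regression
  src_na <- src
  src_na$s3[sample(n, 500)] <- NA
  expect_silent(dw2 <- derive_weighted_exposure(src_na, med))
  expect_false(anyNA(dw2$exposure))

  # an all-missing column imputes to all zeros and is dropped with a report
  src_na$s4 <- NA_real_
  expect_message(dw3 <- derive_weighted_exposure(src_na, med),
                 "zero-variance.*s4")
  expect_false("s4" %in% names(dw3$weights))
})

test_that("a single-variant scan reproduces the direct pathway fit", {
  set.seed(604)
  n <- 600
  g <- rbinom(n, 2, 0.3)
  panel <- toy_panel(matrix(g, ncol = 1, dimnames = list(NULL, "v1")),
                     chrom = "chr1", pos = 1000L)
  ph <- null_phenotypes(n)
  rec <- run_gwis(panel, ph, "expo", "med", "outc")
  d <- data.frame(g = g, e = ph$expo, m_measured = ph$med, y = ph$outc)
  for (pw in c("standard", "upstream", "downstream")) {
    fit <- fit_pathway(d, pw)
    expect_equal(rec$p_int[rec$pathway == pw],
                 unname(fit$p[fit$interaction_term]), tolerance = 1e-12)
    expect_equal(rec$beta_int[rec$pathway == pw],
                 unname(fit$beta[fit$interaction_term]), tolerance = 1e-12)
  }
  expect_equal(unique(rec$n_used), n)
})

test_that("null-cohort scans are calibrated in all three pathways", {
  set.seed(605)
  # biobank-scale-ish n keeps the HC0 normal reference calibrated
  panel <- generate_variant_panel(1500, 800, ld_rho = 0, seed = 606)
  ph <- null_phenotypes(1500)
  rec <- run_gwis(panel, ph, "expo", "med", "outc")
  for (pw in unique(rec$pathway)) {
    frac <- mean(rec$p_int[rec$pathway == pw] < 0.05)
    expect_lt(abs(frac - 0.05), 0.02)
  }
  expect_false(any(rec$genome_wide))
})

test_that("greedy clumping follows the index/radius/r2 rule", {
  set.seed(607)
  n <- 2000
  g1 <- rbinom(n, 2, 0.3)
  g2 <- g1; flip <- sample(n, 120)
  g2[flip] <- rbinom(120, 2, 0.3)       # strongly correlated partner
  g3 <- rbinom(n, 2, 0.3)               # independent, other chromosome
  dos <- cbind(a = g1, b = g2, c = g3)
  panel <- toy_panel(dos, chrom = c("chr1", "chr1", "chr2"),
                     pos = c(100000L, 110000L, 50000L))
  stopifnot(cor(g1, g2)^2 > 0.2)
  rec <- data.frame(variant_id = c("a", "b", "c"),
                    chrom = c("chr1", "chr1", "chr2"),
                    pos = c(100000L, 110000L, 50000L),
                    pathway = "upstream",
                    p_int = c(1e-9, 1e-8, 2e-9), stringsAsFactors = FALSE)
  cl <- clump(rec, panel)
  expect_equal(length(unique(cl$clump)), 2)
  expect_setequal(unique(cl$index_variant), c("a", "c"))
  expect_setequal(cl$variant_id[cl$index_variant == "a"], c("a", "b"))

  # no significant record: empty result
  rec2 <- rec; rec2$p_int <- c(0.5, 0.2, 0.9)
  expect_equal(nrow(clump(rec2, panel)), 0)

  # radius excludes a distant same-chromosome partner
  panel_far <- toy_panel(dos, chrom = c("chr1", "chr1", "chr2"),
                         pos = c(100000L, 100000L + 6e6L, 50000L))
  rec3 <- rec; rec3$pos <- panel_far$variant_map$pos
  cl3 <- clump(rec3, panel_far)
  expect_equal(length(unique(cl3$clump)), 3)

  # unknown variant is a lookup error
  rec4 <- rbind(rec, data.frame(variant_id = "zz", chrom = "chr1",
                                pos = 1L, pathway = "upstream", p_int = 1e-9))
  expect_error(clump(rec4, panel), "absent from panel")
})

test_that("gene windows honor strand-aware boundaries", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                      start = 10000L, end = 20000L, strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  vm <- data.frame(id = sprintf("v%d", 1:6), chrom = "chr1",
                   pos = c(8000L, 7999L, 21000L, 21001L, 22000L, 22001L),
                   stringsAsFactors = FALSE)
  asg <- map_variants_to_genes(vm, genes)
  gp <- asg$variant_id[asg$gene_id == "gp"]
  gm <- asg$variant_id[asg$gene_id == "gm"]
  expect_setequal(gp, c("v1", "v3"))          # [8000, 21000] on + strand
  expect_setequal(gm, c("v3", "v4", "v5"))    # [9000, 22000] on - strand
  # overlapping windows assign the shared variant twice
  expect_equal(sum(asg$variant_id == "v3"), 2)
  expect_error(map_variants_to_genes(vm, transform(genes, strand = "?")),
               "unknown strand")
})

test_that("gene-level combination has the right limits", {
  set.seed(608)
  n <- 4000
  # independent variants: Brown reduces to Fisher
  dos <- sapply(1:3, function(i) rbinom(n, 2, 0.3))
  colnames(dos) <- c("v1", "v2", "v3")
  panel <- toy_panel(dos, chrom = "chr1", pos = c(1000L, 2000L, 3000L))
  rec <- data.frame(variant_id = colnames(dos), pathway = "upstream",
                    p_int = c(0.01, 0.2, 0.6), stringsAsFactors = FALSE)
  asg <- data.frame(variant_id = colnames(dos), gene_id = "gene1",
                    stringsAsFactors = FALSE)
  res <- gene_enrichment(rec, asg, panel)
  fisher <- pchisq(sum(-2 * log(rec$p_int)), df = 6, lower.tail = FALSE)
  expect_equal(res$p_gene, fisher, tolerance = 0.02)

  # single variant: identity
  res1 <- gene_enrichment(rec[1, ], asg[1, ], panel)
  expect_equal(res1$p_gene, 0.01, tolerance = 1e-12)

  # duplicated variant: no double counting
  dos2 <- cbind(v1 = dos[, 1], v1b = dos[, 1])
  panel2 <- toy_panel(dos2, chrom = "chr1", pos = c(1000L, 1001L))
  rec2 <- data.frame(variant_id = c("v1", "v1b"), pathway = "upstream",
                     p_int = c(0.01, 0.01), stringsAsFactors = FALSE)
  asg2 <- data.frame(variant_id = c("v1", "v1b"), gene_id = "gene1",
                     stringsAsFactors = FALSE)
  res2 <- gene_enrichment(rec2, asg2, panel2)
  expect_equal(res2$p_gene, 0.01, tolerance = 1e-6)
})

test_that("gene-level p-values are uniform at the null with and without LD", {
  set.seed(609)
  for (rho in c(0, 0.85)) {
    panel <- generate_variant_panel(800, 450, n_chromosomes = 3,
                                    ld_rho = rho, seed = 610 + rho * 10)
    ph <- null_phenotypes(800)
    rec <- run_gwis(panel, ph, "expo", "med", "outc", pathways = "standard")
    vm <- panel$variant_map
    # one gene per consecutive triple of variants
    asg <- data.frame(variant_id = vm$id,
                      gene_id = paste0("g", (seq_len(nrow(vm)) - 1) %/% 3),
                      stringsAsFactors = FALSE)
    res <- gene_enrichment(rec, asg, panel)
    expect_gt(ks.test(res$p_gene, "punif")$p.value, 0.01)
  }
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(611)
  p <- runif(200)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p - 1e-12) && all(q <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("stratified means expose the generative interaction sign", {
  set.seed(612)
  p <- generate_variant_panel(15000, 10, seed = 613)
  tr <- cohort_truth(missing_rate = 0, gamma_gxd = 0.3)
  gen <- generate_cohort(p, tr, seed = 614)
  co <- gen$cohort
  g <- p$dosages[, gen$truth$causal_variant]
  tab <- stratified_summary(co, g, "oily_fish", "mediator_pct",
                            min_count = 5)
  slope <- function(gt) {
    s <- tab[tab$genotype == gt & !tab$suppressed, ]
    coef(lm(s$mean ~ as.numeric(s$category)))[2]
  }
  # positive gamma_gxd: diet-mediator slope grows with allele count
  expect_gt(slope(2) - slope(0), 0)

  # constant response: all cell means equal
  co$flat <- 1.7
  tabf <- stratified_summary(co, g, "oily_fish", "flat", min_count = 5)
  expect_true(all(abs(tabf$mean[!tabf$suppressed] - 1.7) < 1e-12))

  # unobserved genotype is an absent row; uncertain dosages are excluded
  g2 <- pmin(g, 1)
  tab2 <- stratified_summary(co, g2, "oily_fish", "mediator_pct")
  expect_false(any(tab2$genotype == 2))
  g3 <- rep(c(0.5, 1, 0), length.out = nrow(co))
  tab3 <- stratified_summary(co, g3, "oily_fish", "mediator_pct")
  expect_setequal(unique(tab3$genotype), c(0, 1))
})

test_that("sensitivity specifications expand the covariate set as documented", {
  set.seed(615)
  n <- 4000
  d <- as.data.frame(matrix(rnorm(n * 10), n, 10,
                            dimnames = list(NULL, paste0("pc", 1:10))))
  d$g <- rbinom(n, 2, 0.3)
  d$e <- rnorm(n)
  d$bmi <- rnorm(n, 27, 4)
  d$age <- rnorm(n, 55, 8)
  d$y <- 0.2 * d$e + rnorm(n)
  d$m_measured <- rnorm(n)

  base_cov <- expand_covariates(d["age"])
  cv1 <- apply_sensitivity_spec(d, "age", "gpc_exposure_interactions",
                                exposure = "e")
  expect_equal(ncol(cv1) - ncol(base_cov), 10)
  cv2 <- apply_sensitivity_spec(d, c("age", "bmi"),
                                "genotype_covariate_interactions", g = d$g)
  expect_equal(ncol(cv2), 4)
  cv3 <- apply_sensitivity_spec(d, "age", "bmi_adjustment")
  expect_true("bmi" %in% colnames(cv3))
  expect_error(apply_sensitivity_spec(d["age"], character(0),
                                      "bmi_adjustment"), "BMI")

  # an irrelevant BMI adjustment barely moves the interaction z
  f0 <- fit_pathway(d, "standard", covariates = base_cov)
  f3 <- fit_pathway(d, "standard", covariates = cv3)
  expect_lt(abs(f0$z["g:e"] - f3$z["g:e"]), 0.1)

  # confounded interaction (signal carried by PC1 x E, G tags PC1):
  # the base model flags it, the exposure-by-PC model absorbs it
  d2 <- d
  d2$g <- rbinom(n, 2, plogis(1.5 * d2$pc1 - 1))
  d2$y <- 0.35 * d2$pc1 * d2$e + rnorm(n)
  fb <- fit_pathway(d2, "standard", covariates = expand_covariates(d2["age"]))
  fa <- fit_pathway(d2, "standard",
                    covariates = apply_sensitivity_spec(
                      d2, "age", "gpc_exposure_interactions", exposure = "e"))
  expect_gt(abs(fb$z["g:e"]), 4)
  expect_lt(abs(fa$z["g:e"]), 3)
})

test_that("an upstream-only causal interaction shows the decomposition signature", {
  set.seed(616)
  hits <- replicate(25, {
    n <- 4000
    g <- rbinom(n, 2, 0.25)
    e <- rnorm(n)
    # effect size set by the analytic oracle for ~90% upstream power at 1e-4
    v90 <- uniroot(function(v) analytic_power(n * v * 0.6 / (1 - v), 1e-4) - 0.9,
                   c(1e-5, 0.05))$root
    b <- sqrt(v90 / 0.625)
    m <- b * g * e + rnorm(n, sd = sqrt(1 - v90))
    y <- sqrt(0.1) * m + rnorm(n, sd = sqrt(0.9))
    d <- data.frame(g = g, e = e, m_measured = m, y = y)
    up <- fit_pathway(d, "upstream")
    st <- fit_pathway(d, "standard")
    dn <- fit_pathway(d, "downstream")
    c(up = unname(up$p["g:e"]), st = unname(st$p["g:e"]),
      dn = unname(dn$p["g:m_measured"]))
  })
  expect_gt(mean(hits["up", ] < hits["st", ]), 0.9)
  expect_gt(mean(hits["up", ] < 1e-4), 0.7)
  expect_lt(mean(hits["dn", ] < 1e-4), 0.2)
})
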