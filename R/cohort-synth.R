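#' Generate a variant panel with tunable linkage disequilibrium
#'
#' Dosages are built from two haplotypes per sample. Each haplotype is a
#' latent Gaussian AR(1) process along the variants of a chromosome
#' (parameter `ld_rho`), thresholded at the allele-frequency quantile, so
#' adjacent-variant dosage correlation rises with `ld_rho` and `ld_rho = 0`
#' gives independent variants. LD blocks never span chromosome boundaries.
#'
#' @param n_samples Number of samples (rows).
#' @param n_variants Total number of variants, split evenly across
#'   chromosomes.
#' @param n_chromosomes Number of mock chromosomes (default 3).
#' @param maf_range Length-2 range for per-variant minor allele frequencies;
#'   must lie within (0.01, 0.5\] (the analysis convention keeps MAF > 1%).
#' @param ld_rho AR(1) correlation of the latent haplotype process, in
#'   \[0, 1).
#' @param seed Optional seed.
#' @return An object of class `gxe_panel`: `dosages` (samples x variants
#'   matrix with variant ids as column names), `variant_map` (data.frame:
#'   `id`, `chrom`, `pos` (1-based), `ref`, `alt`, `maf`), `ld_profile`.
#' @export
generate_variant_panel <- function(n_samples, n_variants, n_chromosomes = 3,
                                   maf_range = c(0.05, 0.5), ld_rho = 0.8,
                                   seed = NULL) {
  if (n_variants < 1) stop("`n_variants` must be at least 1", call. = FALSE)
  if (n_samples < 2) stop("`n_samples` must be at least 2", call. = FALSE)
  if (min(maf_range) <= 0.01 || max(maf_range) > 0.5)
    stop("`maf_range` must lie within (0.01, 0.5]", call. = FALSE)
  if (ld_rho < 0 || ld_rho >= 1)
    stop("`ld_rho` must lie in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  per_chr <- diff(round(seq(0, n_variants, length.out = n_chromosomes + 1)))
  bases <- c("A", "C", "G", "T")
  dos <- matrix(0, n_samples, 0)
  maps <- list()
  for (chr in seq_len(n_chromosomes)) {
    m <- per_chr[chr]
    if (m == 0) next
    maf <- stats::runif(m, maf_range[1], maf_range[2])
    thr <- stats::qnorm(maf)
    hap <- function() {
      z <- matrix(stats::rnorm(n_samples * m), n_samples, m)
      if (ld_rho > 0 && m > 1) {
        s <- sqrt(1 - ld_rho^2)
        for (j in 2:m) z[, j] <- ld_rho * z[, j - 1] + s * z[, j]
      }
      sweep(z, 2, thr, "<") + 0
    }
    d <- hap() + hap()
    pos <- cumsum(sample(500:5000, m, replace = TRUE))
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    ids <- sprintf("v%d_%d", chr, seq_len(m))
    colnames(d) <- ids
    dos <- cbind(dos, d)
    maps[[chr]] <- data.frame(id = ids, chrom = paste0("chr", chr), pos = pos,
                              ref = unname(ref), alt = unname(alt), maf = maf,
                              stringsAsFactors = FALSE)
  }
  structure(list(dosages = dos, variant_map = do.call(rbind, maps),
                 ld_profile = list(ld_rho = ld_rho,
                                   n_chromosomes = n_chromosomes,
                                   maf_range = maf_range)),
            class = "gxe_panel")
}

#' @export
print.gxe_panel <- function(x, ...) {
  cat(sprintf("<gxe_panel> %d samples x %d variants on %d chromosome(s), ld_rho=%.2f\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$variant_map$chrom)), x$ld_profile$ld_rho))
  invisible(x)
}

#' Ground-truth configuration for the synthetic cohort generator
#'
#' Parameterizes the generative causal structure: a latent dietary index built
#' from four source variables drives a plasma mediator, which is modified at
#' one causal variant (genotype main effect plus genotype-by-diet
#' interaction), and the mediator in turn drives a log-normal inflammatory
#' outcome. A latent "lifestyle" confounder loads on both the diet sources and
#' the outcome, inducing the marginal diet-outcome confounding that covariate
#' adjustment should attenuate.
#'
#' All coefficients act on standardized (unit-variance) latent scales; the
#' mediator is then mapped to percent units and the outcome exponentiated.
#'
#' @param causal_variant Variant id of the interaction locus; `NULL` picks
#'   the panel variant with MAF closest to 0.25 at generation time.
#' @param source_weights Named weights of the four dietary sources in the
#'   latent diet index (oily fish dominating, as in omega-3 intake).
#' @param gamma_g Genotype main effect on the mediator (per allele; negative
#'   = mediator-decreasing allele).
#' @param gamma_d Diet main effect on the mediator.
#' @param gamma_gxd Genotype-by-diet interaction coefficient on the mediator
#'   (the upstream signal; the product uses the uncentered dosage).
#' @param delta_m Mediator effect on the log outcome (negative:
#'   inflammation-lowering).
#' @param conf_diet,conf_outcome Loadings of the lifestyle confounder on the
#'   diet sources and on the log outcome.
#' @param delta_direct Direct diet effect on the log outcome (the `c'` path;
#'   default 0, full mediation).
#' @param sigma_m,sigma_y Residual SDs of mediator and log outcome.
#' @param mediator_mean,mediator_sd,mediator_range Mapping of the latent
#'   mediator to percent-of-total-fatty-acids units, with a physiological
#'   clamp.
#' @param missing_rate MCAR missingness rate of the two fish-oil columns.
#' @return An object of class `gxe_truth` (a validated parameter list).
#' @export
cohort_truth <- function(causal_variant = NULL,
                         source_weights = c(oily_fish = 1, nonoily_fish = 0.35,
                                            fishoil_touchscreen = 0.6,
                                            fishoil_interview = 0.45),
                         gamma_g = -0.25, gamma_d = 0.45, gamma_gxd = 0.12,
                         delta_m = -0.25, conf_diet = 0.5, conf_outcome = -0.3,
                         delta_direct = 0, sigma_m = 0.8, sigma_y = 0.5,
                         mediator_mean = 4.5, mediator_sd = 1.1,
                         mediator_range = c(0.5, 14), missing_rate = 0.05) {
  need <- c("oily_fish", "nonoily_fish", "fishoil_touchscreen",
            "fishoil_interview")
  if (length(source_weights) != 4 || !all(need %in% names(source_weights)))
    stop("`source_weights` must name the four sources: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  if (sigma_m <= 0 || sigma_y <= 0)
    stop("residual SDs must be positive", call. = FALSE)
  structure(as.list(environment()), class = "gxe_truth")
}

# ordered-category sampler tilted by a latent score
tilted_categories <- function(score, values, base_probs) {
  cutq <- stats::qnorm(cumsum(base_probs)[-length(base_probs)])
  idx <- findInterval(score, cutq) + 1L
  values[idx]
}

#' Generate a synthetic cohort over a variant panel
#'
#' Builds phenotypes on top of an existing [generate_variant_panel()] panel
#' under the causal structure configured in [cohort_truth()]: four dietary
#' source variables (ordered servings/day categories for fish, binary with
#' missingness for fish-oil supplementation), demographic and lifestyle
#' covariates including 10 principal-component-like columns and BMI, a
#' plasma mediator in percent units carrying the genotype-by-diet interaction
#' at the causal variant, and a strictly positive right-skewed outcome whose
#' log is linear in the mediator.
#'
#' @param panel A `gxe_panel`.
#' @param truth A `gxe_truth` configuration.
#' @param seed Optional seed.
#' @return List with `cohort` (data.frame) and `truth` (the input truth,
#'   completed with the resolved `causal_variant` and the implied mediation
#'   paths `a`, `b`, `c_prime`).
#' @export
generate_cohort <- function(panel, truth = cohort_truth(), seed = NULL) {
  stopifnot(inherits(panel, "gxe_panel"), inherits(truth, "gxe_truth"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(panel$dosages)
  cv <- truth$causal_variant
  if (is.null(cv)) {
    cv <- panel$variant_map$id[which.min(abs(panel$variant_map$maf - 0.25))]
  } else if (!cv %in% panel$variant_map$id) {
    stop(sprintf("causal variant '%s' not present in panel", cv), call. = FALSE)
  }
  g <- panel$dosages[, cv]

  lifestyle <- stats::rnorm(n)
  serv <- c(0, 0.14, 0.29, 0.43, 0.71, 1)   # servings/day categories
  oily <- tilted_categories(0.8 * truth$conf_diet * lifestyle + stats::rnorm(n, sd = 0.8),
                            serv, c(0.15, 0.25, 0.3, 0.18, 0.08, 0.04))
  nonoily <- tilted_categories(0.5 * truth$conf_diet * lifestyle + stats::rnorm(n, sd = 0.9),
                               serv, c(0.1, 0.25, 0.35, 0.2, 0.07, 0.03))
  fo_ts <- as.numeric(truth$conf_diet * lifestyle + stats::rnorm(n) > 1)
  fo_iv <- as.numeric(0.8 * truth$conf_diet * lifestyle + stats::rnorm(n) > 1.2)

  w <- truth$source_weights
  diet_raw <- w["oily_fish"] * oily + w["nonoily_fish"] * nonoily +
    w["fishoil_touchscreen"] * fo_ts + w["fishoil_interview"] * fo_iv
  diet <- standardize(diet_raw)

  age <- sample(40:69, n, replace = TRUE)
  age_std <- standardize(age)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  smoking <- tilted_categories(-0.4 * lifestyle + stats::rnorm(n),
                               c("never", "past", "current"), c(0.55, 0.3, 0.15))
  alcohol <- tilted_categories(0.2 * lifestyle + stats::rnorm(n),
                               c("never", "monthly", "weekly", "daily"),
                               c(0.2, 0.3, 0.35, 0.15))
  income <- tilted_categories(0.3 * lifestyle + stats::rnorm(n),
                              paste0("inc", 1:5), c(0.2, 0.25, 0.25, 0.2, 0.1))
  education <- tilted_categories(0.3 * lifestyle + stats::rnorm(n),
                                 paste0("edu", 1:6),
                                 c(0.1, 0.15, 0.2, 0.25, 0.2, 0.1))
  cooked_veg <- tilted_categories(0.3 * lifestyle + stats::rnorm(n), serv,
                                  c(0.1, 0.2, 0.3, 0.25, 0.1, 0.05))
  raw_veg <- tilted_categories(0.4 * lifestyle + stats::rnorm(n), serv,
                               c(0.15, 0.2, 0.3, 0.2, 0.1, 0.05))
  fresh_fruit <- tilted_categories(0.4 * lifestyle + stats::rnorm(n), serv,
                                   c(0.1, 0.15, 0.3, 0.25, 0.12, 0.08))
  processed_meat <- tilted_categories(-0.3 * lifestyle + stats::rnorm(n), serv,
                                      c(0.2, 0.3, 0.3, 0.12, 0.05, 0.03))
  bread_type <- tilted_categories(0.3 * lifestyle + stats::rnorm(n),
                                  c("other", "wholemeal"), c(0.45, 0.55))
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  bmi <- 27 - 1.2 * lifestyle + stats::rnorm(n, sd = 3.5)

  m_lat <- truth$gamma_g * g + truth$gamma_d * diet +
    truth$gamma_gxd * g * diet + 0.15 * lifestyle - 0.1 * age_std +
    stats::rnorm(n, sd = truth$sigma_m)
  mediator_pct <- truth$mediator_mean + truth$mediator_sd * m_lat
  mediator_pct <- pmin(pmax(mediator_pct, truth$mediator_range[1]),
                       truth$mediator_range[2])

  y_log <- 0.4 + truth$delta_m * m_lat + truth$delta_direct * diet +
    truth$conf_outcome * lifestyle + 0.15 * age_std +
    0.2 * (smoking == "current") + stats::rnorm(n, sd = truth$sigma_y)
  outcome_raw <- exp(y_log)

  if (truth$missing_rate > 0) {
    fo_ts[stats::runif(n) < truth$missing_rate] <- NA
    fo_iv[stats::runif(n) < truth$missing_rate] <- NA
  }

  cohort <- data.frame(
    sample_id = sprintf("S%06d", seq_len(n)),
    oily_fish = oily, nonoily_fish = nonoily,
    fishoil_touchscreen = fo_ts, fishoil_interview = fo_iv,
    age = age, sex = sex, smoking = smoking, alcohol = alcohol,
    income = income, education = education,
    cooked_veg = cooked_veg, raw_veg = raw_veg, fresh_fruit = fresh_fruit,
    processed_meat = processed_meat, bread_type = bread_type,
    bmi = bmi, stringsAsFactors = FALSE)
  cohort <- cbind(cohort, pcs)
  cohort$mediator_pct <- mediator_pct
  cohort$outcome_raw <- outcome_raw

  truth$causal_variant <- cv
  # marginal a-path on the latent scale: the uncentered g x diet product
  # contributes gamma_gxd * E[g] to the average diet->mediator slope
  truth$paths <- c(a = truth$gamma_d + truth$gamma_gxd * mean(g),
                   b = truth$delta_m, c_prime = truth$delta_direct)
  list(cohort = cohort, truth = truth)
}

#' Write a synthetic cohort to delimited text
#'
#' Tab-separated with header; missing values as empty fields so they
#' round-trip as missing, not zero.
#'
#' @param cohort Cohort data.frame from [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  ok <- try(utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = ""), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write cohort to ", path, ": ", attr(ok, "condition")$message,
         call. = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#' @param path Cohort TSV path.
#' @return Data.frame with empty fields restored as `NA`.
#' @export
read_cohort <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a variant panel as VCF and as dosage/variant-map TSVs
#'
#' Emits `<prefix>.vcf` (minimal VCF 4.2 with per-sample dosages in the `DS`
#' FORMAT field, records sorted by chromosome and position),
#' `<prefix>_dosages.tsv` (samples x variants, 4 decimals) and
#' `<prefix>_variant_map.tsv`.
#'
#' @param panel A `gxe_panel`.
#' @param path_prefix Output path prefix.
#' @param sample_ids Optional sample names (default `S000001, ...`).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_panel <- function(panel, path_prefix, sample_ids = NULL) {
  stopifnot(inherits(panel, "gxe_panel"))
  vm <- panel$variant_map
  ord <- order(vm$chrom, vm$pos)
  vm <- vm[ord, ]
  dos <- panel$dosages[, vm$id, drop = FALSE]
  n <- nrow(dos)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%06d", seq_len(n))
  vcf_path <- paste0(path_prefix, ".vcf")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_ids), collapse = "\t"))
  fmt_ds <- function(v) ifelse(is.na(v), ".", formatC(v, format = "f", digits = 4))
  body <- vapply(seq_len(nrow(vm)), function(j) {
    paste(c(vm$chrom[j], vm$pos[j], vm$id[j], vm$ref[j], vm$alt[j], ".", ".",
            ".", "DS", fmt_ds(dos[, j])), collapse = "\t")
  }, character(1))
  ok <- try(writeLines(c(header, body), vcf_path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write VCF to ", vcf_path, call. = FALSE)
  dos_path <- paste0(path_prefix, "_dosages.tsv")
  dd <- as.data.frame(round(dos, 4))
  dd <- cbind(sample_id = sample_ids, dd)
  utils::write.table(dd, dos_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  map_path <- paste0(path_prefix, "_variant_map.tsv")
  utils::write.table(vm, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf = vcf_path, dosages = dos_path, variant_map = map_path))
}

#' Read a panel from dosage-matrix and variant-map TSVs
#'
#' @param dosage_path Samples x variants TSV with a `sample_id` column.
#' @param map_path Variant-map TSV (`id`, `chrom`, `pos`, `ref`, `alt`, and
#'   optionally `maf`).
#' @return A `gxe_panel`.
#' @export
read_panel_tsv <- function(dosage_path, map_path) {
  dd <- utils::read.table(dosage_path, sep = "\t", header = TRUE,
                          na.strings = "", check.names = FALSE)
  vm <- utils::read.table(map_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  dos <- as.matrix(dd[, setdiff(names(dd), "sample_id"), drop = FALSE])
  rownames(dos) <- dd$sample_id
  if (!all(vm$id %in% colnames(dos)))
    stop("variant map and dosage matrix disagree on variant ids", call. = FALSE)
  if (is.null(vm$maf)) vm$maf <- pmin(colMeans(dos[, vm$id], na.rm = TRUE) / 2,
                                      1 - colMeans(dos[, vm$id], na.rm = TRUE) / 2)
  structure(list(dosages = dos[, vm$id, drop = FALSE], variant_map = vm,
                 ld_profile = list(ld_rho = NA_real_)),
            class = "gxe_panel")
}
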