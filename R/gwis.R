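#' Prepare a right-skewed positive outcome for analysis
#'
#' Log-transforms strictly positive values and removes outliers lying more
#' than `sd_limit` standard deviations from the mean of the log values (mean
#' and SD computed once on all log values). Nonpositive values are excluded,
#' with a report, before the transform.
#'
#' @param values Numeric vector (e.g. a plasma inflammation marker).
#' @param sd_limit Outlier threshold in log-scale SDs (default 5).
#' @param ids Optional identifiers used in the removal report (defaults to
#'   positional indices).
#' @return List with `values` (log-transformed retained values), `kept`
#'   (logical over the input) and `report` (data.frame `id`, `reason`).
#' @export
prepare_outcome <- function(values, sd_limit = 5, ids = NULL) {
  if (is.null(ids)) ids <- seq_along(values)
  pos <- !is.na(values) & values > 0
  if (sum(pos) < 3)
    stop("fewer than 3 positive values: cannot prepare outcome", call. = FALSE)
  lv <- log(values[pos])
  mu <- mean(lv); s <- stats::sd(lv)
  keep_pos <- abs(lv - mu) <= sd_limit * s
  kept <- pos
  kept[pos] <- keep_pos
  report <- rbind(
    if (any(!pos)) data.frame(id = ids[!pos], reason = "nonpositive or missing",
                              stringsAsFactors = FALSE),
    if (any(!keep_pos)) data.frame(id = ids[pos][!keep_pos],
                                   reason = sprintf("beyond %g SD on log scale", sd_limit),
                                   stringsAsFactors = FALSE))
  if (is.null(report))
    report <- data.frame(id = ids[0], reason = character(0))
  list(values = lv[keep_pos], kept = kept, report = report)
}

#' Derive a weighted dietary exposure from source variables
#'
#' Regresses the mediator on the source columns (multivariable OLS, no
#' covariates) and returns the fitted coefficients as source weights together
#' with the weighted sum as the derived exposure, which therefore carries the
#' mediator's units. Missing values in the sources are imputed as 0 ("no
#' intake") both before the regression and in the weighted sum. Sources with
#' zero variance after imputation are dropped with an explicit report.
#'
#' @param sources Data.frame of numeric source columns (conventionally four:
#'   two fish-intake and two fish-oil variables).
#' @param mediator Aligned numeric mediator vector.
#' @return List with `weights` (named), `exposure` (numeric vector) and
#'   `dropped` (names of zero-variance columns).
#' @export
derive_weighted_exposure <- function(sources, mediator) {
  stopifnot(is.data.frame(sources))
  if (nrow(sources) != length(mediator))
    stop("`sources` and `mediator` are not aligned", call. = FALSE)
  src <- as.matrix(sources)
  if (!is.numeric(src))
    stop("all source columns must be numeric", call. = FALSE)
  src[is.na(src)] <- 0
  vars <- apply(src, 2, stats::var)
  dropped <- colnames(src)[vars == 0]
  if (length(dropped))
    message("dropping zero-variance source column(s): ",
            paste(dropped, collapse = ", "))
  src <- src[, vars > 0, drop = FALSE]
  if (!ncol(src))
    stop("no source column with positive variance remains", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, src)
  fit <- fit_ols_robust(X, mediator)
  w <- fit$beta[colnames(src)]
  list(weights = w, exposure = drop(src %*% w), dropped = dropped)
}

#' Run a decomposed genome-wide interaction scan over a variant panel
#'
#' For every variant passing the MAF filter, fits the requested pathway
#' regressions (intercept, dosage, modifier, dosage-by-modifier product,
#' covariates) with heteroscedasticity-robust SEs and records the
#' interaction-term summary statistics. Pathways use the supplied cohort
#' columns as: standard (`outcome ~ g + exposure + g:exposure`), upstream
#' (`mediator ~ g + exposure + g:exposure`), downstream
#' (`outcome ~ g + mediator + g:mediator`). Per-variant failures are emitted
#' as missing-statistics rows, never fatal.
#'
#' @param panel A `gxe_panel` aligned row-wise with `data`.
#' @param data Cohort data.frame.
#' @param exposure,mediator,outcome Column names in `data`.
#' @param covariates Optional character vector of covariate column names
#'   (categorical columns expanded via [expand_covariates()]).
#' @param pathways Subset of `c("standard", "upstream", "downstream")`.
#' @param maf_min Strict lower MAF bound computed on the analysis sample
#'   (default 0.01).
#' @param se_type Robust covariance flavor.
#' @param sig_threshold Genome-wide significance threshold used for the
#'   `genome_wide` flag (default 5e-8).
#' @return Data.frame of class `gxe_gwis` with one row per variant and
#'   pathway: `variant_id`, `chrom`, `pos`, `ref`, `alt`, `maf`, `pathway`,
#'   `beta_int`, `se_int`, `z_int`, `p_int`, `n_used`, `genome_wide`,
#'   `status`.
#' @export
run_gwis <- function(panel, data, exposure, mediator, outcome,
                     covariates = NULL,
                     pathways = c("standard", "upstream", "downstream"),
                     maf_min = 0.01, se_type = "HC0", sig_threshold = 5e-8) {
  stopifnot(inherits(panel, "gxe_panel"))
  pathways <- match.arg(pathways, several.ok = TRUE)
  if (nrow(panel$dosages) != nrow(data))
    stop("panel and cohort have different numbers of samples", call. = FALSE)
  for (col in c(exposure, mediator, outcome))
    if (!col %in% names(data))
      stop("cohort is missing column: ", col, call. = FALSE)
  cv_mat <- if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(data))
    if (length(miss))
      stop("cohort is missing covariate column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    expand_covariates(data[covariates])
  }
  pheno <- data.frame(e = data[[exposure]], m_measured = data[[mediator]],
                      y = data[[outcome]])
  base_keep <- stats::complete.cases(pheno,
                                     if (is.null(cv_mat)) rep(TRUE, nrow(pheno)) else cv_mat)
  vm <- panel$variant_map
  rows <- vector("list", nrow(vm))
  for (j in seq_len(nrow(vm))) {
    dos <- panel$dosages[, vm$id[j]]
    keep <- base_keep & !is.na(dos)
    af <- mean(dos[keep]) / 2
    maf <- min(af, 1 - af)
    if (!is.finite(maf) || maf <= maf_min) next
    d <- pheno[keep, ]
    d$g <- dos[keep]
    cvk <- if (!is.null(cv_mat)) cv_mat[keep, , drop = FALSE]
    res <- lapply(pathways, function(pw) {
      out <- tryCatch({
        fit <- fit_pathway(d, pw, covariates = cvk, se_type = se_type)
        iw <- interaction_wald_test(fit, fit$interaction_term)
        it <- fit$interaction_term
        data.frame(pathway = pw,
                   beta_int = unname(fit$beta[it]),
                   se_int = unname(fit$se_robust[it]),
                   z_int = iw$z, p_int = iw$p, n_used = fit$n_used,
                   status = "ok", stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(pathway = pw, beta_int = NA_real_, se_int = NA_real_,
                   z_int = NA_real_, p_int = NA_real_, n_used = sum(keep),
                   status = conditionMessage(e), stringsAsFactors = FALSE))
      out
    })
    res <- do.call(rbind, res)
    rows[[j]] <- cbind(data.frame(variant_id = vm$id[j], chrom = vm$chrom[j],
                                  pos = vm$pos[j], ref = vm$ref[j],
                                  alt = vm$alt[j], maf = maf,
                                  stringsAsFactors = FALSE),
                       res)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    stop("no variant passed the MAF filter", call. = FALSE)
  out$genome_wide <- !is.na(out$p_int) & out$p_int < sig_threshold
  class(out) <- c("gxe_gwis", "data.frame")
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping of interaction summary statistics
#'
#' PLINK-style clumping for one pathway: repeatedly take the smallest-p
#' unassigned variant with `p < p_threshold` as an index, then assign to it
#' every unassigned variant on the same chromosome within `radius_kb` whose
#' squared Pearson dosage correlation with the index (computed on the panel)
#' exceeds `r2_threshold`. Each variant belongs to at most one clump.
#'
#' @param records `gxe_gwis` rows for a single pathway (error if mixed).
#' @param panel The `gxe_panel` providing reference dosages.
#' @param p_threshold Index-variant p-value threshold (default 5e-8).
#' @param r2_threshold LD r-squared threshold (default 0.2).
#' @param radius_kb Clumping radius in kilobases (default 5000).
#' @return Data.frame with one row per clumped variant: `clump`, `index_variant`,
#'   `variant_id`, `p_int`, `r2_with_index`. Empty (0-row) when no variant
#'   reaches `p_threshold`.
#' @export
clump <- function(records, panel, p_threshold = 5e-8, r2_threshold = 0.2,
                  radius_kb = 5000) {
  stopifnot(inherits(panel, "gxe_panel"))
  if (length(unique(records$pathway)) > 1)
    stop("`records` must contain a single pathway; filter first", call. = FALSE)
  missing_ids <- setdiff(records$variant_id, colnames(panel$dosages))
  if (length(missing_ids))
    stop("variant(s) absent from panel: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  rec <- records[!is.na(records$p_int), ]
  rec <- rec[order(rec$p_int), ]
  assigned <- character(0)
  out <- list()
  k <- 0L
  repeat {
    cand <- rec[!rec$variant_id %in% assigned & rec$p_int < p_threshold, ]
    if (!nrow(cand)) break
    idx <- cand[1, ]
    k <- k + 1L
    near <- rec[!rec$variant_id %in% assigned &
                  rec$chrom == idx$chrom &
                  abs(rec$pos - idx$pos) <= radius_kb * 1000, ]
    gi <- panel$dosages[, idx$variant_id]
    r2 <- vapply(near$variant_id, function(v) {
      if (v == idx$variant_id) return(1)
      suppressWarnings(stats::cor(gi, panel$dosages[, v],
                                  use = "complete.obs"))^2
    }, numeric(1))
    member <- near[!is.na(r2) & r2 > r2_threshold, ]
    r2m <- r2[!is.na(r2) & r2 > r2_threshold]
    out[[k]] <- data.frame(clump = k, index_variant = idx$variant_id,
                           variant_id = member$variant_id, p_int = member$p_int,
                           r2_with_index = unname(r2m),
                           stringsAsFactors = FALSE)
    assigned <- c(assigned, member$variant_id)
  }
  if (!length(out))
    return(data.frame(clump = integer(0), index_variant = character(0),
                      variant_id = character(0), p_int = numeric(0),
                      r2_with_index = numeric(0)))
  do.call(rbind, out)
}

#' Map variants to strand-aware gene windows
#'
#' A gene's window runs from 2 kb upstream to 1 kb downstream of its limits
#' (defaults): `[start - 2000, end + 1000]` on the + strand and
#' `[start - 1000, end + 2000]` on the - strand, 1-based inclusive. A variant
#' may map to several overlapping genes.
#'
#' @param variant_map Data.frame with `id`, `chrom`, `pos`.
#' @param genes Data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (`"+"` or `"-"`).
#' @param upstream_kb,downstream_kb Window extensions in kb (defaults 2 and 1).
#' @return Data.frame `variant_id`, `gene_id` (one row per assignment).
#' @export
map_variants_to_genes <- function(variant_map, genes, upstream_kb = 2,
                                  downstream_kb = 1) {
  if (!all(genes$strand %in% c("+", "-")))
    stop("unknown strand symbol(s): ",
         paste(unique(setdiff(genes$strand, c("+", "-"))), collapse = ", "),
         call. = FALSE)
  up <- round(upstream_kb * 1000)
  dn <- round(downstream_kb * 1000)
  ws <- ifelse(genes$strand == "+", genes$start - up, genes$start - dn)
  we <- ifelse(genes$strand == "+", genes$end + dn, genes$end + up)
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(pmax(ws, 1), we))
  gr_var <- GenomicRanges::GRanges(variant_map$chrom,
                                   IRanges::IRanges(variant_map$pos,
                                                    variant_map$pos))
  hits <- GenomicRanges::findOverlaps(gr_var, gr_genes)
  data.frame(variant_id = variant_map$id[S4Vectors::queryHits(hits)],
             gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

# Covariance of -2*ln(p) for two-sided normal p-values whose underlying z
# statistics are bivariate normal with correlation r; Gauss-Hermite
# quadrature, memoized on |r| rounded to 3 decimals.
brown_cov_env <- new.env(parent = emptyenv())
brown_cov <- function(r) {
  r <- abs(r)
  if (r >= 0.999) return(4)
  if (r <= 0.001) return(0)
  key <- sprintf("%.3f", r)
  hit <- brown_cov_env[[key]]
  if (!is.null(hit)) return(hit)
  gh <- pracma::gaussHermite(48)
  z1 <- sqrt(2) * gh$x
  wt <- gh$w / sqrt(pi)
  gfun <- function(z) -2 * log(pmax(2 * stats::pnorm(-abs(z)), 1e-320))
  s <- sqrt(1 - r^2)
  inner <- vapply(z1, function(a) {
    sum(wt * gfun(r * a + s * z1))
  }, numeric(1))
  ex <- sum(wt * gfun(z1))          # = 2 (mean of chi^2_2), numerically
  val <- sum(wt * gfun(z1) * inner) - ex^2
  brown_cov_env[[key]] <- val
  val
}

#' LD-aware gene-level combination of interaction p-values
#'
#' For each gene, combines the member variants' interaction p-values with
#' Brown's method: `T = sum(-2 ln p)` is referred to a scaled gamma
#' (equivalently scaled chi-square) null whose mean `2k` and variance
#' `4k + 2 * sum cov_ij` account for LD through the pairwise covariance of
#' the `-2 ln p` terms, computed from reference-panel dosage correlations by
#' numerical quadrature. With independent variants this reduces to Fisher's
#' combination; with a single variant it is the identity. Gene q-values are
#' Benjamini-Hochberg within the supplied (single-pathway) record set.
#'
#' @param records `gxe_gwis` rows for a single pathway.
#' @param assignments Data.frame `variant_id`, `gene_id` from
#'   [map_variants_to_genes()].
#' @param panel The reference `gxe_panel`.
#' @return Data.frame `gene_id`, `n_variants`, `p_gene`, `q_value`, sorted by
#'   `p_gene`. Genes whose assigned variants carry no p-value are omitted.
#' @export
gene_enrichment <- function(records, assignments, panel) {
  stopifnot(inherits(panel, "gxe_panel"))
  if (length(unique(records$pathway)) > 1)
    stop("`records` must contain a single pathway; filter first", call. = FALSE)
  pv <- stats::setNames(records$p_int, records$variant_id)
  genes <- unique(assignments$gene_id)
  rows <- lapply(genes, function(gid) {
    vids <- assignments$variant_id[assignments$gene_id == gid]
    vids <- vids[vids %in% names(pv) & !is.na(pv[vids])]
    if (!length(vids)) return(NULL)
    p <- pmax(pv[vids], 1e-320)
    k <- length(p)
    T <- sum(-2 * log(p))
    if (k == 1) {
      pg <- unname(p)
    } else {
      D <- panel$dosages[, vids, drop = FALSE]
      C <- suppressWarnings(stats::cor(D, use = "pairwise.complete.obs"))
      covsum <- 0
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        rij <- C[i, j]
        if (is.finite(rij)) covsum <- covsum + brown_cov(rij)
      }
      mu <- 2 * k
      v <- 4 * k + 2 * covsum
      scale <- v / (2 * mu)
      df <- 2 * mu^2 / v
      pg <- stats::pchisq(T / scale, df, lower.tail = FALSE)
    }
    data.frame(gene_id = gid, n_variants = k, p_gene = pg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no gene with testable variants", call. = FALSE)
  out$q_value <- bh_fdr(out$p_gene)
  out <- out[order(out$p_gene), ]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment (`stats::p.adjust(method = "BH")`); applied
#' separately per pathway by the pipeline, so callers pass one pathway's
#' p-values at a time.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Mean mediator by genotype and exposure category
#'
#' Dosages are rounded to hard calls \{0, 1, 2\} for stratification; dosages
#' in (0.4, 0.6) or (1.4, 1.6) are treated as uncertain calls and excluded
#' (configurable). Cells below `min_count` are suppressed (mean set to `NA`)
#' with the count retained. Unobserved genotype categories are absent rows,
#' not zero rows.
#'
#' @param data Cohort data.frame.
#' @param dosage Numeric dosage vector aligned with `data`.
#' @param exposure_col Name of the (categorical) exposure column.
#' @param response_col Name of the numeric response column (the mediator).
#' @param min_count Minimum cell size to report a mean (default 10).
#' @param exclude_uncertain Drop dosages near hard-call boundaries
#'   (default `TRUE`).
#' @return Data.frame `genotype`, `category`, `mean`, `n`, `suppressed`.
#' @export
stratified_summary <- function(data, dosage, exposure_col, response_col,
                               min_count = 10, exclude_uncertain = TRUE) {
  for (col in c(exposure_col, response_col))
    if (!col %in% names(data))
      stop("cohort is missing column: ", col, call. = FALSE)
  if (length(dosage) != nrow(data))
    stop("`dosage` is not aligned with `data`", call. = FALSE)
  keep <- !is.na(dosage) & !is.na(data[[exposure_col]]) &
    !is.na(data[[response_col]])
  if (exclude_uncertain)
    keep <- keep & !((dosage > 0.4 & dosage < 0.6) |
                       (dosage > 1.4 & dosage < 1.6))
  if (!any(keep)) stop("no usable rows for stratification", call. = FALSE)
  gt <- as.integer(round(dosage[keep]))
  cat_ <- as.character(data[[exposure_col]][keep])
  resp <- data[[response_col]][keep]
  agg <- stats::aggregate(resp, by = list(genotype = gt, category = cat_),
                          FUN = function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(genotype = agg$genotype, category = agg$category,
                    mean = agg$x[, "mean"], n = as.integer(agg$x[, "n"]),
                    stringsAsFactors = FALSE)
  out$suppressed <- out$n < min_count
  out$mean[out$suppressed] <- NA_real_
  out[order(out$genotype, out$category), ]
}

#' Expand covariates for a sensitivity model
#'
#' Builds the covariate set of one of the three sensitivity analyses run at
#' top loci:
#' \describe{
#'   \item{gpc_exposure_interactions}{adds exposure-by-PC product columns for
#'     the 10 principal-component columns;}
#'   \item{genotype_covariate_interactions}{adds genotype-by-covariate
#'     products for every expanded covariate column;}
#'   \item{bmi_adjustment}{adds BMI as a covariate.}
#' }
#' The interaction term of interest is untouched; the expanded covariates are
#' fed back into the pathway fit and the term re-tested.
#'
#' @param data Cohort data.frame.
#' @param covariates Character vector of base covariate column names.
#' @param mode One of `"gpc_exposure_interactions"`,
#'   `"genotype_covariate_interactions"`, `"bmi_adjustment"`.
#' @param exposure Exposure column name (required for mode 1).
#' @param g Dosage vector (required for mode 2).
#' @param pc_cols PC column names (default `pc1..pc10`).
#' @param bmi_col BMI column name (default `"bmi"`).
#' @return Numeric covariate matrix ready for [fit_pathway()].
#' @export
apply_sensitivity_spec <- function(data, covariates,
                                   mode = c("gpc_exposure_interactions",
                                            "genotype_covariate_interactions",
                                            "bmi_adjustment"),
                                   exposure = NULL, g = NULL,
                                   pc_cols = paste0("pc", 1:10),
                                   bmi_col = "bmi") {
  mode <- match.arg(mode)
  base <- if (length(covariates)) expand_covariates(data[covariates])
  if (mode == "gpc_exposure_interactions") {
    miss <- setdiff(pc_cols, names(data))
    if (length(miss))
      stop("cohort is missing PC column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (is.null(exposure) || !exposure %in% names(data))
      stop("`exposure` column is required for exposure-by-PC interactions",
           call. = FALSE)
    px <- as.matrix(data[pc_cols]) * data[[exposure]]
    colnames(px) <- paste0(exposure, ".x.", pc_cols)
    cbind(base, px)
  } else if (mode == "genotype_covariate_interactions") {
    if (is.null(g))
      stop("`g` (dosage vector) is required for genotype-covariate interactions",
           call. = FALSE)
    if (is.null(base))
      stop("no covariates supplied to interact with genotype", call. = FALSE)
    gx <- base * g
    colnames(gx) <- paste0("g.x.", colnames(base))
    cbind(base, gx)
  } else {
    if (!bmi_col %in% names(data))
      stop("cohort is missing BMI column: ", bmi_col, call. = FALSE)
    bm <- matrix(data[[bmi_col]], ncol = 1, dimnames = list(NULL, bmi_col))
    cbind(base, bm)
  }
}
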