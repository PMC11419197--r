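#' Read dosages from a VCF with a DS FORMAT field
#'
#' Parses a (plain-text) VCF whose FORMAT includes the `DS` per-sample
#' alternate-allele dosage, as written by [write_panel()] or by standard
#' imputation pipelines. Multiallelic records are rejected with their
#' coordinates; a missing DS (`.`) propagates as `NA`.
#'
#' @param path VCF file path.
#' @return A `gxe_panel` (MAF in the variant map is computed from the
#'   dosages).
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)   # single-record VCFs drop to a vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    w <- which(multi)[1]
    stop(sprintf("multiallelic record at %s:%s (ALT = %s): split records before import",
                 fix$CHROM[w], fix$POS[w], fix$ALT[w]), call. = FALSE)
  }
  fmt <- unique(v@gt[, "FORMAT"])
  if (!any(vapply(strsplit(fmt, ":"), function(f) "DS" %in% f, logical(1))))
    stop("VCF FORMAT has no DS (dosage) field", call. = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  # variants x samples -> samples x variants
  dos <- t(ds)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- sprintf("%s:%s", fix$CHROM, fix$POS)[is.na(ids) | ids == "."]
  colnames(dos) <- ids
  af <- colMeans(dos, na.rm = TRUE) / 2
  vm <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT,
                   maf = pmin(af, 1 - af), stringsAsFactors = FALSE)
  structure(list(dosages = dos, variant_map = vm,
                 ld_profile = list(ld_rho = NA_real_)),
            class = "gxe_panel")
}

#' Write GWIS records as GEM-style summary statistics
#'
#' Tab-delimited with the fixed column order `SNPID, CHR, POS,
#' Non_Effect_Allele, Effect_Allele, AF, N, Beta_Int, robust_SE_Int,
#' robust_Z_Int, robust_P_Int, pathway`; p-values in scientific notation with
#' six significant digits; rows ordered by chromosome then position (then
#' pathway).
#'
#' @param records A `gxe_gwis` data.frame from [run_gwis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path) {
  req <- c("variant_id", "chrom", "pos", "ref", "alt", "maf", "pathway",
           "beta_int", "se_int", "z_int", "p_int", "n_used")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  r <- records[order(records$chrom, records$pos, records$pathway), ]
  sci <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "e", digits = 5))
  out <- data.frame(SNPID = r$variant_id, CHR = r$chrom, POS = r$pos,
                    Non_Effect_Allele = r$ref, Effect_Allele = r$alt,
                    AF = r$maf, N = r$n_used, Beta_Int = r$beta_int,
                    robust_SE_Int = r$se_int, robust_Z_Int = r$z_int,
                    robust_P_Int = sci(r$p_int), pathway = r$pathway,
                    stringsAsFactors = FALSE)
  ok <- try(utils::write.table(out, path, sep = "\t", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write summary statistics to ", path, call. = FALSE)
  invisible(path)
}

#' Read summary statistics written by [write_summary_stats()]
#' @param path Summary-statistics TSV path.
#' @return Data.frame in `gxe_gwis` column naming.
#' @export
read_summary_stats <- function(path) {
  s <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  data.frame(variant_id = s$SNPID, chrom = s$CHR, pos = s$POS,
             ref = s$Non_Effect_Allele, alt = s$Effect_Allele, maf = s$AF,
             pathway = s$pathway, beta_int = s$Beta_Int,
             se_int = s$robust_SE_Int, z_int = s$robust_Z_Int,
             p_int = as.numeric(s$robust_P_Int), n_used = s$N,
             stringsAsFactors = FALSE)
}

# ---- strict configuration -------------------------------------------------

config_schema <- function() {
  list(
    seed = 1L, out_dir = ".", log_level = "info",
    power_grid = list(kind = "downstream", n_samples = 1000L, maf = 0.25,
                      v_interaction = 0.005, v_transmit = 0.10, icc_m = 1,
                      product_centering = "none",
                      n_reps = 500L, alpha = 0.05),
    mediate = list(data = NULL, exposure = NULL, mediator = NULL,
                   outcome = NULL, covariates = NULL, draws = 20L,
                   level = 0.95),
    synth = list(n_samples = 20000L, n_variants = 2000L, n_chromosomes = 3L,
                 maf_min = 0.05, maf_max = 0.5, ld_rho = 0.8,
                 missing_rate = 0.05, gamma_gxd = 0.12),
    gwis = list(cohort = NULL, vcf = NULL, dosages = NULL, variant_map = NULL,
                exposure = NULL, mediator = NULL, outcome = NULL,
                covariates = NULL, pathways = c("standard", "upstream",
                                                "downstream"),
                maf_min = 0.01, se_type = "HC0"),
    clump = list(summary_stats = NULL, pathway = NULL, p_threshold = 5e-8,
                 r2_threshold = 0.2, radius_kb = 5000),
    gene_test = list(summary_stats = NULL, pathway = NULL, genes = NULL,
                     upstream_kb = 2, downstream_kb = 1),
    stratify = list(cohort = NULL, variant = NULL, exposure = NULL,
                    response = NULL, min_count = 10L)
  )
}

merge_strict <- function(defaults, supplied, path = character(0)) {
  if (is.null(supplied)) return(defaults)
  if (!is.list(supplied)) return(supplied)
  unknown <- setdiff(names(supplied), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration key '%s'",
                 paste(c(path, unknown[1]), collapse = ".")), call. = FALSE)
  for (nm in names(supplied)) {
    d <- defaults[[nm]]
    if (is.list(d) && !is.null(names(d)))
      defaults[nm] <- list(merge_strict(d, supplied[[nm]], c(path, nm)))
    else defaults[nm] <- list(supplied[[nm]])  # [[<- would drop NULL values
  }
  defaults
}

#' Parse a run configuration file (strict)
#'
#' Reads a YAML configuration and merges it over the package defaults
#' (e.g. `power_grid`: `n_samples = 1000`, `alpha = 0.05`, `n_reps = 500`). Unknown
#' keys are fatal, so a misspelled grid parameter cannot silently fall back
#' to a default; error messages name the offending key.
#'
#' @param path YAML file path.
#' @return An object of class `gxe_config` (nested named list with defaults
#'   filled).
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  supplied <- yaml::read_yaml(path)
  cfg <- merge_strict(config_schema(), supplied)
  structure(cfg, class = c("gxe_config", "list"))
}

#' Write a resolved configuration next to run outputs
#' @param config A `gxe_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

gxe_log_level <- function() getOption("gxedecomp.log_level", "info")

gxe_log <- function(level = "info", ...) {
  ranks <- c(debug = 0, info = 1, warn = 2, quiet = 3)
  if (ranks[[level]] >= ranks[[gxe_log_level()]])
    message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}
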