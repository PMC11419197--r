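#' Ordinary least squares with heteroscedasticity-robust covariance
#'
#' Fits `y ~ design` (the design matrix must already include its intercept)
#' and returns sandwich-covariance Wald statistics for every term:
#' `(X'X)^-1 X' diag(r_i^2 w_i) X (X'X)^-1` with `w_i = 1` (HC0),
#' `n / (n - k)` (HC1) or `1 / (1 - h_i)^2` (HC3, with `h_i` the leverage).
#' Two-sided p-values use the standard normal reference on `z = beta / se`,
#' the large-sample convention of genome-wide interaction software.
#'
#' Rows with any missing value in `design` or `y` are dropped (complete-case);
#' the number retained is reported as `n_used`.
#'
#' @param design Numeric matrix including an intercept column; column names
#'   become term labels (unnamed columns are labelled `x1, x2, ...`).
#' @param y Numeric response vector, `length(y) == nrow(design)`.
#' @param se_type One of `"HC0"` (default), `"HC1"`, `"HC3"`.
#' @return An object of class `gxe_fit`: list with `term_names`, `beta`,
#'   `cov_robust`, `se_robust`, `z`, `p`, `n_used`, `se_type`, plus
#'   `residuals` and `fitted` on the retained rows.
#' @export
fit_ols_robust <- function(design, y, se_type = c("HC0", "HC1", "HC3")) {
  se_type <- match.arg(se_type)
  design <- as.matrix(design)
  if (nrow(design) != length(y))
    stop("`design` and `y` have different numbers of rows", call. = FALSE)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  keep <- stats::complete.cases(design, y)
  X <- design[keep, , drop = FALSE]
  yy <- y[keep]
  n <- nrow(X); k <- ncol(X)
  if (n <= k)
    stop(sprintf("insufficient data: %d complete rows for %d coefficients", n, k),
         call. = FALSE)
  qx <- qr(X)
  if (qx$rank < k) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):k]]
    stop("singular design: collinear term(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  beta <- qr.coef(qx, yy)
  fitted <- drop(X %*% beta)
  r <- yy - fitted
  R <- qr.R(qx)[, order(qx$pivot), drop = FALSE]
  xtx_inv <- chol2inv(chol(crossprod(R)))
  w <- switch(se_type,
              HC0 = rep(1, n),
              HC1 = rep(n / (n - k), n),
              HC3 = {
                h <- rowSums(qr.Q(qx)^2)
                1 / (1 - h)^2
              })
  meat <- crossprod(X * (r * sqrt(w)))
  V <- xtx_inv %*% meat %*% xtx_inv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(V), 0))
  z <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(term_names = colnames(X), beta = beta, cov_robust = V,
         se_robust = se, z = z, p = p, n_used = n, se_type = se_type,
         residuals = r, fitted = fitted),
    class = "gxe_fit")
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat(sprintf("<gxe_fit> n_used=%d, robust SE type=%s\n", x$n_used, x$se_type))
  print(data.frame(beta = x$beta, se = x$se_robust, z = x$z, p = x$p,
                   row.names = x$term_names))
  invisible(x)
}

#' Wald test of a single (interaction) term from a robust fit
#'
#' @param fit A `gxe_fit` from [fit_ols_robust()].
#' @param term Term label to test (typically the product term).
#' @return List with elements `z` and the two-sided normal `p`.
#' @export
interaction_wald_test <- function(fit, term) {
  stopifnot(inherits(fit, "gxe_fit"))
  i <- match(term, fit$term_names)
  if (is.na(i))
    stop(sprintf("term '%s' not found in fit (terms: %s)", term,
                 paste(fit$term_names, collapse = ", ")), call. = FALSE)
  list(z = unname(fit$z[i]), p = unname(fit$p[i]))
}

#' Build the design matrix for one pathway-specific interaction regression
#'
#' The three regressions of the decomposed framework share one shape
#' (intercept, genotype, modifier, genotype-by-modifier product, covariates)
#' and differ in which columns play the outcome and modifier roles:
#' \describe{
#'   \item{standard}{`y ~ g + e + g:e` — outcome vs the raw exposure.}
#'   \item{upstream}{`m_measured ~ g + e + g:e` — the mediator as outcome.}
#'   \item{downstream}{`y ~ g + m + g:m` — the measured mediator as modifier.}
#' }
#' The product column is the elementwise product of the supplied genotype and
#' modifier columns; no re-centering is applied unless requested.
#'
#' @param data A `gxe_simdata` data.frame (or any data.frame with columns
#'   `g`, `e`, `m_measured`/`m_true`, `y`).
#' @param pathway `"standard"`, `"upstream"` or `"downstream"`.
#' @param covariates Optional numeric matrix or data.frame of extra columns.
#' @param center_product If `TRUE`, both genotype and modifier are mean-centered
#'   before the product is formed (the main-effect columns are left as supplied).
#' @param mediator_main For the downstream pathway, which mediator serves as
#'   the main-effect column: `"measured"` (default; what an analyst observes)
#'   or `"true"`. The product term always uses the measured mediator.
#' @return List with `design` (matrix), `y` (response) and `interaction_term`
#'   (the label of the product column).
#' @export
build_pathway_design <- function(data,
                                 pathway = c("standard", "upstream", "downstream"),
                                 covariates = NULL, center_product = FALSE,
                                 mediator_main = c("measured", "true")) {
  pathway <- match.arg(pathway)
  mediator_main <- match.arg(mediator_main)
  need <- switch(pathway,
                 standard = c("g", "e", "y"),
                 upstream = c("g", "e", "m_measured"),
                 downstream = c("g", "m_measured", "y"))
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  g <- data$g
  if (pathway == "standard") {
    mod <- data$e; mod_lab <- "e"; y <- data$y
  } else if (pathway == "upstream") {
    mod <- data$e; mod_lab <- "e"; y <- data$m_measured
  } else {
    mod <- data$m_measured; mod_lab <- "m_measured"
    main_col <- if (mediator_main == "true") {
      if (is.null(data$m_true))
        stop("data is missing required column(s): m_true", call. = FALSE)
      data$m_true
    } else data$m_measured
    y <- data$y
  }
  gp <- if (center_product) g - mean(g, na.rm = TRUE) else g
  mp <- if (center_product) mod - mean(mod, na.rm = TRUE) else mod
  int_lab <- paste0("g:", mod_lab)
  main_mod <- if (pathway == "downstream") main_col else mod
  X <- cbind(`(Intercept)` = 1, g = g, mod = main_mod, int = gp * mp)
  colnames(X) <- c("(Intercept)", "g", mod_lab, int_lab)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (is.null(colnames(cv)))
      colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
    if (nrow(cv) != nrow(X))
      stop("covariate rows do not match data rows", call. = FALSE)
    X <- cbind(X, cv)
  }
  list(design = X, y = y, interaction_term = int_lab)
}

#' Fit one pathway regression and test its interaction term
#'
#' Convenience wrapper: [build_pathway_design()] then [fit_ols_robust()].
#'
#' @inheritParams build_pathway_design
#' @inheritParams fit_ols_robust
#' @return The `gxe_fit`, with the interaction label in `$interaction_term`.
#' @export
fit_pathway <- function(data, pathway, covariates = NULL,
                        se_type = "HC0", center_product = FALSE,
                        mediator_main = "measured") {
  d <- build_pathway_design(data, pathway, covariates = covariates,
                            center_product = center_product,
                            mediator_main = mediator_main)
  fit <- fit_ols_robust(d$design, d$y, se_type = se_type)
  fit$interaction_term <- d$interaction_term
  fit
}

#' Expand a covariate data.frame into a numeric model matrix
#'
#' Numeric columns pass through; factors and character columns become 0/1
#' indicator columns with the most frequent level as the reference. Levels
#' such as "do not know" / "prefer not to answer" are deliberately kept as
#' ordinary levels so they form their own adjustment indicator.
#'
#' @param covariates A data.frame of covariates (may mix numeric and
#'   categorical columns).
#' @return Numeric matrix with one column per numeric covariate or non-reference
#'   level.
#' @export
expand_covariates <- function(covariates) {
  stopifnot(is.data.frame(covariates))
  cols <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
      return(m)
    }
    f <- as.factor(v)
    tab <- table(f)
    ref <- names(tab)[which.max(tab)]
    lv <- setdiff(levels(f), ref)
    if (!length(lv)) return(NULL)  # single-level factor carries no information
    m <- sapply(lv, function(l) as.numeric(f == l))
    m <- matrix(m, ncol = length(lv),
                dimnames = list(NULL, paste0(nm, ".", lv)))
    m[is.na(covariates[[nm]]), ] <- NA
    m
  })
  do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
}
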