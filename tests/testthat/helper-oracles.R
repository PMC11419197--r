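# Independent oracles used across the suite. These deliberately avoid the
# package's own linear-algebra path.

# Elementwise sandwich covariance: (X'X)^-1 X' diag(r^2 w) X (X'X)^-1
brute_force_sandwich <- function(X, y, type = "HC0") {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  r <- as.vector(y - X %*% beta)
  h <- diag(X %*% xtx_inv %*% t(X))
  w <- switch(type, HC0 = rep(1, n), HC1 = rep(n / (n - k), n),
              HC3 = 1 / (1 - h)^2)
  meat <- matrix(0, k, k)
  for (i in seq_len(n)) meat <- meat + r[i]^2 * w[i] * X[i, ] %*% t(X[i, ])
  xtx_inv %*% meat %*% xtx_inv
}

# Linear mediation system with unit-variance traits so a, b, c_prime are the
# standardized path coefficients: x ~ N(0,1); m = a x + e; y = b m + c' x + e.
make_mediation_data <- function(n, a, b, c_prime = 0) {
  x <- rnorm(n)
  m <- a * x + rnorm(n, sd = sqrt(1 - a^2))
  vy <- b^2 + c_prime^2 + 2 * a * b * c_prime
  stopifnot(vy < 1)
  y <- b * m + c_prime * x + rnorm(n, sd = sqrt(1 - vy))
  data.frame(x = x, m = m, y = y)
}

# Hand-built panel around an explicit dosage matrix.
toy_panel <- function(dosages, chrom, pos, ids = colnames(dosages)) {
  maf <- pmin(colMeans(dosages) / 2, 1 - colMeans(dosages) / 2)
  structure(list(
    dosages = dosages,
    variant_map = data.frame(id = ids, chrom = chrom, pos = pos,
                             ref = "A", alt = "G", maf = maf,
                             stringsAsFactors = FALSE),
    ld_profile = list(ld_rho = NA_real_)), class = "gxe_panel")
}

# Null cohort phenotypes independent of any panel.
null_phenotypes <- function(n) {
  data.frame(expo = rnorm(n), med = rnorm(n), outc = rnorm(n))
}
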