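# Small builders used across the suite. Everything is generated in code;
# no stored fixtures.

# A minimal valid sumstats data frame; override any column via ...
ss_df <- function(n = 3, ...) {
  out <- data.frame(
    rsid = sprintf("rs%03d", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 1000L,
    effect_allele = "A",
    other_allele = "G",
    eaf = 0.3,
    beta = seq_len(n) / 10,
    se = 0.05,
    pvalue = 1e-10,
    n = 1000,
    stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

make_ss <- function(n = 3, trait = "X", scale = "sd", ...) {
  sumstats(ss_df(n, ...), trait = trait, trait_scale = scale)
}

# Random harmonized panel with known generating coefficients.
# extra_resid adds exposure-independent scatter to by (heterogeneity).
make_panel <- function(J = 50, K = 3, seed = 1,
                       theta = c(0.4, -0.15, 0.2)[seq_len(K)],
                       alpha = rep(0, J), extra_resid = 0,
                       se_y_range = c(0.01, 0.05)) {
  set.seed(seed)
  B <- matrix(stats::rnorm(J * K, 0, 0.1), J, K)
  se_y <- stats::runif(J, se_y_range[1], se_y_range[2])
  by <- as.numeric(B %*% theta) + alpha +
    stats::rnorm(J) * sqrt(se_y^2 + extra_resid^2)
  new_mr_panel(sprintf("rs%03d", seq_len(J)), rep("1", J),
               seq_len(J) * 1e6L, paste0("X", seq_len(K)),
               B, matrix(0.005, J, K), matrix(1e-10, J, K),
               by, se_y)
}

# Independent normal-equations WLS oracle: (X' W X)^{-1} X' W y with
# elementwise weight algebra, deliberately avoiding the package's QR path.
wls_oracle <- function(X, y, w) {
  W <- diag(w)
  XtWX <- t(X) %*% W %*% X
  inv <- solve(XtWX)
  coef <- inv %*% t(X) %*% W %*% y
  resid <- y - X %*% coef
  rss <- sum(w * resid^2)
  df <- nrow(X) - ncol(X)
  list(coef = as.numeric(coef), cov_fixed = inv, rss = rss, df = df)
}
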