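# Printed per-allele CAD association of the LIPG N396S variant: OR 0.90
# (95% CI 0.86-0.95); its HDL-C effect is recovered from the per-SD OR 0.64.
lipg_by <- log(0.90)
lipg_se <- (log(0.95) - log(0.86)) / (2 * 1.96)
lipg_bx <- log(0.90) / log(0.64)

test_that("single-SNP Wald ratio reproduces the per-SD HDL-C estimate", {
  est <- wald_ratio(lipg_by, lipg_se, lipg_bx, exposure = "HDL")
  expect_equal(round(est$or, 2), 0.64)
  # interval propagates outcome uncertainty only and brackets the OR
  expect_equal(round(est$ci_low, 2), 0.52, tolerance = 0.01)
  expect_equal(round(est$ci_high, 2), 0.79, tolerance = 0.01)
  expect_lt(est$ci_low, est$or)
  expect_gt(est$ci_high, est$or)
  expect_equal(est$pvalue, 2 * pnorm(-abs(lipg_by / lipg_se)))
})

test_that("Wald ratio handles unit, null, negative, and zero exposures", {
  by <- 0.3; se <- 0.1
  unit <- wald_ratio(by, se, 1)
  expect_equal(unit$or, exp(by))
  expect_equal(unit$ci_low, exp(by - 1.96 * se))
  expect_equal(unit$ci_high, exp(by + 1.96 * se))
  null <- wald_ratio(0, se, 0.5)
  expect_equal(null$or, 1)
  expect_equal(log(null$ci_low), -log(null$ci_high))
  # negative bx reorders the interval endpoints ascending
  neg <- wald_ratio(by, se, -0.5)
  expect_lt(neg$ci_low, neg$ci_high)
  expect_equal(neg$theta, -0.6)
  expect_error(wald_ratio(by, se, 0), "zero")
  # delta-method variant widens the SE
  delta <- wald_ratio(by, se, 0.5, se_x = 0.1)
  expect_gt(delta$se_theta, wald_ratio(by, se, 0.5)$se_theta)
})

test_that("odds-ratio conversion matches the printed multivariable estimate", {
  got <- to_odds_ratio(0.4383, 0.0263)
  expect_equal(round(got$or, 2), 1.55)
  expect_equal(round(got$ci95[1], 2), 1.47)
  expect_equal(round(got$ci95[2], 2), 1.63)
  expect_equal(to_odds_ratio(0, 1)$or, 1)
  expect_error(to_odds_ratio(0.1, 0))
})

test_that("multivariable IVW matches the normal-equations oracle and lm", {
  for (seed in c(2, 9, 17)) {
    p <- make_panel(J = 50, K = 3, seed = seed, extra_resid = 0.03)
    w <- 1 / p$se_y^2
    oracle <- wls_oracle(p$B, p$by, w)
    got_f <- ivw_multivariable(p, se_scaling = "fixed")
    got_m <- ivw_multivariable(p, se_scaling = "multiplicative")
    expect_equal(got_f$theta, oracle$coef, tolerance = 1e-8)
    expect_equal(got_f$se_theta, unname(sqrt(diag(oracle$cov_fixed))),
                 tolerance = 1e-8)
    phi <- max(1, oracle$rss / oracle$df)
    expect_equal(got_m$se_theta, unname(sqrt(diag(oracle$cov_fixed) * phi)),
                 tolerance = 1e-8)
    expect_equal(got_m$pvalue,
                 unname(2 * pt(-abs(oracle$coef /
                                      sqrt(diag(oracle$cov_fixed) * phi)),
                               df = oracle$df)), tolerance = 1e-8)
    # second independent route: weighted lm without intercept
    fit <- lm(p$by ~ 0 + p$B, weights = w)
    expect_equal(unname(got_f$theta), unname(coef(fit)), tolerance = 1e-8)
  }
})

test_that("IVW reduces to closed forms in degenerate designs", {
  # J = 1, K = 1: the Wald point estimate
  p1 <- make_panel(J = 1, K = 1)
  expect_equal(ivw_univariable(p1)$theta, unname(p1$by[1] / p1$B[1, 1]))
  # equal weights, K = 1: origin-constrained OLS closed form
  p <- make_panel(J = 10, K = 1, seed = 4)
  p$se_y <- rep(0.02, 10)
  est <- ivw_multivariable(p)
  expect_equal(est$theta, sum(p$B[, 1] * p$by) / sum(p$B[, 1]^2),
               tolerance = 1e-12)
  # duplicated SNP: same estimate as one SNP, smaller SE
  p2 <- make_panel(J = 1, K = 1, seed = 6)
  pdup <- subset_panel(p2, c(1, 1))
  pdup$rsids <- c("a", "b")
  one <- ivw_univariable(p2)
  two <- ivw_univariable(pdup)
  expect_equal(two$theta, one$theta)
  expect_lt(two$se_theta, one$se_theta)
})

test_that("IVW errors on too few instruments and collinear exposures", {
  p <- make_panel(J = 3, K = 3)
  expect_error(ivw_multivariable(p), "insufficient")
  pc <- make_panel(J = 20, K = 2)
  pc$B[, 2] <- 2 * pc$B[, 1]
  expect_error(ivw_multivariable(pc), "collinear")
  pz <- make_panel(J = 20, K = 2)
  pz$B[, 2] <- 0
  expect_error(ivw_multivariable(pz), "all-zero")
})

test_that("Egger coefficients match an intercept-augmented oracle", {
  p <- make_panel(J = 50, K = 3, seed = 12, extra_resid = 0.03)
  o <- orient_to_exposure(p, 2)
  w <- 1 / o$se_y^2
  oracle <- wls_oracle(cbind(1, o$B), o$by, w)
  got <- egger_multivariable(p, 2, se_scaling = "fixed")
  expect_equal(got$theta, oracle$coef[3], tolerance = 1e-8)
  expect_equal(got$intercept, oracle$coef[1], tolerance = 1e-8)
  expect_equal(got$se_intercept, unname(sqrt(oracle$cov_fixed[1, 1])),
               tolerance = 1e-8)
  fit <- lm(o$by ~ o$B, weights = w)
  expect_equal(unname(got$intercept), unname(coef(fit)[1]), tolerance = 1e-8)
  expect_error(egger_multivariable(make_panel(J = 4, K = 3), 1),
               "insufficient")
})

test_that("Egger equals IVW when residuals are weight-orthogonal to the intercept", {
  set.seed(31)
  J <- 40; K <- 2
  B <- cbind(abs(rnorm(J, 0.1, 0.03)), rnorm(J, 0, 0.1))  # col 1 positive:
  se_y <- runif(J, 0.01, 0.03)                            # orientation no-op
  w <- 1 / se_y^2
  theta <- c(0.3, -0.2)
  e0 <- rnorm(J, 0, 0.05)
  X <- cbind(1, B)
  # project the residual out of span(1, B) under the weight inner product
  proj <- X %*% solve(t(X) %*% (w * X), t(X) %*% (w * e0))
  e <- e0 - proj
  panel <- new_mr_panel(sprintf("s%02d", 1:J), rep("1", J), 1:J,
                        c("A", "B"), B, matrix(0.005, J, K),
                        matrix(1e-10, J, K),
                        as.numeric(B %*% theta) + e, se_y)
  ivw <- ivw_multivariable(panel, "fixed")
  egg <- egger_multivariable(panel, 1, "fixed")
  expect_equal(egg$theta, ivw$theta[1], tolerance = 1e-10)
  expect_equal(egg$intercept, 0, tolerance = 1e-10)
})

test_that("rescaling all outcome SEs preserves estimates and scales fixed SEs", {
  p <- make_panel(J = 30, K = 2, seed = 8, extra_resid = 0.02)
  p2 <- p
  p2$se_y <- 3 * p$se_y
  a <- ivw_multivariable(p, "fixed")
  b <- ivw_multivariable(p2, "fixed")
  expect_equal(b$theta, a$theta, tolerance = 1e-10)
  expect_equal(b$se_theta, 3 * a$se_theta, tolerance = 1e-10)
})

test_that("IVW coverage at nominal 95% is calibrated under the null model", {
  reps <- 500
  hits <- 0
  for (r in seq_len(reps)) {
    cfg <- sim_config(J = 100, K = 1, exposure_names = "X",
                      theta = 0.3, pleio_frac = 0, seed = 5000 + r)
    sim <- simulate_sumstats(cfg)
    panel <- harmonize(sim$exposures, sim$outcome)
    est <- ivw_multivariable(panel)
    lo <- est$theta - 1.96 * est$se_theta
    hi <- est$theta + 1.96 * est$se_theta
    hits <- hits + (lo <= 0.3 && 0.3 <= hi)
  }
  expect_gte(hits / reps, 0.92)
  expect_lte(hits / reps, 0.98)
})
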