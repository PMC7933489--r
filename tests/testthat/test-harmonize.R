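test_that("allele swap in the outcome flips the outcome beta sign", {
  exp1 <- make_ss(1, trait = "X", effect_allele = "A", other_allele = "G",
                  beta = 0.10, eaf = 0.3)
  out <- make_ss(1, trait = "Y", effect_allele = "G", other_allele = "A",
                 beta = -0.05, eaf = 0.7, scale = "log_or")
  panel <- harmonize(list(exp1), out)
  expect_equal(panel$by, 0.05)
  expect_equal(unname(panel$B[1, 1]), 0.10)
})

test_that("strand flips are recognized and incompatible alleles dropped", {
  exp1 <- make_ss(2, trait = "X", effect_allele = c("A", "A"),
                  other_allele = c("G", "G"))
  # SNP1 reported on the other strand (T/C = complement of A/G): no flip;
  # SNP2 has alleles incompatible with the reference: dropped
  out <- make_ss(2, trait = "Y", effect_allele = c("T", "A"),
                 other_allele = c("C", "C"), beta = c(0.2, 0.2),
                 scale = "log_or")
  panel <- harmonize(list(exp1), out)
  expect_identical(panel$rsids, "rs001")
  expect_equal(panel$by, 0.2)
  expect_identical(unname(panel$dropped["incompatible"]), 1L)
})

test_that("ambiguous palindromic SNPs are dropped, informative ones aligned by frequency", {
  exp1 <- make_ss(3, trait = "X", effect_allele = "A", other_allele = "T",
                  eaf = c(0.5, 0.1, 0.1))
  out <- make_ss(3, trait = "Y", effect_allele = "A", other_allele = "T",
                 beta = c(0.2, 0.2, 0.2), eaf = c(0.5, 0.1, 0.9),
                 scale = "log_or")
  panel <- harmonize(list(exp1), out, drop_palindromic = TRUE)
  # rs001: eaf 0.5 ambiguous -> dropped; rs002: frequencies agree -> kept
  # as-is; rs003: frequencies disagree -> flipped
  expect_identical(panel$rsids, c("rs002", "rs003"))
  expect_equal(panel$by, c(0.2, -0.2))
  expect_identical(unname(panel$dropped["palindromic"]), 1L)
  # with the flag off, label alignment is used and all three survive
  expect_equal(n_snps(harmonize(list(exp1), out, drop_palindromic = FALSE)),
               3L)
})

test_that("panel is the complete-case intersection of all traits", {
  exp1 <- make_ss(3, trait = "X")
  out <- make_ss(2, trait = "Y", scale = "log_or")  # rs003 absent
  panel <- harmonize(list(exp1), out)
  expect_identical(panel$rsids, c("rs001", "rs002"))
  expect_error(
    harmonize(list(make_ss(2, rsid = c("a", "b"))),
              make_ss(2, rsid = c("c", "d"), scale = "log_or")),
    "no SNPs shared")
})

test_that("harmonization is idempotent on its own output", {
  cfg <- sim_config(J = 30, K = 2, seed = 7)
  sim <- simulate_sumstats(cfg)
  panel <- harmonize(sim$exposures, sim$outcome)
  rt <- panel_to_sumstats(panel)
  panel2 <- harmonize(rt$exposures, rt$outcome)
  expect_equal(panel2$B, panel$B, tolerance = 1e-12)
  expect_equal(panel2$by, panel$by, tolerance = 1e-12)
  expect_identical(panel2$rsids, panel$rsids)
})

test_that("flipping alleles and negating beta in an input leaves the panel unchanged", {
  cfg <- sim_config(J = 20, K = 2, seed = 11)
  sim <- simulate_sumstats(cfg)
  base <- harmonize(sim$exposures, sim$outcome)
  flipped <- as.data.frame(sim$outcome)
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  out2 <- sumstats(flipped, trait = "outcome", trait_scale = "log_or")
  alt <- harmonize(sim$exposures, out2)
  expect_equal(alt$by, base$by, tolerance = 1e-12)
  expect_equal(alt$B, base$B, tolerance = 1e-12)
})

test_that("orientation negates flipped rows, is an involution, preserves magnitudes", {
  p <- make_panel(J = 40, K = 3, seed = 3)
  o <- orient_to_exposure(p, 2)
  expect_true(all(o$B[, 2] >= 0))
  expect_equal(abs(o$B), abs(p$B))
  expect_equal(abs(o$by), abs(p$by))
  expect_identical(o$se_y, p$se_y)
  expect_identical(o$SE_B, p$SE_B)
  expect_identical(o$P_B, p$P_B)
  # idempotent once oriented; re-flipping the flipped rows restores the input
  expect_equal(orient_to_exposure(o, 2), o)
  flip <- p$B[, 2] < 0
  o2 <- o
  o2$B[flip, ] <- -o2$B[flip, , drop = FALSE]
  o2$by[flip] <- -o2$by[flip]
  expect_equal(o2$B, p$B)
  expect_equal(o2$by, p$by)
})

test_that("zero-intercept IVW is invariant to orientation to any exposure", {
  p <- make_panel(J = 50, K = 3, seed = 5, extra_resid = 0.02)
  base <- ivw_multivariable(p)
  for (k in 1:3) {
    ivw_k <- ivw_multivariable(orient_to_exposure(p, k))
    expect_equal(ivw_k$theta, base$theta, tolerance = 1e-10)
    expect_equal(ivw_k$se_theta, base$se_theta, tolerance = 1e-10)
  }
})
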