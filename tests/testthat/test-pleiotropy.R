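test_that("Bonferroni thresholds reproduce the standard printed values", {
  expect_equal(bonferroni_threshold(0.05, 2338, sig_figs = 1), 2e-5)
  expect_equal(bonferroni_threshold(0.05, 6, sig_figs = 2), 0.0083)
  expect_equal(bonferroni_threshold(0.05, 3, sig_figs = 3), 0.0167)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 2338), 0.05 / 2338)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("crosstab percentages are counts over complete denominators", {
  inst <- list(E = make_ss(4, trait = "E"))
  sec <- list(
    E = make_ss(4, trait = "E", pvalue = rep(1e-10, 4)),
    S = make_ss(4, trait = "S", pvalue = c(1e-6, 1e-6, 0.5, 0.5)))
  tab <- pleiotropy_crosstab(inst, sec, threshold = 2e-5)
  expect_equal(tab$percent["E", "S"], 50)
  expect_equal(tab$counts["E", "S"], 2)
  # self-comparison: every instrument is genome-wide significant -> 100%
  expect_equal(tab$percent["E", "E"], 100)
})

test_that("missing secondary statistics shrink the denominator, empty sets flag", {
  inst <- list(E = make_ss(4, trait = "E"))
  sec <- list(S = make_ss(2, trait = "S", pvalue = c(1e-6, 0.5)))  # 2 missing
  tab <- pleiotropy_crosstab(inst, sec, threshold = 2e-5)
  expect_equal(tab$denominators["E", "S"], 2)
  expect_equal(tab$percent["E", "S"], 50)
  expect_equal(tab$missing["E", "S"], 2L)
  empty <- pleiotropy_crosstab(list(E = subset_sumstats(inst$E, integer(0))),
                               sec, threshold = 2e-5)
  expect_true(nrow(empty$undefined) >= 1)
})

test_that("composite any-of column and threshold monotonicity behave", {
  inst <- list(E = make_ss(4, trait = "E"))
  sec <- list(S1 = make_ss(4, pvalue = c(1e-6, 0.5, 0.5, 0.5), trait = "S1"),
              S2 = make_ss(4, pvalue = c(0.5, 1e-6, 0.5, 0.5), trait = "S2"))
  tab <- pleiotropy_crosstab(inst, sec, 2e-5, composite = c("S1", "S2"))
  expect_equal(tab$percent["E", "composite"], 50)
  tighter <- pleiotropy_crosstab(inst, sec, 1e-7, composite = c("S1", "S2"))
  expect_true(all(tighter$percent <= tab$percent, na.rm = TRUE))
  # invariance to instrument order
  perm <- pleiotropy_crosstab(list(E = subset_sumstats(inst$E, 4:1)), sec,
                              2e-5, composite = c("S1", "S2"))
  expect_equal(perm$percent, tab$percent)
  expect_true(all(tab$counts <= tab$denominators, na.rm = TRUE))
})

test_that("restricted-set filtering removes exactly the sub-threshold SNPs", {
  inst <- make_ss(3, trait = "E")
  sec <- list(S = make_ss(3, trait = "S", pvalue = c(1e-6, 0.3, 0.8)))
  out <- restricted_set_filter(inst, sec, threshold = 2e-5)
  expect_identical(out$removed, "rs001")
  expect_identical(out$retained$rsid, c("rs002", "rs003"))
  # survivors have all secondary p >= threshold, exactly assertable
  pv <- sec$S$pvalue[match(out$retained$rsid, sec$S$rsid)]
  expect_true(all(pv >= 2e-5))
  expect_equal(out$diagnostics$n_retained, 2L)
})

test_that("under uniform-null secondary traits retention follows the closed form", {
  set.seed(77)
  n <- 4000
  inst <- make_ss(n, trait = "E",
                  rsid = sprintf("v%05d", 1:n), pos = 1:n)
  mk_sec <- function(nm) make_ss(n, trait = nm,
                                 rsid = sprintf("v%05d", 1:n), pos = 1:n,
                                 pvalue = runif(n))
  sec <- list(A = mk_sec("A"), B = mk_sec("B"), C = mk_sec("C"))
  thr <- 0.01
  out <- restricted_set_filter(inst, sec, threshold = thr)
  expect_equal(out$diagnostics$n_retained / n, (1 - thr)^3, tolerance = 0.01)
  # retained p-values are uniform on [thr, 1]: P(p < 0.1) = (0.1-thr)/(1-thr)
  expect_equal(out$diagnostics$frac_p_below_0.1, (0.1 - thr) / (1 - thr),
               tolerance = 0.02)
})

test_that("strong pleiotropy leaves a near-empty survivor set", {
  cfg <- sim_config(J = 60, K = 3, seed = 21, pleio_frac = 0.95,
                    pleio_scale = 1)
  sim <- simulate_sumstats(cfg)
  inst <- select_genome_wide(sim$exposures[[1]])
  sec <- list(HDL = sim$exposures[[2]], TG = sim$exposures[[3]])
  out <- restricted_set_filter(inst, sec, threshold = 0.1)
  expect_lt(out$diagnostics$n_retained, nrow(inst) / 2)
})
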