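test_that("genome-wide selection uses strict inequality and is idempotent", {
  s <- make_ss(3, pvalue = c(1e-9, 2e-8, 1e-8))
  sel <- select_genome_wide(s, 1e-8)
  expect_identical(sel$rsid, "rs001")
  expect_identical(select_genome_wide(sel, 1e-8)$rsid, sel$rsid)
  expect_equal(nrow(select_genome_wide(subset_sumstats(s, integer(0)))), 0L)
  # alpha = 1 retains everything except p exactly 1
  s2 <- make_ss(2, pvalue = c(0.9999, 1))
  expect_identical(select_genome_wide(s2, 1)$rsid, "rs001")
})

test_that("clumping keeps the smaller-p SNP of a linked pair, both if distant", {
  mk <- function(pos) make_ss(2, pos = pos, pvalue = c(1e-10, 1e-9))
  ld2 <- ld_matrix(c("rs001", "rs002"),
                   matrix(c(1, 0.5, 0.5, 1), 2), rep("1", 2), c(1e6, 2e6))
  expect_identical(clump(mk(c(1e6, 2e6)), ld2)$rsid, "rs001")
  ld_far <- ld_matrix(c("rs001", "rs002"),
                      matrix(c(1, 0.5, 0.5, 1), 2), rep("1", 2),
                      c(1e6, 21e6))
  expect_identical(sort(clump(mk(c(1e6, 21e6)), ld_far)$rsid),
                   c("rs001", "rs002"))
})

test_that("an asymmetric LD matrix is rejected", {
  m <- matrix(c(1, 0.5, 0.2, 1), 2)
  expect_error(ld_matrix(c("a", "b"), m, rep("1", 2), c(1, 2)),
               "symmetric")
  expect_error(ld_matrix(c("a", "b"), matrix(c(1, 2, 2, 1), 2),
                         rep("1", 2), c(1, 2)), "\\[0, 1\\]")
})

# Direct re-statement of the greedy definition, written over data frames with
# a repeat loop, independent of the package's index bookkeeping.
clump_oracle <- function(snps, ld, r2_max = 0.01, window_bp = 10e6) {
  df <- as.data.frame(snps)
  kept <- character(0)
  repeat {
    if (nrow(df) == 0) break
    df <- df[order(df$pvalue, df$pos, df$rsid), ]
    idx <- df[1, ]
    kept <- c(kept, idx$rsid)
    drop <- vapply(seq_len(nrow(df)), function(i) {
      r <- df[i, ]
      if (r$rsid == idx$rsid) return(TRUE)
      if (r$chrom != idx$chrom) return(FALSE)
      if (abs(r$pos - idx$pos) > window_bp) return(FALSE)
      both_in <- r$rsid %in% ld$rsids && idx$rsid %in% ld$rsids
      r2 <- if (both_in) ld$r2[r$rsid, idx$rsid] else 0
      r2 > r2_max
    }, logical(1))
    df <- df[!drop, ]
  }
  kept
}

test_that("clump matches a brute-force oracle on random block-LD fixtures", {
  for (seed in 1:5) {
    cfg <- sim_config(J = 20, K = 1, seed = seed,
                      ld_blocks = list(sizes = c(5, 5, 4), r2 = 0.6,
                                       decay = (seed %% 2 == 0),
                                       within_bp = 5e5, between_bp = 2e7))
    sim <- simulate_sumstats(cfg)
    ld <- simulate_ld_blocks(cfg)
    snps <- sim$exposures[[1]]
    got <- clump(snps, ld, r2_max = 0.01, window_bp = 10e6)
    expect_identical(got$rsid, clump_oracle(snps, ld))
    # no kept pair within 10 Mb exceeds the r2 threshold
    for (i in seq_len(nrow(got))) for (j in seq_len(nrow(got))) {
      if (i < j && abs(got$pos[i] - got$pos[j]) <= 10e6) {
        expect_lte(ld$r2[got$rsid[i], got$rsid[j]], 0.01)
      }
    }
    # maximality: every removed SNP conflicts with a kept SNP of smaller p
    removed <- setdiff(snps$rsid, got$rsid)
    for (r in removed) {
      ri <- match(r, snps$rsid)
      conflict <- any(vapply(seq_len(nrow(got)), function(k) {
        got$pvalue[k] <= snps$pvalue[ri] &&
          got$chrom[k] == snps$chrom[ri] &&
          abs(got$pos[k] - snps$pos[ri]) <= 10e6 &&
          ld$r2[got$rsid[k], r] > 0.01
      }, logical(1)))
      expect_true(conflict)
    }
    # invariance to input row order
    perm <- sample(nrow(snps))
    expect_identical(clump(subset_sumstats(snps, perm), ld)$rsid, got$rsid)
  }
})

test_that("SNPs absent from the LD matrix are treated as unlinked with a warning", {
  snps <- make_ss(2, pos = c(1e6, 2e6), pvalue = c(1e-10, 1e-9))
  ld1 <- ld_matrix("rs001", matrix(1), "1", 1e6)
  expect_warning(out <- clump(snps, ld1), "absent")
  expect_equal(nrow(out), 2L)
})

test_that("locus windows are closed +/- 1 Mb intervals on the locus chromosome", {
  loc <- locus("LIPG", "18", 5e7)
  s <- make_ss(4, chrom = c("18", "18", "18", "2"),
               pos = c(5e7 + 999999, 5e7 + 1000000, 5e7 + 1000001, 5e7))
  got <- locus_window(s, loc)
  expect_identical(got$rsid, c("rs001", "rs002"))
  expect_equal(nrow(locus_window(subset_sumstats(s, integer(0)), loc)), 0L)
})
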