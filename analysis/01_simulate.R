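#!/usr/bin/env Rscript
# Stage 1: build the synthetic two-sample MR study.
#
# Generates GWAS summary statistics for six exposures (three lipid traits in
# SD units: LDL-C, HDL-C, TG; three metabolic syndrome traits: BMI in SD,
# T2D in log-OR, SBP untransformed) and a binary outcome in log-OR, under a
# causal diagram with known effects, 30% cross-trait pleiotropy, block LD,
# and three SNPs carrying large direct outcome effects for the outlier test
# to find. Writes the per-trait TSVs, the LD matrix, a locus table, and the
# ground truth under results/data/.

suppressPackageStartupMessages(library(mrpleio))
suppressPackageStartupMessages(library(jsonlite))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# true causal log-ORs chosen at the scale reported for lipid and metabolic
# trait associations with CAD (OR ~1.5 per SD LDL-C down to ~1.04 per mmHg)
theta <- c(LDL = log(1.48), HDL = log(0.87), TG = log(1.17),
           BMI = log(1.33), T2D = log(1.07), SBP = log(1.037))

cfg <- sim_config(
  J = 600, K = 6,
  exposure_names = names(theta),
  trait_scales = c("sd", "sd", "sd", "sd", "log_or", "raw"),
  theta = unname(theta),
  pleio_frac = 0.30, pleio_scale = 0.7,
  n_outliers = 3, outlier_size = 8,
  ld_blocks = list(sizes = c(5, 4, 3), r2 = 0.6),
  seed = 20240901)

sim <- simulate_sumstats(cfg)
ld <- simulate_ld_blocks(cfg)

for (s in sim$exposures) {
  write_sumstats(s, file.path(out, paste0(tolower(trait_name(s)), ".tsv")))
}
write_sumstats(sim$outcome, file.path(out, "outcome.tsv"))

# LD as long-format triples (only non-trivial pairs)
pairs <- which(upper.tri(ld$r2) & ld$r2 > 0, arr.ind = TRUE)
write.table(data.frame(rsid_a = ld$rsids[pairs[, 1]],
                       rsid_b = ld$rsids[pairs[, 2]],
                       r2 = ld$r2[pairs]),
            file.path(out, "ld_long.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# loci for monogenic MR: the first two LD blocks, named after HDL-C- and
# TG-modifying genes to mirror the locus-specific analyses
loci <- data.frame(gene = c("LIPG", "LPL"), chrom = c("1", "2"),
                   tss = c(20000L, 20000L), trait = c("HDL", "TG"))
write.table(loci, file.path(out, "loci.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

write_json(list(theta = as.list(theta),
                pleiotropic_snps = sim$truth$pleiotropic_snps,
                outlier_snps = sim$truth$outlier_snps,
                seed = cfg$seed),
           file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("wrote %d traits x %d SNPs to %s\n", 7, cfg$J, out))
cat(sprintf("ground truth: %d SNPs with cross-trait pleiotropy (%.0f%%), %d planted outliers: %s\n",
            length(sim$truth$pleiotropic_snps),
            100 * length(sim$truth$pleiotropic_snps) / cfg$J,
            length(sim$truth$outlier_snps),
            paste(sim$truth$outlier_snps, collapse = ", ")))
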