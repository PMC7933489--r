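#' Configuration for the summary-statistics generator
#'
#' Describes a two-sample MR study under an explicit causal diagram: J SNPs
#' affect K exposures through the instrument-strength matrix gamma; each
#' exposure affects a binary outcome (log-OR scale) through the causal vector
#' theta; a configurable fraction of SNPs additionally carries a direct
#' (exposure-independent) outcome effect alpha. Exposure and outcome
#' associations are measured in independent samples, so their sampling errors
#' are independent (the two-sample design). Standard errors follow the
#' GWAS scaling `1 / sqrt(2 maf (1 - maf) n)` (times
#' `1 / sqrt(phi (1 - phi))` for the binary outcome with case fraction phi).
#'
#' The defaults mirror a large lipid-traits-in-CAD study: J = 343 instruments
#' for K = 3 exposures in SD units (LDL-C, HDL-C, TG), exposure GWAS
#' n = 291,746, outcome GWAS n = 547,261 with case fraction 0.224, 30% of
#' SNPs with a cross-trait effect on a second exposure, and no direct outcome
#' effects.
#'
#' @param J number of SNPs.
#' @param K number of exposures.
#' @param exposure_names,trait_scales names and scales (length K).
#' @param theta true causal effects, log-OR per unit exposure (length K).
#' @param gamma optional J x K matrix of true SNP-exposure effects; when
#'   `NULL` it is drawn from the sparse law below.
#' @param gamma_min,gamma_scale instrument-strength law: each SNP has one
#'   primary exposure (assigned round-robin) with effect magnitude
#'   `gamma_min + |Normal(0, gamma_scale)|`, guaranteeing genome-wide
#'   detectability at `n_exp`.
#' @param gamma_sign `"random"` (default) gives each primary effect a random
#'   sign; `"positive"` keeps them positive, so orientation to that exposure
#'   flips no rows (used when the Egger intercept must estimate the raw mean
#'   direct effect).
#' @param pleio_frac fraction of SNPs with a cross-trait effect on one other
#'   randomly chosen exposure.
#' @param pleio_scale magnitude of the cross-trait effect relative to the
#'   primary effect.
#' @param direct_frac fraction of SNPs with a direct outcome effect.
#' @param alpha_mean,alpha_sd law of the direct effects
#'   `Normal(alpha_mean, alpha_sd)`; a nonzero mean produces directional
#'   pleiotropy.
#' @param n_outliers,outlier_size number of SNPs given an additional
#'   point-mass direct effect of `outlier_size` log-OR units (targets for the
#'   outlier test).
#' @param n_exp exposure GWAS sample size (scalar or length K).
#' @param n_out,case_fraction outcome GWAS size and case fraction.
#' @param maf_range allele frequencies drawn uniformly on this interval.
#' @param ld_blocks list describing the LD fixture: `sizes` (block sizes
#'   summing to at most J; remaining SNPs are singletons), `r2` (within-block
#'   r-squared), `decay` (if `TRUE`, AR-style decay `r2^|i-j|`),
#'   `within_bp` (spacing of SNPs inside a block), `between_bp` (spacing of
#'   block starts).
#' @param seed RNG seed.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(J = 343L, K = 3L,
                       exposure_names = NULL,
                       trait_scales = rep("sd", K),
                       theta = NULL,
                       gamma = NULL, gamma_min = 0.03, gamma_scale = 0.04,
                       gamma_sign = c("random", "positive"),
                       pleio_frac = 0.3, pleio_scale = 0.7,
                       direct_frac = 0, alpha_mean = 0, alpha_sd = 0,
                       n_outliers = 0L, outlier_size = 0,
                       n_exp = 291746, n_out = 547261,
                       case_fraction = 0.224,
                       maf_range = c(0.05, 0.5),
                       ld_blocks = list(sizes = integer(), r2 = 0.8,
                                        decay = FALSE, within_bp = 1e4,
                                        between_bp = 2e7),
                       seed = 1L) {
  gamma_sign <- match.arg(gamma_sign)
  J <- as.integer(J)
  K <- as.integer(K)
  if (is.null(exposure_names)) {
    exposure_names <- c("LDL", "HDL", "TG",
                        paste0("X", seq_len(max(0, K - 3)) + 3))[seq_len(K)]
  }
  if (is.null(theta)) {
    theta <- c(0.44, -0.15, 0.21, rep(0.1, max(0, K - 3)))[seq_len(K)]
  }
  stopifnot(J >= 1, K >= 1, length(exposure_names) == K,
            length(theta) == K, direct_frac >= 0, direct_frac <= 1,
            pleio_frac >= 0, pleio_frac <= 1,
            all(n_exp > 0), n_out > 0,
            case_fraction > 0, case_fraction < 1)
  if (!is.null(gamma)) {
    gamma <- as.matrix(gamma)
    stopifnot(nrow(gamma) == J, ncol(gamma) == K)
  }
  if (length(n_exp) == 1) n_exp <- rep(n_exp, K)
  defaults <- list(sizes = integer(), r2 = 0.8, decay = FALSE,
                   within_bp = 1e4, between_bp = 2e7)
  ld_blocks <- utils::modifyList(defaults, ld_blocks)
  if (sum(ld_blocks$sizes) > J) {
    stop("sim_config: ld_blocks sizes exceed J", call. = FALSE)
  }
  if (ld_blocks$r2 < 0 || ld_blocks$r2 > 1) {
    stop("sim_config: within-block r2 must lie in [0, 1]", call. = FALSE)
  }
  structure(list(J = J, K = K, exposure_names = exposure_names,
                 trait_scales = trait_scales, theta = theta, gamma = gamma,
                 gamma_min = gamma_min, gamma_scale = gamma_scale,
                 gamma_sign = gamma_sign,
                 pleio_frac = pleio_frac, pleio_scale = pleio_scale,
                 direct_frac = direct_frac, alpha_mean = alpha_mean,
                 alpha_sd = alpha_sd, n_outliers = as.integer(n_outliers),
                 outlier_size = outlier_size,
                 n_exp = n_exp, n_out = n_out, case_fraction = case_fraction,
                 maf_range = maf_range, ld_blocks = ld_blocks,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic genomic layout shared by simulate_sumstats and
# simulate_ld_blocks: blocks first, then singletons. Blocks cycle over the 22
# autosomes so positions stay inside the 32-bit integer range at any J;
# consecutive blocks on one chromosome are spaced `between_bp` apart (beyond
# the clumping window), SNPs within a block `within_bp` apart (inside it).
.sim_layout <- function(config) {
  sizes <- config$ld_blocks$sizes
  n_in_blocks <- sum(sizes)
  sizes <- c(sizes, rep(1L, config$J - n_in_blocks))
  block <- rep(seq_along(sizes), sizes)
  within <- unlist(lapply(sizes, seq_len)) - 1L
  chrom <- (block - 1L) %% 22L + 1L
  rank_on_chrom <- (block - 1L) %/% 22L
  pos <- rank_on_chrom * config$ld_blocks$between_bp +
    within * config$ld_blocks$within_bp + 1
  if (max(pos) > .Machine$integer.max) {
    stop("simulated layout exceeds the integer position range; reduce J or ",
         "between_bp", call. = FALSE)
  }
  data.frame(rsid = sprintf("rs%05d", seq_len(config$J)),
             chrom = as.character(chrom), pos = as.integer(pos),
             block = block)
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Draws per-SNP effects under the configured causal diagram. The true
#' outcome association of SNP j is
#' `by_j = sum_k gamma[j, k] theta[k] + alpha_j`; observed exposure effects
#' are `gamma + Normal(0, se_x)` and observed outcome effects
#' `by + Normal(0, se_y)` with independent draws (two-sample independence).
#' P-values are two-sided normal. Fully reproducible given `config$seed`.
#'
#' @param config a [sim_config].
#' @return list with `exposures` (list of K [sumstats]), `outcome` (a
#'   [sumstats] on the log-OR scale), and `truth`: realized `gamma`, `theta`,
#'   `alpha`, `maf`, rsid sets `pleiotropic_snps` (cross-trait effects) and
#'   `outlier_snps` (point-mass direct effects), and per-SNP `se_x`, `se_y`.
#' @export
simulate_sumstats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  J <- config$J
  K <- config$K
  layout <- .sim_layout(config)
  maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
  het <- 2 * maf * (1 - maf)
  se_x <- sqrt(1 / outer(het, config$n_exp))            # J x K, SD-unit traits
  phi <- config$case_fraction
  se_y <- sqrt(1 / (het * config$n_out * phi * (1 - phi)))

  if (is.null(config$gamma)) {
    primary <- rep(seq_len(K), length.out = J)
    mag <- config$gamma_min + abs(stats::rnorm(J, 0, config$gamma_scale))
    sgn <- if (config$gamma_sign == "positive") rep(1, J)
           else sample(c(-1, 1), J, replace = TRUE)
    gamma <- matrix(0, J, K)
    gamma[cbind(seq_len(J), primary)] <- sgn * mag
    pleio <- stats::runif(J) < config$pleio_frac & K > 1
    if (any(pleio)) {
      other <- vapply(primary[pleio], function(p) {
        if (K == 1) p else sample(setdiff(seq_len(K), p), 1L)
      }, integer(1))
      gamma[cbind(which(pleio), other)] <-
        sample(c(-1, 1), sum(pleio), replace = TRUE) *
        config$pleio_scale * mag[pleio]
    }
  } else {
    gamma <- config$gamma
    pleio <- rowSums(gamma != 0) > 1
  }

  alpha <- numeric(J)
  direct <- stats::runif(J) < config$direct_frac
  alpha[direct] <- stats::rnorm(sum(direct), config$alpha_mean,
                                config$alpha_sd)
  outlier_idx <- integer(0)
  if (config$n_outliers > 0) {
    outlier_idx <- sample(seq_len(J), config$n_outliers)
    alpha[outlier_idx] <- alpha[outlier_idx] +
      config$outlier_size * se_y[outlier_idx]
  }

  by_true <- as.numeric(gamma %*% config$theta) + alpha
  bx_obs <- gamma + matrix(stats::rnorm(J * K), J, K) * se_x
  by_obs <- by_true + stats::rnorm(J) * se_y

  base <- data.frame(rsid = layout$rsid, chrom = layout$chrom,
                     pos = layout$pos, effect_allele = "A",
                     other_allele = "G", eaf = maf,
                     stringsAsFactors = FALSE)
  # p-values from two-sided normal tests, floored at the smallest positive
  # double so extreme associations stay inside the (0, 1] invariant
  two_sided <- function(z) pmax(2 * stats::pnorm(-abs(z)),
                                .Machine$double.xmin)
  exposures <- lapply(seq_len(K), function(k) {
    df <- base
    df$beta <- bx_obs[, k]
    df$se <- se_x[, k]
    df$pvalue <- two_sided(df$beta / df$se)
    df$n <- config$n_exp[k]
    sumstats(df, trait = config$exposure_names[k],
             trait_scale = config$trait_scales[k])
  })
  df <- base
  df$beta <- by_obs
  df$se <- se_y
  df$pvalue <- two_sided(df$beta / df$se)
  df$n <- config$n_out
  outcome <- sumstats(df, trait = "outcome", trait_scale = "log_or")

  list(exposures = exposures, outcome = outcome,
       truth = list(gamma = gamma, theta = config$theta, alpha = alpha,
                    maf = maf, se_x = se_x, se_y = se_y,
                    pleiotropic_snps = layout$rsid[pleio],
                    outlier_snps = layout$rsid[outlier_idx],
                    direct_snps = layout$rsid[direct | seq_len(J) %in%
                                                outlier_idx],
                    config = config))
}

#' Block-diagonal LD fixture matching a simulation's layout
#'
#' Builds the r-squared matrix implied by `config$ld_blocks`: within a block,
#' r-squared is the configured constant, or decays as `r2^|i - j|` when
#' `decay` is set; across blocks it is zero. Positions match those emitted by
#' [simulate_sumstats] for the same config, so blocks sit inside the clumping
#' window and distinct blocks outside it.
#'
#' @param config a [sim_config].
#' @return an [ld_matrix].
#' @export
simulate_ld_blocks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- .sim_layout(config)
  J <- config$J
  r2 <- matrix(0, J, J)
  r2_base <- config$ld_blocks$r2
  for (b in unique(layout$block)) {
    idx <- which(layout$block == b)
    if (length(idx) == 1) {
      r2[idx, idx] <- 1
    } else {
      d <- abs(outer(seq_along(idx), seq_along(idx), `-`))
      r2[idx, idx] <- if (isTRUE(config$ld_blocks$decay)) r2_base^d
                      else ifelse(d == 0, 1, r2_base)
    }
  }
  ld_matrix(layout$rsid, r2, layout$chrom, layout$pos)
}
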