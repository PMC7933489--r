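#' Harmonized SNP-by-trait effect panel
#'
#' The design matrix of all MR regressions: for J SNPs shared by every trait,
#' the J x K matrix of exposure effects `B` with matching standard errors
#' `SE_B` and p-values `P_B`, and the outcome log-OR vector `by` with standard
#' errors `se_y`, all expressed relative to a single effect allele per SNP.
#'
#' @param rsids,chrom,pos per-SNP identifiers and coordinates (length J).
#' @param exposures exposure trait names (length K).
#' @param B,SE_B,P_B J x K matrices of exposure betas, SEs, p-values.
#' @param by,se_y outcome effect (log-OR) and SE vectors (length J).
#' @param outcome outcome trait name.
#' @param effect_allele,other_allele optional per-SNP alleles after alignment.
#' @param dropped named integer vector of per-reason drop counts from
#'   harmonization.
#' @return an object of class `mr_panel`.
#' @export
new_mr_panel <- function(rsids, chrom, pos, exposures, B, SE_B, P_B, by, se_y,
                         outcome = "outcome",
                         effect_allele = NULL, other_allele = NULL,
                         dropped = integer()) {
  J <- length(rsids)
  K <- length(exposures)
  B <- matrix(as.numeric(B), J, K, dimnames = list(NULL, exposures))
  SE_B <- matrix(as.numeric(SE_B), J, K, dimnames = list(NULL, exposures))
  P_B <- matrix(as.numeric(P_B), J, K, dimnames = list(NULL, exposures))
  stopifnot(length(by) == J, length(se_y) == J,
            length(chrom) == J, length(pos) == J)
  if (J > 0 && any(!is.finite(se_y) | se_y <= 0)) {
    stop("mr_panel: outcome SEs must be positive and finite", call. = FALSE)
  }
  structure(list(rsids = as.character(rsids), chrom = as.character(chrom),
                 pos = as.integer(pos), exposures = as.character(exposures),
                 B = B, SE_B = SE_B, P_B = P_B,
                 by = as.numeric(by), se_y = as.numeric(se_y),
                 outcome = outcome,
                 effect_allele = effect_allele, other_allele = other_allele,
                 dropped = dropped),
            class = "mr_panel")
}

#' @export
print.mr_panel <- function(x, ...) {
  cat(sprintf("Harmonized MR panel: %d SNPs x %d exposures (%s) -> %s\n",
              length(x$rsids), length(x$exposures),
              paste(x$exposures, collapse = ", "), x$outcome))
  if (length(x$dropped)) {
    cat("dropped during harmonization:",
        paste(names(x$dropped), x$dropped, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of SNPs / exposures in a panel
#' @param x an `mr_panel`.
#' @return integer.
#' @export
n_snps <- function(x) length(x$rsids)

#' @rdname n_snps
#' @export
n_exposures <- function(x) length(x$exposures)

#' Restrict a panel to a subset of SNP rows
#' @param panel an `mr_panel`.
#' @param keep logical or integer row index, or character rsids.
#' @return an `mr_panel` with the selected rows.
#' @export
subset_panel <- function(panel, keep) {
  if (is.character(keep)) keep <- match(keep, panel$rsids)
  new_mr_panel(panel$rsids[keep], panel$chrom[keep], panel$pos[keep],
               panel$exposures,
               panel$B[keep, , drop = FALSE],
               panel$SE_B[keep, , drop = FALSE],
               panel$P_B[keep, , drop = FALSE],
               panel$by[keep], panel$se_y[keep], outcome = panel$outcome,
               effect_allele = panel$effect_allele[keep],
               other_allele = panel$other_allele[keep],
               dropped = panel$dropped)
}

#' Restrict a panel to a single exposure column
#' @param panel an `mr_panel`.
#' @param exposure exposure name or column index.
#' @return an `mr_panel` with K = 1.
#' @export
panel_exposure <- function(panel, exposure) {
  k <- if (is.character(exposure)) match(exposure, panel$exposures) else exposure
  if (is.na(k) || k < 1 || k > length(panel$exposures)) {
    stop("panel_exposure: unknown exposure", call. = FALSE)
  }
  new_mr_panel(panel$rsids, panel$chrom, panel$pos, panel$exposures[k],
               panel$B[, k, drop = FALSE], panel$SE_B[, k, drop = FALSE],
               panel$P_B[, k, drop = FALSE], panel$by, panel$se_y,
               outcome = panel$outcome,
               effect_allele = panel$effect_allele,
               other_allele = panel$other_allele)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) .COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome summary statistics into an MR panel
#'
#' Restricts all traits to the SNPs present with complete data in every trait
#' (complete-case across all K+1 traits) and aligns each trait's effects to a
#' common effect allele per SNP. The reference allele is the first exposure's
#' effect allele. Where a trait reports the alleles swapped, its beta sign is
#' flipped and its effect-allele frequency replaced by 1 - eaf; strand flips
#' (complement alleles) are recognized. Strand-ambiguous A/T and C/G SNPs
#' cannot be disambiguated by allele labels: with `drop_palindromic = TRUE`
#' (default) they are dropped when any trait's eaf is missing or in
#' `[0.42, 0.58]`, and otherwise aligned by matching which allele is the minor
#' one; with `drop_palindromic = FALSE` they are aligned by allele labels
#' alone. SNPs whose alleles are incompatible with the reference under swap
#' and strand-flip are dropped; all drop reasons are counted in the panel's
#' `dropped` attribute.
#'
#' @param exposures list of [sumstats] objects (at least one).
#' @param outcome a [sumstats] object for the (binary) outcome on the log-OR
#'   scale.
#' @param drop_palindromic drop ambiguous palindromic SNPs (see Details).
#' @param ambiguous_eaf frequency band treated as uninformative for
#'   palindromic alignment.
#' @return an [new_mr_panel] object.
#' @export
harmonize <- function(exposures, outcome, drop_palindromic = TRUE,
                      ambiguous_eaf = c(0.42, 0.58)) {
  if (inherits(exposures, "sumstats")) exposures <- list(exposures)
  stopifnot(length(exposures) >= 1, inherits(outcome, "sumstats"))
  traits <- c(exposures, list(outcome))
  shared <- Reduce(intersect, lapply(traits, function(s) s$rsid))
  if (length(shared) == 0) {
    stop("harmonize: no SNPs shared by all traits", call. = FALSE)
  }
  ref <- exposures[[1]]
  shared <- ref$rsid[ref$rsid %in% shared]  # order by reference trait
  rows <- lapply(traits, function(s) {
    as.data.frame(s)[match(shared, s$rsid), , drop = FALSE]
  })
  K <- length(exposures)
  J <- length(shared)
  dropped <- c(missing = 0L, palindromic = 0L, incompatible = 0L)

  # complete-case across all traits
  complete <- Reduce(`&`, lapply(rows, function(r) {
    is.finite(r$beta) & is.finite(r$se) & is.finite(r$pvalue)
  }))
  dropped["missing"] <- sum(!complete)

  ref_ea <- rows[[1]]$effect_allele
  ref_oa <- rows[[1]]$other_allele
  palin <- .is_palindromic(ref_ea, ref_oa)

  keep <- complete
  aligned <- vector("list", length(rows))
  for (t in seq_along(rows)) {
    r <- rows[[t]]
    same <- r$effect_allele == ref_ea & r$other_allele == ref_oa
    swap <- r$effect_allele == ref_oa & r$other_allele == ref_ea
    flip_same <- .COMPLEMENT[r$effect_allele] == ref_ea &
      .COMPLEMENT[r$other_allele] == ref_oa
    flip_swap <- .COMPLEMENT[r$effect_allele] == ref_oa &
      .COMPLEMENT[r$other_allele] == ref_ea
    # for palindromic SNPs labels cannot distinguish swap from strand flip;
    # treat label-identical as same and label-swapped as swap, refined below
    do_flip <- !same & (swap | (flip_swap & !palin))
    compatible <- same | swap | flip_same | flip_swap
    if (t > 1 && any(palin & keep)) {
      if (drop_palindromic) {
        ambiguous <- is.na(r$eaf) | is.na(rows[[1]]$eaf) |
          (r$eaf >= ambiguous_eaf[1] & r$eaf <= ambiguous_eaf[2]) |
          (rows[[1]]$eaf >= ambiguous_eaf[1] & rows[[1]]$eaf <= ambiguous_eaf[2])
        pal_drop <- palin & ambiguous
        dropped["palindromic"] <- dropped["palindromic"] +
          sum(pal_drop & keep & compatible)
        keep <- keep & !pal_drop
        # align retained palindromic SNPs by minor-allele matching
        freq_flip <- palin & !pal_drop &
          (sign(r$eaf - 0.5) != sign(rows[[1]]$eaf - 0.5))
        do_flip <- ifelse(palin & !pal_drop, freq_flip, do_flip)
      }
    }
    dropped["incompatible"] <- dropped["incompatible"] +
      sum(!compatible & keep)
    keep <- keep & compatible
    r$beta <- ifelse(do_flip, -r$beta, r$beta)
    r$eaf <- ifelse(do_flip, 1 - r$eaf, r$eaf)
    aligned[[t]] <- r
  }

  if (!any(keep)) stop("harmonize: all shared SNPs dropped", call. = FALSE)
  idx <- which(keep)
  B <- sapply(aligned[seq_len(K)], function(r) r$beta[idx])
  SE_B <- sapply(aligned[seq_len(K)], function(r) r$se[idx])
  P_B <- sapply(aligned[seq_len(K)], function(r) r$pvalue[idx])
  out <- aligned[[K + 1]]
  new_mr_panel(rsids = shared[idx], chrom = rows[[1]]$chrom[idx],
               pos = rows[[1]]$pos[idx],
               exposures = vapply(exposures, trait_name, ""),
               B = B, SE_B = SE_B, P_B = P_B,
               by = out$beta[idx], se_y = out$se[idx],
               outcome = trait_name(outcome),
               effect_allele = ref_ea[idx], other_allele = ref_oa[idx],
               dropped = dropped)
}

#' Orient a panel to a positive effect on one exposure
#'
#' For every SNP whose effect on the chosen exposure is negative, negates all
#' K exposure betas and the outcome beta (equivalent to switching which
#' allele is counted), leaving SEs and p-values untouched. The chosen
#' exposure's column is elementwise non-negative afterwards; zero betas are
#' left unchanged. Zero-intercept IVW estimates are invariant to this
#' per-row sign change; MR-Egger is not, which is why Egger fits re-orient to
#' their exposure of interest.
#'
#' @param panel an `mr_panel`.
#' @param exposure exposure name or column index (default first).
#' @return the oriented `mr_panel`.
#' @export
orient_to_exposure <- function(panel, exposure = 1L) {
  k <- if (is.character(exposure)) match(exposure, panel$exposures) else exposure
  if (is.na(k) || k < 1 || k > length(panel$exposures)) {
    stop("orient_to_exposure: unknown exposure", call. = FALSE)
  }
  flip <- panel$B[, k] < 0
  if (any(flip)) {
    panel$B[flip, ] <- -panel$B[flip, , drop = FALSE]
    panel$by[flip] <- -panel$by[flip]
  }
  panel
}

#' Re-express a harmonized panel as per-trait sumstats
#'
#' Inverse of [harmonize] up to the information a panel retains: returns one
#' [sumstats] object per exposure plus one for the outcome, sharing the
#' panel's alleles. Useful for checking that harmonization is idempotent.
#'
#' @param panel an `mr_panel` built by [harmonize] (alleles retained).
#' @return list with elements `exposures` (list of sumstats) and `outcome`.
#' @export
panel_to_sumstats <- function(panel) {
  stopifnot(!is.null(panel$effect_allele))
  base <- data.frame(rsid = panel$rsids, chrom = panel$chrom, pos = panel$pos,
                     effect_allele = panel$effect_allele,
                     other_allele = panel$other_allele,
                     stringsAsFactors = FALSE)
  exps <- lapply(seq_along(panel$exposures), function(k) {
    df <- base
    df$beta <- panel$B[, k]
    df$se <- panel$SE_B[, k]
    df$pvalue <- panel$P_B[, k]
    sumstats(df, trait = panel$exposures[k], trait_scale = "sd")
  })
  df <- base
  df$beta <- panel$by
  df$se <- panel$se_y
  df$pvalue <- 2 * stats::pnorm(-abs(panel$by / panel$se_y))
  outc <- sumstats(df, trait = panel$outcome, trait_scale = "log_or")
  list(exposures = exps, outcome = outc)
}
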