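#' Bonferroni-corrected significance threshold
#'
#' `alpha / m` for a family of `m` tests, optionally rounded to a number of
#' significant figures for display (e.g. 0.05/2338 printed as 2e-5 at one
#' significant figure, 0.05/6 as 0.0083 at two).
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests (>= 1).
#' @param sig_figs significant figures for display rounding; `NULL` (default)
#'   returns the exact quotient.
#' @return numeric threshold.
#' @export
bonferroni_threshold <- function(alpha, m, sig_figs = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  m <- as.integer(m)
  if (is.na(m) || m < 1) {
    stop("bonferroni_threshold: m must be a positive integer", call. = FALSE)
  }
  out <- alpha / m
  if (!is.null(sig_figs)) out <- signif(out, sig_figs)
  out
}

#' Cross-trait pleiotropy tabulation
#'
#' For each exposure trait's instrument set, the percentage of instruments
#' whose association p-value with each secondary trait falls below a
#' Bonferroni-corrected threshold — the genetic-overlap table of a
#' multi-trait MR study. A composite "any of" column reports the percentage
#' of instruments significant for at least one trait of a named set (no
#' multiplicity re-adjustment, mirroring how such composite columns are
#' conventionally reported). Instruments missing from a secondary trait's
#' statistics are removed from that cell's denominator, with counts logged.
#'
#' @param instrument_sets named list of [sumstats], one per exposure, after
#'   selection and clumping.
#' @param secondary_stats named list of [sumstats] covering every secondary
#'   trait (a trait may appear in both lists).
#' @param threshold p-value threshold, e.g.
#'   `bonferroni_threshold(0.05, 2338)`.
#' @param composite character vector of secondary trait names for the
#'   "any of" column; `NULL` for none.
#' @return object of class `pleio_table`: list with `percent` and `counts`
#'   matrices (rows = exposures, cols = secondary traits + composite),
#'   `denominators`, `missing` counts, and `threshold`. Cells with an empty
#'   denominator are `NaN` and listed in `undefined`.
#' @export
pleiotropy_crosstab <- function(instrument_sets, secondary_stats, threshold,
                                composite = NULL) {
  stopifnot(is.list(instrument_sets), is.list(secondary_stats))
  exposures <- names(instrument_sets)
  secondaries <- names(secondary_stats)
  cols <- c(secondaries, if (!is.null(composite)) "composite")
  percent <- counts <- denom <- matrix(
    NA_real_, length(exposures), length(cols),
    dimnames = list(exposures, cols))
  missing_n <- matrix(0L, length(exposures), length(secondaries),
                      dimnames = list(exposures, secondaries))
  for (e in exposures) {
    inst <- instrument_sets[[e]]
    if (nrow(inst) == 0) {
      next  # leaves the whole row NA -> flagged undefined below
    }
    pmat <- sapply(secondaries, function(s) {
      sec <- secondary_stats[[s]]
      sec$pvalue[match(inst$rsid, sec$rsid)]
    })
    pmat <- matrix(pmat, nrow = nrow(inst),
                   dimnames = list(inst$rsid, secondaries))
    for (s in secondaries) {
      present <- !is.na(pmat[, s])
      missing_n[e, s] <- sum(!present)
      denom[e, s] <- sum(present)
      counts[e, s] <- sum(pmat[present, s] < threshold)
      percent[e, s] <- if (denom[e, s] > 0) 100 * counts[e, s] / denom[e, s]
                       else NaN
    }
    if (!is.null(composite)) {
      sub <- pmat[, composite, drop = FALSE]
      present <- rowSums(!is.na(sub)) > 0
      hit <- rowSums(sub < threshold, na.rm = TRUE) > 0
      denom[e, "composite"] <- sum(present)
      counts[e, "composite"] <- sum(hit & present)
      percent[e, "composite"] <-
        if (sum(present) > 0) 100 * sum(hit & present) / sum(present) else NaN
    }
  }
  undefined <- which(is.nan(percent) | is.na(percent), arr.ind = TRUE)
  structure(list(percent = percent, counts = counts, denominators = denom,
                 missing = missing_n, threshold = threshold,
                 composite = composite,
                 undefined = undefined),
            class = "pleio_table")
}

#' @export
print.pleio_table <- function(x, ...) {
  cat(sprintf("Cross-trait pleiotropy at P < %.3g (%% of instruments)\n",
              x$threshold))
  print(round(x$percent, 1))
  if (nrow(x$undefined)) cat("undefined cells:", nrow(x$undefined), "\n")
  invisible(x)
}

#' Write a pleiotropy table as TSV
#' @param x a `pleio_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pleio_table <- function(x, path) {
  df <- data.frame(exposure = rownames(x$percent),
                   round(x$percent, 1), check.names = FALSE)
  .write_delim(df, path)
}

#' Filter instruments for a restricted non-pleiotropic set
#'
#' Removes every instrument with any secondary-trait p below `threshold` and
#' reports diagnostics on the survivors: how many remain, the fraction of
#' their secondary p-values below 0.1 (a left-shift of the retained p
#' distribution indicates residual pleiotropy too weakly estimated for the
#' filter to catch), and deciles of the retained secondary p distribution.
#'
#' @param instruments a [sumstats] object (one exposure's instrument set).
#' @param secondary_stats named list of [sumstats] for the traits to screen
#'   against; instruments missing from a secondary trait are not filtered on
#'   it.
#' @param threshold filtering p-value threshold.
#' @return list with `retained` (a [sumstats]), `removed` (rsids),
#'   `diagnostics`: `n_retained`, `frac_p_below_0.1`, `p_deciles`.
#' @export
restricted_set_filter <- function(instruments, secondary_stats, threshold) {
  stopifnot(inherits(instruments, "sumstats"))
  if (nrow(instruments) == 0) {
    return(list(retained = instruments, removed = character(),
                diagnostics = list(n_retained = 0L,
                                   frac_p_below_0.1 = NaN,
                                   p_deciles = rep(NA_real_, 11))))
  }
  pmat <- sapply(secondary_stats, function(sec) {
    sec$pvalue[match(instruments$rsid, sec$rsid)]
  })
  pmat <- matrix(pmat, nrow = nrow(instruments))
  drop <- rowSums(pmat < threshold, na.rm = TRUE) > 0
  retained <- subset_sumstats(instruments, !drop)
  pv <- as.numeric(pmat[!drop, , drop = FALSE])
  pv <- pv[!is.na(pv)]
  list(retained = retained,
       removed = instruments$rsid[drop],
       diagnostics = list(
         n_retained = nrow(retained),
         frac_p_below_0.1 = if (length(pv)) mean(pv < 0.1) else NaN,
         p_deciles = if (length(pv)) {
           stats::quantile(pv, probs = seq(0, 1, 0.1), names = TRUE)
         } else rep(NA_real_, 11)))
}
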