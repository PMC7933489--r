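#' Linkage-disequilibrium matrix
#'
#' Pairwise r-squared between variants, with per-SNP coordinates, as used by
#' [clump]. The matrix must be symmetric with unit diagonal and entries in
#' `[0, 1]`.
#'
#' @param rsids variant identifiers (length M).
#' @param r2 M x M symmetric matrix.
#' @param chrom,pos per-SNP coordinates.
#' @return an object of class `ld_matrix`.
#' @export
ld_matrix <- function(rsids, r2, chrom, pos) {
  M <- length(rsids)
  r2 <- as.matrix(r2)
  stopifnot(nrow(r2) == M, ncol(r2) == M,
            length(chrom) == M, length(pos) == M)
  if (any(r2 < 0 | r2 > 1)) {
    stop("ld_matrix: r2 entries must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(r2 - t(r2))) > 1e-8) {
    stop("ld_matrix: r2 matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(r2) - 1) > 1e-8)) {
    stop("ld_matrix: r2 diagonal must be 1", call. = FALSE)
  }
  dimnames(r2) <- list(rsids, rsids)
  structure(list(rsids = as.character(rsids), r2 = r2,
                 chrom = as.character(chrom), pos = as.integer(pos)),
            class = "ld_matrix")
}

#' Read an LD matrix from delimited text
#'
#' Two layouts are supported: a square TSV whose first column and header row
#' are rsids, or a long-format triple file with columns `rsid_a`, `rsid_b`,
#' `r2` (pairs absent from the file are taken as r2 = 0). Coordinates are
#' supplied separately because LD files conventionally carry none.
#'
#' @param path file path.
#' @param chrom,pos named vectors (by rsid) or vectors aligned with the file's
#'   rsid order.
#' @param format `"square"` or `"long"`; guessed from the header when omitted.
#' @return an [ld_matrix] object.
#' @export
read_ld_matrix <- function(path, chrom, pos, format = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(format)) {
    format <- if (all(c("rsid_a", "rsid_b", "r2") %in% names(df))) "long"
              else "square"
  }
  if (format == "long") {
    rsids <- sort(unique(c(df$rsid_a, df$rsid_b)))
    M <- length(rsids)
    r2 <- matrix(0, M, M, dimnames = list(rsids, rsids))
    diag(r2) <- 1
    ia <- match(df$rsid_a, rsids)
    ib <- match(df$rsid_b, rsids)
    r2[cbind(ia, ib)] <- df$r2
    r2[cbind(ib, ia)] <- df$r2
  } else {
    rsids <- as.character(df[[1]])
    r2 <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(r2) <- "double"
  }
  if (!is.null(names(chrom))) chrom <- chrom[rsids]
  if (!is.null(names(pos))) pos <- pos[rsids]
  ld_matrix(rsids, r2, chrom, pos)
}

#' Select genome-wide-significant variants
#'
#' Subsets to records with `pvalue < alpha` (strict inequality), preserving
#' input order. The default threshold of 1e-8 is one order stricter than the
#' conventional 5e-8, accounting for low-frequency variants and dense
#' imputation.
#'
#' @param sumstats a [sumstats] object.
#' @param alpha significance threshold.
#' @return a [sumstats] object with the significant subset.
#' @export
select_genome_wide <- function(sumstats, alpha = 1e-8) {
  stopifnot(inherits(sumstats, "sumstats"))
  subset_sumstats(sumstats, sumstats$pvalue < alpha)
}

#' Greedy LD clumping of GWAS summary statistics
#'
#' Repeatedly takes the remaining variant with the smallest p-value (ties
#' broken by position, then rsid) as an index SNP and removes every remaining
#' variant on the same chromosome within `window_bp` of it whose r-squared
#' with the index exceeds `r2_max`. The kept set is returned in selection
#' order; every kept pair within the window satisfies r2 <= `r2_max`.
#' Clumping is per-chromosome; pairs absent from the LD matrix are treated as
#' unlinked (r2 = 0) with a warning, which permits sparse LD fixtures.
#'
#' @param snps a [sumstats] object (typically genome-wide-significant SNPs).
#' @param ld an [ld_matrix].
#' @param r2_max r-squared threshold above which SNPs are clumped away.
#' @param window_bp half-window in base pairs around the index SNP
#'   (default 10 Mb, i.e. a 20 Mb span).
#' @return a [sumstats] object with the retained index SNPs, in selection
#'   order.
#' @export
clump <- function(snps, ld, r2_max = 0.01, window_bp = 10e6) {
  stopifnot(inherits(snps, "sumstats"), inherits(ld, "ld_matrix"))
  J <- nrow(snps)
  if (J == 0) return(snps)
  in_ld <- snps$rsid %in% ld$rsids
  if (!all(in_ld)) {
    warning(sum(!in_ld), " SNP(s) absent from the LD matrix treated as ",
            "unlinked (r2 = 0)", call. = FALSE)
  }
  ord <- order(snps$pvalue, snps$pos, snps$rsid)
  remaining <- rep(TRUE, J)
  kept <- integer(0)
  ld_idx <- match(snps$rsid, ld$rsids)
  for (i in ord) {
    if (!remaining[i]) next
    kept <- c(kept, i)
    remaining[i] <- FALSE
    cand <- which(remaining & snps$chrom == snps$chrom[i] &
                    abs(snps$pos - snps$pos[i]) <= window_bp)
    if (length(cand)) {
      r2 <- rep(0, length(cand))
      ok <- !is.na(ld_idx[cand]) & !is.na(ld_idx[i])
      if (any(ok)) r2[ok] <- ld$r2[ld_idx[cand[ok]], ld_idx[i]]
      remaining[cand[r2 > r2_max]] <- FALSE
    }
  }
  subset_sumstats(snps, kept)
}

#' Gene locus for monogenic MR
#' @param gene gene symbol.
#' @param chrom chromosome.
#' @param tss transcription start site, 1-based base pairs.
#' @return an object of class `locus`.
#' @export
locus <- function(gene, chrom, tss) {
  tss <- as.integer(tss)
  stopifnot(tss >= 1)
  structure(list(gene = gene, chrom = as.character(chrom), tss = tss),
            class = "locus")
}

#' Read a locus table (gene, chrom, tss)
#' @param path TSV path with columns `gene`, `chrom`, `tss`.
#' @return list of [locus] objects, named by gene.
#' @export
read_locus_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chrom", "tss") %in% names(df)))
  out <- lapply(seq_len(nrow(df)),
                function(i) locus(df$gene[i], df$chrom[i], df$tss[i]))
  stats::setNames(out, df$gene)
}

#' Variants within a window of a gene's transcription start site
#'
#' Keeps SNPs on the locus chromosome with `|pos - tss| <= half_width_bp`
#' (closed interval, 1-based coordinates).
#'
#' @param snps a [sumstats] object.
#' @param locus a [locus].
#' @param half_width_bp half-width of the window (default 1 Mb).
#' @return a [sumstats] object.
#' @export
locus_window <- function(snps, locus, half_width_bp = 1e6) {
  stopifnot(inherits(snps, "sumstats"), inherits(locus, "locus"))
  keep <- snps$chrom == locus$chrom &
    abs(snps$pos - locus$tss) <= half_width_bp
  subset_sumstats(snps, keep)
}
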