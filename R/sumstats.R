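#' Per-trait GWAS summary statistics
#'
#' A `sumstats` object is a data frame with one row per variant and the
#' columns `rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pvalue`, `n`, carrying the trait name and the scale of its
#' effect sizes as attributes. Effect sizes are in SD units for
#' inverse-normal-transformed continuous traits (`trait_scale = "sd"`), log
#' odds ratios for binary traits (`"log_or"`), or untransformed units such as
#' mmHg for blood pressure (`"raw"`).
#'
#' @param x data frame with at least `rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue`; `eaf` and `n` are optional and
#'   filled with `NA` when absent.
#' @param trait trait name.
#' @param trait_scale one of `"sd"`, `"log_or"`, `"raw"`.
#' @param strict if `TRUE` (default), rows violating the record invariants
#'   (`se > 0`, `0 < pvalue <= 1`, `eaf` in `[0, 1]` when present,
#'   `effect_allele != other_allele`, `pos >= 1`) raise an error naming the
#'   offending rsid; if `FALSE`, such rows are dropped and their count stored
#'   in the `dropped` attribute.
#' @return A validated `sumstats` data frame; row order preserved, alleles
#'   upper-cased, rsids unique.
#' @export
sumstats <- function(x, trait, trait_scale = c("sd", "log_or", "raw"),
                     strict = TRUE) {
  trait_scale <- match.arg(trait_scale)
  needed <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
              "beta", "se", "pvalue")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("sumstats: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(x$eaf)) x$eaf <- NA_real_
  if (is.null(x$n)) x$n <- NA_real_
  x <- x[c(needed[1:5], "eaf", "beta", "se", "pvalue", "n")]
  x$rsid <- as.character(x$rsid)
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  if (anyDuplicated(x$rsid)) {
    stop("sumstats: duplicated rsid(s): ",
         paste(unique(x$rsid[duplicated(x$rsid)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.finite(x$se) | x$se <= 0 |
    !is.finite(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1 |
    (!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1)) |
    x$effect_allele == x$other_allele |
    is.na(x$pos) | x$pos < 1 |
    !is.finite(x$beta)
  if (any(bad)) {
    if (strict) {
      stop("sumstats: invalid record(s) for trait '", trait, "': ",
           paste(x$rsid[bad], collapse = ", "), call. = FALSE)
    }
    x <- x[!bad, , drop = FALSE]
  }
  rownames(x) <- NULL
  structure(x,
            trait = trait, trait_scale = trait_scale,
            dropped = sum(bad),
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (scale: %s), %d variants\n",
              attr(x, "trait"), attr(x, "trait_scale"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Trait name and effect-size scale of a sumstats object
#' @param x a `sumstats` object.
#' @return character scalar.
#' @export
trait_name <- function(x) attr(x, "trait")

#' @rdname trait_name
#' @export
trait_scale <- function(x) attr(x, "trait_scale")

#' Subset a sumstats object, keeping its metadata
#' @param x a `sumstats` object.
#' @param keep logical or integer row index.
#' @return a `sumstats` object.
#' @keywords internal
subset_sumstats <- function(x, keep) {
  out <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait = attr(x, "trait"), trait_scale = attr(x, "trait_scale"),
            dropped = attr(x, "dropped"),
            class = c("sumstats", "data.frame"))
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a headered TSV or CSV (gzip-compressed files are read transparently)
#' into a validated [sumstats] object. Column names in the file are mapped to
#' the canonical names through `column_map`.
#'
#' @param path file path; `.csv` is parsed comma-delimited, anything else
#'   tab-delimited; a `.gz` suffix is decompressed on the fly.
#' @param trait trait name.
#' @param trait_scale effect-size scale, see [sumstats].
#' @param column_map named character vector mapping canonical names
#'   (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pvalue`, `n`) to the column names in the file. Defaults to the
#'   identity mapping; entries for optional columns may be omitted.
#' @param strict passed to [sumstats]; in lenient mode invalid rows are
#'   dropped with a count retained in the `dropped` attribute.
#' @return a [sumstats] object, file row order preserved.
#' @export
read_sumstats <- function(path, trait, trait_scale = c("sd", "log_or", "raw"),
                          column_map = NULL, strict = TRUE) {
  trait_scale <- match.arg(trait_scale)
  sep <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  raw <- utils::read.table(con, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  canonical <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pvalue", "n")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  required <- setdiff(canonical, c("eaf", "n"))
  absent <- required[!map[required] %in% names(raw)]
  if (length(absent)) {
    stop("read_sumstats: mapped column(s) not found in ", path, ": ",
         paste(map[absent], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (cn in canonical) {
    out[[cn]] <- if (map[[cn]] %in% names(raw)) raw[[map[[cn]]]] else NA
  }
  sumstats(out, trait = trait, trait_scale = trait_scale, strict = strict)
}

#' Write summary statistics or a harmonized panel to delimited text
#'
#' `write_sumstats()` writes the canonical ten-column table; reading it back
#' with [read_sumstats] recovers the records. `write_panel()` writes a
#' harmonized panel as one row per SNP with columns `rsid`, `chrom`, `pos`,
#' then per exposure `beta_<name>`, `se_<name>`, `p_<name>` (3K columns), then
#' `beta_outcome`, `se_outcome` — i.e. `2 + 3K + 2` data columns after `rsid`.
#'
#' @param x object to write.
#' @param path output path; `.csv` selects comma separation, `.gz` gzip.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  .write_delim(as.data.frame(x), path)
}

#' @rdname write_sumstats
#' @export
write_panel <- function(x, path) {
  stopifnot(inherits(x, "mr_panel"))
  df <- data.frame(rsid = x$rsids, chrom = x$chrom, pos = x$pos,
                   stringsAsFactors = FALSE)
  for (k in seq_along(x$exposures)) {
    nm <- x$exposures[k]
    df[[paste0("beta_", nm)]] <- x$B[, k]
    df[[paste0("se_", nm)]] <- x$SE_B[, k]
    df[[paste0("p_", nm)]] <- x$P_B[, k]
  }
  df$beta_outcome <- x$by
  df$se_outcome <- x$se_y
  .write_delim(df, path)
}

#' Read a harmonized panel written by [write_panel]
#' @param path file path.
#' @param outcome outcome trait name to attach.
#' @return an `mr_panel` object.
#' @export
read_panel <- function(path, outcome = "outcome") {
  sep <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  df <- utils::read.table(con, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  beta_cols <- grep("^beta_", names(df), value = TRUE)
  beta_cols <- setdiff(beta_cols, "beta_outcome")
  exposures <- sub("^beta_", "", beta_cols)
  J <- nrow(df)
  B <- SE_B <- P_B <- matrix(NA_real_, J, length(exposures),
                             dimnames = list(NULL, exposures))
  for (nm in exposures) {
    B[, nm] <- df[[paste0("beta_", nm)]]
    SE_B[, nm] <- df[[paste0("se_", nm)]]
    P_B[, nm] <- df[[paste0("p_", nm)]]
  }
  new_mr_panel(rsids = df$rsid, chrom = as.character(df$chrom), pos = df$pos,
               exposures = exposures, B = B, SE_B = SE_B, P_B = P_B,
               by = df$beta_outcome, se_y = df$se_outcome, outcome = outcome)
}

.write_delim <- function(df, path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
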