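#' Read a run configuration from YAML
#'
#' The configuration names the per-trait summary-statistic files and scales,
#' the outcome file, the LD matrix, an optional locus table, and the
#' analysis thresholds. See [run_full_analysis] for the recognized fields.
#'
#' @param path YAML file path.
#' @return configuration list with defaults filled in.
#' @export
read_run_config <- function(path) {
  .fill_run_config(yaml::read_yaml(path))
}

.default_thresholds <- list(gw_alpha = 1e-8, clump_r2 = 0.01,
                            clump_window_bp = 1e7, locus_half_width_bp = 1e6,
                            presso_alpha = 0.05, n_sim = 1000L, seed = 1L,
                            mr_alpha = 0.05, pleiotropy_alpha = 0.05,
                            pleiotropy_m = NULL)

.fill_run_config <- function(config) {
  config$thresholds <- utils::modifyList(.default_thresholds,
                                         config$thresholds %||% list())
  if (is.null(config$primary_exposures)) {
    config$primary_exposures <- names(config$traits)
  }
  if (is.null(config$extended_exposures)) {
    config$extended_exposures <- names(config$traits)
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Load one trait entry: either an in-memory sumstats under $data or a file
# path under $path.
.load_trait <- function(entry, name) {
  if (!is.null(entry$data)) {
    stopifnot(inherits(entry$data, "sumstats"))
    return(entry$data)
  }
  read_sumstats(entry$path, trait = name,
                trait_scale = entry$scale %||% "sd",
                column_map = entry$column_map, strict = FALSE)
}

#' Flag estimates significant at a Bonferroni-corrected level
#'
#' Adds a `significant` column: `pvalue < alpha / m`, where `m` is the number
#' of exposures modeled jointly (1 for univariable MR, 3 or 6 for the
#' three- and six-exposure multivariable models, giving thresholds 0.05,
#' 0.0167, 0.0083).
#'
#' @param estimates an `mr_result` data frame.
#' @param m number of jointly modeled associations.
#' @param alpha family-wise level (default 0.05).
#' @return the estimates with a `significant` logical column and the
#'   threshold as attribute `sig_threshold`.
#' @export
significance_annotation <- function(estimates, m, alpha = 0.05) {
  thr <- bonferroni_threshold(alpha, m)
  estimates$significant <- estimates$pvalue < thr
  attr(estimates, "sig_threshold") <- thr
  estimates
}

#' Run the full multivariable MR analysis
#'
#' Orchestrates the stages in their reporting order: per-trait instrument
#' selection at genome-wide significance and LD clumping; cross-trait
#' pleiotropy tabulation; harmonization of the primary exposure set with the
#' outcome; multivariable IVW and Egger with and without exclusion of
#' outlier-test SNPs; the same for the extended exposure set; and
#' univariable MR at each configured gene locus. Every SNP dropped between
#' stages is counted in the `counts` log.
#'
#' @param config a configuration list (or a YAML path read through
#'   [read_run_config]) with fields:
#'   \describe{
#'     \item{traits}{named list; each entry has `path` (+ optional
#'       `column_map`) or an in-memory `data` [sumstats], and `scale`.}
#'     \item{outcome}{one such entry for the outcome (log-OR scale).}
#'     \item{ld}{LD matrix: `path` (+ optional `chrom`/`pos` named vectors)
#'       or in-memory `data` [ld_matrix]; omit to skip clumping.}
#'     \item{primary_exposures, extended_exposures}{character vectors of
#'       trait names for the two multivariable models (e.g. the three lipid
#'       traits, then lipids + metabolic traits).}
#'     \item{loci}{optional data frame or TSV path with `gene`, `chrom`,
#'       `tss`, `trait` for monogenic univariable MR.}
#'     \item{thresholds}{`gw_alpha`, `clump_r2`, `clump_window_bp`,
#'       `locus_half_width_bp`, `presso_alpha`, `n_sim`, `seed`, `mr_alpha`,
#'       `pleiotropy_m` (Bonferroni m for the pleiotropy table; default the
#'       total de-duplicated instrument count).}
#'     \item{out_dir}{optional; when set, all tables are written there as
#'       TSV plus a JSON manifest.}
#'   }
#' @param presso run the outlier test and exclusion refits (default `TRUE`;
#'   when `FALSE` the with/without-exclusion tables are identical).
#' @return an `analysis_report` list: `instruments` (per-trait clumped sets),
#'   `pleiotropy` (the crosstab), `mr_primary` / `mr_extended` (each with
#'   `presso`, `with_exclusion`, `with_inclusion`), `locus_mr`, `counts`,
#'   `provenance`.
#' @export
run_full_analysis <- function(config, presso = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- .fill_run_config(config)
  thr <- config$thresholds
  counts <- list()
  note <- function(stage, trait, n_in, n_out, reason = "") {
    counts[[length(counts) + 1]] <<- data.frame(
      stage = stage, trait = trait, n_in = n_in, n_out = n_out,
      dropped = n_in - n_out, reason = reason, stringsAsFactors = FALSE)
  }

  traits <- lapply(names(config$traits),
                   function(nm) .load_trait(config$traits[[nm]], nm))
  names(traits) <- names(config$traits)
  outcome <- .load_trait(config$outcome, config$outcome$name %||% "outcome")

  ld <- NULL
  if (!is.null(config$ld)) {
    ld <- if (!is.null(config$ld$data)) config$ld$data
          else read_ld_matrix(config$ld$path, config$ld$chrom, config$ld$pos)
  }

  # stage 1: selection + clumping per trait
  instruments <- lapply(names(traits), function(nm) {
    sel <- select_genome_wide(traits[[nm]], thr$gw_alpha)
    note("select_genome_wide", nm, nrow(traits[[nm]]), nrow(sel),
         sprintf("p >= %g", thr$gw_alpha))
    if (!is.null(ld)) {
      cl <- suppressWarnings(clump(sel, ld, thr$clump_r2,
                                   thr$clump_window_bp))
      note("clump", nm, nrow(sel), nrow(cl),
           sprintf("r2 > %g within %g bp", thr$clump_r2,
                   thr$clump_window_bp))
      cl
    } else sel
  })
  names(instruments) <- names(traits)
  all_rsids <- unique(unlist(lapply(instruments, function(s) s$rsid)))

  # stage 2: cross-trait pleiotropy table
  m_pleio <- thr$pleiotropy_m %||% length(all_rsids)
  pleio_thr <- bonferroni_threshold(thr$pleiotropy_alpha, m_pleio)
  composite <- config$composite %||%
    setdiff(names(traits), config$primary_exposures)
  if (!length(composite)) composite <- NULL
  pleio <- pleiotropy_crosstab(instruments, traits, pleio_thr,
                               composite = composite)

  # stages 3-4: multivariable MR on primary then extended exposure set,
  # each with outlier screening and exclusion refit
  run_mv <- function(exposure_names, label) {
    inst_union <- unique(unlist(lapply(instruments[exposure_names],
                                       function(s) s$rsid)))
    pooled <- lapply(exposure_names, function(nm) {
      subset_sumstats(traits[[nm]], traits[[nm]]$rsid %in% inst_union)
    })
    panel <- harmonize(pooled, outcome)
    note(paste0("harmonize_", label), paste(exposure_names, collapse = "+"),
         length(inst_union), n_snps(panel),
         paste(names(panel$dropped), panel$dropped, sep = "=",
               collapse = ","))
    if (presso) {
      pr <- presso_test(panel, n_sim = thr$n_sim, alpha = thr$presso_alpha,
                        seed = thr$seed)
      refit <- exclude_and_refit(panel, pr)
      note(paste0("presso_", label), "", n_snps(panel),
           n_snps(refit$panel), "outlier-test exclusion")
    } else {
      pr <- NULL
      fits <- list(ivw = ivw_multivariable(panel),
                   egger = egger_table(panel))
      refit <- list(panel = panel, excluded = character(),
                    with_exclusion = fits, with_inclusion = fits)
    }
    m <- length(exposure_names)
    for (side in c("with_exclusion", "with_inclusion")) {
      refit[[side]]$ivw <-
        significance_annotation(refit[[side]]$ivw, m, thr$mr_alpha)
      refit[[side]]$egger <-
        significance_annotation(refit[[side]]$egger, m, thr$mr_alpha)
    }
    list(panel = panel, presso = pr, excluded = refit$excluded,
         with_exclusion = refit$with_exclusion,
         with_inclusion = refit$with_inclusion)
  }
  mr_primary <- run_mv(config$primary_exposures, "primary")
  mr_extended <- if (identical(sort(config$extended_exposures),
                               sort(config$primary_exposures))) mr_primary
                 else run_mv(config$extended_exposures, "extended")

  # stage 5: monogenic univariable MR at configured loci
  locus_mr <- NULL
  if (!is.null(config$loci)) {
    loci <- if (is.character(config$loci)) {
      utils::read.table(config$loci, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    } else as.data.frame(config$loci)
    locus_mr <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
      loc <- locus(loci$gene[i], loci$chrom[i], loci$tss[i])
      trait_nm <- loci$trait[i]
      snps <- locus_window(instruments[[trait_nm]], loc,
                           thr$locus_half_width_bp)
      note("locus_window", paste(loc$gene, trait_nm),
           nrow(instruments[[trait_nm]]), nrow(snps),
           sprintf("outside %g bp of TSS", thr$locus_half_width_bp))
      if (nrow(snps) == 0) return(NULL)
      panel <- harmonize(list(snps), outcome)
      est <- ivw_univariable(panel)
      est <- significance_annotation(est, 1, thr$mr_alpha)
      est$gene <- loc$gene
      est
    }))
  }

  counts <- do.call(rbind, counts)
  report <- structure(
    list(instruments = instruments, pleiotropy = pleio,
         mr_primary = mr_primary, mr_extended = mr_extended,
         locus_mr = locus_mr, counts = counts,
         provenance = list(seed = thr$seed,
                           n_sim = thr$n_sim,
                           pleiotropy_threshold = pleio_thr,
                           pleiotropy_m = m_pleio,
                           package_version =
                             as.character(utils::packageVersion("mrpleio")),
                           config_hash = .config_hash(
                             config[setdiff(names(config), "out_dir")]))),
    class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Order-stable FNV-1a hash of the serialized configuration, for provenance.
.config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                          digits = NA)
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write every table of an analysis report to a directory
#'
#' Emits TSVs for the pleiotropy table, the four multivariable estimate
#' tables (primary/extended x with/without exclusion, IVW and Egger bound
#' together), the locus table, the outlier-test per-SNP tables, the stage
#' counts log, and a JSON manifest with the provenance block.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_pleio_table(report$pleiotropy, p("pleiotropy_table.tsv"))
  for (set in c("mr_primary", "mr_extended")) {
    blk <- report[[set]]
    for (side in c("with_exclusion", "with_inclusion")) {
      tab <- rbind(blk[[side]]$ivw, blk[[side]]$egger)
      write_mr_result(tab, p(sprintf("%s_%s.tsv", set, side)))
    }
    if (!is.null(blk$presso)) {
      write_presso_result(blk$presso, p(sprintf("%s_presso.tsv", set)))
    }
  }
  if (!is.null(report$locus_mr)) {
    write_mr_result(report$locus_mr, p("locus_mr.tsv"))
  }
  .write_delim(report$counts, p("stage_counts.tsv"))
  jsonlite::write_json(report$provenance, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
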