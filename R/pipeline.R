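## End-to-end identification pipeline: CAPS panel design -> per-sample
## digestion and class calling -> flow-cytometry ploidy -> genomic
## formula -> taxon -> cohort report.

#' Run the integrated identification pipeline on a cohort
#'
#' Takes the observable layers of a cohort (allele registry, per-sample
#' clone sequences and rbcL haplotype, flow peak pairs), designs the
#' diagnostic CAPS panel, and for every sample: digests the distinct
#' cloned alleles in silico and calls the genotype-class set from the
#' pooled band pattern, estimates the 2C genome size and ploidy,
#' classifies each clone against the registry, assembles the genomic
#' formula and assigns the taxon. Inconsistencies between the CAPS call
#' and the cloned classes, and clone counts below the 2.5x rule, are
#' flagged per sample rather than fatal.
#'
#' @param cohort a cohort as produced by [make_cohort()], or a list with
#'   the same `registry`, `samples` and `flow` members read from disk.
#' @param enzymes candidate enzyme list (default `enzyme_db()`
#'   restricted to SacI + HinfI, the assay's catalogue).
#' @param min_band_bp,min_diff_bp,tolerance_bp CAPS thresholds, see
#'   [select_diagnostic_enzymes()] and [call_classes()].
#' @param monoploid_1Cx monoploid genome size in pg for ploidy rounding.
#' @param max_mismatch clone classification mismatch budget.
#' @return a `pipeline_report`: `panel`, per-sample data.frame
#'   `results` (formula, taxon, ploidy, 2C, caps call, flags) and the
#'   [cohort_summary()] in `summary`.
#' @export
run_pipeline <- function(cohort,
                         enzymes = enzyme_db(c("SacI", "HinfI")),
                         min_band_bp = 60L, min_diff_bp = 20L,
                         tolerance_bp = 0L, monoploid_1Cx = 6.5,
                         max_mismatch = 10L) {
  stopifnot(is.list(cohort), !is.null(cohort$registry),
            !is.null(cohort$samples), !is.null(cohort$flow))
  if (length(cohort$samples) == 0L) stop("no samples in cohort")

  panel <- select_diagnostic_enzymes(cohort$registry, enzymes,
                                     min_band_bp = min_band_bp,
                                     min_diff_bp = min_diff_bp)
  flow <- cohort$flow
  rows <- list()
  for (id in names(cohort$samples)) {
    smp <- cohort$samples[[id]]
    frow <- flow[flow$sample_id == id, , drop = FALSE]
    if (nrow(frow) != 1L) stop("missing flow record for sample ", id)
    res <- tryCatch(
      pipeline_one(id, smp, frow, cohort$registry, panel,
                   min_band_bp, tolerance_bp, monoploid_1Cx, max_mismatch),
      error = function(e) stop("sample ", id, ": ", conditionMessage(e)))
    rows[[id]] <- res
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  summary <- cohort_summary(results)
  structure(list(panel = panel, results = results, summary = summary),
            class = "pipeline_report")
}

pipeline_one <- function(id, smp, frow, registry, panel,
                         min_band_bp, tolerance_bp, monoploid_1Cx,
                         max_mismatch) {
  flags <- character(0)

  ## CAPS: pooled digest of the distinct cloned alleles
  distinct_seqs <- unique(unname(smp$clones))
  observed <- lapply(panel$enzymes, function(e) {
    bands <- unlist(lapply(distinct_seqs, function(s) {
      to_band_pattern(digest(s, e), min_band_bp, panel$drop_shared)$bands
    }))
    band_pattern(bands)
  })
  caps_call <- tryCatch(call_classes(observed, panel, tolerance_bp),
                        error = function(e) {
                          flags <<- c(flags, "caps_uncalled")
                          character(0)
                        })

  ## ploidy from the flow peak pair
  std <- if (!is.null(frow$standard_2C_pg)) frow$standard_2C_pg else 9.2
  gs <- genome_size(frow$sample_peak, frow$standard_peak, std)
  pcall <- assign_ploidy(gs, monoploid_1Cx = monoploid_1Cx)

  ## clone classification and formula assembly
  clone_alleles <- lapply(distinct_seqs, classify_allele,
                          registry = registry, max_mismatch = max_mismatch)
  clone_classes <- vapply(clone_alleles, `[[`, character(1), "genome_class")
  if (length(smp$clones) < required_clones(pcall$ploidy)) {
    flags <- c(flags, "below_clone_depth_rule")
  }
  if (length(caps_call) > 0L &&
      !setequal(caps_call, unique(clone_classes))) {
    flags <- c(flags, "caps_clone_mismatch")
  }
  f <- withCallingHandlers(
    assemble_formula(smp$haplotype, clone_classes, pcall$ploidy),
    warning = function(w) invokeRestart("muffleWarning"))
  flags <- c(flags, f$flags)
  tx <- classify_taxon(f)

  data.frame(sample_id = id,
             haplotype = smp$haplotype,
             caps_classes = paste(caps_call, collapse = ""),
             genome_size_2C = gs,
             ploidy = pcall$ploidy,
             formula = format(f),
             taxon = tx$taxon,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report: %d samples, panel %s>\n",
              nrow(x$results), paste(names(x$panel$enzymes), collapse = " + ")))
  print(x$summary$groups)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Per-sample TSV plus a cohort JSON of counts and percentages.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$results, file.path(dir, "samples.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  jsonlite::write_json(report$summary, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
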