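## Pipeline orchestration: one call from raw input files (trace,
## boundaries, PSMs, family map, optional ELISA plate) to the full report
## bundle, mirroring the bench workflow HPLC -> identification/filtering ->
## quantification -> immunoprofiling. Every stage error is re-raised with
## the stage name so failures are attributable.

.withStage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      if (inherits(e, "dcx_stage_error")) return()
      stop(errorCondition(
        sprintf("[stage %s] %s", stage, conditionMessage(e)),
        class = unique(c("dcx_stage_error", class(e))),
        stage = stage))
    })
}

.requireKeys <- function(config, keys) {
  missing_keys <- setdiff(keys, names(config))
  if (length(missing_keys))
    dcxError("dcx_config_error",
             paste("config is missing required key(s):",
                   paste(missing_keys, collapse = ", ")))
  invisible(config)
}

#' Run the decomplexing venomics pipeline
#'
#' Executes the full analysis for one venom: read and baseline-correct the
#' chromatogram, integrate the collection windows into fraction shares,
#' read the PSM table, apply the score/SPI cascade and target-decoy FDR
#' control, quantify within-fraction MSI proportions, combine into
#' whole-venom abundances, aggregate into toxin families, and (when an
#' ELISA file is configured) summarise the immunoprofile.
#'
#' @param config Path to a YAML file or a named list. Required keys:
#'   \code{venom_id}, \code{trace}, \code{boundaries}, \code{psms},
#'   \code{family_map}. Optional: \code{unidentified} (fraction ids),
#'   \code{thresholds} (list with \code{min_protein_score},
#'   \code{min_peptide_score}, \code{min_spi}, \code{max_fdr}),
#'   \code{baseline_method}, \code{decoy_prefix}, \code{elisa},
#'   \code{reference_antivenom}, \code{comparator_antivenom},
#'   \code{negative_control}, \code{positive_control}, \code{out_dir}.
#' @param outDir Output directory overriding \code{config$out_dir}; when
#'   set, the report bundle is written there (per-protein and per-family
#'   TSVs, immunoprofile TSV, \code{report.json} run log).
#' @return List (invisibly when writing) with elements \code{shares},
#'   \code{filter} (cutoff, achieved FDR, per-stage counts),
#'   \code{abundance} (\linkS4class{AbundanceTable}), \code{families},
#'   \code{counts}, \code{immunoprofile}, \code{relative},
#'   \code{controls}, \code{files}.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      dcxError("dcx_config_error",
               sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    dcxError("dcx_config_error", "config must be a file path or a list")
  .requireKeys(config, c("venom_id", "trace", "boundaries", "psms",
                         "family_map"))
  if (is.null(outDir)) outDir <- config$out_dir

  th <- FilterThresholds(
    minProteinScore = config$thresholds$min_protein_score %||% 20,
    minPeptideScore = config$thresholds$min_peptide_score %||% 10,
    minSpi = config$thresholds$min_spi %||% 70,
    maxFdr = config$thresholds$max_fdr %||% 0.01)

  chrom <- .withStage("read_chromatogram", readChromatogram(config$trace))
  chrom <- .withStage("baseline",
    correctBaseline(chrom,
                    method = config$baseline_method %||% "linear_endpoints"))
  bounds <- .withStage("read_boundaries", readBoundaries(config$boundaries))
  shareTable <- .withStage("integrate_fractions",
                           integrateFractions(chrom, bounds))

  psms <- .withStage("read_psms",
                     readPsmTable(config$psms,
                                  decoyPrefix = config$decoy_prefix))
  fmap <- .withStage("read_family_map", readFamilyMap(config$family_map))
  filt <- .withStage("filter_psms", filterPsms(psms, th))

  wft <- .withStage("within_fraction", withinFractionAbundance(filt$psms))
  unid <- as.character(config$unidentified %||% character())
  abundance <- .withStage("whole_venom",
    wholeVenomAbundance(shareTable, wft, unidentified = unid,
                        venomId = config$venom_id))
  families <- .withStage("aggregate_families",
                         aggregateFamilies(abundance, fmap = fmap))
  counts <- .withStage("count_nonredundant",
                       countNonredundant(abundance, fmap = fmap))

  immuno <- relative <- controls <- NULL
  if (!is.null(config$elisa)) {
    plate <- .withStage("read_elisa", readElisaPlate(config$elisa))
    immuno <- .withStage("summarize_plate", summarizePlate(plate))
    immuno$class <- classifyReactivity(immuno$mean)
    ref <- config$reference_antivenom
    cmp <- config$comparator_antivenom
    if (!is.null(ref) && !is.null(cmp)) {
      relative <- .withStage("relative_immunoreactivity",
        relativeImmunoreactivity(
          immuno[immuno$antivenom == ref, , drop = FALSE],
          immuno[immuno$antivenom == cmp, , drop = FALSE]))
    }
    controls <- .withStage("control_check",
      controlCheck(immuno,
                   negative = as.character(config$negative_control %||%
                                             character()),
                   positive = as.character(config$positive_control %||%
                                             character())))
  }

  files <- character()
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- c(proteins = file.path(outDir, "proteins.tsv"),
               families = file.path(outDir, "families.tsv"),
               report = file.path(outDir, "report.json"))
    writeAbundanceTable(abundance, files[["proteins"]],
                        familyPath = files[["families"]], fmap = fmap)
    if (!is.null(immuno)) {
      files[["immunoprofile"]] <- file.path(outDir, "immunoprofile.tsv")
      utils::write.table(immuno, files[["immunoprofile"]], sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    log <- list(
      package = "decomplexR",
      version = as.character(utils::packageVersion("decomplexR")),
      venom_id = config$venom_id,
      thresholds = list(min_protein_score = th@minProteinScore,
                        min_peptide_score = th@minPeptideScore,
                        min_spi = th@minSpi, max_fdr = th@maxFdr),
      filter_report = filt$report,
      chosen_cutoff = filt$cutoff,
      achieved_fdr = filt$achievedFdr,
      n_proteins = counts$proteins,
      n_families = counts$families,
      unidentified_pct = unidentifiedShare(abundance))
    jsonlite::write_json(log, files[["report"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  res <- list(shares = shareTable, filter = filt[c("cutoff", "achievedFdr",
                                                   "report")],
              abundance = abundance, families = families, counts = counts,
              immunoprofile = immuno, relative = relative,
              controls = controls, files = files)
  if (length(files)) invisible(res) else res
}

#' Compare two venoms from precomputed abundance tables
#'
#' The precomputed-abundance entry point: accepts
#' \linkS4class{AbundanceTable}s directly (e.g. the curated reference
#' proteomes, or tables read back from a pipeline run) and produces the
#' family-level comparison, optionally written as JSON.
#'
#' @param a,b \linkS4class{AbundanceTable}s.
#' @param fmap Optional \linkS4class{FamilyMap}.
#' @param path Optional JSON output path.
#' @return A \linkS4class{VenomComparison}.
#' @export
#' @examples
#' ref <- referenceProteomes()
#' cmp <- comparisonReport(ref$thailand, ref$indonesia)
#' comparisonCounts(cmp)
comparisonReport <- function(a, b, fmap = NULL, path = NULL) {
  cmp <- compareVenoms(a, b, fmap = fmap)
  if (!is.null(path)) writeComparison(cmp, path)
  cmp
}

`%||%` <- function(a, b) if (is.null(a)) b else a
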