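## Census orchestration: simulate -> detect -> type -> spacers -> trace ->
## pam -> report, with plain-file artifacts per stage so any stage can be
## rerun in isolation.

#' Percentage of spacers with a traced target
#'
#' Rounded half-up to two decimals, locale-independent; NA (not 0) when no
#' spacer exists.
#'
#' @param nTraced,nTotal unique spacer counts.
#' @return numeric percentage, 2 decimals.
#' @export
pctTraced <- function(nTraced, nTotal) {
  if (is.na(nTotal) || nTotal == 0) return(NA_real_)
  roundHalfUp(100 * nTraced / nTotal, 2L)
}

#' Assemble the census report from per-type tallies
#'
#' The arithmetic core of the census summary: per-type spacer and array
#' counts are aggregated into totals, and the traced percentage is derived
#' from the unique-spacer tallies.
#'
#' @param nSpacersByType named numeric, spacers per type label.
#' @param nArraysByType named numeric, arrays per type label (optional).
#' @param nTraced number of unique spacers with at least one traced target
#'   (NA when tracing was skipped).
#' @param pamProfiles optional list of per-type [PamProfile-class] bundles.
#' @param meta optional run metadata (seed, config hash, versions).
#' @return list of class "CensusReport".
#' @export
censusReport <- function(nSpacersByType, nArraysByType = NULL,
                         nTraced = NA_real_, pamProfiles = NULL,
                         meta = list()) {
  nSpacersTotal <- sum(nSpacersByType)
  rep <- list(
    n_arrays_by_type = nArraysByType,
    n_arrays_total = if (is.null(nArraysByType)) NA_real_
                     else sum(nArraysByType),
    n_spacers_by_type = nSpacersByType,
    n_spacers_total = nSpacersTotal,
    n_spacers_traced = nTraced,
    n_spacers_untraced = if (is.na(nTraced)) NA_real_
                         else nSpacersTotal - nTraced,
    pct_traced = pctTraced(nTraced, nSpacersTotal),
    pam_profiles = pamProfiles,
    meta = meta)
  class(rep) <- c("CensusReport", "list")
  rep
}

#' Census summary from stage objects
#'
#' Tallies arrays and unique spacers per type and derives the traced
#' percentage: 100 x (unique spacers with >= 1 hit) / (unique spacers),
#' rounded half-up to 2 decimals.
#'
#' @param arrays list of [CrisprArray-class].
#' @param typeCalls named list from [typeArrays()].
#' @param spacerCatalog spacer data.frame from [extractSpacers()].
#' @param hits hit data.frame, or NULL when tracing was skipped.
#' @param pamProfiles,meta passed through to [censusReport()].
#' @return a "CensusReport" list.
#' @export
summaryReport <- function(arrays, typeCalls, spacerCatalog, hits = NULL,
                          pamProfiles = NULL, meta = list()) {
  ids <- vapply(arrays, arrayId, character(1))
  if (!all(ids %in% names(typeCalls)))
    stop("consistency error: arrays without a type call")
  if (nrow(spacerCatalog) &&
      !all(spacerCatalog$array_id %in% ids))
    stop("consistency error: spacer records reference unknown arrays")
  labels <- vapply(typeCalls[ids], typeLabel, character(1))
  lvl <- c("C", "B", "G", "E", "U")
  nArr <- stats::setNames(as.numeric(table(factor(labels, levels = lvl))),
                          lvl)
  uni <- dedupeSpacers(spacerCatalog)$unique
  recLab <- labels[match(uni$array_id, ids)]
  nSp <- stats::setNames(as.numeric(table(factor(recLab, levels = lvl))),
                         lvl)
  nTraced <- if (is.null(hits)) NA_real_ else {
    traced <- unique(hits$spacer_id)
    sum(uni$spacer_id %in% traced)
  }
  censusReport(nSp, nArr, nTraced, pamProfiles, meta)
}

#' @export
print.CensusReport <- function(x, ...) {
  cat("CRISPR census report\n")
  if (!is.null(x$n_arrays_by_type)) {
    cat("  arrays:", x$n_arrays_total, "(",
        paste(sprintf("%s=%g", names(x$n_arrays_by_type),
                      x$n_arrays_by_type), collapse = ", "), ")\n")
  }
  cat("  spacers:", x$n_spacers_total, "(",
      paste(sprintf("%s=%g", names(x$n_spacers_by_type),
                    x$n_spacers_by_type), collapse = ", "), ")\n")
  if (!is.na(x$n_spacers_traced)) {
    cat("  traced:", x$n_spacers_traced,
        sprintf("(%.2f%%); untraced: %g\n", x$pct_traced,
                x$n_spacers_untraced))
  }
  invisible(x)
}

## PamProfile -> plain list for JSON serialisation.
.pamProfileAsList <- function(p) {
  list(stratum = p@stratum, n_targets = p@nTargets,
       tri_counts = as.list(p@triCounts),
       preferred = p@preferred,
       position_matrix = p@positionMatrix,
       degenerate = p@degenerate,
       degenerate_coverage = p@degenerateCoverage)
}

## md5 of the canonical YAML rendering of a config list.
.configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the census pipeline
#'
#' Orchestrates simulate -> detect -> type -> spacers -> trace -> pam ->
#' report.  All stage artifacts are plain files (FASTA / GFF3 / TSV / JSON)
#' written to `outdir`; a fixed seed and config give byte-identical
#' reports.  When no target database is configured (and the simulator
#' plants no protospacers) the tracing and PAM stages are skipped and the
#' corresponding report fields stay NA/null.
#'
#' @param config a list, or path to a YAML file, with optional sections:
#'   `simulate` ([simConfig()] arguments), `genome` (FASTA path),
#'   `targets` (FASTA path), `detect` ([scanConfig()] arguments),
#'   `trace` ([traceConfig()] arguments).
#' @param outdir run directory (created if needed).
#' @param seed overrides `config$simulate$seed`.
#' @return the "CensusReport", invisibly; artifacts in `outdir`.
#' @export
runPipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed) && !is.null(config$simulate))
    config$simulate$seed <- as.integer(seed)
  usedSeed <- if (!is.null(config$simulate)) config$simulate$seed else seed
  truth <- NULL
  targets <- NULL

  genome <- .stage("input", {
    if (!is.null(config$simulate)) {
      simArgs <- config$simulate
      if (!is.null(simArgs$arraySpecs))
        simArgs$arraySpecs <- lapply(simArgs$arraySpecs, function(a)
          if (inherits(a, "arraySpec")) a else do.call(arraySpec, a))
      cfg <- do.call(simConfig, simArgs)
      host <- generateHostGenome(cfg)
      truth <- host$truth
      writeGenomeFasta(host$seq, file.path(outdir, "genome.fasta"))
      if (cfg$nProtospacers > 0L) {
        mge <- generateMge(cfg, truthSpacers(host$truth))
        truth <- TruthTable(arrays = truthArrays(host$truth),
                            protospacers = truthProtospacers(mge$truth))
        targets <- mge$seq
        writeGenomeFasta(mge$seq, file.path(outdir, "targets.fasta"))
      }
      writeTruthTable(truth, file.path(outdir, "truth_arrays.tsv"),
                      file.path(outdir, "truth_protospacers.tsv"))
      host$seq
    } else if (!is.null(config$genome)) {
      if (!file.exists(config$genome))
        stop("input error: genome FASTA '", config$genome, "' not found")
      Biostrings::readDNAStringSet(config$genome)
    } else stop("input error: neither a simulate block nor a genome path")
  })
  if (is.null(targets) && !is.null(config$targets)) {
    targets <- .stage("input", Biostrings::readDNAStringSet(config$targets))
  }

  scfg <- do.call(scanConfig, if (is.null(config$detect)) list()
                  else config$detect)
  arrays <- .stage("detect", detectArrays(genome, scfg))
  message("stage detect: ", length(genome), " contig(s) in, ",
          length(arrays), " array(s) out")
  writeArrayGff3(arrays, file.path(outdir, "arrays.gff3"))

  calls <- .stage("type", typeArrays(arrays))
  arrays <- orientArrays(arrays, calls)
  writeArrayTable(arrays, file.path(outdir, "arrays.tsv"), calls)

  catalog <- .stage("spacers", extractSpacers(arrays))
  message("stage spacers: ", nrow(catalog), " spacer(s)")
  if (nrow(catalog))
    writeSpacerFasta(catalog, file.path(outdir, "spacers.fasta"))
  uni <- dedupeSpacers(catalog)$unique

  hits <- NULL
  profiles <- NULL
  if (!is.null(targets)) {
    tcfg <- do.call(traceConfig, if (is.null(config$trace)) list()
                    else config$trace)
    hits <- .stage("trace", traceSpacers(uni, targets, tcfg))
    message("stage trace: ", nrow(hits), " hit(s)")
    writeHitTable(hits, file.path(outdir, "hits.tsv"))
    nr <- .stage("trace", dedupeTargets(hits))
    writeHitTable(nr, file.path(outdir, "targets_nonredundant.tsv"))
    profiles <- .stage("pam", pamProfiles(nr))
    jsonlite::write_json(lapply(profiles, .pamProfileAsList),
                         file.path(outdir, "pam.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }

  meta <- list(seed = usedSeed, config_hash = .configHash(config),
               package_version =
                 as.character(utils::packageVersion("crisprCensus")),
               r_version = R.version.string)
  report <- .stage("report",
                   summaryReport(arrays, calls, catalog, hits,
                                 pamProfiles = profiles, meta = meta))
  repOut <- report
  repOut$pam_profiles <- if (is.null(profiles)) NULL
                         else lapply(profiles, .pamProfileAsList)
  jsonlite::write_json(unclass(repOut), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  counts <- data.frame(type = names(report$n_spacers_by_type),
                       n_arrays = as.numeric(report$n_arrays_by_type),
                       n_spacers = as.numeric(report$n_spacers_by_type))
  utils::write.table(counts, file.path(outdir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(report)
}
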