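## Array output in the standard CRISPR GFF3 convention and a flat TSV.

#' Write arrays as GFF3
#'
#' One `repeat_region` per array with `direct_repeat` and `spacer`
#' children (the usual CRISPR GFF convention).  Internal 0-based half-open
#' coordinates are converted to the 1-based inclusive GFF3 convention by
#' the GRanges construction.
#'
#' @param arrays list of [CrisprArray-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeArrayGff3 <- function(arrays, path) {
  if (!length(arrays)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rows <- list()
  for (a in arrays) {
    aid <- arrayId(a)
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = contigId(a), start = arrayStart(a) + 1L, end = arrayEnd(a),
      strand = orientation(a), type = "repeat_region", ID = aid,
      Parent = NA_character_, stringsAsFactors = FALSE)
    us <- unitStarts(a); ue <- unitEnds(a)
    for (i in seq_along(us)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = contigId(a), start = us[i] + 1L, end = ue[i],
        strand = orientation(a), type = "direct_repeat",
        ID = sprintf("%s_DR%d", aid, i), Parent = aid,
        stringsAsFactors = FALSE)
      if (i < length(us)) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqnames = contigId(a), start = ue[i] + 1L, end = us[i + 1L],
          strand = orientation(a), type = "spacer",
          ID = sprintf("%s_sp%03d", aid, i - 1L), Parent = aid,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = ifelse(df$strand == "*", "*", df$strand))
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write the flat array table
#'
#' @param arrays list of [CrisprArray-class].
#' @param path output TSV.
#' @param typeCalls optional named list from [typeArrays()]; adds type
#'   columns.
#' @return the path, invisibly.
#' @export
writeArrayTable <- function(arrays, path, typeCalls = NULL) {
  df <- arrayTable(arrays, typeCalls)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summarise arrays (and typing calls) as a data.frame
#'
#' @inheritParams writeArrayTable
#' @return data.frame, one row per array (0-based half-open coordinates).
#' @export
arrayTable <- function(arrays, typeCalls = NULL) {
  df <- data.frame(
    array_id = vapply(arrays, arrayId, character(1)),
    contig_id = vapply(arrays, contigId, character(1)),
    start = vapply(arrays, arrayStart, numeric(1)),
    end = vapply(arrays, arrayEnd, numeric(1)),
    n_units = vapply(arrays, nUnits, integer(1)),
    conservation = vapply(arrays, conservation, numeric(1)),
    consensus = vapply(arrays, consensusRepeat, character(1)),
    orientation = vapply(arrays, orientation, character(1)),
    truncated = vapply(arrays, truncated, logical(1)),
    stringsAsFactors = FALSE)
  if (!is.null(typeCalls)) {
    idx <- match(df$array_id, names(typeCalls))
    df$type <- vapply(idx, function(i)
      if (is.na(i)) NA_character_ else typeLabel(typeCalls[[i]]),
      character(1))
    df$oriented_consensus <- vapply(idx, function(i)
      if (is.na(i)) NA_character_ else typeCalls[[i]]@orientedConsensus,
      character(1))
    df$motif <- vapply(idx, function(i)
      if (is.na(i)) NA_character_ else typeCalls[[i]]@matchedMotif,
      character(1))
    df$motif_mismatches <- vapply(idx, function(i)
      if (is.na(i)) NA_real_ else typeCalls[[i]]@motifMismatches,
      numeric(1))
    df$hairpin_stem <- vapply(idx, function(i)
      if (is.na(i)) NA_real_ else typeCalls[[i]]@hairpin[["stem"]],
      numeric(1))
    df$hairpin_loop <- vapply(idx, function(i)
      if (is.na(i)) NA_real_ else typeCalls[[i]]@hairpin[["loop"]],
      numeric(1))
  }
  df
}

#' Write a hit table as TSV
#'
#' @param hits hit data.frame from the tracer.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
writeHitTable <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
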