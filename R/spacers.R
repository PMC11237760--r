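## Spacer cataloguing: extraction, strand-normalised deduplication and
## per-type summary statistics (length distribution, GC quartiles, per-array
## counts).

#' Extract spacer records from arrays
#'
#' One record per inter-repeat interval.  Sequences stay uppercase
#' forward-strand as detected; index 0 is the array end nearest the leader
#' when the orientation is known (leftmost for "+"/"*", rightmost for "-"),
#' which affects reporting order only.
#'
#' @param arrays list of [CrisprArray-class].
#' @return data.frame (spacer_id, array_id, index, sequence, length, gc).
#' @export
extractSpacers <- function(arrays) {
  rows <- lapply(arrays, function(a) {
    sp <- spacerSeqs(a)
    if (!length(sp)) return(NULL)
    idx <- seq_along(sp) - 1L
    if (orientation(a) == "-") idx <- rev(idx)
    data.frame(
      spacer_id = sprintf("%s_sp%03d", arrayId(a), idx),
      array_id = arrayId(a), index = idx,
      sequence = toupper(sp), length = nchar(sp),
      gc = gcFraction(sp), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, Filter(Negate(is.null), rows))
         else NULL
  if (is.null(out))
    out <- data.frame(spacer_id = character(0), array_id = character(0),
                      index = integer(0), sequence = character(0),
                      length = integer(0), gc = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Deduplicate spacers
#'
#' Uniqueness is on the exact sequence after strand normalisation (a spacer
#' and its reverse complement are the same spacer; the lexicographically
#' smaller string is the canonical key).  The first record of each key is
#' kept as representative.
#'
#' @param records data.frame from [extractSpacers()].
#' @return list with `unique` (representative records plus a `canonical`
#'   column) and `multiplicity` (data.frame canonical / count).
#' @export
dedupeSpacers <- function(records) {
  if (!nrow(records)) {
    return(list(unique = cbind(records, canonical = character(0)),
                multiplicity = data.frame(canonical = character(0),
                                          count = integer(0))))
  }
  canon <- pmin(records$sequence, revComp(records$sequence))
  records$canonical <- canon
  uni <- records[!duplicated(canon), , drop = FALSE]
  tab <- table(canon)
  mult <- data.frame(canonical = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  mult <- mult[match(uni$canonical, mult$canonical), , drop = FALSE]
  rownames(uni) <- NULL; rownames(mult) <- NULL
  list(unique = uni, multiplicity = mult)
}

#' Per-type spacer statistics
#'
#' Summaries mirroring a per-type census: total spacer count, normalised
#' length distribution (ratios sum to 1), mean length, GC quartiles
#' (Q1/median/Q3, linear interpolation) and the maximum per-array spacer
#' count.
#'
#' @param records data.frame from [extractSpacers()].
#' @param typeCalls named list of [RepeatTypeCall-class] (from
#'   [typeArrays()]) or a named character vector of labels, keyed by
#'   array id; every record's array must be present.
#' @return named list per type label, each with `n`, `lengthDist`
#'   (data.frame length/count/ratio), `meanLength`, `gcQuartiles`,
#'   `maxPerArray`.
#' @export
spacerStats <- function(records, typeCalls) {
  labels <- if (is.character(typeCalls)) typeCalls
            else vapply(typeCalls, typeLabel, character(1))
  missing <- setdiff(unique(records$array_id), names(labels))
  if (length(missing))
    stop("consistency error: no type call for array(s) ",
         paste(missing, collapse = ", "))
  if (!nrow(records)) return(list())
  recLab <- labels[records$array_id]
  out <- lapply(split(seq_len(nrow(records)), recLab), function(ii) {
    sub <- records[ii, , drop = FALSE]
    tl <- table(sub$length)
    lengthDist <- data.frame(length = as.integer(names(tl)),
                             count = as.integer(tl),
                             ratio = as.numeric(tl) / nrow(sub))
    perArray <- table(sub$array_id)
    list(n = nrow(sub),
         lengthDist = lengthDist,
         meanLength = mean(sub$length),
         gcQuartiles = stats::quantile(sub$gc, c(0.25, 0.5, 0.75),
                                       type = 7, names = FALSE),
         maxPerArray = max(as.integer(perArray)))
  })
  out
}

#' Write spacers as FASTA
#'
#' Headers follow `arrayID|index`.
#'
#' @param records data.frame from [extractSpacers()].
#' @param path output FASTA.
#' @return the path, invisibly.
#' @export
writeSpacerFasta <- function(records, path) {
  seqs <- Biostrings::DNAStringSet(stats::setNames(
    records$sequence, sprintf("%s|%d", records$array_id, records$index)))
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}
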