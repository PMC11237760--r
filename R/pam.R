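## PAM inference from hit flanks.  The PAM window is the trinucleotide
## immediately 5' of the protospacer (the last 3 nt of the 8-nt 5' flank);
## the full 8-nt flank feeds the per-position profile used for logos.
## Because target and spacer sequences mutate with age, candidate PAMs are
## stratified by mismatch count, and the degenerate consensus is called from
## perfectly matched targets only, where mutations are least likely.

#' Stratify non-redundant hits by mismatch count
#'
#' Strata are nested: perfect (m = 0) within high_confidence (m <= 3) within
#' extended (m <= 6) within all.
#'
#' @param hits deduplicated hit data.frame (see [dedupeTargets()]).
#' @param strata mismatch bounds for the named strata.
#' @return named list of hit subsets (perfect, high_confidence, extended,
#'   all).
#' @export
stratifyHits <- function(hits, strata = c(0L, 3L, 6L)) {
  list(perfect = hits[hits$mismatches <= strata[1L], , drop = FALSE],
       high_confidence = hits[hits$mismatches <= strata[2L], , drop = FALSE],
       extended = hits[hits$mismatches <= strata[3L], , drop = FALSE],
       all = hits)
}

## PAM trinucleotides of hits with an available 5' flank; hits without a
## flank are excluded (their number is reported via attribute).
.pamTrinucleotides <- function(hits, flankLen = 8L) {
  ok <- !is.na(hits$flank5) & nchar(hits$flank5) >= 3L
  tri <- substr(hits$flank5[ok], nchar(hits$flank5[ok]) - 2L,
                nchar(hits$flank5[ok]))
  attr(tri, "excluded") <- sum(!ok)
  tri
}

#' PAM trinucleotide counts and ratios
#'
#' Counts the 3 nt immediately 5'-adjacent to each protospacer; ratios are
#' over targets with an available flank, so the table renormalises exactly
#' after exclusions.
#'
#' @param hits deduplicated hit data.frame.
#' @param preferredMin inclusive ratio for the preferred-PAM list (a 10%
#'   entry is listed).
#' @return list with `counts` (named, sorted desc), `ratios`, `n`,
#'   `excluded` (hits lacking a flank) and `preferred` (data.frame pam,
#'   count, ratio).
#' @export
pamCounts <- function(hits, preferredMin = 0.10) {
  tri <- .pamTrinucleotides(hits)
  excluded <- attr(tri, "excluded")
  if (excluded > 0L)
    message(excluded, " hit(s) without an available 5' flank excluded ",
            "from PAM counting")
  if (!length(tri)) {
    return(list(counts = integer(0), ratios = numeric(0), n = 0L,
                excluded = excluded,
                preferred = data.frame(pam = character(0),
                                       count = integer(0),
                                       ratio = numeric(0))))
  }
  tab <- sort(table(tri), decreasing = TRUE)
  counts <- stats::setNames(as.integer(tab), names(tab))
  ratios <- counts / sum(counts)
  sel <- ratios >= preferredMin
  preferred <- data.frame(pam = names(counts)[sel],
                          count = counts[sel],
                          ratio = as.numeric(ratios[sel]),
                          stringsAsFactors = FALSE)
  preferred <- preferred[order(-preferred$ratio, preferred$pam), ,
                         drop = FALSE]
  rownames(preferred) <- NULL
  list(counts = counts, ratios = ratios, n = sum(counts),
       excluded = excluded, preferred = preferred)
}

#' Per-position base frequencies of the 5' flank
#'
#' @param hits deduplicated hit data.frame.
#' @param flankLen flank length (columns of the matrix).
#' @return 4 x flankLen matrix (rows A, C, G, T; columns positions
#'   -flankLen..-1 relative to the protospacer); every column sums to 1.
#'   Ambiguous bases are excluded per column before normalising.
#' @export
positionProfile <- function(hits, flankLen = 8L) {
  ok <- !is.na(hits$flank5) & nchar(hits$flank5) == flankLen
  fl <- hits$flank5[ok]
  mat <- matrix(0, nrow = 4L, ncol = flankLen,
                dimnames = list(DNA_BASES,
                                sprintf("%d", -(flankLen:1))))
  if (!length(fl)) return(mat)
  m <- seqMatrix(fl)
  for (j in seq_len(flankLen)) {
    col <- m[, j]
    col <- col[col %in% DNA_BASES]
    if (!length(col)) next
    mat[, j] <- tabulate(factor(col, levels = DNA_BASES),
                         nbins = 4L) / length(col)
  }
  mat
}

#' Degenerate IUPAC consensus from perfect-stratum PAMs
#'
#' For each of the 3 PAM positions, the bases reaching `posThreshold`
#' frequency among perfectly matched targets form the position's base set,
#' encoded as an IUPAC letter; coverage is the fraction of perfect PAMs the
#' motif subsumes.  0.15 is the smallest threshold that keeps the motif
#' shapes crisp on synthetic mixtures while absorbing the variable third
#' base typical of type I PAMs.
#'
#' @param pams character vector of perfect-target PAM trinucleotides, or a
#'   hit data.frame (the perfect stratum) from which they are read.
#' @param posThreshold per-position base frequency threshold.
#' @return `list(consensus =, coverage =)`; both NA (with a warning) when no
#'   perfect PAM is available.
#' @export
degenerateConsensus <- function(pams, posThreshold = 0.15) {
  if (is.data.frame(pams)) pams <- as.character(.pamTrinucleotides(pams))
  pams <- toupper(pams[!is.na(pams) & nchar(pams) == 3L])
  if (!length(pams)) {
    warning("no perfectly matched target with an available flank; ",
            "degenerate PAM consensus unavailable")
    return(list(consensus = NA_character_, coverage = NA_real_))
  }
  m <- seqMatrix(pams)
  sets <- lapply(1:3, function(j) {
    col <- m[, j]
    col <- col[col %in% DNA_BASES]
    freq <- tabulate(factor(col, levels = DNA_BASES), nbins = 4L) /
      length(col)
    DNA_BASES[freq >= posThreshold]
  })
  if (any(lengths(sets) == 0L)) {
    warning("a PAM position has no base above the threshold")
    return(list(consensus = NA_character_, coverage = NA_real_))
  }
  consensus <- paste(vapply(sets, iupacFromBases, character(1)),
                     collapse = "")
  match3 <- vapply(pams, function(p) {
    b <- strsplit(p, "", fixed = TRUE)[[1]]
    all(vapply(1:3, function(j) b[j] %in% sets[[j]], logical(1)))
  }, logical(1))
  list(consensus = consensus, coverage = mean(match3))
}

#' Full PAM profile for one stratum
#'
#' Bundles the trinucleotide table, the preferred list, the 8-nt position
#' profile and (for strata that contain perfect targets) the degenerate
#' consensus into a [PamProfile-class].
#'
#' @param hits deduplicated hit data.frame for the stratum.
#' @param stratum stratum label.
#' @param perfectHits the perfect stratum used for the degenerate consensus
#'   (defaults to the m = 0 subset of `hits`).
#' @param flankLen,preferredMin,posThreshold see the component functions.
#' @return a [PamProfile-class].
#' @export
pamProfile <- function(hits, stratum = "all",
                       perfectHits = hits[hits$mismatches == 0L, ,
                                          drop = FALSE],
                       flankLen = 8L, preferredMin = 0.10,
                       posThreshold = 0.15) {
  pc <- suppressMessages(pamCounts(hits, preferredMin))
  deg <- if (nrow(perfectHits)) {
    suppressWarnings(degenerateConsensus(perfectHits, posThreshold))
  } else list(consensus = NA_character_, coverage = NA_real_)
  new("PamProfile", stratum = stratum, nTargets = pc$n,
      triCounts = stats::setNames(as.numeric(pc$counts), names(pc$counts)),
      preferred = pc$preferred,
      positionMatrix = positionProfile(hits, flankLen),
      degenerate = deg$consensus,
      degenerateCoverage = deg$coverage)
}

#' PAM profiles for all mismatch strata
#'
#' @param hits deduplicated hit data.frame.
#' @param ... passed to [pamProfile()].
#' @return named list of [PamProfile-class] (perfect, high_confidence,
#'   extended, all).
#' @export
pamProfiles <- function(hits, ...) {
  strata <- stratifyHits(hits)
  perfect <- strata$perfect
  lapply(stats::setNames(names(strata), names(strata)), function(s) {
    pamProfile(strata[[s]], stratum = s, perfectHits = perfect, ...)
  })
}
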