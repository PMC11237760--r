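#' @import methods
NULL

## ---------------------------------------------------------------------------
## CrisprArray
## ---------------------------------------------------------------------------

#' CrisprArray: one detected (or planted) CRISPR array
#'
#' Container for a repeat--spacer--repeat structure on a contig.  All genomic
#' coordinates are 0-based half-open on the forward strand; GFF3 export
#' converts to 1-based inclusive.
#'
#' @slot arrayId character(1), stable identifier.
#' @slot contigId character(1).
#' @slot start,end numeric(1), 0-based half-open span of the array.
#' @slot unitStarts,unitEnds numeric, per-repeat-unit intervals (0-based
#'   half-open), ordered and non-overlapping.
#' @slot repeatSeqs character, the observed repeat copies (forward strand).
#' @slot spacerSeqs character, the inter-repeat sequences; always one fewer
#'   than the repeat copies.
#' @slot consensusRepeat character(1), per-column majority consensus.
#' @slot conservation numeric(1) in \[0,1\], mean per-column identity of the
#'   units to the consensus.
#' @slot orientation character(1), one of "+", "-", "*" (unknown until repeat
#'   typing resolves the motif strand).
#' @slot truncated logical(1), TRUE when the array abuts a contig end closely
#'   enough that further units could have been lost to assembly fragmentation.
#' @export
setClass("CrisprArray",
  representation(
    arrayId = "character",
    contigId = "character",
    start = "numeric",
    end = "numeric",
    unitStarts = "numeric",
    unitEnds = "numeric",
    repeatSeqs = "character",
    spacerSeqs = "character",
    consensusRepeat = "character",
    conservation = "numeric",
    orientation = "character",
    truncated = "logical"
  )
)

setValidity("CrisprArray", function(object) {
  msg <- character(0)
  nu <- length(object@unitStarts)
  if (length(object@unitEnds) != nu)
    msg <- c(msg, "unitStarts and unitEnds differ in length")
  if (length(object@repeatSeqs) != nu)
    msg <- c(msg, "one repeat sequence per unit required")
  if (length(object@spacerSeqs) != max(nu - 1L, 0L))
    msg <- c(msg, "spacer count must equal repeat count - 1")
  if (nu >= 2L) {
    if (any(diff(object@unitStarts) <= 0))
      msg <- c(msg, "units must be ordered by position")
    if (any(object@unitStarts[-1L] < object@unitEnds[-nu]))
      msg <- c(msg, "units must not overlap")
  }
  if (nu >= 1L && any(object@unitEnds <= object@unitStarts))
    msg <- c(msg, "unit intervals must be non-empty (0-based half-open)")
  if (object@conservation < 0 || object@conservation > 1)
    msg <- c(msg, "conservation must lie in [0, 1]")
  cl <- nchar(object@consensusRepeat)
  if (cl < 23L || cl > 55L)
    msg <- c(msg, "consensus repeat length must lie in [23, 55]")
  if (!object@orientation %in% c("+", "-", "*"))
    msg <- c(msg, "orientation must be '+', '-' or '*'")
  if (length(msg)) msg else TRUE
})

#' Construct a CrisprArray
#'
#' @param contigId contig identifier.
#' @param unitStarts,unitEnds repeat-unit intervals, 0-based half-open.
#' @param repeatSeqs,spacerSeqs observed repeat and spacer sequences
#'   (forward strand, uppercase).
#' @param consensusRepeat majority consensus of the repeat copies; computed
#'   from `repeatSeqs` when NULL.
#' @param conservation mean per-column identity to the consensus; computed
#'   when NULL.
#' @param arrayId identifier (default derived from contig and start).
#' @param orientation "+", "-" or "*".
#' @param truncated logical flag.
#' @return a [CrisprArray-class] object.
#' @export
CrisprArray <- function(contigId, unitStarts, unitEnds, repeatSeqs, spacerSeqs,
                        consensusRepeat = NULL, conservation = NULL,
                        arrayId = NULL, orientation = "*", truncated = FALSE) {
  repeatSeqs <- toupper(repeatSeqs)
  spacerSeqs <- toupper(spacerSeqs)
  if (is.null(consensusRepeat)) consensusRepeat <- majorityConsensus(repeatSeqs)
  if (is.null(conservation)) {
    L <- nchar(consensusRepeat)
    conservation <- mean(vapply(repeatSeqs, function(r) {
      seqIdentity(r, consensusRepeat)
    }, numeric(1)))
  }
  if (is.null(arrayId)) {
    arrayId <- sprintf("%s:%d-%d", contigId, min(unitStarts), max(unitEnds))
  }
  new("CrisprArray",
      arrayId = arrayId, contigId = contigId,
      start = min(unitStarts), end = max(unitEnds),
      unitStarts = as.numeric(unitStarts), unitEnds = as.numeric(unitEnds),
      repeatSeqs = repeatSeqs, spacerSeqs = spacerSeqs,
      consensusRepeat = toupper(consensusRepeat),
      conservation = conservation,
      orientation = orientation, truncated = truncated)
}

setMethod("show", "CrisprArray", function(object) {
  cat("CrisprArray ", object@arrayId, "\n",
      "  contig: ", object@contigId,
      sprintf("  [%d, %d) %s%s\n", object@start, object@end,
              object@orientation,
              if (object@truncated) " (truncated)" else ""),
      "  units: ", length(object@unitStarts),
      "  spacers: ", length(object@spacerSeqs),
      sprintf("  conservation: %.3f\n", object@conservation),
      "  consensus: ", object@consensusRepeat, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## RepeatTypeCall
## ---------------------------------------------------------------------------

#' RepeatTypeCall: repeat-based type assignment for one consensus repeat
#'
#' @slot label one of "C", "B", "G", "E", "U" (U = unclassified, i.e. no rule
#'   satisfied).
#' @slot orientedConsensus consensus on the canonical (motif) strand, 5'->3'.
#' @slot strandFlipped TRUE when the input was reverse-complemented to reach
#'   the canonical orientation.
#' @slot matchedMotif the terminal/internal motif that fired, or NA.
#' @slot motifMismatches mismatches within the motif window (NA for U).
#' @slot hairpin named numeric: stem length, loop length and 1-based start
#'   positions (i, j) of the two stem arms in the oriented consensus.
#' @export
setClass("RepeatTypeCall",
  representation(
    label = "character",
    orientedConsensus = "character",
    strandFlipped = "logical",
    matchedMotif = "character",
    motifMismatches = "numeric",
    hairpin = "numeric"
  )
)

setValidity("RepeatTypeCall", function(object) {
  msg <- character(0)
  if (!object@label %in% c("C", "B", "G", "E", "U"))
    msg <- c(msg, "label must be one of C, B, G, E, U")
  if (object@label == "U" && !is.na(object@matchedMotif))
    msg <- c(msg, "U calls carry no matched motif")
  if (object@label != "U" && is.na(object@matchedMotif))
    msg <- c(msg, "typed calls must carry the matched motif")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RepeatTypeCall", function(object) {
  cat("RepeatTypeCall: ", object@label, "-Type\n",
      "  oriented consensus: ", object@orientedConsensus,
      if (object@strandFlipped) "  (strand flipped)" else "", "\n",
      "  motif: ", ifelse(is.na(object@matchedMotif), "-",
                          object@matchedMotif),
      "  mismatches: ", ifelse(is.na(object@motifMismatches), "-",
                               object@motifMismatches), "\n",
      sprintf("  hairpin: stem %d nt, loop %d nt\n",
              as.integer(object@hairpin[["stem"]]),
              as.integer(object@hairpin[["loop"]])), sep = "")
})

## ---------------------------------------------------------------------------
## PamProfile
## ---------------------------------------------------------------------------

#' PamProfile: PAM summary for one mismatch stratum
#'
#' @slot stratum "perfect" (m = 0), "high_confidence" (m <= 3), "extended"
#'   (m <= 6) or "all".
#' @slot nTargets number of non-redundant targets with an available 5' flank.
#' @slot triCounts named integer, counts of the trinucleotide immediately 5'
#'   of the protospacer (last 3 nt of the 8-nt flank).
#' @slot preferred data.frame (pam, count, ratio) for PAMs at ratio >= 0.10,
#'   sorted by ratio descending.
#' @slot positionMatrix 4 x flank-length base-frequency matrix (rows A,C,G,T;
#'   columns are flank positions -flankLen..-1); columns sum to 1.
#' @slot degenerate IUPAC 3-mer consensus from perfect-stratum PAMs, or NA.
#' @slot degenerateCoverage fraction of perfect PAMs matching the degenerate
#'   motif (NA when no consensus).
#' @export
setClass("PamProfile",
  representation(
    stratum = "character",
    nTargets = "numeric",
    triCounts = "numeric",
    preferred = "data.frame",
    positionMatrix = "matrix",
    degenerate = "character",
    degenerateCoverage = "numeric"
  )
)

setValidity("PamProfile", function(object) {
  msg <- character(0)
  if (object@nTargets > 0 && length(object@triCounts)) {
    if (abs(sum(object@triCounts) - object@nTargets) > 1e-9)
      msg <- c(msg, "trinucleotide counts must sum to nTargets")
  }
  if (!is.na(object@degenerateCoverage) &&
      (object@degenerateCoverage < 0 || object@degenerateCoverage > 1))
    msg <- c(msg, "coverage must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PamProfile", function(object) {
  cat("PamProfile [", object@stratum, "]  n = ", object@nTargets, "\n",
      sep = "")
  if (nrow(object@preferred)) {
    cat("  preferred PAMs (ratio >= 0.10):\n")
    for (i in seq_len(nrow(object@preferred))) {
      cat(sprintf("    5'-%s-3'  %.2f%%\n", object@preferred$pam[i],
                  100 * object@preferred$ratio[i]))
    }
  }
  if (!is.na(object@degenerate)) {
    cat(sprintf("  degenerate consensus: 5'-%s-3' (coverage %.2f%%)\n",
                object@degenerate, 100 * object@degenerateCoverage))
  }
})

## ---------------------------------------------------------------------------
## TruthTable
## ---------------------------------------------------------------------------

#' TruthTable: planted ground truth emitted by the simulator
#'
#' @slot arrays data.frame of planted arrays (array_id, contig_id, start, end,
#'   repeat_type, repeat_template, unit_starts, unit_ends, spacer_ids,
#'   spacer_seqs, truncated); coordinates 0-based half-open; list-like columns
#'   are comma-joined strings so the table round-trips through TSV.
#' @slot protospacers data.frame of planted protospacers (proto_id, element_id,
#'   start, end, strand, spacer_id, spacer_seq, planted_mismatches,
#'   planted_pam, truncated).
#' @export
setClass("TruthTable",
  representation(arrays = "data.frame", protospacers = "data.frame"))

setMethod("show", "TruthTable", function(object) {
  cat("TruthTable: ", nrow(object@arrays), " planted array(s), ",
      nrow(object@protospacers), " planted protospacer(s)\n", sep = "")
})

TruthTable <- function(arrays = emptyTruthArrays(),
                       protospacers = emptyTruthProtospacers()) {
  new("TruthTable", arrays = arrays, protospacers = protospacers)
}

emptyTruthArrays <- function() {
  data.frame(array_id = character(0), contig_id = character(0),
             start = numeric(0), end = numeric(0),
             repeat_type = character(0), repeat_template = character(0),
             unit_starts = character(0), unit_ends = character(0),
             spacer_ids = character(0), spacer_seqs = character(0),
             truncated = logical(0), stringsAsFactors = FALSE)
}

emptyTruthProtospacers <- function() {
  data.frame(proto_id = character(0), element_id = character(0),
             start = numeric(0), end = numeric(0), strand = character(0),
             spacer_id = character(0), spacer_seq = character(0),
             planted_mismatches = numeric(0), planted_pam = character(0),
             truncated = logical(0), stringsAsFactors = FALSE)
}
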