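## Internal sequence utilities shared across modules.
## Genomic coordinates are 0-based half-open throughout the package's data
## structures; conversion to 1-based happens only at GFF3 export and in
## internal substring arithmetic.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA character vectors
#'
#' A light wrapper used throughout the package; operates on plain character
#' vectors (IUPAC ambiguity codes are complemented, case preserved).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' revComp("ACGTN")
#' @export
revComp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    s <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' GC fraction of DNA sequences
#'
#' Counts G and C over A+C+G+T; N and other ambiguity codes are excluded from
#' both numerator and denominator, so assemblies carrying Ns do not bias the
#' statistic.
#'
#' @param x character vector of DNA sequences.
#' @return numeric vector of GC fractions in \[0, 1\] (NA for sequences with
#'   no unambiguous base).
#' @export
gcFraction <- function(x) {
  vapply(x, function(s) {
    b <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    n_acgt <- sum(b %in% DNA_BASES)
    if (n_acgt == 0) return(NA_real_)
    sum(b %in% c("G", "C")) / n_acgt
  }, numeric(1), USE.NAMES = FALSE)
}

#' Hamming distance between two equal-length sequences
#'
#' Ambiguous bases never match: a position where either sequence (or both)
#' carries an N counts as a mismatch.
#'
#' @param a,b single sequences of equal length.
#' @return integer mismatch count.
#' @export
hammingDist <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("hammingDist() requires equal-length sequences (", nchar(a), " vs ",
         nchar(b), ")")
  }
  x <- charToRaw(toupper(a))
  y <- charToRaw(toupper(b))
  nraw <- charToRaw("N")
  sum(x != y | (x == nraw & y == nraw))
}

## Ungapped identity of two sequences, anchored left or right; mismatching
## lengths are penalised by dividing matches by the longer length.
seqIdentity <- function(a, b, anchor = c("left", "right")) {
  anchor <- match.arg(anchor)
  la <- nchar(a); lb <- nchar(b)
  L <- min(la, lb)
  if (L == 0L) return(0)
  if (anchor == "right") {
    aa <- substr(a, la - L + 1L, la); bb <- substr(b, lb - L + 1L, lb)
  } else {
    aa <- substr(a, 1L, L); bb <- substr(b, 1L, L)
  }
  (L - hammingDist(aa, bb)) / max(la, lb)
}

## Strand-insensitive identity (max over b and its reverse complement).
strandIdentity <- function(a, b, anchor = "left") {
  max(seqIdentity(a, b, anchor), seqIdentity(a, revComp(b), anchor))
}

## Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched.  All stochastic operations in the package go
## through this helper so equal seeds give byte-identical outputs.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Round half away from zero
#'
#' Deterministic, locale-independent half-up rounding (base `round()` rounds
#' half to even), used for reported percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(70.015, 2)   # 70.02
#' @export
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Random DNA string of length n with expected GC content `gc` (i.i.d. bases).
randomDna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

## Character matrix (rows = sequences, cols = positions); equal lengths only.
seqMatrix <- function(seqs) {
  do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
}

## Majority-vote consensus of equal-length sequences; per-column ties resolve
## to the alphabetically first base (deterministic).
majorityConsensus <- function(seqs) {
  if (length(seqs) == 1L) return(toupper(seqs))
  m <- seqMatrix(seqs)
  cons <- apply(m, 2L, function(col) {
    tab <- table(col)
    cand <- names(tab)[tab == max(tab)]
    sort(cand)[1L]
  })
  paste(cons, collapse = "")
}

## Inverse IUPAC lookup: a sorted set of bases -> one-letter degenerate code.
iupacFromBases <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  map <- Biostrings::IUPAC_CODE_MAP
  hit <- names(map)[vapply(map, function(v) {
    paste(sort(strsplit(v, "")[[1]]), collapse = "") == key
  }, logical(1))]
  if (length(hit) == 0L) stop("no IUPAC code for base set '", key, "'")
  hit[1L]
}

## Does `base` fall within degenerate IUPAC letter `code`?
iupacMatches <- function(base, code) {
  set <- strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]
  base %in% set
}
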