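## De-novo CRISPR array detection: exact k-mer seeding (CRT-style), boundary
## refinement by column-wise consensus agreement, consensus-guided recovery of
## units whose seed word was mutated, and confidence filters approximating a
## high-evidence extraction tier.

#' Detector configuration
#'
#' @param kSeed seed word length in nt; identical k-mers recurring at
#'   array-like spacings start a candidate.
#' @param repeatLenRange,spacerLenRange admissible repeat and spacer lengths
#'   in bp; together they bound the repeat period.
#' @param minUnits minimum repeat copies for a reported array (4 approximates
#'   the high-evidence tier of the common array finders; `permissive` lowers
#'   it to 3).
#' @param minRepeatConservation minimum mean per-column identity of the
#'   repeat copies to their consensus.
#' @param maxSpacerIdentity maximum pairwise (strand-insensitive) identity
#'   between spacers of one array; removes tandem repeats.
#' @param boundaryAgreement column agreement level at which boundary
#'   extension stops paying off (see the methods vignette).
#' @param extendIdentity minimum identity to the running consensus for
#'   consensus-guided recovery of additional units.
#' @param permissive retain 3-unit arrays.
#' @return a list of class "scanConfig".
#' @export
scanConfig <- function(kSeed = 9L, repeatLenRange = c(23L, 55L),
                       spacerLenRange = c(18L, 60L), minUnits = 4L,
                       minRepeatConservation = 0.80, maxSpacerIdentity = 0.60,
                       boundaryAgreement = 0.75, extendIdentity = 0.70,
                       permissive = FALSE) {
  stopifnot(kSeed >= 3L, kSeed <= repeatLenRange[1L],
            repeatLenRange[1L] <= repeatLenRange[2L],
            spacerLenRange[1L] <= spacerLenRange[2L],
            minUnits >= 2L,
            minRepeatConservation >= 0, minRepeatConservation <= 1,
            maxSpacerIdentity >= 0, maxSpacerIdentity <= 1)
  if (isTRUE(permissive)) minUnits <- min(minUnits, 3L)
  structure(list(kSeed = as.integer(kSeed),
                 repeatLenRange = as.integer(repeatLenRange),
                 spacerLenRange = as.integer(spacerLenRange),
                 minUnits = as.integer(minUnits),
                 minRepeatConservation = minRepeatConservation,
                 maxSpacerIdentity = maxSpacerIdentity,
                 boundaryAgreement = boundaryAgreement,
                 extendIdentity = extendIdentity),
            class = "scanConfig")
}

#' Find chains of recurring seed words
#'
#' Scans a contig for identical k-mers recurring at spacings compatible with
#' a repeat--spacer period and returns maximal chains.  Seed words with fewer
#' than three distinct bases are ignored (low-complexity guard against
#' homopolymer blow-up), as are words containing ambiguity codes.  The scan
#' works on forward coordinates only; an array is seen identically whichever
#' strand it was drawn from, so detection is strand-agnostic.
#'
#' @param contig single sequence (character or DNAString).
#' @param cfg a [scanConfig()].
#' @return list of chains, each `list(kmer =, starts =)` with 0-based seed
#'   start positions, ordered by first position.
#' @export
findSeedRepeats <- function(contig, cfg = scanConfig()) {
  seq <- toupper(as.character(contig))
  n <- nchar(seq)
  k <- cfg$kSeed
  if (n < 2L * cfg$repeatLenRange[1L]) return(list())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  dup <- duplicated(kmers) | duplicated(kmers, fromLast = TRUE)
  if (!any(dup)) return(list())
  pos <- starts[dup]
  km <- kmers[dup]
  clean <- !grepl("[^ACGT]", km)
  pos <- pos[clean]; km <- km[clean]
  if (!length(pos)) return(list())
  complex <- vapply(strsplit(unique(km), "", fixed = TRUE),
                    function(b) length(unique(b)) >= 3L, logical(1))
  okWords <- unique(km)[complex]
  sel <- km %in% okWords
  pos <- pos[sel]; km <- km[sel]
  if (!length(pos)) return(list())
  lo <- cfg$repeatLenRange[1L] + cfg$spacerLenRange[1L]
  hi <- cfg$repeatLenRange[2L] + cfg$spacerLenRange[2L]
  chains <- list()
  for (grp in split(pos, km)) {
    p <- sort(grp)
    okd <- diff(p) >= lo & diff(p) <= hi
    r <- rle(okd)
    at <- 1L
    for (j in seq_along(r$lengths)) {
      if (r$values[j]) {
        idx <- at:(at + r$lengths[j])
        chains[[length(chains) + 1L]] <-
          list(kmer = substring(seq, p[idx[1L]], p[idx[1L]] + k - 1L),
               starts = p[idx] - 1L)            # 0-based out
      }
      at <- at + r$lengths[j]
    }
  }
  if (!length(chains)) return(list())
  ## many k-mers of the same repeat produce equivalent chains; keep one
  ## representative per locus (most units, then leftmost, then smallest word)
  first <- vapply(chains, function(ch) ch$starts[1L], numeric(1))
  last <- vapply(chains, function(ch)
    ch$starts[length(ch$starts)] + nchar(ch$kmer), numeric(1))
  o <- order(first, last)
  grp <- integer(length(chains)); gidx <- 0L; hiEnd <- -1
  for (i in o) {
    if (first[i] > hiEnd) { gidx <- gidx + 1L; hiEnd <- last[i] }
    else hiEnd <- max(hiEnd, last[i])
    grp[i] <- gidx
  }
  reps <- vapply(split(seq_along(chains), grp), function(ii) {
    nu <- vapply(chains[ii], function(ch) length(ch$starts), integer(1))
    km <- vapply(chains[ii], `[[`, character(1), "kmer")
    ii[order(-nu, first[ii], km)][1L]
  }, integer(1))
  chains <- chains[reps]
  chains[order(vapply(chains, function(ch) ch$starts[1L], numeric(1)))]
}

## Column agreement across anchored units: fraction of units carrying the
## majority base at a fixed offset from their anchors.
.colAgreement <- function(seq, anchors1, off) {
  b <- substring(seq, anchors1 + off, anchors1 + off)
  b <- b[b %in% DNA_BASES]
  if (!length(b)) return(0)
  max(tabulate(factor(b, levels = DNA_BASES))) / length(anchors1)
}

## Best extension length under cumulative (agreement - theta) gain.
## Returns the outermost maximiser, so a boundary column that ties exactly is
## kept rather than trimmed; `cums[0]` is implicitly 0 (no extension).
.bestExtension <- function(cums, maxAllowed) {
  if (maxAllowed <= 0L || !length(cums)) return(c(val = 0, len = 0L))
  cums <- cums[seq_len(min(length(cums), maxAllowed))]
  best <- max(0, cums)
  hits <- which(cums >= best - 1e-9)
  len <- if (best < 1e-9 && !any(abs(cums) <= 1e-9)) 0L else max(hits, 0L)
  if (best < 1e-9 && !any(abs(cums) <= 1e-9)) len <- 0L
  c(val = best, len = len)
}

## Refine one seed chain into full repeat units: symmetric column-wise
## extension from the shared k-mer, maximising cumulative agreement above
## cfg$boundaryAgreement, jointly constrained so repeats stay within the
## length range and leave room for minimal spacers.
.refineChain <- function(chain, seq, n, cfg) {
  a <- chain$starts + 1L                      # 1-based anchor starts
  k <- nchar(chain$kmer)
  u <- length(a)
  period <- min(diff(a))
  maxLen <- min(cfg$repeatLenRange[2L], period - cfg$spacerLenRange[1L])
  if (maxLen < k) maxLen <- k
  lim <- maxLen - k
  maxL <- min(min(a) - 1L, lim)
  maxR <- min(n - (max(a) + k - 1L), lim)
  theta <- cfg$boundaryAgreement
  gainL <- if (maxL > 0L)
    vapply(seq_len(maxL), function(d)
      .colAgreement(seq, a, -d) - theta, numeric(1)) else numeric(0)
  gainR <- if (maxR > 0L)
    vapply(seq_len(maxR), function(d)
      .colAgreement(seq, a, k - 1L + d) - theta, numeric(1)) else numeric(0)
  cumL <- cumsum(gainL)
  cumR <- cumsum(gainR)
  best <- c(-Inf, 0L, 0L)                     # value, l, r
  for (l in 0:length(cumL)) {
    vl <- if (l == 0L) 0 else cumL[l]
    r <- .bestExtension(cumR, lim - l)
    v <- vl + r[["val"]]
    cand <- c(v, l, r[["len"]])
    if (v > best[1L] + 1e-12 ||
        (abs(v - best[1L]) <= 1e-12 &&
         (cand[2L] + cand[3L]) > (best[2L] + best[3L])))
      best <- cand
  }
  l <- best[2L]; r <- best[3L]
  L <- k + l + r
  if (L < cfg$repeatLenRange[1L]) return(NULL)
  list(starts = a - l, len = L)               # 1-based unit starts
}

## Consensus-guided stepwise recovery of units missed by the seed chain
## (e.g. copies whose seed word was mutated), outward in both directions.
.extendUnits <- function(starts, L, seq, n, cfg, cons) {
  spMin <- cfg$spacerLenRange[1L]; spMax <- cfg$spacerLenRange[2L]
  probe <- function(cand) {
    cand <- cand[cand >= 1L & cand + L - 1L <= n]
    if (!length(cand)) return(NULL)
    ident <- vapply(cand, function(s)
      1 - hammingDist(substring(seq, s, s + L - 1L), cons) / L, numeric(1))
    best <- max(ident)
    if (best < cfg$extendIdentity) return(NULL)
    cand[which(ident == best)[1L]]
  }
  repeat {
    lastEnd <- starts[length(starts)] + L - 1L
    hit <- probe(seq.int(lastEnd + 1L + spMin, lastEnd + 1L + spMax))
    if (is.null(hit)) break
    starts <- c(starts, hit)
  }
  repeat {
    first <- starts[1L]
    hit <- probe(seq.int(first - spMax - L, first - spMin - L))
    if (is.null(hit)) break
    starts <- c(hit, starts)
  }
  sort(starts)
}

#' Build candidate arrays from seed chains
#'
#' Chains covering the same locus are grouped; the chain with most units
#' seeds the locus.  Units are extended to full repeats by maximising
#' cumulative per-column agreement with the running consensus (ties push the
#' boundary outward), then additional units whose seed word was mutated are
#' recovered by consensus matching at spacer-compatible gaps.  Overlapping
#' candidates are resolved greedily (more units, then higher conservation,
#' then leftmost).
#'
#' @param chains output of [findSeedRepeats()].
#' @param contig the same sequence the chains came from.
#' @param cfg a [scanConfig()].
#' @return list of [CrisprArray-class] candidates ordered by start (not yet
#'   confidence-filtered; see [filterArrays()]).
#' @export
buildArrays <- function(chains, contig, cfg = scanConfig()) {
  if (!length(chains)) return(list())
  seq <- toupper(as.character(contig))
  n <- nchar(seq)
  spans <- cbind(vapply(chains, function(ch) ch$starts[1L], numeric(1)),
                 vapply(chains, function(ch)
                   ch$starts[length(ch$starts)] + nchar(ch$kmer),
                   numeric(1)))
  o <- order(spans[, 1L], spans[, 2L])
  grp <- integer(length(chains)); g <- 0L; hi <- -1
  for (i in o) {
    if (spans[i, 1L] > hi) { g <- g + 1L; hi <- spans[i, 2L] }
    else hi <- max(hi, spans[i, 2L])
    grp[i] <- g
  }
  cands <- list()
  for (gi in seq_len(g)) {
    sub <- chains[grp == gi]
    nu <- vapply(sub, function(ch) length(ch$starts), integer(1))
    first <- vapply(sub, function(ch) ch$starts[1L], numeric(1))
    seedChain <- sub[[order(-nu, first,
                            vapply(sub, `[[`, character(1), "kmer"))[1L]]]
    ref <- .refineChain(seedChain, seq, n, cfg)
    if (is.null(ref)) next
    L <- ref$len
    reps0 <- substring(seq, ref$starts, ref$starts + L - 1L)
    cons <- majorityConsensus(reps0)
    starts <- .extendUnits(ref$starts, L, seq, n, cfg, cons)
    reps <- substring(seq, starts, starts + L - 1L)
    cons <- majorityConsensus(reps)
    conserv <- mean(vapply(reps, function(r)
      1 - hammingDist(r, cons) / L, numeric(1)))
    ends <- starts + L - 1L
    spacers <- if (length(starts) > 1L)
      substring(seq, ends[-length(ends)] + 1L, starts[-1L] - 1L)
      else character(0)
    edge <- L + cfg$spacerLenRange[1L]
    trunc <- (starts[1L] - 1L) < edge || (n - ends[length(ends)]) < edge
    cands[[length(cands) + 1L]] <- CrisprArray(
      contigId = "contig", unitStarts = starts - 1L, unitEnds = ends,
      repeatSeqs = reps, spacerSeqs = spacers, consensusRepeat = cons,
      conservation = conserv, truncated = trunc)
  }
  if (!length(cands)) return(list())
  o <- order(-vapply(cands, nUnits, integer(1)),
             -vapply(cands, conservation, numeric(1)),
             vapply(cands, arrayStart, numeric(1)))
  kept <- list()
  for (i in o) {
    cand <- cands[[i]]
    clash <- any(vapply(kept, function(kp)
      arrayStart(cand) < arrayEnd(kp) && arrayEnd(cand) > arrayStart(kp),
      logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- cand
  }
  kept[order(vapply(kept, arrayStart, numeric(1)))]
}

## Max pairwise strand-insensitive spacer identity within an array.
maxPairSpacerIdentity <- function(spacers) {
  ns <- length(spacers)
  if (ns < 2L) return(0)
  best <- 0
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    best <- max(best, strandIdentity(spacers[i], spacers[j]))
  }
  best
}

#' Confidence-filter candidate arrays
#'
#' Retains arrays with at least `minUnits` repeat copies, repeat conservation
#' at or above `minRepeatConservation`, and maximum pairwise spacer identity
#' at or below `maxSpacerIdentity` (the tandem-repeat guard).  Together these
#' approximate a highest-evidence extraction tier.
#'
#' @param arrays list of [CrisprArray-class] from [buildArrays()].
#' @param cfg a [scanConfig()].
#' @return the retained arrays.
#' @export
filterArrays <- function(arrays, cfg = scanConfig()) {
  Filter(function(a) {
    nUnits(a) >= cfg$minUnits &&
      conservation(a) >= cfg$minRepeatConservation &&
      maxPairSpacerIdentity(spacerSeqs(a)) <= cfg$maxSpacerIdentity
  }, arrays)
}

#' Detect CRISPR arrays in an assembly
#'
#' Runs seeding, boundary refinement and confidence filtering per contig and
#' concatenates the results in a deterministic order (contig id, then start)
#' independent of the input contig order.
#'
#' @param assembly path to a FASTA file, or a DNAStringSet / named character
#'   vector of contigs.
#' @param cfg a [scanConfig()].
#' @return list of [CrisprArray-class], ids `<contig>_CRISPR_<i>`.
#' @export
detectArrays <- function(assembly, cfg = scanConfig()) {
  seqs <- if (is.character(assembly) && length(assembly) == 1L &&
              file.exists(assembly)) {
    Biostrings::readDNAStringSet(assembly)
  } else if (methods::is(assembly, "XStringSet")) {
    assembly
  } else {
    Biostrings::DNAStringSet(assembly)
  }
  if (!length(seqs) || all(Biostrings::width(seqs) == 0L))
    stop("input error: assembly is empty")
  nm <- names(seqs)
  if (is.null(nm)) nm <- sprintf("contig%d", seq_along(seqs))
  out <- list()
  for (ci in order(nm)) {
    contig <- as.character(seqs[[ci]])
    chains <- findSeedRepeats(contig, cfg)
    arrays <- filterArrays(buildArrays(chains, contig, cfg), cfg)
    for (i in seq_along(arrays)) {
      a <- arrays[[i]]
      a@contigId <- nm[ci]
      a@arrayId <- sprintf("%s_CRISPR_%d", nm[ci], i)
      out[[length(out) + 1L]] <- a
    }
  }
  out
}
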