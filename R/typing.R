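## Repeat-based typing: terminal-motif classes let fragmented genomes be
## typed without any cas genes.  Four conserved repeat classes are
## recognised -- C (terminal TTGAAAC, 37 bp), G (terminal TTGAAGC, 36 bp),
## B (terminal TTGAGCAC, 36 bp; covers the two adjoint subtypes that share
## this repeat) and E (internal palindrome CCCCGCNNNNGCGGGG, no conserved
## tail) -- everything else is U (unclassified).

#' Typing rules
#'
#' Returns the rule set in precedence order (longest terminal motif first:
#' B, G, C, then the internal-palindrome E rule).  Length ranges are the
#' printed type lengths +/- 2 bp; the E repeat length is never printed, so
#' its range \[27, 33\] brackets typical I-E repeats.
#'
#' @return list of rules, each `list(label, motif, position, lengthRange)`;
#'   `position` is "terminal" (3' end) or "internal" (N positions are
#'   wildcards).
#' @export
typeRules <- function() {
  list(
    list(label = "B", motif = "TTGAGCAC", position = "terminal",
         lengthRange = c(34L, 38L)),
    list(label = "G", motif = "TTGAAGC", position = "terminal",
         lengthRange = c(34L, 38L)),
    list(label = "C", motif = "TTGAAAC", position = "terminal",
         lengthRange = c(35L, 39L)),
    list(label = "E", motif = "CCCCGCNNNNGCGGGG", position = "internal",
         lengthRange = c(27L, 33L))
  )
}

## Mismatches between the 3' end of `s` and a terminal motif (Inf when the
## sequence is shorter than the motif); N anywhere counts as mismatch.
.suffixMismatch <- function(s, motif) {
  L <- nchar(s); m <- nchar(motif)
  if (L < m) return(Inf)
  hammingDist(substr(s, L - m + 1L, L), motif)
}

#' Canonical (motif-strand) orientation of a repeat
#'
#' Returns the strand on which a terminal typing motif matches with fewest
#' mismatches (within `maxMismatch`).  When neither strand carries a motif,
#' or both match equally well, the lexicographically smaller of the sequence
#' and its reverse complement is returned, which makes the operation an
#' involution: orienting a sequence and orienting its reverse complement
#' give the same result.
#'
#' @param x a DNA string (A/C/G/T/N).
#' @param rules rule set from [typeRules()].
#' @param maxMismatch motif mismatch tolerance used only for strand choice.
#' @return `list(oriented =, flipped =)`.
#' @export
canonicalOrientation <- function(x, rules = typeRules(), maxMismatch = 1L) {
  x <- toupper(x)
  if (!nchar(x) || grepl("[^ACGTN]", x))
    stop("input error: repeat must be a non-empty A/C/G/T/N string")
  rc <- revComp(x)
  terminal <- Filter(function(r) r$position == "terminal", rules)
  mm <- function(s) min(vapply(terminal, function(r)
    .suffixMismatch(s, r$motif), numeric(1)))
  mf <- mm(x); mr <- mm(rc)
  oriented <- if (min(mf, mr) <= maxMismatch && mf != mr) {
    if (mf < mr) x else rc
  } else {
    if (x <= rc) x else rc
  }
  list(oriented = oriented, flipped = !identical(oriented, x))
}

#' Longest hairpin stem in a repeat
#'
#' Finds the longest L such that `substr(seq, i, i+L-1)` is the reverse
#' complement of `substr(seq, j, j+L-1)` with a loop of at least `minLoop`
#' bases between the arms (`j >= i + L + minLoop`).  Ties resolve to the
#' smallest i, then the smallest j.  Positions are 1-based within the
#' sequence.
#'
#' @param seq DNA string.
#' @param minLoop minimum loop length in nt.
#' @return named numeric `c(stem, loop, i, j)`; stem 0 (and NA positions)
#'   when no complementary pair exists.
#' @export
hairpinStem <- function(seq, minLoop = 3L) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < minLoop + 2L) stop("sequence shorter than minLoop + 2")
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")[b]   # N -> NA, never pairs
  best <- c(stem = 0, loop = NA_real_, i = NA_real_, j = NA_real_)
  for (i in 1:(n - minLoop - 1L)) {
    for (e in (i + minLoop + 1L):n) {
      cap <- (e - i + 1L - minLoop) %/% 2L
      L <- 0L
      while (L < cap) {
        ci <- comp[[i + L]]
        if (is.na(ci) || ci != b[e - L]) break
        L <- L + 1L
      }
      if (L > best[["stem"]]) {
        j <- e - L + 1L
        best <- c(stem = L, loop = j - (i + L), i = i, j = j)
      }
    }
  }
  best
}

#' Assign a repeat type from a consensus repeat
#'
#' Orients the consensus canonically, then applies the rules in precedence
#' order: a terminal rule fires when its motif matches the 3' end within the
#' tolerance and the consensus length falls in the rule's range; the E rule
#' fires on the internal palindrome (N wildcards).  With the default exact
#' matching the C and G motifs (one base apart) can never both fire; under
#' `fuzzy = TRUE` one motif mismatch is tolerated and competing rules are
#' resolved by fewest mismatches first, then precedence.  If no rule fires
#' the call is U.  The result is invariant under reverse complementation of
#' the input.
#'
#' @param consensus consensus repeat (23--55 nt).
#' @param rules rule set from [typeRules()].
#' @param fuzzy allow one mismatch inside the terminal motif.
#' @return a [RepeatTypeCall-class].
#' @export
assignType <- function(consensus, rules = typeRules(), fuzzy = FALSE) {
  consensus <- toupper(consensus)
  L <- nchar(consensus)
  if (L < 23L || L > 55L)
    stop("input error: consensus length must lie in [23, 55]")
  co <- canonicalOrientation(consensus, rules)
  s <- co$oriented
  tol <- if (isTRUE(fuzzy)) 1L else 0L
  hits <- list()
  for (r in rules) {
    if (L < r$lengthRange[1L] || L > r$lengthRange[2L]) next
    if (r$position == "terminal") {
      m <- .suffixMismatch(s, r$motif)
      if (m <= tol)
        hits[[length(hits) + 1L]] <- list(rule = r, mm = m)
    } else {
      pat <- gsub("N", ".", r$motif, fixed = TRUE)
      if (grepl(pat, s))
        hits[[length(hits) + 1L]] <- list(rule = r, mm = 0L)
    }
  }
  hp <- hairpinStem(s)
  if (!length(hits)) {
    return(new("RepeatTypeCall", label = "U", orientedConsensus = s,
               strandFlipped = co$flipped, matchedMotif = NA_character_,
               motifMismatches = NA_real_, hairpin = hp))
  }
  mms <- vapply(hits, `[[`, numeric(1), "mm")
  pick <- hits[[which(mms == min(mms))[1L]]]   # precedence = rule order
  new("RepeatTypeCall", label = pick$rule$label, orientedConsensus = s,
      strandFlipped = co$flipped, matchedMotif = pick$rule$motif,
      motifMismatches = pick$mm, hairpin = hp)
}

#' Type the consensus repeats of detected arrays
#'
#' Convenience wrapper: one [assignType()] call per array.
#'
#' @param arrays list of [CrisprArray-class].
#' @param rules,fuzzy passed to [assignType()].
#' @return named list of [RepeatTypeCall-class] keyed by array id.
#' @export
typeArrays <- function(arrays, rules = typeRules(), fuzzy = FALSE) {
  calls <- lapply(arrays, function(a)
    assignType(consensusRepeat(a), rules, fuzzy))
  names(calls) <- vapply(arrays, arrayId, character(1))
  calls
}

#' Set array orientation from typing calls
#'
#' Writes the motif strand back into each array: "+" when the forward
#' consensus already carried the motif, "-" when the canonical orientation
#' required a flip, "*" for U calls (lexicographic orientation carries no
#' strand information).
#'
#' @param arrays list of [CrisprArray-class].
#' @param calls named list from [typeArrays()].
#' @return the arrays with orientation slots updated.
#' @export
orientArrays <- function(arrays, calls) {
  lapply(arrays, function(a) {
    call <- calls[[arrayId(a)]]
    if (!is.null(call) && typeLabel(call) != "U")
      a@orientation <- if (call@strandFlipped) "-" else "+"
    a
  })
}

#' Single-linkage clustering of repeats
#'
#' Clusters strand-normalised repeats under ungapped identity at or above
#' `idThreshold`, anchored at the 3' (motif) end so repeats of slightly
#' different length align at their conserved tail.  Per cluster a majority
#' consensus and the conservation (mean member identity to the consensus)
#' are reported.
#'
#' @param repeats character vector of repeat sequences.
#' @param idThreshold single-linkage identity threshold.
#' @return list with `membership` (integer cluster per input) and `clusters`
#'   (list of `list(members, consensus, conservation, size)`).
#' @export
clusterRepeats <- function(repeats, idThreshold = 0.90) {
  stopifnot(length(repeats) > 0L)
  seqs <- vapply(repeats, function(r)
    canonicalOrientation(r)$oriented, character(1), USE.NAMES = FALSE)
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      if (seqIdentity(seqs[i], seqs[j], anchor = "right") >= idThreshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  membership <- as.integer(factor(roots, levels = unique(roots)))
  clusters <- lapply(seq_len(max(membership)), function(ci) {
    mem <- seqs[membership == ci]
    lens <- nchar(mem)
    tl <- table(lens)
    consLen <- max(as.integer(names(tl)[tl == max(tl)]))
    ## right-anchored columns; majority over covering members only
    mat <- do.call(rbind, lapply(mem, function(s) {
      c(rep(NA_character_, max(lens) - nchar(s)),
        strsplit(s, "", fixed = TRUE)[[1]])
    }))
    consFull <- apply(mat, 2L, function(col) {
      col <- col[!is.na(col)]
      if (!length(col)) return("N")
      tab <- table(col)
      sort(names(tab)[tab == max(tab)])[1L]
    })
    cons <- paste(utils::tail(consFull, consLen), collapse = "")
    conserv <- mean(vapply(mem, function(s)
      seqIdentity(s, cons, anchor = "right"), numeric(1)))
    list(members = mem, consensus = cons, conservation = conserv,
         size = length(mem))
  })
  list(membership = membership, clusters = clusters)
}
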