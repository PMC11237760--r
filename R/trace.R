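## Spacer-to-protospacer target tracing with the ungapped +1/-1 scoring used
## by the common CRISPR target finders: score = L - 2m for a spacer of
## length L matching a window with m mismatches, reported at or above a
## score threshold (default 20, so a spacer is reported iff
## m <= (L - 20) / 2).  Gapless by design: indel alignment would break the
## L - 2m bookkeeping and is the package's single largest simplification.

#' Tracer configuration
#'
#' @param matchReward,mismatchPenalty per-column scores (+1 / -1 defaults).
#' @param scoreThreshold minimum reported score.
#' @param maxMismatchesReport upper mismatch bound for reporting regardless
#'   of score.
#' @param flankLen flank length extracted on either side of a hit (8 nt, the
#'   window used for PAM prediction).
#' @param seedWord exact seed word length; the tracer shrinks the effective
#'   word to floor(L / (m_allowed + 1)) when that is smaller, which makes
#'   seeding complete at the threshold by the pigeonhole principle.
#' @return a list of class "traceConfig".
#' @export
traceConfig <- function(matchReward = 1L, mismatchPenalty = -1L,
                        scoreThreshold = 20L, maxMismatchesReport = 10L,
                        flankLen = 8L, seedWord = 11L) {
  stopifnot(scoreThreshold > 0L, flankLen >= 3L, seedWord >= 1L,
            matchReward > 0L, mismatchPenalty < matchReward)
  structure(list(matchReward = as.integer(matchReward),
                 mismatchPenalty = as.integer(mismatchPenalty),
                 scoreThreshold = as.integer(scoreThreshold),
                 maxMismatchesReport = as.integer(maxMismatchesReport),
                 flankLen = as.integer(flankLen),
                 seedWord = as.integer(seedWord)),
            class = "traceConfig")
}

## Largest mismatch count still meeting the score threshold for length L.
.mAllowed <- function(L, cfg) {
  m <- floor((L * cfg$matchReward - cfg$scoreThreshold) /
             (cfg$matchReward - cfg$mismatchPenalty))
  min(m, cfg$maxMismatchesReport)
}

#' Score one ungapped spacer/window pair
#'
#' @param spacer,subjectWindow equal-length sequences.
#' @param cfg a [traceConfig()].
#' @return named numeric `c(score, mismatches)`; mismatches is the Hamming
#'   distance (N counts as mismatch), score = (L-m)*reward + m*penalty.
#' @export
scoreHit <- function(spacer, subjectWindow, cfg = traceConfig()) {
  if (nchar(spacer) != nchar(subjectWindow))
    stop("input error: spacer and window must have equal length ",
         "(ungapped model)")
  L <- nchar(spacer)
  m <- hammingDist(spacer, subjectWindow)
  c(score = (L - m) * cfg$matchReward + m * cfg$mismatchPenalty,
    mismatches = m)
}

.emptyHits <- function() {
  data.frame(spacer_id = character(0), subject_id = character(0),
             start = numeric(0), end = numeric(0), strand = character(0),
             mismatches = numeric(0), score = numeric(0),
             protospacer = character(0), flank5 = character(0),
             flank3 = character(0), stringsAsFactors = FALSE)
}

## Assemble hit rows for candidate 1-based window starts on one subject
## strand, computing flanks in protospacer orientation.
.hitRows <- function(spacerId, pattern, subjId, subj, cand, strand, L, cfg) {
  n <- nchar(subj)
  mm <- vapply(cand, function(s)
    hammingDist(substring(subj, s, s + L - 1L), pattern), numeric(1))
  keep <- mm <= .mAllowed(L, cfg)
  cand <- cand[keep]; mm <- mm[keep]
  if (!length(cand)) return(.emptyHits())
  fl <- cfg$flankLen
  window <- substring(subj, cand, cand + L - 1L)
  left <- ifelse(cand - fl >= 1L,
                 substring(subj, cand - fl, cand - 1L), NA_character_)
  right <- ifelse(cand + L - 1L + fl <= n,
                  substring(subj, cand + L, cand + L - 1L + fl),
                  NA_character_)
  if (strand == "+") {
    proto <- window; f5 <- left; f3 <- right
  } else {
    proto <- revComp(window)
    f5 <- ifelse(is.na(right), NA_character_, revComp(right))
    f3 <- ifelse(is.na(left), NA_character_, revComp(left))
  }
  data.frame(spacer_id = spacerId, subject_id = subjId,
             start = cand - 1L, end = cand - 1L + L, strand = strand,
             mismatches = mm,
             score = (L - mm) * cfg$matchReward + mm * cfg$mismatchPenalty,
             protospacer = proto, flank5 = f5, flank3 = f3,
             stringsAsFactors = FALSE)
}

.sortHits <- function(hits) {
  hits <- hits[order(-hits$score, hits$subject_id, hits$start,
                     hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Trace a spacer against a subject database
#'
#' Seeded ungapped search: candidate windows share an exact seed word with
#' the spacer and are verified by Hamming distance; both subject strands are
#' scanned and every window meeting the score threshold is reported with its
#' 8-nt flanks in protospacer orientation.  Subject coordinates are 0-based
#' half-open on the forward strand.
#'
#' @param spacer a single spacer sequence.
#' @param subjects subject database: DNAStringSet or named character vector.
#' @param cfg a [traceConfig()].
#' @param spacerId id carried into the hit table.
#' @return hit data.frame sorted by score descending then subject position:
#'   spacer_id, subject_id, start, end, strand, mismatches, score,
#'   protospacer, flank5, flank3 (flanks NA when the subject ends within
#'   flank reach).
#' @export
traceSpacer <- function(spacer, subjects, cfg = traceConfig(),
                        spacerId = "spacer") {
  spacer <- toupper(spacer)
  L <- nchar(spacer)
  if (L < cfg$seedWord)
    stop("input error: spacer shorter than the seed word")
  mAll <- .mAllowed(L, cfg)
  if (mAll < 0L) return(.emptyHits())
  w <- min(cfg$seedWord, max(1L, L %/% (mAll + 1L)))
  if (methods::is(subjects, "XStringSet")) {
    nms <- names(subjects)
    subjects <- as.character(subjects)
    names(subjects) <- nms
  }
  if (is.null(names(subjects)))
    names(subjects) <- sprintf("subject%d", seq_along(subjects))
  out <- list()
  for (si in seq_along(subjects)) {
    subj <- toupper(subjects[[si]])
    n <- nchar(subj)
    if (n < L) next
    subjDna <- Biostrings::DNAString(subj)
    for (strand in c("+", "-")) {
      pattern <- if (strand == "+") spacer else revComp(spacer)
      cand <- integer(0)
      for (off in 0:(L - w)) {
        word <- substr(pattern, off + 1L, off + w)
        if (grepl("[^ACGT]", word)) next
        mp <- Biostrings::matchPattern(word, subjDna)
        if (length(mp))
          cand <- c(cand, BiocGenerics::start(mp) - off)
      }
      cand <- sort(unique(cand))
      cand <- cand[cand >= 1L & cand + L - 1L <= n]
      if (!length(cand)) next
      out[[length(out) + 1L]] <-
        .hitRows(spacerId, pattern, names(subjects)[si], subj, cand,
                 strand, L, cfg)
    }
  }
  if (!length(out)) return(.emptyHits())
  .sortHits(do.call(rbind, out))
}

#' Exhaustive tracing oracle
#'
#' Scans every window on both strands of the subject(s) -- no seeding --
#' with the same reporting contract as [traceSpacer()].  Intended as the
#' testing oracle for the seeded tracer; on every tested instance the two
#' must agree exactly.
#'
#' @inheritParams traceSpacer
#' @return hit data.frame, same contract as [traceSpacer()].
#' @export
bruteForceTrace <- function(spacer, subjects, cfg = traceConfig(),
                            spacerId = "spacer") {
  spacer <- toupper(spacer)
  L <- nchar(spacer)
  mAll <- .mAllowed(L, cfg)
  if (mAll < 0L) return(.emptyHits())
  if (methods::is(subjects, "XStringSet")) {
    nms <- names(subjects)
    subjects <- as.character(subjects)
    names(subjects) <- nms
  }
  if (is.null(names(subjects)))
    names(subjects) <- sprintf("subject%d", seq_along(subjects))
  nraw <- charToRaw("N")
  out <- list()
  for (si in seq_along(subjects)) {
    subj <- toupper(subjects[[si]])
    n <- nchar(subj)
    if (n < L) next
    sraw <- charToRaw(subj)
    nWin <- n - L + 1L
    for (strand in c("+", "-")) {
      pattern <- if (strand == "+") spacer else revComp(spacer)
      praw <- charToRaw(pattern)
      mm <- integer(nWin)
      for (d in seq_len(L)) {
        sv <- sraw[d:(nWin + d - 1L)]
        mm <- mm + as.integer(sv != praw[d] |
                              (sv == nraw & praw[d] == nraw))
      }
      cand <- which(mm <= mAll)
      if (!length(cand)) next
      out[[length(out) + 1L]] <-
        .hitRows(spacerId, pattern, names(subjects)[si], subj, cand,
                 strand, L, cfg)
    }
  }
  if (!length(out)) return(.emptyHits())
  .sortHits(do.call(rbind, out))
}

#' Extract flanks for one hit
#'
#' `flank5` is the `flankLen` bases immediately 5' of the protospacer in
#' protospacer orientation (reverse-complemented for minus-strand hits);
#' NA when fewer than `flankLen` bases exist on that side of the subject.
#'
#' @param hit one-row hit data.frame (needs start, end, strand).
#' @param subject the subject sequence the hit lies on.
#' @param flankLen flank length in nt.
#' @return `list(flank5 =, flank3 =)`.
#' @export
extractFlanks <- function(hit, subject, flankLen = 8L) {
  subj <- toupper(as.character(subject))
  n <- nchar(subj)
  s1 <- hit$start + 1L                        # 1-based
  e1 <- hit$end                               # inclusive end
  left <- if (s1 - flankLen >= 1L)
    substring(subj, s1 - flankLen, s1 - 1L) else NA_character_
  right <- if (e1 + flankLen <= n)
    substring(subj, e1 + 1L, e1 + flankLen) else NA_character_
  if (hit$strand == "+") {
    list(flank5 = left, flank3 = right)
  } else {
    list(flank5 = if (is.na(right)) NA_character_ else revComp(right),
         flank3 = if (is.na(left)) NA_character_ else revComp(left))
  }
}

#' Collapse hits to non-redundant targets
#'
#' Targets are identical when their (protospacer sequence, flank5, flank3)
#' tuples coincide; the lowest-mismatch representative is kept, ties broken
#' by subject id then position.
#'
#' @param hits hit data.frame (possibly from several spacers/subjects).
#' @return the non-redundant hit data.frame.
#' @export
dedupeTargets <- function(hits) {
  if (!nrow(hits)) return(hits)
  key <- paste(hits$protospacer,
               ifelse(is.na(hits$flank5), "<na>", hits$flank5),
               ifelse(is.na(hits$flank3), "<na>", hits$flank3), sep = "|")
  o <- order(key, hits$mismatches, hits$subject_id, hits$start)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(key[o]), , drop = FALSE]
  .sortHits(hits)
}

#' Flag hits that fall inside detected CRISPR loci
#'
#' Self-matched targets (a spacer matching a CRISPR array itself, typically
#' when the subject database contains the host genomes) are kept but
#' flagged.
#'
#' @param hits hit data.frame.
#' @param arrays list of [CrisprArray-class] detected on the subjects.
#' @return hits with a logical `self_hit` column.
#' @export
flagSelfHits <- function(hits, arrays) {
  if (!nrow(hits)) { hits$self_hit <- logical(0); return(hits) }
  hits$self_hit <- vapply(seq_len(nrow(hits)), function(i) {
    any(vapply(arrays, function(a) {
      contigId(a) == hits$subject_id[i] &&
        hits$start[i] < arrayEnd(a) && hits$end[i] > arrayStart(a)
    }, logical(1)))
  }, logical(1))
  hits
}

#' Trace a whole spacer catalogue
#'
#' @param records spacer data.frame from [extractSpacers()] (deduplicated or
#'   not); one [traceSpacer()] call per record.
#' @param subjects subject database.
#' @param cfg a [traceConfig()].
#' @return combined hit data.frame.
#' @export
traceSpacers <- function(records, subjects, cfg = traceConfig()) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    traceSpacer(records$sequence[i], subjects, cfg,
                spacerId = records$spacer_id[i])
  })
  res <- do.call(rbind, c(list(.emptyHits()), out))
  rownames(res) <- NULL
  res
}
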