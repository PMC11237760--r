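## Independent oracles and small fixture builders used across the suite.
## Oracles deliberately re-derive results by brute force, sharing no code
## with the implementation paths they check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rndDna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rndProt <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

rcOracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

## Exhaustive hairpin search over every (L, i, j) triple.
hairpinOracle <- function(s, minLoop = 3L) {
  s <- toupper(s)
  n <- nchar(s)
  for (L in rev(seq_len(n %/% 2))) {
    for (i in 1:(n - L + 1L)) {
      jmin <- i + L + minLoop
      if (jmin > n - L + 1L) next
      for (j in jmin:(n - L + 1L)) {
        if (substr(s, i, i + L - 1L) == rcOracle(substr(s, j, j + L - 1L)))
          return(c(stem = L, loop = j - i - L, i = i, j = j))
      }
    }
  }
  c(stem = 0, loop = NA_real_, i = NA_real_, j = NA_real_)
}

## Gotoh local-alignment score under BLOSUM62 / affine gaps; independent
## quadratic DP used as the alignment oracle.
swScoreOracle <- function(a, b, open = 11, ext = 1) {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(-Inf, n + 1L, m + 1L)
  Y <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2:(n + 1L)) for (j in 2:(m + 1L)) {
    X[i, j] <- max(M[i - 1L, j] - open - ext, X[i - 1L, j] - ext)
    Y[i, j] <- max(M[i, j - 1L] - open - ext, Y[i, j - 1L] - ext)
    M[i, j] <- max(0, BLOSUM62[A[i - 1L], B[j - 1L]] +
                     max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                         Y[i - 1L, j - 1L]))
    best <- max(best, M[i, j], X[i, j], Y[i, j])
  }
  best
}

## Right-anchored ungapped identity, re-derived for the clustering oracle.
identOracle <- function(a, b) {
  la <- nchar(a); lb <- nchar(b); L <- min(la, lb)
  aa <- strsplit(substr(a, la - L + 1L, la), "")[[1]]
  bb <- strsplit(substr(b, lb - L + 1L, lb), "")[[1]]
  sum(aa == bb) / max(la, lb)
}

## Connected components of the >=threshold identity graph (BFS), the
## single-linkage clustering oracle.
clusterOracle <- function(seqs, thr = 0.90) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- identOracle(seqs[i], seqs[j]) >= thr
  }
  comp <- rep(NA_integer_, n); cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

## Convenience: a small host genome config with given specs.
hostConfig <- function(seed, specs, genomeLength = 30000L, ...) {
  simConfig(seed = seed, genomeLength = genomeLength, arraySpecs = specs,
            ...)
}

## Spacer id/sequence vector from a truth table (thin alias over the
## package accessor, kept for test readability).
truthSpacerVec <- function(truth) truthSpacers(truth)

## Per-array truth unit coordinate lists.
truthUnits <- function(truthRow) {
  list(starts = as.numeric(strsplit(truthRow$unit_starts, ",")[[1]]),
       ends = as.numeric(strsplit(truthRow$unit_ends, ",")[[1]]))
}

## Random synthetic gene table for the context module (proteins attached).
geneTable <- function(contig, prots, startAt = 0L, gap = 300L,
                      geneLen = 1200L, idPrefix = contig) {
  n <- length(prots)
  starts <- startAt + (geneLen + gap) * (seq_len(n) - 1L)
  data.frame(gene_id = sprintf("%s_g%d", idPrefix, seq_len(n)),
             contig_id = contig, start = starts, end = starts + geneLen,
             strand = "+", protein = prots, stringsAsFactors = FALSE)
}
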