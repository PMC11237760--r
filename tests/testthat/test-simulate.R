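test_that("equal seeds give byte-identical genomes, elements and truth", {
  cfg <- hostConfig(1L, list(arraySpec("C", nUnits = 5),
                             arraySpec("G", nUnits = 4)),
                    nProtospacers = 4L, plantedMismatches = 1L)
  a <- generateHostGenome(cfg)
  b <- generateHostGenome(cfg)
  expect_identical(as.character(a$seq), as.character(b$seq))
  expect_identical(truthArrays(a$truth), truthArrays(b$truth))
  sp <- truthSpacerVec(a$truth)
  ma <- generateMge(cfg, sp)
  mb <- generateMge(cfg, sp)
  expect_identical(as.character(ma$seq), as.character(mb$seq))
  expect_identical(truthProtospacers(ma$truth), truthProtospacers(mb$truth))
  ## FASTA bytes, not just in-memory strings
  fa <- tempfile(fileext = ".fasta"); fb <- tempfile(fileext = ".fasta")
  writeGenomeFasta(a$seq, fa); writeGenomeFasta(b$seq, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("planted arrays carry the type template, motif and spacer count", {
  cfg <- hostConfig(7L, list(arraySpec("C", nUnits = 5),
                             arraySpec("C", nUnits = 5),
                             arraySpec("C", nUnits = 5)),
                    genomeLength = 20000L)
  host <- generateHostGenome(cfg)
  tr <- truthArrays(host$truth)
  expect_equal(nrow(tr), 3L)
  expect_true(all(endsWith(tr$repeat_template, "TTGAAAC")))
  ## nUnits = 5 -> exactly 4 spacers per array
  expect_true(all(lengths(strsplit(tr$spacer_seqs, ",")) == 4L))
  ## truth fidelity: re-measure units and spacers from the emitted sequence
  g <- as.character(host$seq)[[1]]
  for (r in seq_len(nrow(tr))) {
    u <- truthUnits(tr[r, ])
    reps <- substring(g, u$starts + 1L, u$ends)
    expect_identical(unique(reps), tr$repeat_template[r])  # subRate = 0
    gaps <- substring(g, u$ends[-length(u$ends)] + 1L, u$starts[-1L])
    expect_identical(gaps, strsplit(tr$spacer_seqs[r], ",")[[1]])
  }
})

test_that("repeat mutation respects rate and motif protection", {
  cfg <- hostConfig(13L, list(arraySpec("B", nUnits = 30, subRate = 0.05)),
                    genomeLength = 20000L)
  host <- generateHostGenome(cfg)
  tr <- truthArrays(host$truth)
  g <- as.character(host$seq)[[1]]
  u <- truthUnits(tr[1, ])
  reps <- substring(g, u$starts + 1L, u$ends)
  tpl <- tr$repeat_template[1]
  L <- nchar(tpl)
  ## last 8 nt (motif window) untouched in every copy
  expect_true(all(substr(reps, L - 7L, L) == substr(tpl, L - 7L, L)))
  mm <- vapply(reps, hammingDist, numeric(1), b = tpl)
  ## 30 copies x 28 mutable positions at 5%: mean within a loose band
  expect_gt(mean(mm), 0.4)
  expect_lt(mean(mm), 3.5)
})

test_that("planted protospacers honour mismatch count, strand and PAM", {
  for (m in c(0L, 2L)) {
    cfg <- hostConfig(21L + m, list(arraySpec("C", nUnits = 12)),
                      nProtospacers = 8L, plantedMismatches = m,
                      pam = "TTC")
    host <- generateHostGenome(cfg)
    mge <- generateMge(cfg, truthSpacerVec(host$truth))
    pt <- truthProtospacers(mge$truth)
    el <- as.character(mge$seq)[[1]]
    expect_equal(nrow(pt), 8L)
    for (i in seq_len(nrow(pt))) {
      w <- substr(el, pt$start[i] + 1L, pt$end[i])
      proto <- if (pt$strand[i] == "+") w else revComp(w)
      expect_equal(unname(hammingDist(proto, pt$spacer_seq[i])), m)
      ## PAM: 3 nt immediately 5' of the protospacer on its own strand
      pam <- if (pt$strand[i] == "+") {
        substr(el, pt$start[i] - 2L, pt$start[i])
      } else {
        revComp(substr(el, pt$end[i] + 1L, pt$end[i] + 3L))
      }
      expect_identical(unname(pam), "TTC")
    }
  }
})

test_that("mismatched protospacers cannot exceed the spacer length", {
  cfg <- hostConfig(3L, list(arraySpec("C", nUnits = 4)))
  sp <- c(s1 = "ACGTACGTAC")
  cfg$plantedMismatches <- 10L
  expect_error(generateMge(cfg, sp), "smaller than every spacer length")
})

test_that("fragmentation partitions the sequence and remaps truth", {
  cfg <- hostConfig(31L, list(arraySpec("C", nUnits = 6),
                              arraySpec("G", nUnits = 6)),
                    genomeLength = 24000L,
                    fragmentation = list(nContigs = 1L, minContig = 500L))
  host <- generateHostGenome(cfg)
  ## nContigs = 1: identity, no renaming, no truncation flags
  id <- fragmentAssembly(host$seq, host$truth, cfg)
  expect_identical(as.character(id$seq), as.character(host$seq))
  expect_false(any(truthArrays(id$truth)$truncated))

  ## conservation of bases for several random seeds
  for (s in c(31L, 32L, 33L)) {
    cfg$seed <- s
    cfg$fragmentation <- list(nContigs = 4L, minContig = 1000L)
    fr <- fragmentAssembly(host$seq, host$truth, cfg)
    expect_equal(sum(nchar(as.character(fr$seq))),
                 nchar(as.character(host$seq)[[1]]))
    expect_identical(paste(as.character(fr$seq), collapse = ""),
                     as.character(host$seq)[[1]])
  }

  ## a forced breakpoint at an array midpoint flags truncation
  tr <- truthArrays(host$truth)
  mid <- floor((tr$start[1] + tr$end[1]) / 2)
  fr <- fragmentAssembly(host$seq, host$truth, cfg, breakpoints = mid)
  fa <- truthArrays(fr$truth)
  pieces <- fa[fa$array_id == tr$array_id[1], , drop = FALSE]
  expect_gte(nrow(pieces), 1L)
  expect_true(all(pieces$truncated))
  ## untouched array not flagged
  other <- fa[fa$array_id == tr$array_id[2], , drop = FALSE]
  expect_false(any(other$truncated))
  ## remapped units still carry the template (re-measure from contigs)
  ctg <- as.character(fr$seq)
  for (r in seq_len(nrow(fa))) {
    u <- truthUnits(fa[r, ])
    reps <- substring(ctg[[fa$contig_id[r]]], u$starts + 1L, u$ends)
    expect_true(all(reps == fa$repeat_template[r]))
  }
})

test_that("impossible fragmentation or placement is a configuration error", {
  cfg <- hostConfig(2L, list(arraySpec("C", nUnits = 4)),
                    genomeLength = 5000L,
                    fragmentation = list(nContigs = 10L, minContig = 1000L))
  host <- generateHostGenome(cfg)
  expect_error(fragmentAssembly(host$seq, host$truth, cfg),
               "configuration error")
  cramped <- hostConfig(2L, list(arraySpec("C", nUnits = 40),
                                 arraySpec("C", nUnits = 40)),
                        genomeLength = 4000L)
  expect_error(generateHostGenome(cramped), "placement error")
})

test_that("truth tables round-trip through TSV", {
  cfg <- hostConfig(5L, list(arraySpec("E", nUnits = 5)),
                    nProtospacers = 3L)
  host <- generateHostGenome(cfg)
  mge <- generateMge(cfg, truthSpacerVec(host$truth))
  truth <- TruthTable(arrays = truthArrays(host$truth),
                      protospacers = truthProtospacers(mge$truth))
  fa <- tempfile(fileext = ".tsv"); fp <- tempfile(fileext = ".tsv")
  writeTruthTable(truth, fa, fp)
  back <- readTruthTable(fa, fp)
  expect_identical(truthArrays(back), truthArrays(truth))
  expect_identical(truthProtospacers(back), truthProtospacers(truth))
})
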