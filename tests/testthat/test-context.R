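test_that("flank gene extraction respects window, order and contig ends", {
  set.seed(157)
  prots <- vapply(1:24, function(i) rndProt(120L), character(1))
  ann <- geneTable("ctg1", prots)
  locus <- c(ann$end[12] + 10, ann$start[13] - 10)   # between genes 12/13
  fl <- extractFlankGenes(ann, "ctg1", locus[1], locus[2], w = 10L)
  expect_equal(nrow(fl$upstream), 10L)
  expect_equal(nrow(fl$downstream), 10L)
  expect_identical(fl$upstream$gene_id, ann$gene_id[3:12])
  expect_identical(fl$downstream$gene_id, ann$gene_id[13:22])
  expect_false(fl$truncatedUpstream)
  ## three genes from the contig end: 3 downstream, truncation flagged
  locus2 <- c(ann$end[21] + 10, ann$start[22] - 10)
  fl2 <- extractFlankGenes(ann, "ctg1", locus2[1], locus2[2], w = 10L)
  expect_equal(nrow(fl2$downstream), 3L)
  expect_true(fl2$truncatedDownstream)
  ## w = 0 gives empty libraries; unknown contig is an input error
  fl0 <- extractFlankGenes(ann, "ctg1", locus[1], locus[2], w = 0L)
  expect_equal(nrow(fl0$upstream) + nrow(fl0$downstream), 0L)
  expect_error(extractFlankGenes(ann, "nope", 0, 1), "input error")
})

test_that("protein alignment matches the quadratic DP oracle", {
  set.seed(2)
  p <- rndProt(100L)
  al <- alignProteins(p, p)
  expect_equal(al$pident, 100)
  expect_equal(al$coverage, 1.0)
  ## constructed pair: 30 substitutions spread along the backbone give a
  ## full-length local alignment at exactly 70% identity
  qs <- strsplit(p, "")[[1]]
  pos <- seq(10, by = 3, length.out = 30)
  for (i in pos) qs[i] <- sample(setdiff(AA20, qs[i]), 1)
  q <- paste(qs, collapse = "")
  al2 <- alignProteins(p, q)
  expect_equal(al2$pident, 70)
  expect_equal(al2$coverage, 1.0)
  expect_equal(al2$score, swScoreOracle(p, q))
  ## unrelated random proteins fail the pident >= 70 filter
  set.seed(163)
  for (i in 1:3) {
    r <- alignProteins(rndProt(100L), rndProt(100L))
    expect_lt(r$pident * (r$coverage >= 0.5), 70)
  }
  ## score equality with the oracle across random pairs
  for (i in 1:5) {
    a <- rndProt(sample(60:140, 1)); b <- rndProt(sample(60:140, 1))
    expect_equal(alignProteins(a, b)$score, swScoreOracle(a, b))
  }
  expect_error(alignProteins("ACDE1", "ACDE"), "input error")
})

test_that("context comparison passes identity and flags missing genes", {
  set.seed(167)
  prots <- vapply(1:12, function(i) rndProt(110L), character(1))
  ref <- geneTable("ref", prots)
  fl <- extractFlankGenes(ref, "ref", ref$end[6] + 5, ref$start[7] - 5,
                          w = 4L)
  lib <- rbind(fl$upstream, fl$downstream)
  ## genome vs itself: every anchor matched at pident 100, all passed
  m <- compareContexts(lib, ref)
  expect_true(all(m$passed))
  expect_true(all(m$pident == 100))
  expect_identical(m$query_gene_id, lib$gene_id)
  ## query lacking two anchor genes: those anchors fail, others pass
  query <- ref[!ref$gene_id %in% lib$gene_id[c(2, 6)], , drop = FALSE]
  m2 <- compareContexts(lib, query)
  expect_true(all(m2$passed[!m2$ref_gene_id %in% lib$gene_id[c(2, 6)]]))
  expect_false(any(m2$passed[m2$ref_gene_id %in% lib$gene_id[c(2, 6)]]))
  ## empty query: nothing passes
  m3 <- compareContexts(lib, ref[0, , drop = FALSE])
  expect_false(any(m3$passed))
  expect_true(all(is.na(m3$query_gene_id)))
})

test_that("locus states move present -> absent_with_context -> unresolved", {
  set.seed(173)
  prots <- vapply(1:14, function(i) rndProt(110L), character(1))
  ref <- geneTable("ref", prots)
  locus <- c(ref$end[7] + 50, ref$end[7] + 650)   # between genes 7 and 8
  fl <- extractFlankGenes(ref, "ref", locus[1], locus[2], w = 4L)
  lib <- rbind(fl$upstream, fl$downstream)
  loci <- data.frame(contig_id = "ref", start = locus[1], end = locus[2])

  ## intact query with the locus present
  m <- compareContexts(lib, ref)
  expect_identical(inferLocusState(m, loci), "present")
  ## locus excised (coordinates shifted, no locus between the flanks)
  m2 <- compareContexts(lib, ref)
  expect_identical(inferLocusState(m2, list()), "absent_with_context")
  ## flanks split over two contigs: unresolved
  qSplit <- ref
  qSplit$contig_id <- ifelse(qSplit$start < locus[1], "ctgA", "ctgB")
  m3 <- compareContexts(lib, qSplit)
  expect_identical(inferLocusState(m3, loci), "unresolved")
  ## too few passing anchors: unresolved
  m4 <- m
  upIdx <- which(m4$side == "upstream")
  m4$passed[upIdx[-(1:2)]] <- FALSE
  expect_identical(inferLocusState(m4, loci), "unresolved")

  ## invariance: contig renamed/reordered and strand flipped coordinates
  n <- 20000L
  qFlip <- ref
  qFlip$contig_id <- "flipped"
  tmp <- n - qFlip$end
  qFlip$end <- n - qFlip$start
  qFlip$start <- tmp
  qFlip$protein <- ref$protein
  lociFlip <- data.frame(contig_id = "flipped",
                         start = n - locus[2], end = n - locus[1])
  m5 <- compareContexts(lib, qFlip)
  expect_identical(inferLocusState(m5, lociFlip), "present")
})

test_that("annotations round-trip through GFF3 + protein FASTA", {
  set.seed(179)
  prots <- vapply(1:6, function(i) rndProt(90L), character(1))
  ann <- geneTable("ctgZ", prots)
  gff <- tempfile(fileext = ".gff3")
  faa <- tempfile(fileext = ".faa")
  gr <- GenomicRanges::GRanges("ctgZ",
          IRanges::IRanges(ann$start + 1L, ann$end), strand = ann$strand)
  gr$type <- "CDS"
  gr$ID <- ann$gene_id
  gr$phase <- 0L
  rtracklayer::export(gr, gff, format = "gff3")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(ann$protein, ann$gene_id)), faa)
  back <- readGeneAnnotation(gff, faa)
  expect_identical(back$gene_id, ann$gene_id)
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_identical(back$protein, ann$protein)
})
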