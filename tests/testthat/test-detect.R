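test_that("homopolymer and motif-free sequences yield no seed chains", {
  expect_identical(findSeedRepeats(strrep("A", 2000L)), list())
  ## low-complexity guard: a 2-letter word repeating at array spacing
  lc <- paste0(strrep("AT", 200L))
  expect_identical(findSeedRepeats(lc), list())
  set.seed(11)
  expect_identical(findSeedRepeats(rndDna(3000L)), list())
})

test_that("a planted 4-copy repeat yields one chain, strand-agnostically", {
  set.seed(5)
  rep37 <- rndDna(37L)
  contig <- paste0(rndDna(200L), rep37, rndDna(34L), rep37, rndDna(34L),
                   rep37, rndDna(34L), rep37, rndDna(200L))
  ch <- findSeedRepeats(contig)
  expect_length(ch, 1L)
  expect_length(ch[[1]]$starts, 4L)
  ## reverse-complemented contig: same single 4-seed chain, mirrored span
  rc <- revComp(contig)
  ch2 <- findSeedRepeats(rc)
  expect_length(ch2, 1L)
  expect_length(ch2[[1]]$starts, 4L)
  n <- nchar(contig); k <- nchar(ch[[1]]$kmer)
  span <- c(ch[[1]]$starts[1], ch[[1]]$starts[4] + k)
  span2 <- c(ch2[[1]]$starts[1], ch2[[1]]$starts[4] + k)
  ## array span is mirrored within the repeat region
  arr1 <- filterArrays(buildArrays(ch, contig), scanConfig())
  arr2 <- filterArrays(buildArrays(ch2, rc), scanConfig())
  expect_length(arr1, 1L)
  expect_length(arr2, 1L)
  expect_equal(arrayStart(arr2[[1]]), n - arrayEnd(arr1[[1]]))
  expect_equal(arrayEnd(arr2[[1]]), n - arrayStart(arr1[[1]]))
  expect_identical(sort(repeatSeqs(arr2[[1]])),
                   sort(revComp(repeatSeqs(arr1[[1]]))))
})

test_that("planted arrays are recovered with exact unit coordinates", {
  cfg <- hostConfig(42L, list(arraySpec("C", nUnits = 5),
                              arraySpec("B", nUnits = 6),
                              arraySpec("G", nUnits = 10, subRate = 0.02)))
  host <- generateHostGenome(cfg)
  arrays <- detectArrays(host$seq)
  tr <- truthArrays(host$truth)
  tr <- tr[order(tr$start), , drop = FALSE]
  expect_length(arrays, nrow(tr))
  for (i in seq_along(arrays)) {
    u <- truthUnits(tr[i, ])
    expect_equal(unitStarts(arrays[[i]]), u$starts)
    expect_equal(unitEnds(arrays[[i]]), u$ends)
    ## spacer count invariant and truth spacers recovered verbatim
    expect_length(spacerSeqs(arrays[[i]]), nUnits(arrays[[i]]) - 1L)
    expect_identical(spacerSeqs(arrays[[i]]),
                     strsplit(tr$spacer_seqs[i], ",")[[1]])
  }
  ## consensus of the 2%-mutated array equals the unmutated template
  gi <- which(tr$repeat_type == "G")
  expect_identical(consensusRepeat(arrays[[gi]]), tr$repeat_template[gi])
})

test_that("confidence filters drop short, tandem and degraded candidates", {
  set.seed(23)
  cfgS <- scanConfig()
  ## 2- and 3-unit arrays are built but filtered at minUnits = 4
  rep37 <- rndDna(37L)
  for (copies in c(2L, 3L)) {
    sp <- replicate(copies - 1L, rndDna(34L))
    contig <- paste0(rndDna(300L),
                     paste(c(rbind(rep(rep37, copies),
                                   c(sp, "")))[seq_len(2L * copies - 1L)],
                           collapse = ""),
                     rndDna(300L))
    built <- buildArrays(findSeedRepeats(contig, cfgS), contig, cfgS)
    expect_gte(length(built), 1L)
    expect_identical(filterArrays(built, cfgS), list())
    if (copies == 3L) {
      ## retained under the permissive tier
      expect_length(filterArrays(built, scanConfig(permissive = TRUE)), 1L)
    }
  }
  ## tandem repeat: identical "spacers" trip the spacer-identity rule
  spacer <- rndDna(34L)
  tandem <- paste0(rndDna(300L),
                   paste(rep(paste0(rep37, spacer), 5L), collapse = ""),
                   rep37, rndDna(300L))
  built <- buildArrays(findSeedRepeats(tandem, cfgS), tandem, cfgS)
  expect_gte(length(built), 1L)
  expect_identical(filterArrays(built, cfgS), list())
  ## a clean 5-unit array with dissimilar spacers and high conservation stays
  cfg <- hostConfig(77L, list(arraySpec("C", nUnits = 5, subRate = 0.01)))
  host <- generateHostGenome(cfg)
  arrays <- detectArrays(host$seq)
  expect_length(arrays, 1L)
  expect_gte(conservation(arrays[[1]]), 0.95)
})

test_that("detection is empty on array-free contigs and errors on empty input", {
  set.seed(9)
  bg <- rndDna(20000L, gc = 0.69)
  expect_identical(detectArrays(c(bare = bg)), list())
  expect_error(detectArrays(Biostrings::DNAStringSet()), "input error")
})

test_that("arrays split across contigs surface only as flagged fragments", {
  cfg <- hostConfig(55L, list(arraySpec("C", nUnits = 8),
                              arraySpec("G", nUnits = 8)),
                    genomeLength = 24000L)
  host <- generateHostGenome(cfg)
  tr <- truthArrays(host$truth)
  tr <- tr[order(tr$start), , drop = FALSE]
  u <- truthUnits(tr[1, ])
  mid <- floor((u$starts[4] + u$ends[4]) / 2)    # cut inside unit 4
  fr <- fragmentAssembly(host$seq, host$truth, cfg, breakpoints = mid)
  arrays <- detectArrays(fr$seq)
  fa <- truthArrays(fr$truth)
  for (a in arrays) {
    hit <- fa[fa$contig_id == contigId(a) &
              fa$start < arrayEnd(a) & fa$end > arrayStart(a), ,
              drop = FALSE]
    expect_equal(nrow(hit), 1L)
    if (hit$truncated) expect_true(truncated(a))
    ## no fragment pretends to span the breakpoint
    expect_lte(nUnits(a), length(truthUnits(hit)$starts))
  }
})

test_that("output is ordered and independent of contig input order", {
  cfg1 <- hostConfig(61L, list(arraySpec("C", nUnits = 5)),
                     genomeLength = 15000L, contigId = "ctgA")
  cfg2 <- hostConfig(62L, list(arraySpec("G", nUnits = 5)),
                     genomeLength = 15000L, contigId = "ctgB")
  h1 <- generateHostGenome(cfg1)
  h2 <- generateHostGenome(cfg2)
  fwd <- c(as.character(h1$seq), as.character(h2$seq))
  revd <- fwd[c(2L, 1L)]
  t1 <- arrayTable(detectArrays(fwd))
  t2 <- arrayTable(detectArrays(revd))
  expect_identical(t1, t2)
  expect_identical(t1$contig_id, sort(t1$contig_id))
})
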