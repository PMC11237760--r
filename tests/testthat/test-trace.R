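test_that("ungapped scoring follows L - 2m and the threshold boundary", {
  set.seed(101)
  sp20 <- rndDna(20L)
  expect_equal(scoreHit(sp20, sp20), c(score = 20, mismatches = 0))
  mutate <- function(s, m) {
    ch <- strsplit(s, "")[[1]]
    for (p in sample(length(ch), m))
      ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  sp36 <- rndDna(36L)
  expect_equal(unname(scoreHit(sp36, mutate(sp36, 8L))["score"]), 20)
  sp34 <- rndDna(34L)
  expect_equal(unname(scoreHit(sp34, mutate(sp34, 8L))["score"]), 18)
  expect_error(scoreHit("ACGT", "ACGTA"), "input error")

  ## threshold: a 36-mer with 8 mismatches is reported, a 34-mer is not
  bg <- rndDna(5000L)
  subj <- c(db = paste0(substr(bg, 1, 2000),
                        mutate(sp36, 8L), mutate(sp34, 8L),
                        substr(bg, 2001, 5000)))
  expect_equal(nrow(traceSpacer(sp36, subj)), 1L)
  expect_equal(nrow(traceSpacer(sp34, subj)), 0L)
})

test_that("planted protospacers are traced with exact coordinates and strand", {
  cfg <- hostConfig(103L, list(arraySpec("C", nUnits = 10)),
                    nProtospacers = 6L, plantedMismatches = 0L,
                    pam = "TTC")
  host <- generateHostGenome(cfg)
  sp <- truthSpacerVec(host$truth)
  mge <- generateMge(cfg, sp)
  pt <- truthProtospacers(mge$truth)
  for (i in seq_len(nrow(pt))) {
    hits <- traceSpacer(sp[[pt$spacer_id[i]]], mge$seq,
                        spacerId = pt$spacer_id[i])
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$start, pt$start[i])
    expect_equal(hits$end, pt$end[i])
    expect_identical(hits$strand, pt$strand[i])
    expect_equal(hits$mismatches, 0)
    ## the planted PAM is the last 3 nt of the 5' flank, whatever the strand
    expect_identical(substr(hits$flank5, 6L, 8L), "TTC")
    ## score bookkeeping
    expect_equal(hits$score, nchar(sp[[pt$spacer_id[i]]]) -
                   2 * hits$mismatches)
  }
  ## an absent spacer finds nothing
  set.seed(104)
  expect_equal(nrow(traceSpacer(rndDna(34L), mge$seq)), 0L)
})

test_that("seeded tracing equals the exhaustive oracle", {
  set.seed(107)
  for (rep in 1:8) {
    subj <- c(s = rndDna(8000L))
    spacer <- rndDna(sample(28:40, 1L))
    ## plant one noisy copy so non-trivial hits exist
    m <- sample(0:6, 1L)
    ch <- strsplit(spacer, "")[[1]]
    for (p in sample(length(ch), m))
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    planted <- paste(ch, collapse = "")
    ins <- if (rep %% 2) planted else rcOracle(planted)
    at <- sample(1000:6000, 1L)
    subj <- c(s = paste0(substr(subj, 1, at), ins,
                         substr(subj, at + 1, 8000)))
    a <- traceSpacer(spacer, subj)
    b <- bruteForceTrace(spacer, subj)
    expect_identical(a, b)
    if (m <= (nchar(spacer) - 20) / 2) expect_gte(nrow(a), 1L)
    ## every emitted hit respects score = L - 2m >= threshold
    if (nrow(a)) {
      expect_true(all(a$score == nchar(spacer) - 2 * a$mismatches))
      expect_true(all(a$score >= 20))
    }
  }
})

test_that("tracing against the reverse-complemented subject mirrors hits", {
  set.seed(109)
  spacer <- rndDna(34L)
  n <- 6000L
  subj <- paste0(rndDna(3000L), spacer, rndDna(n - 3034L))
  fwd <- bruteForceTrace(spacer, c(s = subj))
  rev <- bruteForceTrace(spacer, c(s = rcOracle(subj)))
  expect_equal(nrow(fwd), nrow(rev))
  expect_setequal(n - fwd$end, rev$start)
  expect_setequal(ifelse(fwd$strand == "+", "-", "+"), rev$strand)
  expect_setequal(fwd$mismatches, rev$mismatches)
})

test_that("flank extraction respects orientation and sequence ends", {
  subj <- "AACCGGTTACGTACGTACGTAAACCCGGGTTT"
  hit <- data.frame(start = 10, end = 20, strand = "+")
  fl <- extractFlanks(hit, subj, flankLen = 8L)
  expect_identical(fl$flank5, substr(subj, 3, 10))
  expect_identical(fl$flank3, substr(subj, 21, 28))
  ## minus strand: flank5 is the revcomp of the bases 3' of the interval
  hitM <- data.frame(start = 10, end = 20, strand = "-")
  flM <- extractFlanks(hitM, subj, flankLen = 8L)
  expect_identical(flM$flank5, rcOracle(substr(subj, 21, 28)))
  expect_identical(flM$flank3, rcOracle(substr(subj, 3, 10)))
  ## protospacer starting at position 2 (0-based) has no room for flank5
  hit2 <- data.frame(start = 2, end = 12, strand = "+")
  expect_true(is.na(extractFlanks(hit2, subj, flankLen = 8L)$flank5))
})

test_that("target deduplication collapses on (protospacer, flanks)", {
  hit <- function(id, subj, start, proto, f5, f3, m) {
    data.frame(spacer_id = id, subject_id = subj, start = start,
               end = start + nchar(proto), strand = "+", mismatches = m,
               score = nchar(proto) - 2 * m, protospacer = proto,
               flank5 = f5, flank3 = f3, stringsAsFactors = FALSE)
  }
  set.seed(113)
  p <- rndDna(34L); f5 <- rndDna(8L); f3 <- rndDna(8L)
  hits <- rbind(hit("s1", "e1", 100, p, f5, f3, 2),
                hit("s1", "e2", 900, p, f5, f3, 1),
                hit("s1", "e3", 500, p, rndDna(8L), f3, 1))
  dd <- dedupeTargets(hits)
  expect_equal(nrow(dd), 2L)                 # different flank5 => distinct
  expect_equal(dd$subject_id[dd$mismatches == 1 & dd$flank5 == f5], "e2")
  ## identical planted protospacers in two elements collapse to one
  cfg <- hostConfig(127L, list(arraySpec("C", nUnits = 6)),
                    nProtospacers = 2L)
  host <- generateHostGenome(cfg)
  sp <- truthSpacerVec(host$truth)
  mge <- generateMge(cfg, sp)
  two <- c(as.character(mge$seq), e2 = as.character(mge$seq)[[1]])
  names(two)[1] <- "e1"
  recs <- data.frame(spacer_id = names(sp), sequence = unname(sp),
                     stringsAsFactors = FALSE)
  hits2 <- traceSpacers(recs, two)
  expect_equal(nrow(hits2), 4L)
  expect_equal(nrow(dedupeTargets(hits2)), 2L)
})

test_that("self-hits against detected arrays are flagged, not dropped", {
  cfg <- hostConfig(131L, list(arraySpec("C", nUnits = 6)))
  host <- generateHostGenome(cfg)
  arrays <- detectArrays(host$seq)
  recs <- extractSpacers(arrays)
  hits <- traceSpacers(recs, host$seq)      # spacers match their own array
  expect_gte(nrow(hits), nrow(recs))
  fl <- flagSelfHits(hits, arrays)
  expect_true(all(fl$self_hit[fl$mismatches == 0]))
})
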