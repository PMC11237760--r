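## Locus-context comparison: the genes flanking a CRISPR-Cas locus in a
## reference genome form an anchor library; matching those anchors in a
## query genome locates the corresponding region in incomplete assemblies
## and classifies the locus as present, absent-with-context (flanks align
## contiguously with nothing between) or unresolved (flanks fall on contig
## ends / too few anchors).  Anchor matches use local protein alignment
## filtered at e-value <= 1 and percent identity >= 70.

#' Read a gene annotation (GFF3 + protein FASTA)
#'
#' CDS/gene features are paired with protein sequences by their `ID`
#' attribute.  Coordinates are converted to 0-based half-open.
#'
#' @param gff3 path to a GFF3 file.
#' @param proteins path to the matching protein FASTA (names = gene ids).
#' @param featureType feature type(s) to keep.
#' @return gene data.frame (gene_id, contig_id, start, end, strand,
#'   protein), sorted by contig then start.
#' @export
readGeneAnnotation <- function(gff3, proteins,
                               featureType = c("CDS", "gene")) {
  gr <- rtracklayer::import(gff3)
  gr <- gr[gr$type %in% featureType]
  prot <- Biostrings::readAAStringSet(proteins)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID)
         else sprintf("gene%d", seq_along(gr))
  df <- data.frame(
    gene_id = ids,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    protein = as.character(prot[ids]),
    stringsAsFactors = FALSE)
  df[order(df$contig_id, df$start), , drop = FALSE]
}

#' Genes flanking a locus
#'
#' Up to `w` genes on each side of the locus interval, in genomic order;
#' fewer when the contig runs out (flagged truncated).
#'
#' @param annotation gene data.frame (see [readGeneAnnotation()]); 0-based
#'   half-open coordinates.
#' @param contig locus contig id.
#' @param start,end locus interval, 0-based half-open.
#' @param w genes per side.
#' @return list(upstream, downstream, truncatedUpstream,
#'   truncatedDownstream); upstream/downstream are gene data.frames in
#'   genomic order with a `side` column.
#' @export
extractFlankGenes <- function(annotation, contig, start, end, w = 10L) {
  if (!contig %in% annotation$contig_id)
    stop("input error: locus contig '", contig, "' absent from annotation")
  genes <- annotation[annotation$contig_id == contig, , drop = FALSE]
  genes <- genes[order(genes$start), , drop = FALSE]
  upAll <- genes[genes$end <= start, , drop = FALSE]
  downAll <- genes[genes$start >= end, , drop = FALSE]
  up <- utils::tail(upAll, w)
  down <- utils::head(downAll, w)
  if (nrow(up)) up$side <- "upstream"
  else up <- cbind(up, data.frame(side = character(0)))
  if (nrow(down)) down$side <- "downstream"
  else down <- cbind(down, data.frame(side = character(0)))
  rownames(up) <- NULL; rownames(down) <- NULL
  list(upstream = up, downstream = down,
       truncatedUpstream = nrow(upAll) < w,
       truncatedDownstream = nrow(downAll) < w)
}

#' Local protein alignment with BLAST-like statistics
#'
#' Smith--Waterman local alignment under BLOSUM62 with affine gaps (open 11,
#' extend 1).  Percent identity is computed over aligned columns (gaps
#' included in the denominator, as in tabular BLAST output); coverage is the
#' fraction of the shorter protein's residues inside the aligned region; the
#' e-value comes from the Karlin--Altschul formula E = K m n exp(-lambda S)
#' with the standard ungapped BLOSUM62 constants (K = 0.041,
#' lambda = 0.267), an approximation of gapped BLAST statistics -- the
#' pident filter dominates in practice.
#'
#' @param a,b protein sequences (single-letter code).
#' @param gapOpen,gapExtend affine gap penalties.
#' @param K,lambda Karlin--Altschul parameters.
#' @return `list(pident, coverage, evalue, score)`.
#' @export
alignProteins <- function(a, b, gapOpen = 11, gapExtend = 1,
                          K = 0.041, lambda = 0.267) {
  a <- toupper(a); b <- toupper(b)
  if (!nchar(a) || !nchar(b))
    stop("input error: empty protein sequence")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYBZX*]", a) ||
      grepl("[^ACDEFGHIKLMNPQRSTVWYBZX*]", b))
    stop("input error: invalid amino-acid residues")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gapOpen, gapExtension = gapExtend)
  alnP <- as.character(Biostrings::alignedPattern(pa))
  alnS <- as.character(Biostrings::alignedSubject(pa))
  alnLen <- nchar(alnP)
  pident <- if (alnLen) 100 * Biostrings::nmatch(pa) / alnLen else 0
  shorter <- min(nchar(a), nchar(b))
  residA <- nchar(gsub("-", "", alnP, fixed = TRUE))
  residB <- nchar(gsub("-", "", alnS, fixed = TRUE))
  covResid <- if (nchar(a) <= nchar(b)) residA else residB
  coverage <- covResid / shorter
  S <- Biostrings::score(pa)
  evalue <- K * nchar(a) * nchar(b) * exp(-lambda * S)
  list(pident = pident, coverage = coverage, evalue = evalue, score = S)
}

#' Match a reference anchor library against a query annotation
#'
#' Every reference gene is aligned against every query protein; the best
#' query gene (by alignment score) is its anchor match.  A match passes
#' when e-value <= `evalueMax`, pident >= `pidentMin` and coverage >=
#' `coverageMin` (the coverage guard rejects short spurious local hits).
#' Reciprocal-best status is recorded.
#'
#' @param refLib reference gene data.frame (typically the concatenated
#'   flanks from [extractFlankGenes()], carrying a `side` column).
#' @param queryAnnotation query gene data.frame.
#' @param evalueMax,pidentMin,coverageMin pass filters.
#' @return anchor data.frame: ref_gene_id, side, query_gene_id (NA when the
#'   query is empty), query_contig, query_start, query_end, pident,
#'   coverage, evalue, score, passed, reciprocal_best.
#' @export
compareContexts <- function(refLib, queryAnnotation, evalueMax = 1,
                            pidentMin = 70, coverageMin = 0.5) {
  side <- if ("side" %in% names(refLib)) refLib$side
          else rep(NA_character_, nrow(refLib))
  if (!nrow(refLib)) stop("input error: empty reference library")
  nq <- nrow(queryAnnotation)
  if (!nq) {
    return(data.frame(ref_gene_id = refLib$gene_id, side = side,
                      query_gene_id = NA_character_,
                      query_contig = NA_character_,
                      query_start = NA_real_, query_end = NA_real_,
                      pident = NA_real_, coverage = NA_real_,
                      evalue = NA_real_, score = NA_real_,
                      passed = FALSE, reciprocal_best = FALSE,
                      stringsAsFactors = FALSE))
  }
  nr <- nrow(refLib)
  scoreMat <- matrix(-Inf, nr, nq)
  stats <- vector("list", nr * nq)
  for (i in seq_len(nr)) for (j in seq_len(nq)) {
    al <- alignProteins(refLib$protein[i], queryAnnotation$protein[j])
    scoreMat[i, j] <- al$score
    stats[[(i - 1L) * nq + j]] <- al
  }
  bestQ <- apply(scoreMat, 1L, which.max)
  bestR <- apply(scoreMat, 2L, which.max)
  rows <- lapply(seq_len(nr), function(i) {
    j <- bestQ[i]
    al <- stats[[(i - 1L) * nq + j]]
    data.frame(ref_gene_id = refLib$gene_id[i], side = side[i],
               query_gene_id = queryAnnotation$gene_id[j],
               query_contig = queryAnnotation$contig_id[j],
               query_start = queryAnnotation$start[j],
               query_end = queryAnnotation$end[j],
               pident = al$pident, coverage = al$coverage,
               evalue = al$evalue, score = al$score,
               passed = al$evalue <= evalueMax & al$pident >= pidentMin &
                 al$coverage >= coverageMin,
               reciprocal_best = bestR[j] == i,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the locus state in a query genome
#'
#' `present` when at least `minAnchors` anchors pass on each side, both
#' anchor blocks fall on one query contig, and a CRISPR array or supplied
#' locus annotation lies between them; `absent_with_context` when the
#' flanks anchor contiguously on one contig with no locus between;
#' `unresolved` when too few anchors pass, the two flanks land on different
#' contigs (assembly fragmentation), or the blocks interleave.  The
#' decision is symmetric in the two sides, so it is invariant under contig
#' reordering and strand flipping of the query.
#'
#' @param matches anchor data.frame from [compareContexts()] (needs `side`).
#' @param loci detected loci in the query: a list of [CrisprArray-class]
#'   and/or a data.frame (contig_id, start, end); may be empty.
#' @param minAnchors passing anchors required per side.
#' @return one of "present", "absent_with_context", "unresolved".
#' @export
inferLocusState <- function(matches, loci = list(), minAnchors = 3L) {
  lociDf <- if (is.data.frame(loci)) loci else if (length(loci)) {
    data.frame(
      contig_id = vapply(loci, contigId, character(1)),
      start = vapply(loci, arrayStart, numeric(1)),
      end = vapply(loci, arrayEnd, numeric(1)), stringsAsFactors = FALSE)
  } else data.frame(contig_id = character(0), start = numeric(0),
                    end = numeric(0))
  up <- matches[matches$passed & matches$side == "upstream", , drop = FALSE]
  down <- matches[matches$passed & matches$side == "downstream", ,
                  drop = FALSE]
  if (nrow(up) < minAnchors || nrow(down) < minAnchors) return("unresolved")
  contigs <- unique(c(up$query_contig, down$query_contig))
  if (length(contigs) != 1L) return("unresolved")
  blockU <- c(min(up$query_start), max(up$query_end))
  blockD <- c(min(down$query_start), max(down$query_end))
  gap <- c(min(blockU[2L], blockD[2L]), max(blockU[1L], blockD[1L]))
  if (gap[1L] > gap[2L]) return("unresolved")   # blocks interleave
  onContig <- lociDf[lociDf$contig_id == contigs, , drop = FALSE]
  between <- nrow(onContig) > 0L &&
    any(onContig$start < gap[2L] & onContig$end > gap[1L])
  if (between) "present" else "absent_with_context"
}
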