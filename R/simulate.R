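## Synthetic genomes, mobile elements and fragmented assemblies with planted
## CRISPR structure.  The generator is the package's ground-truth source:
## every downstream stage is validated against the TruthTable it emits.
## A single seeded RNG stream (R's default Mersenne-Twister with the
## "Rejection" sample kind, R >= 3.6) drives each operation, so a fixed seed
## gives byte-identical FASTA and truth output.

## Canonical terminal motifs and default unit sizes per repeat type.  Repeat
## lengths follow the printed type lengths (C 37 bp, B/G 36 bp); the E repeat
## length is not printed anywhere, 29 bp is a realistic I-E repeat size within
## the typing range [27, 33].
simTypeDefaults <- function(type) {
  switch(type,
    C = list(repeatLength = 37L, motif = "TTGAAAC",  spacerLength = 34L),
    B = list(repeatLength = 36L, motif = "TTGAGCAC", spacerLength = 35L),
    G = list(repeatLength = 36L, motif = "TTGAAGC",  spacerLength = 36L),
    E = list(repeatLength = 29L, motif = "CCCCGCNNNNGCGGGG",
             spacerLength = 31L),
    U = list(repeatLength = 32L, motif = NA_character_, spacerLength = 34L),
    stop("unknown repeat type '", type, "'")
  )
}

#' Specification of one planted CRISPR array
#'
#' @param type repeat type to plant: "C", "B", "G", "E" or "U" (motif-free).
#' @param nUnits number of repeat copies (>= 2); the array carries
#'   `nUnits - 1` spacers.
#' @param subRate per-base substitution probability applied independently to
#'   each repeat copy (the final 8 nt -- the typing motif window -- are
#'   protected unless `motifAblated`).
#' @param repeatLength repeat unit length in bp (default: the type's printed
#'   length); must lie in \[23, 55\].
#' @param spacerLength spacer length in bp.
#' @param spacerGc spacer GC fraction (default 0.65, matching the high-GC
#'   spacer content of the source genomes).
#' @param motifAblated if TRUE, substitutions may also hit the terminal motif,
#'   so typing robustness can be probed separately from typing accuracy.
#' @return a list of class "arraySpec".
#' @export
arraySpec <- function(type = "C", nUnits = 10L, subRate = 0,
                      repeatLength = NULL, spacerLength = NULL,
                      spacerGc = 0.65, motifAblated = FALSE) {
  type <- match.arg(type, c("C", "B", "G", "E", "U"))
  def <- simTypeDefaults(type)
  if (is.null(repeatLength)) repeatLength <- def$repeatLength
  if (is.null(spacerLength)) spacerLength <- def$spacerLength
  stopifnot(repeatLength >= 23L, repeatLength <= 55L,
            nUnits >= 2L, subRate >= 0, subRate <= 1,
            spacerLength > 0L, spacerGc >= 0, spacerGc <= 1)
  structure(list(type = type, nUnits = as.integer(nUnits),
                 subRate = subRate, repeatLength = as.integer(repeatLength),
                 spacerLength = as.integer(spacerLength),
                 spacerGc = spacerGc, motifAblated = isTRUE(motifAblated)),
            class = "arraySpec")
}

#' Simulator configuration
#'
#' Default values emulate the study corpus: high-GC host contigs
#' (`gcBackground = 0.69`, the lower quartile of spacer GC in the source
#' genomes exceeds 0.60) carrying arrays of defined type, copy number and
#' per-copy mutation rate, plus mobile elements carrying protospacers with a
#' planted PAM and a controlled mismatch count.
#'
#' @param seed integer seed; equal seeds give byte-identical outputs.
#' @param gcBackground host background GC fraction.
#' @param genomeLength host contig length in bp.
#' @param arraySpecs list of [arraySpec()] objects, one per planted array.
#' @param nProtospacers protospacers planted per mobile element.
#' @param pam 3-nt PAM planted immediately 5' of every protospacer (on the
#'   protospacer strand).
#' @param plantedMismatches exact Hamming distance between each protospacer
#'   and its source spacer.
#' @param elementLength mobile-element length in bp.
#' @param mgeGc mobile-element background GC (phage-like, below the host's).
#' @param fragmentation list(nContigs, minContig) controlling
#'   [fragmentAssembly()].
#' @param contigId,elementId sequence names used in FASTA/truth output.
#' @return a list of class "simConfig".
#' @export
simConfig <- function(seed = 1L, gcBackground = 0.69, genomeLength = 50000L,
                      arraySpecs = list(arraySpec()), nProtospacers = 0L,
                      pam = "TTC", plantedMismatches = 0L,
                      elementLength = 20000L, mgeGc = 0.55,
                      fragmentation = list(nContigs = 1L, minContig = 1000L),
                      contigId = "sim_genome", elementId = "sim_mge") {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            gcBackground >= 0, gcBackground <= 1,
            genomeLength >= 1L, nchar(pam) == 3L,
            plantedMismatches >= 0L, elementLength >= 1L)
  if (!length(arraySpecs) || !all(vapply(arraySpecs, inherits, logical(1),
                                         "arraySpec")))
    stop("arraySpecs must be a non-empty list of arraySpec() objects")
  structure(list(seed = as.integer(seed), gcBackground = gcBackground,
                 genomeLength = as.integer(genomeLength),
                 arraySpecs = arraySpecs,
                 nProtospacers = as.integer(nProtospacers),
                 pam = toupper(pam),
                 plantedMismatches = as.integer(plantedMismatches),
                 elementLength = as.integer(elementLength), mgeGc = mgeGc,
                 fragmentation = fragmentation,
                 contigId = contigId, elementId = elementId),
            class = "simConfig")
}

## Unmutated repeat template for a type: random prefix + terminal motif
## (C/B/G), internal palindrome with random N fill (E), or motif-free random
## sequence (U, rejected until no typing rule fires on either strand).
## Draws from the current RNG stream.
repeatTemplate <- function(type, repeatLength, gc = 0.6) {
  def <- simTypeDefaults(type)
  for (try in seq_len(200L)) {
    if (type %in% c("C", "B", "G")) {
      motif <- def$motif
      tpl <- paste0(randomDna(repeatLength - nchar(motif), gc), motif)
    } else if (type == "E") {
      fill <- randomDna(4L, gc)
      pal <- paste0("CCCCGC", fill, "GCGGGG")
      lead <- (repeatLength - 16L) %/% 2L
      tpl <- paste0(randomDna(lead, gc), pal,
                    randomDna(repeatLength - 16L - lead, gc))
      ## the 3' end must not mimic a terminal-motif type
      if (typeLabel(assignType(tpl)) != "E") next
    } else { # U
      tpl <- randomDna(repeatLength, gc)
      if (typeLabel(assignType(tpl)) != "U") next
    }
    return(tpl)
  }
  stop("failed to build a clean ", type, "-type repeat template")
}

## Substitute each base independently with probability `rate`; the final
## `protectTail` bases (the typing motif window) are untouched unless ablated.
mutateRepeat <- function(template, rate, protectTail = 8L,
                         motifAblated = FALSE) {
  if (rate <= 0) return(template)
  b <- strsplit(template, "", fixed = TRUE)[[1]]
  n <- length(b)
  idx <- if (motifAblated) seq_len(n) else seq_len(max(n - protectTail, 0L))
  hit <- idx[stats::runif(length(idx)) < rate]
  for (i in hit) b[i] <- sample(setdiff(DNA_BASES, b[i]), 1L)
  paste(b, collapse = "")
}

## n spacers with pairwise strand-insensitive identity < maxIdentity
## (rejection sampling), so planted arrays always pass the detector's
## tandem-repeat filter.
sampleSpacers <- function(n, len, gc, maxIdentity = 0.60) {
  out <- character(0)
  for (i in seq_len(n)) {
    for (try in seq_len(2000L)) {
      cand <- randomDna(len, gc)
      if (!length(out) ||
          max(vapply(out, strandIdentity, numeric(1), b = cand)) <
            maxIdentity) {
        out <- c(out, cand)
        break
      }
      if (try == 2000L) stop("could not sample spacers below the pairwise ",
                             "identity bound; relax spacer length or GC")
    }
  }
  out
}

## Exact-Hamming-distance mutant of a spacer (protospacer body).
mutateExact <- function(seq, m) {
  if (m == 0L) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (m >= length(b)) stop("planted mismatches must be < spacer length")
  pos <- sample(length(b), m)
  for (i in pos) b[i] <- sample(setdiff(DNA_BASES, b[i]), 1L)
  paste(b, collapse = "")
}

## Non-overlapping placement of fragment lengths inside [1, n] with a minimum
## separation: fragments keep their input order and random slack is
## distributed between them, so the construction succeeds whenever the
## fragments fit at all.  Deterministic under the active RNG stream.
placeFragments <- function(lens, n, gap = 150L, margin = 0L) {
  k <- length(lens)
  slack <- n - 2L * margin - sum(lens) - (k - 1L) * gap
  if (slack < 0L)
    stop("placement error: cannot place ", k, " fragments of total length ",
         sum(lens), " without overlap in a sequence of length ", n,
         " (min gap ", gap, ")")
  offs <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
  starts <- margin + offs + (seq_len(k) - 1L) * gap +
    c(0L, cumsum(lens))[seq_len(k)] + 1L
  data.frame(start = starts, end = starts + lens - 1L)
}

#' Generate a host contig with planted CRISPR arrays
#'
#' Builds one contig of `cfg$genomeLength` with each array of
#' `cfg$arraySpecs` planted at a non-overlapping locus: `nUnits` copies of an
#' unmutated type template (each copy independently substituted at the
#' spec's rate, motif window protected) interleaved with `nUnits - 1`
#' mutually dissimilar random spacers.
#'
#' @param cfg a [simConfig()] object.
#' @return list with `seq` (a named length-1 [Biostrings::DNAStringSet]) and
#'   `truth` (a [TruthTable-class]); truth coordinates are 0-based half-open.
#' @export
generateHostGenome <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  withSeed(cfg$seed, {
    genome <- randomDna(cfg$genomeLength, cfg$gcBackground)
    rows <- vector("list", length(cfg$arraySpecs))
    built <- vector("list", length(cfg$arraySpecs))
    for (j in seq_along(cfg$arraySpecs)) {
      sp <- cfg$arraySpecs[[j]]
      tpl <- repeatTemplate(sp$type, sp$repeatLength)
      spacers <- sampleSpacers(sp$nUnits - 1L, sp$spacerLength, sp$spacerGc)
      units <- vapply(seq_len(sp$nUnits), function(i) {
        mutateRepeat(tpl, sp$subRate, motifAblated = sp$motifAblated)
      }, character(1))
      pieces <- character(2L * sp$nUnits - 1L)
      pieces[seq(1L, by = 2L, length.out = sp$nUnits)] <- units
      if (sp$nUnits > 1L)
        pieces[seq(2L, by = 2L, length.out = sp$nUnits - 1L)] <- spacers
      built[[j]] <- list(spec = sp, template = tpl, spacers = spacers,
                         seq = paste(pieces, collapse = ""))
    }
    lens <- vapply(built, function(b) nchar(b$seq), numeric(1))
    pos <- placeFragments(lens, cfg$genomeLength, gap = 150L)
    for (j in seq_along(built)) {
      b <- built[[j]]; sp <- b$spec
      s1 <- pos$start[j]                       # 1-based insert position
      substr(genome, s1, pos$end[j]) <- b$seq
      period <- sp$repeatLength + sp$spacerLength
      ustarts0 <- (s1 - 1L) + period * (seq_len(sp$nUnits) - 1L)
      uends0 <- ustarts0 + sp$repeatLength
      aid <- sprintf("%s_arr%d", cfg$contigId, j)
      rows[[j]] <- data.frame(
        array_id = aid, contig_id = cfg$contigId,
        start = as.numeric(ustarts0[1L]), end = as.numeric(uends0[sp$nUnits]),
        repeat_type = sp$type, repeat_template = b$template,
        unit_starts = paste(ustarts0, collapse = ","),
        unit_ends = paste(uends0, collapse = ","),
        spacer_ids = paste(sprintf("%s_sp%03d", aid,
                                   seq_len(sp$nUnits - 1L) - 1L),
                           collapse = ","),
        spacer_seqs = paste(b$spacers, collapse = ","),
        truncated = FALSE, stringsAsFactors = FALSE)
    }
    arrays <- do.call(rbind, rows)
    arrays <- arrays[order(arrays$start), , drop = FALSE]
    rownames(arrays) <- NULL
    seqs <- Biostrings::DNAStringSet(stats::setNames(genome, cfg$contigId))
    list(seq = seqs, truth = TruthTable(arrays = arrays))
  })
}

#' Generate a mobile element carrying planted protospacers
#'
#' For each selected spacer the element receives a protospacer at exactly
#' `cfg$plantedMismatches` Hamming distance from the spacer, on a random
#' strand, with `cfg$pam` immediately 5' of the protospacer on the
#' protospacer strand; the rest of the element is random background.
#'
#' @param cfg a [simConfig()] object (`nProtospacers`, `pam`,
#'   `plantedMismatches`, `elementLength`, `mgeGc` are used).
#' @param spacers named character vector of spacer sequences (names become
#'   `spacer_id` in the truth table; auto-named when missing).
#' @return list with `seq` (named length-1 DNAStringSet) and `truth`
#'   (a [TruthTable-class] with the protospacer table filled).
#' @export
generateMge <- function(cfg, spacers) {
  stopifnot(inherits(cfg, "simConfig"), length(spacers) > 0L)
  spacers <- toupper(spacers)
  if (is.null(names(spacers)))
    names(spacers) <- sprintf("spacer%03d", seq_along(spacers))
  if (any(cfg$plantedMismatches >= nchar(spacers)))
    stop("plantedMismatches must be smaller than every spacer length")
  n_proto <- if (cfg$nProtospacers > 0L) cfg$nProtospacers else length(spacers)
  if (n_proto > length(spacers))
    stop("placement error: ", n_proto, " protospacers requested but only ",
         length(spacers), " spacers supplied")
  withSeed((cfg$seed + 104729L) %% .Machine$integer.max, {
    element <- randomDna(cfg$elementLength, cfg$mgeGc)
    chosen <- sample(names(spacers), n_proto)
    fragLens <- nchar(spacers[chosen]) + 3L
    if (sum(fragLens + 10L) + 16L > cfg$elementLength)
      stop("placement error: requested protospacers exceed element capacity")
    pos <- placeFragments(fragLens, cfg$elementLength, gap = 10L,
                          margin = 8L)
    rows <- vector("list", n_proto)
    for (i in seq_len(n_proto)) {
      sid <- chosen[i]
      proto <- mutateExact(spacers[[sid]], cfg$plantedMismatches)
      strand <- sample(c("+", "-"), 1L)
      frag <- paste0(cfg$pam, proto)           # protospacer-strand layout
      ins <- if (strand == "+") frag else revComp(frag)
      s1 <- pos$start[i]
      substr(element, s1, pos$end[i]) <- ins
      L <- nchar(proto)
      if (strand == "+") {
        p0 <- (s1 - 1L) + 3L                   # protospacer follows the PAM
      } else {
        p0 <- s1 - 1L                          # revcomp(PAM) trails it
      }
      rows[[i]] <- data.frame(
        proto_id = sprintf("proto%03d", i), element_id = cfg$elementId,
        start = as.numeric(p0), end = as.numeric(p0 + L), strand = strand,
        spacer_id = sid, spacer_seq = spacers[[sid]],
        planted_mismatches = as.numeric(cfg$plantedMismatches),
        planted_pam = cfg$pam, truncated = FALSE, stringsAsFactors = FALSE)
    }
    protos <- do.call(rbind, rows)
    protos <- protos[order(protos$start), , drop = FALSE]
    rownames(protos) <- NULL
    seqs <- Biostrings::DNAStringSet(stats::setNames(element, cfg$elementId))
    list(seq = seqs, truth = TruthTable(protospacers = protos))
  })
}

#' Fragment a simulated sequence into contigs and remap the truth
#'
#' The contigs partition the source sequence exactly (no base duplicated or
#' lost).  Truth records fully inside one contig are shifted; arrays split by
#' a breakpoint are clipped to their fully contained units and flagged
#' `truncated`, as are split protospacers.
#'
#' @param record named length-1 DNAStringSet (or single named character), as
#'   returned by [generateHostGenome()].
#' @param truth the matching [TruthTable-class].
#' @param cfg a [simConfig()] object; `cfg$fragmentation$nContigs` and
#'   `$minContig` control random breakpoints.
#' @param breakpoints optional explicit 0-based cut positions (overrides the
#'   random choice; minContig is not enforced for explicit cuts).
#' @return list with `seq` (DNAStringSet of contigs) and remapped `truth`.
#' @export
fragmentAssembly <- function(record, truth, cfg, breakpoints = NULL) {
  seqchr <- as.character(record)[1L]
  name <- names(as.character(record))[1L]
  if (is.null(name)) name <- "contig"
  n <- nchar(seqchr)
  nc <- cfg$fragmentation$nContigs
  minc <- cfg$fragmentation$minContig
  if (is.null(breakpoints)) {
    if (nc < 1L || minc < 1L || minc * nc > n)
      stop("configuration error: ", nc, " contigs of >= ", minc,
           " bp do not fit in ", n, " bp")
    if (nc == 1L) return(list(seq = record, truth = truth))
    breakpoints <- withSeed((cfg$seed + 224737L) %% .Machine$integer.max, {
      for (t in seq_len(10000L)) {
        cuts <- sort(sample(seq.int(minc, n - minc), nc - 1L))
        if (all(diff(c(0L, cuts, n)) >= minc)) break
        if (t == 10000L) stop("configuration error: cannot draw breakpoints ",
                              "honouring minContig")
      }
      cuts
    })
  } else {
    breakpoints <- sort(unique(as.integer(breakpoints)))
    stopifnot(all(breakpoints > 0L), all(breakpoints < n))
  }
  bounds <- c(0L, breakpoints, n)              # 0-based half-open pieces
  k <- length(bounds) - 1L
  ctgNames <- sprintf("%s_ctg%d", name, seq_len(k))
  pieces <- substring(seqchr, bounds[-length(bounds)] + 1L, bounds[-1L])
  newArrays <- list(); newProtos <- list()
  arr <- truthArrays(truth)
  for (r in seq_len(nrow(arr))) {
    us <- as.numeric(strsplit(arr$unit_starts[r], ",")[[1]])
    ue <- as.numeric(strsplit(arr$unit_ends[r], ",")[[1]])
    sids <- strsplit(arr$spacer_ids[r], ",")[[1]]
    sseqs <- strsplit(arr$spacer_seqs[r], ",")[[1]]
    for (ci in seq_len(k)) {
      cs <- bounds[ci]; ce <- bounds[ci + 1L]
      if (arr$end[r] <= cs || arr$start[r] >= ce) next
      keep <- which(us >= cs & ue <= ce)
      if (!length(keep)) next
      split_arr <- arr$start[r] < cs || arr$end[r] > ce
      keepSp <- keep[-length(keep)]            # spacer i sits after unit i
      keepSp <- keepSp[(keepSp + 1L) %in% keep]
      row <- arr[r, , drop = FALSE]
      row$contig_id <- ctgNames[ci]
      row$start <- us[keep[1L]] - cs
      row$end <- ue[keep[length(keep)]] - cs
      row$unit_starts <- paste(us[keep] - cs, collapse = ",")
      row$unit_ends <- paste(ue[keep] - cs, collapse = ",")
      row$spacer_ids <- paste(sids[keepSp], collapse = ",")
      row$spacer_seqs <- paste(sseqs[keepSp], collapse = ",")
      row$truncated <- split_arr || isTRUE(row$truncated)
      newArrays[[length(newArrays) + 1L]] <- row
    }
  }
  pro <- truthProtospacers(truth)
  for (r in seq_len(nrow(pro))) {
    for (ci in seq_len(k)) {
      cs <- bounds[ci]; ce <- bounds[ci + 1L]
      if (pro$end[r] <= cs || pro$start[r] >= ce) next
      row <- pro[r, , drop = FALSE]
      split_pro <- pro$start[r] < cs || pro$end[r] > ce
      row$element_id <- ctgNames[ci]
      row$start <- max(pro$start[r], cs) - cs
      row$end <- min(pro$end[r], ce) - cs
      row$truncated <- split_pro || isTRUE(row$truncated)
      newProtos[[length(newProtos) + 1L]] <- row
    }
  }
  arrays <- if (length(newArrays)) do.call(rbind, newArrays)
            else emptyTruthArrays()
  protos <- if (length(newProtos)) do.call(rbind, newProtos)
            else emptyTruthProtospacers()
  rownames(arrays) <- NULL; rownames(protos) <- NULL
  list(seq = Biostrings::DNAStringSet(stats::setNames(pieces, ctgNames)),
       truth = TruthTable(arrays = arrays, protospacers = protos))
}

## ---------------------------------------------------------------------------
## Simulator I/O
## ---------------------------------------------------------------------------

#' Write sequences as wrapped FASTA
#' @param seqs DNAStringSet or named character vector.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGenomeFasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}

#' Write / read a TruthTable as two TSV files
#'
#' Coordinates stay 0-based half-open on disk; list-like columns are
#' comma-joined strings, so the round trip is exact.
#'
#' @param truth a [TruthTable-class].
#' @param arraysPath,protosPath TSV file paths.
#' @return `writeTruthTable`: the paths, invisibly; `readTruthTable`: a
#'   [TruthTable-class].
#' @export
writeTruthTable <- function(truth, arraysPath, protosPath) {
  utils::write.table(truthArrays(truth), arraysPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truthProtospacers(truth), protosPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(arraysPath, protosPath))
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(arraysPath, protosPath) {
  arr <- utils::read.delim(arraysPath, colClasses = "character")
  pro <- utils::read.delim(protosPath, colClasses = "character")
  for (cc in c("start", "end")) {
    if (nrow(arr)) arr[[cc]] <- as.numeric(arr[[cc]])
    if (nrow(pro)) pro[[cc]] <- as.numeric(pro[[cc]])
  }
  if (nrow(arr)) arr$truncated <- as.logical(arr$truncated)
  if (nrow(pro)) {
    pro$planted_mismatches <- as.numeric(pro$planted_mismatches)
    pro$truncated <- as.logical(pro$truncated)
  }
  if (!nrow(arr)) arr <- emptyTruthArrays()
  if (!nrow(pro)) pro <- emptyTruthProtospacers()
  TruthTable(arrays = arr, protospacers = pro)
}

#' Planted spacers of a truth table as a named vector
#'
#' Convenience accessor: the `spacer_ids` / `spacer_seqs` columns of the
#' truth array table, flattened to a named character vector suitable for
#' [generateMge()] or a tracing run.
#'
#' @param truth a [TruthTable-class].
#' @return named character vector (names = spacer ids).
#' @export
truthSpacers <- function(truth) {
  tr <- truthArrays(truth)
  if (!nrow(tr)) return(stats::setNames(character(0), character(0)))
  unlist(lapply(seq_len(nrow(tr)), function(i) {
    stats::setNames(strsplit(tr$spacer_seqs[i], ",")[[1]],
                    strsplit(tr$spacer_ids[i], ",")[[1]])
  }))
}

#' Read a simulator configuration from a YAML key/value file
#'
#' Top-level keys mirror [simConfig()] arguments; `arraySpecs` is a list of
#' maps mirroring [arraySpec()] arguments.
#'
#' @param path YAML file.
#' @return a [simConfig()] object.
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$arraySpecs))
    y$arraySpecs <- lapply(y$arraySpecs, function(a) do.call(arraySpec, a))
  do.call(simConfig, y)
}
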