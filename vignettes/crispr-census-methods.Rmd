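---
title: "Methods: a repeat-centred census of endogenous CRISPR-Cas systems"
author: "crisprCensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a repeat-centred census of endogenous CRISPR-Cas systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most bacterial genome collections are dominated by incomplete assemblies:
scaffolds, contigs and metagenome-assembled genomes in which a CRISPR-Cas
locus is often split across sequences or stripped of its *cas* genes.
Subtyping by *cas* gene phylogeny then fails, but the direct repeats of a
CRISPR array are short, highly conserved within a type, and carry conserved
terminal motifs at fixed positions — so the repeat sequence alone can report
both the presence of a system and its type, even on a lone contig fragment.
crisprCensus implements that idea end to end for high-GC hosts such as
myxobacteria: de-novo array detection, repeat-based typing, spacer
cataloguing, spacer-to-protospacer target tracing, PAM inference, and
synteny-based locus-context comparison, all validated against a simulator
that plants arrays, protospacers and PAMs with an exact truth table.

## Array detection

Detection is CRT-style: identical seed words (default `kSeed = 9` nt)
recurring at spacings compatible with one repeat--spacer period (repeat
23–55 bp, spacer 18–60 bp, hence period 41–115 bp) start a candidate chain;
chains from different words covering the same locus are collapsed to the
one with most units.  Seed words with fewer than three distinct bases are
ignored — a low-complexity guard that keeps homopolymer and dinucleotide
runs from flooding the scan.  The scan works on forward coordinates only;
because a repeat array looks the same from either strand, detection is
strand-agnostic and orientation is deferred to typing.

Unit boundaries are refined by column-wise consensus agreement: extending a
column is worth `agreement − boundaryAgreement` (default 0.75), and the
extension maximising the cumulative gain is kept, jointly constrained so
the repeat stays within the length range and leaves room for a minimal
spacer.  On exact ties the boundary is pushed outward; a mutated terminal
column in a minority of units is therefore retained rather than trimmed,
which is what makes boundary calls exact on mutated arrays.  With ten
units, a spurious external column needs eight of ten matching bases by
chance — rare enough that boundary exactness holds at the 2% per-copy
substitution level the validation uses.  Units whose seed word was mutated
are recovered afterwards by stepping outward one period at a time and
accepting windows with identity ≥ `extendIdentity` (0.70) to the running
consensus.

Three confidence filters approximate a highest-evidence extraction tier:
at least `minUnits = 4` repeat copies (3 under `permissive = TRUE`),
repeat conservation ≥ 0.80, and maximum pairwise spacer identity ≤ 0.60
(computed strand-insensitively), which removes tandem repeats whose
"spacers" are all alike.  Conservation is the mean per-column identity of
the units to their majority consensus, ungapped — indel-tolerant repeat
alignment is out of scope, and every tie in a majority vote resolves to the
alphabetically first base so consensus calls are deterministic.

Coordinates are 0-based half-open in every in-memory table and in the
truth files; GFF3 export converts to the 1-based inclusive convention with
`repeat_region` / `direct_repeat` / `spacer` features.

## Repeat typing

Four repeat classes are recognised, in rule precedence B, G, C, E (longest
terminal motif first):

| label | signature                      | position | length range |
|-------|--------------------------------|----------|--------------|
| B     | `TTGAGCAC`                     | 3' end   | 34–38 bp     |
| G     | `TTGAAGC`                      | 3' end   | 34–38 bp     |
| C     | `TTGAAAC`                      | 3' end   | 35–39 bp     |
| E     | `CCCCGCNNNNGCGGGG` (palindrome)| internal | 27–33 bp     |

Anything matching no rule is U (unclassified).  Length ranges are the
printed type lengths ± 2 bp; the E repeat length is never printed anywhere
we could anchor to, so its range brackets typical I-E repeats and is a
package choice, not a literature value.  B deliberately covers the two
adjoint subtypes that share this repeat.

The motif window tolerates zero mismatches by default: the C and G motifs
differ by a single base, so any tolerance would merge them.  Under
`fuzzy = TRUE` one mismatch is allowed and competing rules are resolved by
fewest motif mismatches first, then precedence — an exact C motif therefore
never drifts to G.  A consensus is first oriented to the strand where a
terminal motif fits best; motif-free repeats take the lexicographically
smaller of the two strands, which makes orientation an involution and the
type call invariant under reverse complement (a property the suite checks
on random inputs).

`hairpinStem()` reports the longest reverse-complementary arm pair with a
loop of ≥ 3 nt, ties resolved to the leftmost arms; it is checked against
an exhaustive oracle over all (i, j, L) triples.  Repeat clustering is
single-linkage at ≥ 0.90 ungapped identity, right-anchored at the motif
end so repeats of slightly different length align at their conserved tail;
whether a global alignment should be used instead is genuinely open, and
motif-anchored identity was chosen because the conserved tail is the
defining feature of each class.

## Spacer catalogue

Spacers are the inter-repeat intervals, reported forward-strand as
detected; index 0 is the leader-proximal end when typing has resolved the
orientation, else the leftmost (this affects reporting order only).
Deduplication treats a spacer and its reverse complement as the same
molecule (canonical key = lexicographic minimum), and is per-genome by
default — whether corpus-wide deduplication is wanted depends on the
question and is left to the caller by pooling catalogues first.  GC
content counts G+C over A+C+G+T with N excluded from both numerator and
denominator; quartiles use linear interpolation (type 7).

## Target tracing

Scoring is the ungapped +1 match / −1 mismatch model of the common CRISPR
target finders: a spacer of length L matching a window with m mismatches
scores `L − 2m`, reported at or above the threshold of 20 — so a 34-nt
spacer tolerates up to 7 mismatches.  Gaplessness is the package's single
largest simplification: indels would break the `L − 2m` bookkeeping, and
the upstream tools use the same default.  N counts as a mismatch on either
side.

The tracer seeds candidate windows with an exact word shared between
spacer and window (default 11 nt) and verifies by Hamming distance on both
subject strands.  When the threshold admits many mismatches an 11-mer is
not guaranteed to survive, so the effective word shrinks to
`floor(L / (m_allowed + 1))`, the pigeonhole bound that makes seeding
provably complete at the threshold; the suite still cross-checks the
seeded tracer against an exhaustive window scan on every tested instance.
Hits overlapping detected arrays (self-matches) are flagged, never
dropped.  Non-redundant targets collapse on the (protospacer, 5' flank,
3' flank) tuple, keeping the lowest-mismatch representative.

## PAM inference

The PAM window is the trinucleotide immediately 5' of the protospacer —
the last 3 nt of the 8-nt flank that also feeds the per-position
base-frequency matrix used for logos.  Because spacers and targets mutate
with age, candidates are stratified by mismatch count (perfect m = 0,
high-confidence m ≤ 3, extended m ≤ 6, all), computed on non-redundant
targets; ratios use the per-stratum target count as denominator (the
natural reading; pass the `all` stratum if a global denominator is
wanted).  The preferred list is inclusive at ratio ≥ 10%, so a PAM sitting
exactly at 10% is listed.  The degenerate IUPAC consensus is called from
perfect targets only, where mutation is least likely: each PAM position
keeps the bases reaching `posThreshold = 0.15` frequency, the smallest
value that keeps motif shapes crisp on synthetic mixtures while absorbing
the variable third base typical of type I PAMs; coverage is the fraction
of perfect PAMs the motif subsumes.  Flankless hits (protospacer at a
subject end) are excluded and counted, and every frequency table
renormalises over what remains.

## Locus context

The genes flanking a locus in a well-assembled reference form an anchor
library (default `w = 10` per side — the source procedure names no count).
Anchors are matched into a query annotation by Smith–Waterman local
alignment under BLOSUM62 with affine gaps (open 11, extend 1), provided by
`Biostrings::pairwiseAlignment` and cross-checked against an independent
quadratic DP in the test suite.  The e-value uses the Karlin–Altschul
formula with the standard ungapped constants (K = 0.041, λ = 0.267) — an
approximation of gapped BLAST statistics; the pass filter (e-value ≤ 1,
pident ≥ 70 over aligned columns, plus a coverage ≥ 0.5 guard against
short spurious local hits) is dominated by the identity term in practice.
A locus is `present` when ≥ 3 anchors pass per side on one contig with an
array between the blocks, `absent_with_context` when the blocks are
contiguous with nothing between, and `unresolved` when anchors are too few
or the flanks land on different contigs.  The decision is symmetric in the
two sides, so it survives contig reordering and strand flips.

## The simulator, and what passing tests do not show

The generator emulates the study conditions: host contigs at background GC
0.69 (the source genomes' spacer GC lower quartiles all exceed 60%),
arrays of a chosen type/length/copy number with an independent per-copy,
per-base substitution rate, spacers drawn i.i.d. at GC 0.65 with pairwise
identity forced below 60% by rejection, mobile elements at phage-like GC
0.55 carrying protospacers at an exact planted Hamming distance with the
PAM immediately 5' on the protospacer strand, and assembly fragmentation
that partitions the sequence and remaps (or truncates) the truth.
Substitutions spare the terminal 8 nt unless `motifAblated` is set, so
typing accuracy and motif robustness can be probed separately.  A single
seeded Mersenne-Twister stream (R ≥ 3.6 "Rejection" sampling) drives each
operation; equal seeds give byte-identical FASTA and truth files.

Real data differ in ways the simulator does not model: repeats age along
the array (old, cas-distal units are more diverged — the generator's flat
per-copy rate is a deliberate simplification), repeats can carry indels,
spacers are not i.i.d. sequence, leaders and *cas* genes are absent, and
real phage genomes have composition structure.  Passing the suite
therefore demonstrates algorithmic correctness against planted truth, not
field performance on arbitrary assemblies.

## Validation problem sizes

The property suite runs on 100 planted arrays at 2% per-copy substitution
(ten genomes of 40 kb, ten 10-unit arrays each) for detector recall and
boundary exactness; 200 motif-intact consensus repeats (50 per type, one
substitution outside the motif) for typing accuracy and strand invariance;
50 random spacer/100-kb-subject pairs (half with a planted 0–6-mismatch
copy) for tracer-vs-oracle equivalence; 100 perfect protospacers carrying
a planted `TTC` for PAM recovery; and a constructed
deletion/fragmentation series for the context state machine.  These sizes
give stable pass/fail behaviour at fixed seeds while keeping a full run in
about a minute.  `scripts/acceptance.R` recomputes the same quantities
from scratch at any seed.

## Known limitations

* Ungapped everywhere: neither the repeat consensus nor the tracer handles
  indels; an array with an indel-bearing unit will shift its boundary or
  split.
* Typing covers the four motif classes plus U; rare or hybrid subtypes are
  reported as U rather than guessed.
* The Karlin–Altschul e-value is an ungapped approximation; at desk-scale
  library sizes the identity filter decides, but e-values near the cutoff
  should not be over-interpreted.
* Detection needs `minUnits` copies of the repeat on one contig; a
  fragment carrying a single repeat copy is invisible (by design — it is
  also invisible to the evidence tier the filters emulate).
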