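---
title: "miRNA gene discovery from small RNA sequencing: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRNA gene discovery from small RNA sequencing: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mirdisc)
```

`mirdisc` implements a complete miRNA gene discovery-and-annotation
pipeline for a species with a draft genome and multi-tissue small RNA
libraries, together with a synthetic-data generator that plants the ground
truth the pipeline is validated against. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic validation does and does not establish about real data.

## The evidence model

Mature miRNAs are ~20–24 nt products excised by Drosha/Dicer from 60–80 nt
hairpin precursors. In deep-sequencing data this leaves a characteristic
signature: reads pile up in discrete *stacks* at the 5p and 3p arms of a
genomic hairpin, most reads on an arm share the same 5′ nucleotide
(consistent Dicer processing), one arm usually dominates the other in read
count (arm selection, often by an order of magnitude or more), and a minor
*star* stack from the opposite arm corroborates processing from a duplex.
The pipeline turns each part of this signature into a score component and
calibrates the score threshold against sequence-composition-preserving
permutations of the candidate windows.

## Preprocessing

Reads are quality-filtered (default: any base below Q20, or an `N`, drops
the read; the criterion is configurable because published datasets rarely
state theirs precisely), then the 3′ adaptor is clipped. The clipping rule
is deliberately conservative at the boundary: any terminal adaptor prefix
of two or more nucleotides (or a full internal adaptor) is removed from its
earliest occurrence, while a single terminal base matching the adaptor's
first base is left in place, since one matching nucleotide is most likely
genomic. Clipping is applied to a fixpoint so that the operation is
idempotent — a clip can expose a further terminal adaptor prefix when the
insert itself ends in the adaptor's first bases. The size filter defaults
to 18–26 nt, bracketing the 20–24 nt mature range with a small margin; the
window is a parameter because size-selection protocols differ.

## Stacks, excision, and the hairpin gate

Mapping is exact-match on both strands (short mature reads are expected to
match the reference perfectly; mismatch tolerance would mostly admit
cross-mapping between paralogs). Reads mapping to more than `max_loci`
(default 50) loci are flagged and excluded from stack formation, but their
locus counts are retained — multi-locus behaviour is exactly what the later
repeat screen reasons about. Overlapping same-strand alignments chain into
stacks capped at 40 nt of span; each stack is excised in two ~107 nt
windows (stack as 5p arm: 15 nt upstream / 70 nt downstream flanks in
transcription orientation; stack as 3p arm: mirrored). No score floor
beyond the 2-read stack minimum is applied at excision, so every discrete
stack is evaluated.

Windows are folded with a stacking-aware Nussinov dynamic program: maximum
total pair weight (GC = 3, AU = 2, GU = 1) plus a +1 bonus per stacked
pair, nested structures only, hairpin loops ≥ 3 nt, deterministic traceback
breaking ties toward 5′-most pairing. This scoring is self-contained and
oracle-verifiable (the test suite checks it against exhaustive structure
enumeration); it is not a thermodynamic free energy, and published
free-energy values are not reproduced — only rank behaviour is relied on. A
thermodynamic folder could be substituted behind the same contract.

The putative mature of a candidate window is the stack's *modal read*
(modal 5′ end, count-weighted modal length) rather than the raw stack
span: loop or background fragments that chain into a stack can inflate its
span well beyond a mature product. A window then passes the hairpin gate
when (i) at least 70% of its pairs nest around a single loop center (the
dominant helix is a single stem-loop), (ii) at least 60% of the mature
bases are paired, and (iii) the mature lies on one arm. The geometry is
assessed within a precursor-sized region anchored at the putative mature
on the hypothesized arm, so base pairs formed entirely by the far excision
flank do not dilute the dominant stem. Arm placement uses pairing
direction — at least 70% of the mature's paired bases must pair with
partners downstream (5p arm) or upstream (3p arm) — rather than distance
to the loop, because the maximum-pairing fold of a genuine precursor
sometimes decorates it with small spurious side-branches that shift
apparent loop boundaries; pairing direction is insensitive to this.
Permuted controls in the calibration are re-gated with exactly the same
region and mature definition.

## Scoring and signal-to-noise calibration

Hairpin-passing candidates are scored

`S = w_s · z_struct + w_f · f_consistent + w_r · log2(1 + n_consistent) + w_star · [star]`

with default weights 1, 3, 1, 2. `z_struct` standardizes the fold score
against 25 dinucleotide shuffles of the window (an Altschul–Erickson
Eulerian-path shuffle that preserves dinucleotide counts exactly, so the
null respects local composition such as CpG content). `f_consistent` and
`n_consistent` use a ±2 nt tolerance around each arm's modal 5′ end.

The cutoff is not fixed: for each of 100 rounds, every candidate window is
dinucleotide-shuffled, refolded, re-gated and rescored with its read
components retained, and the signal-to-noise ratio `n_real(S ≥ c) / mean
n_permuted(S ≥ c)` is evaluated on a grid of 1% percentiles of the real
scores. The chosen cutoff is the smallest grid value reaching 40:1, with
the permuted mean floored at 1/rounds when no permuted control survives.
Because a dinucleotide shuffle of a window has the same dinucleotide
composition as the window, the null distribution of fold scores is shared:
the 25-shuffle moments are computed once per window and reused when
rescoring the 100 permuted controls, which makes the calibration affordable
without changing its definition. Discovery and calibration run per library
by default (tissues differ in which genes are expressed, and per-library
calibration matches per-library discovery); a global mode pools all
libraries.

## Homology, screens, and novel validation

Called loci are merged across libraries by genomic overlap, and each merged
locus is reported as the precursor spanned by its 5′-consistent reads. The
consistency restriction matters for duplicate accounting: stray background
fragments inside a window would otherwise perturb the reported precursor
boundaries differently at each copy of a duplicated gene, breaking
byte-identity.

Classification replaces an external BLAST with an internal Smith–Waterman
(match +1, mismatch −2, gap open −5, gap extend −2) and Karlin–Altschul
E-values, with λ solved from the ungapped score system under uniform base
frequencies and K taken from the standard tabulation for +1/−2 (0.621);
gapped alignments reuse the ungapped parameters, a documented
approximation. The scheme is chosen so that hairpins within ~10% divergence
of a reference stem-loop clear E ≤ 1e−7 against a reference of realistic
size while unrelated hairpins do not; the tests verify both directions.
The repeat screen scans the candidate against both genome strands,
projects hits to genomic coordinates (a hairpin matches its own locus on
both strands, since its reverse complement is hairpin-like) and merges
nearby positions into loci; more than 5 loci at E ≤ 1e−6 excludes the
candidate as a likely interspersed or tandem repeat. The ncRNA screen
applies the same threshold against an optional database, a symmetry choice
since published screen thresholds are usually unstated. Novel candidates
must then be detected (≥ 1 perfect mature read) in at least two samples,
have perfect mature reads from both arms, and show > 50% of mature-arm
reads sharing the modal 5′ start.

## Annotation

Byte-identical precursors at distinct loci form copy groups. Names follow
miRBase conventions: conserved genes inherit their best-hit family, novel
genes draw fresh family numbers (default from 8000) in locus order, one
family's distinct matures receive letters, identical matures from different
precursors receive numbered iso-miR suffixes, and identical precursors
share one name. All suffix assignment is ordered by (contig, coordinate),
making names deterministic. Arm dominance uses a 2-fold threshold —
"balanced" covers genes whose arms are within 2× of each other; the
threshold is a parameter since arm-selection strength varies continuously.
Clusters are same-contig, same-strand chains with inter-precursor gaps
(end-to-start) strictly below 10 kb; cluster groups collect clusters
sharing an ordered family signature along the transcription direction, and
conservation is a family-multiset containment test against a bundled
reference cluster table with letter/copy suffixes harmonized away.

## Expression

Counting is deliberately strict: only reads exactly equal to a mature
sequence count, and a read matching two genes' matures counts for both.
Size factors are total miRNA counts scaled by their geometric mean — the
stated normalization of the original analysis style, not median-of-ratios.
The one-tissue-versus-rest test is a conditional exact test on summed
counts with negative-binomial group distributions, moment-matched from a
method-of-moments common dispersion across miRNAs (per-gene dispersion is
unidentifiable with one focal sample against eleven), falling back to the
conditional binomial when the data are sub-Poisson. Fold changes are
reported rest-over-tissue (tissue-enriched genes are negative), infinite
when a group mean is zero (no pseudocount), and BH-adjusted within each
contrast. Total-count normalization has a known composition artifact: a
library dominated by a few highly expressed genes (the brain library here)
depresses its other genes' normalized values, which can yield modest
spurious calls in that contrast; the planted signals exceed this artifact
by many orders of magnitude.

## The synthetic study and what it shows

The generator's defaults define a twelve-library, nine-tissue study on a
500 kb, 20-contig genome at 50,000 reads per library: ten conserved
families (one heart-restricted; a brain-enriched 212/132-like cluster pair
duplicated identically on two contigs; two further families planted as
identical two-copy duplicates), four novel genes (one restricted to the two
liver libraries), one repeat decoy hairpin at 8 loci, and one structural
ncRNA. Hairpins are STEM(26–30) + LOOP(8–15) + revcomp(STEM) with 1–3
mismatches; one mismatch is forced at the stem position complementary to
the middle of the 5p mature because a perfect inverted repeat would let
mature reads exact-match the antisense strand of their own locus, making
the transcribed strand unidentifiable from exact mapping — real precursors
essentially always carry internal mismatches. Reads carry a 20:1 (or
inverted, or balanced) arm ratio, 5′ jitter (80/15/5% at 0/±1/±2 nt), 2%
loop fragments, and the 21-nt adaptor appended and truncated to the fixed
32 nt read length. Expression weights are drawn per tissue (log-normal,
sd 0.25) and shared by replicate libraries, which add smaller library-level
noise (sd 0.08); the degradation background (random genome windows plus
ncRNA fragments) is 5% of each library, reflecting adaptor-ligation
protocols that strongly enrich intact small RNAs. Problem sizes (genome,
depth, gene counts) were chosen so the whole study runs in minutes on one
CPU; reduced-size configurations used in some structural tests shrink the
genome and depth but not the evidence model.

Passing the planted-truth checks shows the pipeline correctly implements
its own evidence model: recovery of hairpin genes with Dicer-like read
signatures, exclusion of multi-locus decoys, the conserved/novel split at
the designed divergence, and detection of planted tissue restriction. It
does not establish performance on real libraries, where sequencing error,
RNA modification, incomplete genomes, paralog cross-mapping and richer
background classes (tRNA/rRNA fragments with their own stacking behaviour)
all blur the signature; the screens and thresholds exist precisely because
real data need them more than the simulation does.

## Numerical and design notes

- Coordinates are 1-based inclusive throughout (the native convention of
  the IRanges/GenomicRanges stack used internally); GFF3 output is 1-based
  inclusive by format definition. Minus-strand windows are excised from the
  reverse complement so precursors always read 5′→3′.
- Identical windows recur across libraries; fold results and shuffle-null
  moments are memoized per window sequence within a run. Results are
  identical with or without the cache for a fixed seed and execution order.
- Ties: fold traceback prefers 5′-most pairing; alignment traceback
  prefers diagonal over vertical over horizontal; the score cutoff is
  inclusive; representative windows per merged locus break score ties
  deterministically.
- Degenerate inputs: empty reads trim to empty; a homopolymer has exactly
  one dinucleotide-preserving arrangement and shuffles to itself;
  zero-total libraries get `NA` size factors with a warning; a candidate
  with no reads is a contract violation and errors.
- The per-library calibration's warning path (no cutoff reaches 40:1)
  returns the maximum grid value flagged with `warning = TRUE` rather than
  failing, so a weak library degrades gracefully.
- The interface is a set of R functions (`run_simulate()`,
  `run_discovery()`, `report_tables()`) plus `scripts/acceptance.R`; the
  package is designed to be driven from R scripts rather than a shell CLI.

## Known limitations

Exact-match mapping cannot place reads from loci absent from the assembly;
the local-alignment screens use ungapped Karlin–Altschul parameters for
gapped alignments; the folding score is combinatorial, not thermodynamic;
common-dispersion testing understates per-gene variability for genes with
unusual dispersion; and total-count normalization carries the composition
artifact discussed above.
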