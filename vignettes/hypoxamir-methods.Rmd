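---
title: "Methods: models, parameters and design choices in hypoxamir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in hypoxamir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind each pipeline stage, the
parameters that matter (units, defaults, rationale), what the synthetic
data does and does not emulate, and the design decisions taken where the
method leaves room. It states no empirical result that the package's test
suite or `scripts/acceptance.R` does not itself compute.

## Preprocessing

Reads are 3'-adapter-ligated inserts. `trim_adapter3()` returns the read
prefix before the *leftmost* window at which an adapter prefix of at
least `min_overlap` nucleotides (default 8) matches with at most
`max_mismatches` (default 1) Hamming mismatches. Reads without such a
match are discarded rather than passed through untrimmed: in this
protocol every genuine insert is adapter-ligated, and an untrimmed read
is either read-through genomic sequence or a failed ligation, both of
which would contaminate the tag space. Length filtering (inclusive
16–35 nt) runs after trimming; `collapse_reads()` then aggregates
identical inserts into tags. The *total clone count* — the sum of all tag
counts — is the TPM denominator, so it is fixed before any annotation
step can drop tags.

## Elimination annotation

A tag belongs to the first class in the fixed order
mature miRNA → ncRNA → piRNA → rRNA/mRNA → exon → intergenic/intronic
that matches it. The mature stage demands exact (0-mismatch,
U/T-insensitive) identity; all later stages allow ungapped substring
alignment with up to `max_mismatches` (default 2) Hamming mismatches —
forward strand for transcript databases, both strands for the genome.
Ungapped matching is deliberate: in 16–35 nt tags an indel is
indistinguishable from an isomiR end-shift, so gapped alignment would
blur the class boundaries the hierarchy is meant to draw. The ncRNA
database includes the precursor sequences (as real ncRNA collections
do), which is what absorbs isomiR variants at the ncRNA stage instead of
letting them leak into novel-miRNA discovery.

Ties are resolved deterministically: fewer mismatches first, then
subject in lexicographic name order, then `+` strand before `-`, then
the leftmost position. Coordinates are handled 1-based inclusive
throughout (the IRanges/GFF3 convention of this ecosystem), so no
conversion happens at the GFF3 boundary.

Exactly matching intergenic/intronic tags are extracted with
`flank = 70` nt on either side as candidate precursor windows; the flank
is sized to cover a full hairpin arm plus loop on whichever side of the
tag the rest of the precursor lies.

## Quantification and differential calls

TPM is reads per million clone count; RPKM here is TPM divided by the
mature length in nucleotides, so `RPKM * L = TPM` holds exactly and the
two scales give identical fold changes (the length cancels between
conditions). The fold change uses a pseudocount of one raw read added to
*both* counts *only when either is zero*: condition-specific miRNAs get
finite folds without perturbing abundant ones. The differential
threshold is 1.5 with strict inequalities — FC exactly 1.5 is
"unchanged" — because the threshold is defined as the minimum change
that *counts as* differential.

TPM measures relative abundance. The pipeline therefore assumes the
two libraries have broadly comparable composition; a condition that
globally shifted total small-RNA content would compress or inflate every
fold. This is the standard caveat of single-library (no-replicate)
fold-change calling; the package deliberately does not fit a variance
model, since the design it implements has one library per condition.

Clusters are chains of precursors on the same contig and strand with
start-to-start distances ≤ 10 kb (the usual miRNA cluster convention); a
cluster is co-regulated when it has at least one regulated member and
all regulated members share a direction.

## isomiR grouping

A tag joins a mature miRNA's isomiR family when the maximal prefix of
the tag that occurs in the precursor aligns with a 5' offset within ±3
nt of the anchor start, the templated 3' end lies within ±4 nt of the
anchor end, and the unmatched 3' suffix (non-templated addition) is at
most 2 nt. These bounds quantify "a few nucleotides of end
heterogeneity" generously enough to capture the simulator's variant
grid with margin, and are configurable. A tag that exactly equals
another miRNA's mature sequence is excluded — exact annotation wins over
isomiR membership. The representative is the variant with the highest
total count, ties broken toward the lexicographically smaller sequence
so the choice is reproducible.

One canonicalisation subtlety: a non-templated addition whose base
coincides with the next templated base is indistinguishable from a
templated extension. Grouping and the simulator's ground truth therefore
both aggregate variants *by sequence*, which is the observable unit.

## Folding and the novel-miRNA filter

`fold_hairpin()` maximizes total pair weight (GC = 3, AU = 2, GU = 1)
over nested structures with a minimum hairpin loop of 3 nt — an exactly
testable optimum (the suite checks it against exhaustive enumeration)
that preserves the geometric decisions the precursor filter needs, at
the cost of thermodynamic realism. The traceback is deterministic:
pairing the smallest admissible `i` with the smallest partner is
preferred whenever it attains the optimum.

Pure pair maximization has one pathological habit: any two chance
complementary bases with three intervening nucleotides form a
"free" hairpin, so optima are maximally branchy. The folder therefore
takes a `hairpin_penalty` (default 0, preserving pure maximization):
each terminal-loop closure costs `q`, so a helix must pay for the loop
it opens, as in thermodynamic models. Implementing the penalty needs the
standard three-matrix decomposition (closed / at-least-one-pair / best),
because a helix amortizes the penalty across its stacked pairs and
intermediate scores must be allowed to go negative.

`evaluate_precursor()` passes a candidate iff (a) the stem pair score is
at least `min_score = 25`, (b) the structure is a single stem-loop with
a terminal loop of 3–20 nt, (c) the mature does not intersect the
terminal loop ("from the stem, not the loop"), and (d) at least 60 % of
mature positions are paired. Two scopes are offered. `scope = "global"`
applies (b) to the whole structure, which is the right reading when the
input is a precursor-extent sequence. The default `scope =
"mature_stem"` instead excises the maximal simple stem-loop containing
the mature (walking outward from its terminal loop to the first
multiloop branch point) and applies the rules there: a candidate
*window* (tag ± 70 nt) carries ~70 nt of unrelated flank whose own small
hairpins would otherwise veto every genuine precursor. `predict_novel()`
additionally folds a small grid of padded subwindows (pads 10/40/70 nt,
penalty 8) and accepts if any passes, because the hairpin may sit
asymmetrically around the expressed tag (5p versus 3p arm). This scan is
deliberately recall-oriented; the discriminative content lives in the
score, loop and pairing rules, and the specificity observed against
dinucleotide-shuffled sequences is measured by the test suite and the
acceptance script rather than asserted here.

## Promoter HRE scanning

Promoters are the `span = 5000` nt upstream of the precursor 5' end
(strand-aware, truncated at contig bounds). The motif is the HIF-binding
core consensus RCGTG scanned on both strands with overlaps allowed;
offsets are negative, −1 being the base immediately upstream. The
pattern is a configurable IUPAC string, so a position-weight-matrix
scanner could be slotted in behind the same interface; consensus
scanning was chosen because the matrix libraries used by
transcription-factor prediction services are proprietary, and the core
consensus is the part of the site that is unambiguous. Consensus
scanning necessarily reports more (chance) hits than a thresholded
matrix would; downstream summaries count miRNAs with at least one hit.

## Seed matching and target consensus

`find_seed_sites()` implements the canonical site taxonomy: the 6mer
core is the reverse complement of miRNA positions 2–7; a match to
position 8 immediately 5' of the core gives 7mer-m8; an adenine
immediately 3' of the core (opposite miRNA position 1) gives 7mer-A1;
both give 8mer; priority 8mer > 7mer-m8 > 7mer-A1 > 6mer, mutually
exclusive per locus. The A1 adenine is a property of the site, not of
the miRNA sequence, following the canonical taxonomy.
`consensus_targets()` keeps genes supported by at least `min_support =
3` of the supplied sources; external prediction programs are inputs
(named gene lists), not reimplementations — the implemented contribution
is the consensus rule, with the built-in seed matcher usable as one
source.

## The synthetic-data generator

The generator is the package's instrument for making every stage
testable; its defaults define the simulated study conditions.

* **Design.** Twelve miRNAs: four induced 4-fold (baseline mean 50
  reads), one miR-210-like species induced 25-fold (baseline 20), two
  repressed 4-fold (baseline 600), five unchanged (baseline 150). The
  first five lie in two genomic clusters; strands alternate among the
  singletons. Up- and down-regulation approximately balance total
  read mass: TPM is compositional, and a grossly unbalanced design
  would distort every fold by the ratio of library totals. Background
  piRNA, rRNA/mRNA-fragment and exon-fragment classes are anchored to
  the baseline miRNA mass (5 %, 8 % and 5 % scale factors), identical in
  expectation across conditions — structural RNA content does not track
  the induction of specific miRNAs.
* **Counts.** Read counts are negative binomial with variance
  `(1 + dispersion) * mean` (size = mean/dispersion), i.e. `dispersion`
  is overdispersion relative to Poisson and 0 recovers Poisson. This
  parameterisation is the one under which the package's stated
  calibration targets (high recall on 4-fold plants *and* a low null
  call rate at the 1.5 threshold, both at the default dispersion 0.05)
  are jointly achievable; with a quadratic DESeq2-style dispersion of
  0.05 the null fold-change noise alone would exceed the threshold far
  too often, at any mean.
* **isomiRs.** The unshifted mature carries probability 0.6; the rest is
  uniform over 5' shifts {−1, 0, +1} × 3' shifts {−2…+2} (minus the
  representative cell), with a single non-templated 3' A/U at rate 0.15
  per read. Sequencing substitution errors default to 0.001 per base
  (an Illumina-like rate); planted-truth tests set the error rate to 0
  so class counts are exactly predictable.
* **Hairpins and HREs.** Two intergenic hairpins (not present in any
  database) are planted with ~60 reads per condition each. Their loop
  is all-A and the five loop-proximal bases of the 5' arm are all-C:
  loop adenines then have no pairing partner near the loop, making the
  planted stem-loop the unambiguous fold optimum — the generator plants
  *clean* hairpins by design, so filter sensitivity is a statement about
  the filter, not about folding ambiguity. One to three RCGTG motifs are
  planted at known offsets within 5 kb upstream of each induced
  precursor, avoiding collisions with loci and with each other.
* **Determinism.** One master seed; the reference and each library draw
  from seeds derived at fixed offsets. The same seed reproduces FASTA,
  GFF3 and FASTQ output byte for byte.

What the generator does **not** emulate: ligation and PCR bias, quality
score structure, multi-mapping repeat families, spliced or antisense
transcription, A-to-I editing, and genuinely ambiguous (bulged,
asymmetric) precursor folds. Passing the planted-truth suite therefore
demonstrates that the implementation recovers what it is specified to
recover under controlled conditions; it does not certify performance on
the messier structure of real libraries.

## Problem sizes

The test suite and the acceptance script run the full pipeline on
libraries of roughly 5,000–6,000 reads per condition over a 150 kb
single-contig genome, across 20 simulation seeds, with 100-sequence
folding-oracle comparisons and 50 hairpin/shuffle pairs. These sizes
were chosen so that planted effects are comfortably detectable at the
default dispersion while the whole suite re-runs in minutes, which keeps
the feedback loop for development and review tight.

## Known limitations

* Fold-change calling has no replicate-based error model; calls near the
  1.5 threshold are sensitive to sampling noise at low counts.
* The folding model scores pairs, not stacking energies; structures
  with many short alternative helices can fold differently from a
  thermodynamic prediction, and the window scan is recall-oriented.
* Consensus RCGTG scanning reports all core matches; it cannot rank
  sites the way a calibrated matrix or ChIP evidence would.
* The elimination hierarchy's database precedence (ncRNA before piRNA
  before rRNA/mRNA) is fixed but, like every stage parameter, exposed in
  the configuration.
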