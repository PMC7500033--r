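---
title: "Detecting and modelling mitochondrial DNA deletions with mitoarc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and modelling mitochondrial DNA deletions with mitoarc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoarc)
```

## The problem

Human mitochondrial DNA (mtDNA) is a 16.6-kb closed circle present in
hundreds to thousands of copies per cell. Cells carry mixtures of wild-type
and mutant molecules (heteroplasmy), and acquired deletions — molecules
missing an arc of the circle — accumulate in postmitotic tissue with age
and in mitochondrial disease. mitoarc detects such deletions from
paired-end short reads, converts junction read counts into per-species
population frequencies and an overall *ablation* level (the fraction of
mtDNA sequence lost to deletions, as opposed to *depletion*, the loss of
whole circles), annotates each junction's sequence context, summarises
deletion patterns across samples, and fits Monte Carlo models of
replication-coupled deletion formation to the positional distribution of
deletion termini.

## Coordinates and deletion identity

All coordinates are 1-based and inclusive on `[1, L_u]`, where `L_u` is
the genome length (16,571 bp for the bundled reference). A deletion is
identified by the positions of the **last missing bases** in the
light-strand 5' direction (`ls5`) and the heavy-strand 5' direction
(`hs5`); both termini are inclusive, so the well-known "common deletion"
with termini (8471, 13447) removes 4977 bp. This symmetric convention
deliberately avoids implying a direction of deletion formation. Spans
whose deleted arc crosses reference position 1 carry an explicit `wraps`
flag rather than being encoded by `ls5 > hs5`, which keeps the
non-wrapping invariant (`ls5 <= hs5`) simple.

When a deletion sits in a repeat context, several (ls5, hs5) pairs
describe the same molecule. `left_align()` shifts a span downward while
the base before `ls5` equals the base at `hs5` (circularly) — the
transformation that provably preserves the post-deletion sequence — and
the leftmost representation is canonical. All detection output is
left-aligned, which is what makes exact-junction matching (e.g., in
background subtraction) sound.

## Split-read detection on a circular genome

Reads are aligned against two copies of the reference arranged in tandem,
so alignments crossing the coordinate origin are ordinary contiguous
alignments, and indices are folded back onto the circle afterwards
(`canonicalize()`). The aligner (C++ core) uses exact 16-mer seeds and
ungapped extension tolerating up to 2 mismatches, with extension ends
trimmed to exact matches:

* one anchor covering essentially the whole read → contiguous alignment;
* two anchors at distinct loci in consistent orientation → a candidate
  junction. The breakpoint is placed by scanning the overlap window for
  the split that maximises total matches to both loci, which resolves
  junction-flanking microhomology deterministically (homologous bases go
  to the left anchor; `left_align()` then canonicalises). The implied
  deletion length must lie in `[1, L_u - 1]`: a deletant retains at least
  one base, and the apparent "deletion of the whole circle" that a
  doubled reference would otherwise admit is rejected.
* reverse-complement alignment is attempted when the forward orientation
  fails; coordinates are always reported on the reference axis.

Anchors shorter than `min_anchor` (default 20 bp) are not trusted on a
16.6-kb genome, so junctions with a flank shorter than that are
uncallable by design; such reads count as contiguous for depth purposes.
Junctions inside perfect repeats longer than the read length cannot be
observed as split reads at all — they are a documented blind spot, not a
miscall, because the repeat-unit contraction leaves no unique anchor.

Mate pairs are reconciled: a junction reported by one mate is suppressed
when the partner mate aligns contiguously **across** the junction locus,
since both mates derive from one fragment and cannot disagree. "Across"
requires a margin (6 bp) on both sides of the junction boundary so that
mismatch-tolerant alignment tails that drift a base or two past a
junction by chance matches (probability 1/4 per base) do not manufacture
conflicts. Each supporting mate contributes one read to the junction's
support `x_i`; a pair whose two mates both show the junction contributes
two, the literal reading of "reads spanning the junction".

Reads are pre-filtered on mean Phred quality (default 20), applied per
pair — if either mate fails, the pair is dropped — which is slightly
stricter than per-read filtering and keeps the mate logic simple.

## From counts to frequencies

The model assumes sequencing depth is proportional to population
fraction, and that each molecule carries at most one deletion (a
documented simplification that degrades gracefully at very high
cumulative deletion loads). For deletion *i* with supporting reads
$x_i$, mappability factor $\delta_i$, deletant length $L_i = L_u -$
(deleted bases), mean read length $L_r$ and total mapped reads $r_t$:

$$
f_i \;=\; \frac{L_u\,\delta_i x_i}
{L_r r_t \;-\; \sum_j L_j \delta_j x_j \;+\; \sum_j L_u \delta_j x_j},
\qquad
f_u = 1 - \sum_i f_i ,
$$

with the upper-bound approximation $f_i \lesssim L_u \delta_i x_i / (L_r
r_t)$ reported alongside (the exact value can never exceed it, which the
test suite asserts as an invariant). The mappability factor is the median
control-sample depth divided by the mean control depth at the two
junction-defining positions; with no control sample $\delta_i = 1$
(recorded in the output), and when both junction positions have zero
control depth the factor is capped at 10 and flagged, since an unbounded
correction would let single reads dominate ablation.

One finite-detector correction is applied before the formula: the model
equates $x_i$ with the average depth of species *i*, i.e., the count of
*all* reads overlapping the junction, but a split-read caller only
detects reads with at least `min_anchor` bases on each side. The
detectable fraction is exactly $(L_r - 2\,\texttt{min\_anchor} + 1)/L_r$
(111/150 at the defaults), so detected counts are rescaled by its
reciprocal. Without this correction every recovered frequency would be
biased low by ~26%.

Background subtraction uses a control sample (a cultured-cell catalog in
practice): the per-junction mean control frequency is subtracted with a
floor at zero. Matching is by exact left-aligned junction — no fuzzy
window is needed because representations are canonical.

Ablation at biopsy is $a = \sum_i f_i (L_u - L_i)/L_u$ over
background-subtracted frequencies; it equals (to numerical identity) the
area above the per-position remaining-fraction curve. Ablation at
symptom onset is projected linearly through zero at birth:
$a_\mathrm{onset} = a\, y_\mathrm{onset}/y_\mathrm{biopsy}$ — a stated
first approximation, not a growth model. Feature-set ablation sums the
frequency of deletions removing any base of a named feature set, and
independent sets combine multiplicatively
($1 - \prod_s (1 - a_s)$), the form that best tracks histological
respiratory deficiency when COX genes are combined with
transcription/translation machinery.

The sample-geometry helper (`multi_fiber_boundaries()`) reproduces the
order-of-magnitude chain from sample mass to fiber count: a 20-mg sample
at 1.06 mg/µL is ≈ 18.9 µL; as a cube that face is ≈ 7.09 mm²; at
3630 µm² per fiber cross-section that is ≈ 1950 truncated fibers, so any
species above ≈ 5.1 × 10⁻⁴ of the population must occupy multiple
fibers.

## Sequence context

Terminal microhomology (TMH) is the total length of identical sequence
shared between one deletion terminus and the flank of the other — the
direct repeat at the junction. It is computed as the sum of two exact
extensions (rightward from the first deleted base vs the first retained
base after the junction; leftward from the bases preceding each
terminus), circularly indexed and capped at 100 bp per side (no
biological TMH approaches this). The sum-of-extensions definition is the
one that reproduces the common deletion's 13-bp direct repeat and is
invariant under the choice of equivalent representation, which the suite
asserts. Only perfect identity counts; mismatch-tolerant homology is
deliberately excluded. A deletion whose TMH is at least its own length
is a contraction of a perfect local repeat (e.g., the control-region
poly-C runs) and is flagged as such. The qualitative mechanism classes
are exposed as a convenience mapping — class 1: TMH ≤ 3 (ligation-like),
class 2: TMH ≥ 10 (slippage-like), class 3: the intermediate residue —
with the caveat that the class boundaries are descriptive, not fitted.

## Pattern summaries

For cross-sample analyses each sample's breakpoints are binned into an
80 × 80 matrix by (ls5-bin, hs5-bin), genome positions divided into 80
equal bins (the last bin absorbs the 11-bp remainder of 16,571/80).
Two exclusion filters precede binning: spans under 40 bp (the scale of
short-read indel artifacts), and a T-shaped region of the terminus plane
(ls5 ∈ [1, 5700] × hs5 ∈ [15949, 16156], and ls5 ∈ [3107, 3314] × hs5 ∈
[12000, 16156]) where commercial DNA preparations show age-independent
artifact peaks. Both are configurable for non-default references. The
matrix is normalised by total binned weight; by default each breakpoint
is weighted by its supporting reads (`x_i`) — pattern analyses operate
on the composition of the *deletion pool*, not on population
frequencies — with frequency weighting available.

Samples are clustered by complete-linkage hierarchical clustering on the
Euclidean distance between flattened matrices; samples are sorted by id
first so the tree is input-order invariant, and the tree is exportable
as Newick. PCA is mean-centred but unscaled (the inputs are already
normalized fractions on one scale); component vectors have unit norm and
are reshaped back to the bin grid as weight maps. Selection of a
representative sample subset for PCA is the caller's decision, not
automated — idiosyncratic samples otherwise consume leading components.

Deletion length spectra sum background-subtracted frequency by deleted
length (1-bp or 400-bp bins), flagging the > 15-kbp tail where, on a
circular reference, junctions of very large deletions are
indistinguishable from insertions. Terminus histograms sum LS5' and HS5'
frequencies separately in 250-bp bins, excluding TMH ≥ 10 junctions; in
replication-stressed samples they show the "double bowtie": LS5' mass
falling off from oriL into the major arc and HS5' mass falling off from
the 7S-DNA 3' terminus.

## Monte Carlo models of deletion formation

Six generation schemata share one skeleton — draw a start point, draw an
end point, filter — and at most five adjustable parameters (`scale`,
`sel`, `mu`, `sigma`, `shape`), with clockwise and counterclockwise
directions sharing parameters. The distribution assignments are this
package's concrete reading of the six verbal mechanisms (the
replication-independent pair, unidirectional H-strand synthesis with and
without light-strand origin selection, bidirectional synthesis, and
asynchronous strand displacement):

| model | start | length | directions | hard origin | soft selection |
|---|---|---|---|---|---|
| 1 | uniform | implied (uniform end) | both | — | 7S-3' |
| 2 | uniform | Normal(mu, sigma) | both | — | 7S-3' |
| 3 | 7S-3' − Exp(shape) | Normal | cw only | 7S-3' | oriL |
| 4 | 7S-3' − Exp(shape) | Normal | cw only | 7S-3' | — |
| 5 | 7S-3' ± Exp(shape) | Normal | both | 7S-3' | oriL |
| 6 | cw: 7S-3' − Exp; ccw: oriL + Exp | Normal | both | own origin | other origin |

Candidates are filtered in order: impossible lengths (< 1 bp or > L_u)
are removed; replication-anchored models hard-reject candidates that
impinge on (i.e., delete) their own anchoring origin; candidates
covering a *selected-against* origin survive with probability `sel` (a
uniform draw per candidate). Model 5 is given the same exponential start
offset as models 3, 4 and 6: anchoring every deletion exactly at the
origin would put all terminus mass in a single bin and make the model
trivially refutable, and the offset keeps it within the five-parameter
limit. Model 4's `sel` is structurally inert — its only selected-against
origin is also its own hard-rejected origin — and is reported as such
rather than removed, keeping the parameter inventory uniform. "Impinge"
means the deleted arc covers the single-bp origin position. Origin
default positions are oriL = 5780 and 7S-3' = 16070, the terminus-ridge
positions observed in diseased muscle; both are configurable.

Simulation draws candidates in adaptively sized vectorised chunks until
the requested number are *accepted* per direction (the convention chosen
for "n simulated deletions"; 240,000 per direction by default), records
rejection counts by rule so that attempts = accepted + rejected exactly,
and aborts with a diagnostic when the acceptance rate falls below 10⁻⁴.

### Fitting

`fit_model()` minimises the log-domain least-squares difference between
simulated and observed terminus densities over the model's free
parameters. The pseudo-count added before taking logs is half the
smallest nonzero observed bin — small enough not to distort occupied
bins, large enough to keep empty bins finite. The linear `scale` is
profiled out by a one-dimensional search inside the objective. Each
objective evaluation simulates with a fixed per-evaluation seed (common
random numbers), making the surface deterministic. Because that surface
still has a Monte Carlo noise floor that manufactures shallow local
minima along a curved sel/mu/shape ridge, the optimiser is staged: a
Latin-hypercube pre-screen (16 points per free dimension) picks starting
basins; Nelder-Mead runs in bound-normalised coordinates (all parameters
mapped to [0, 1], clipped) from the two best pre-screen points; and two
chained refinement rounds re-inflate the simplex around the incumbent at
a larger simulation size, each refinement round using a distinct
common-random-number stream so that a noise artifact of one stream is
not revisited by the next — the lower noise floor separates the true
minimum from ridge artifacts. Recovery of (mu, sigma) to within 10% and
sel to within 0.1 on self-generated strand-displacement data is part of
the acceptance suite, as is the requirement that the strand-displacement
model outranks the five alternatives by log-domain R² on data it
generated. `compare_models()` reports that ranking.

## The synthetic-data generator

`population_spec()` / `generate_reads()` emulate the sampling physics
the frequency model assumes: a population of circular molecules
(wild-type, deletants with specified frequencies, optional plasmid-like
spike-ins), fragments drawn with probability proportional to abundance ×
molecule length with uniformly random circular start positions, paired
reads from fragment ends, and per-base substitution errors. Every
junction-spanning read is recorded in a truth table, so the caller's
support count can be audited against ground truth (reconciliation can
only suppress, never add). In the strict profile (default) no errors are
placed within ±5 bp of a junction inside a read, isolating pipeline
logic from error modelling; the realistic profile (window 0) applies
errors everywhere. Fragment sizes are Normal (mean 350, SD 50 bp),
truncated below at the read length, redrawn (and counted) when longer
than the molecule.

What the generator does **not** emulate: tagmentation insertion bias, GC
bias, chimera formation during library preparation, nuclear
mitochondrial segments (NUMTs), or multi-deletion molecules. Passing
recovery tests on this substrate therefore demonstrates the pipeline's
arithmetic and calling logic, not robustness to every artifact of real
libraries — the control-subtraction step exists precisely because real
backgrounds are not clean.

The bundled reference is a **synthetic** 16,571-bp sequence (generated
deterministically; `synthetic_mt_sequence()`) with human-mtDNA base
composition and the landmarks the arithmetic depends on implanted at
their human positions: the 13-bp direct repeat flanking the common
deletion and the control-region poly-C tracts. It carries no human
sequence beyond those motifs; any analysis of real data should supply
the real reference FASTA.

## Validation problem sizes and numerical choices

The frequency-recovery validation simulates ten deletant species at
frequencies 10⁻⁴–10⁻¹ and checks that a linear fit of recovered against
true frequencies has slope 1 ± 0.05 with R² > 0.99. The number of
junction-supporting reads, not genome coverage per se, sets the
precision of each recovered frequency (CV ≈ 1/√x_i), and at 2000×
coverage the whole population yields only ≈ 300 junction reads — a ≈ 6%
sampling CV on the slope, incompatible with a ±5% assertion. The
validation therefore runs at 20,000× (≈ 1.1 M read pairs), where the
slope's sampling error is ≈ 2%, making the stated tolerance a ≈ 2.5 σ
check. Monte Carlo validation uses 240,000 accepted deletions per
direction for data generation, fitting simulations of 24,000 per
evaluation with a 120,000 refinement round, and model ranking at 12,000.

Other numerical constants, all documented at their definition sites:
seed k-mer 16 with seeds every 8 bp near read ends; ≤ 2 mismatches per
ungapped extension; `min_anchor` 20 bp; mate-conflict margin 6 bp;
TMH extension cap 100 bp/side; mappability cap 10; deletions > 15 kbp
flagged `possible_insertion`; pattern exclusions (< 40 bp, T-region) as
above.

## Known limitations

* Deletions with a flank shorter than `min_anchor`, or inside perfect
  repeats longer than the read length, are not callable (reported as a
  design property, not silently miscalled).
* The one-deletion-per-molecule assumption biases frequencies at very
  high cumulative loads.
* Frequencies below roughly one junction read per sample are reported as
  zero; collective (not individual) rates are meaningful there.
* The Monte Carlo distribution table is a committed interpretation of
  verbally described mechanisms; alternative shape choices are
  configurable but not fitted.
* No structural variants other than simple deletions (no inversions,
  duplications, NUMT disambiguation), and no base-quality recalibration.
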