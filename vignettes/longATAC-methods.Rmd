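---
title: "longATAC: models and methods"
author: "longATAC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{longATAC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science behind each stage:
the models, their assumptions, the tunable parameters, and the design
choices made where the design was genuinely open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Data model and coordinates

The atomic unit is the **fragment**: one aligned long read of one cell,
held as a `GRanges` subclass (`ScFragments`) with per-fragment cell id,
mapping quality, CIGAR string and split-alignment anchors. Internally
everything is 1-based closed, the native Bioconductor convention;
0-based half-open coordinates are honoured at every format boundary (BED,
fragment tables, the SV table), and VCF positions stay 1-based. Each
fragment contributes exactly two single-bp **Tn5 insertion ends**; the
default +4/−5 shift is the standard ATAC offset correction for the Tn5
dimer footprint (the choice is exposed because different upstream
pipelines bake in different conventions). The default mapping-quality
floor is 30 — a common threshold for long reads that must support
variant evidence; it is a knob, not a claim.

## The fragment model behind the simulator

Every analysis stage is validated against synthetic experiments with
planted truth, so the generative model matters. A fragment anchors **one
Tn5 insertion** (its left end) either inside an accessible peak (with
probability `fracPeakReads`, default 0.5 — a FRIP-like quantity in the
range of good ATAC libraries) or uniformly in the background; the other
end follows from a log-normal fragment-length law
(`fragMedianBp = 4500`, matching the 4–4.9 kb per-library medians this
kind of protocol reports; `fragSigma = 0.45` gives visible kb-scale
tails while keeping essentially all mass below ~20 kb). Per-cell yield
defaults to 2000 fragments — comfortably under the ~10,000 reads/cell
ceiling of a plate-based long-read run, which
`downsamplePseudobulk()` accepts as a configuration for throughput
titrations.

Why *one* anchored end rather than drawing both ends from the
accessibility profile? Because the co-accessibility statistic (below)
conditions on left-anchored molecules and asks whether their right ends
reach a second peak more often than the length law predicts. If the
generator enriched both ends independently, nearby peak pairs would
share molecules at elevated rates *by construction* — which is precisely
co-accessibility signal, not a null. The anchored model is therefore the
calibratable independent-ends null, and planted co-accessible molecules
(one end drawn uniformly in each peak of a pair, with Poisson count
`(enrichment − 1)·λ0` over the analytically computed null expectation
`λ0`) are the alternative. The cost is mild asymmetry — right ends are
only length-driven — which the QC stages do not depend on.

Layered on top are: haplotypes (each read is maternal/paternal with
probability 0.5, or `aspSkew` when anchored in a planted ASP — the same
mechanism expresses X-inactivation-like maternal skew), SNP allele
observations (each spanned het SNP emits the haplotype allele, flipped
with probability `baseError`), SV evidence (carrier-cell reads spanning
a planted event receive the corresponding `D`/`I` CIGAR operation or a
split anchor, with small breakpoint/length jitter emulating alignment
noise), per-cell CNV sampling intensity proportional to copy number, and
cross-species doublets (merged pairs with ~50/50 fragment mixtures,
against a 0.5% background mislabel rate for singlets).

What the generator does **not** emulate: base-level sequences and
nanopore error profiles, mappability and GC biases, chromatin contact
structure, PCR duplication, or peak-width/shape heterogeneity. Passing
recovery tests therefore demonstrate that the algorithms are correct
under idealised noise of the stated magnitudes, not that real-data
performance will match; thresholds that depend on alignment artefacts
(e.g. SV breakpoint tolerances) should be re-examined on real data.
A single RNG stream seeded once per experiment makes output
byte-identical for a fixed seed.

## QC

TSS enrichment aggregates end counts in 10-bp bins over ±2 kb around
TSSs, strand-oriented; the score divides the centre bin by the mean of
the outermost 10% of bins per side. This is the ENCODE-style
normalisation; published work in this area shows the profiles without a
formula, so the window and bin are explicit parameters. Degenerate
inputs are defined rather than errors: no ends in the flanks gives `NaN`
(with a warning), empty outer flanks with a populated centre give
`+Inf`. Footprint profiles are the unstranded variant without a scalar.
Doublet classification flags a cell when its minor-species fragment
fraction exceeds 0.1 — published analyses report doublet *counts*, not
the rule, so the threshold is a documented knob; it sits far above the
singlet mislabel noise and far below a genuine 50/50 mixture.

## Peak calling

An explicit local-λ Poisson caller (MACS-like): 500-bp windows advance
by 100 bp; a window with `k` ends is scored by the Poisson upper tail
`P(X ≥ k)` with rate `max(genome-wide, local-10-kb) × window`; windows
need `k ≥ 5` and `p ≤ 1e-5`; called windows merge across gaps ≤ 100 bp
and the peak score is the max −log10 p. Taking the *max* of global and
local rate is the conservative choice: enriched neighbourhoods raise
their own bar, and sparse chromosomes do not fall below the genome-wide
floor. Calling is deterministic; relaxing the p threshold can only grow
the called set. On a uniform background the expected number of
significant windows is bounded by `p_threshold × #windows` (the discrete
Poisson tail makes the bound conservative), which the calibration test
checks at 3× that bound.

## Allele-specific peaks

Reads are haplotyped by counting observed alleles matching haplotype 1
vs 2 over the phased het SNPs they span — crucially, SNPs *outside* the
peak count, because a 4-kb molecule anchored in a 500-bp peak spans
kilobases of flanking sequence. Assignment needs a majority with margin
≥ 1 and consistency ≥ 0.67 (i.e. a 2-vs-1 read passes, 2-vs-2 and 3-vs-2
do not; with a ~2–5% per-base error the expected consistency of a true
assignment is far above the cut). A read supports a peak when one of its
insertion ends falls inside it — the same convention as FRIP — and
counts once per peak.

The test is a two-sided exact binomial against 0.5 per peak with ≥ 10
haplotyped reads, BH-corrected jointly across all tested peaks. The 0.5
null mirrors the symmetric maternal/paternal design of the assay; an
empirical null proportion can be supplied (`nullProp`) for libraries
with global allelic imbalance. `minTotal = 10` guards against
degenerate tests where even a fully skewed peak cannot reach
significance; whether the published analysis corrected per chromosome or
globally is not stated, and the global choice is the stricter,
simpler one.

## Phasing and switch error

Unphased het SNPs are phased from read co-coverage: each co-covered pair
gets edge weight (#cis − #trans); zero-weight (tied) edges are dropped;
each connected component is phased by propagating along its
maximum-weight spanning tree (positive edge: same orientation; negative:
flipped). Greedy MST phasing is deterministic and near-optimal at
ATAC-like coverage; exact MEC optimisation would buy little here and
costs determinism. Switch error is the fraction of consecutive
truth-phased SNP pairs (within one called block) whose relative phase
disagrees — invariant to whole-block flips, as phase orientation is
arbitrary.

## Structural variants

Candidates come from CIGAR `I`/`D` operations ≥ 50 bp and from
split-alignment anchors on another chromosome (TRA, breakpoints = primary
alignment end + anchor position). Single-linkage clustering merges
INS/DEL candidates within 500 bp and size ratio ≥ 0.7, TRA when both
breakpoints agree within tolerance; cluster position/length are member
medians and support is the set of **distinct cells** — ten reads from
one cell are one cell of support. The 500 bp cluster / 1000 bp benchmark
tolerances sit near common long-read SV-merge defaults and are exposed;
single linkage is robust to ONT-scale breakpoint jitter and, with sorted
input, order-invariant. Calling keeps clusters with ≥ 5 supporting
cells; benchmarking matches greedily by breakpoint distance, one-to-one,
and sweeps the cell threshold to trace the precision/recall trade-off.
Inversions and duplications are outside the candidate grammar — the
analysed classes are INS/DEL/TRA.

## Copy number

Fragments are assigned to 1-Mb bins by midpoint (long fragments spanning
a bin edge are never double-counted). Depth of cell *i* in bin *j* is
`raw_ij / total_i / ref_j`, rescaled so each cell's autosomal median
equals the ploidy; integer CN rounds half away from zero, and the
continuous depth is always reported alongside. The per-bin reference
removes bin-specific rate differences; the default is the median across
cells (requiring ≥ 10 cells), which is the right reference for subclone
detection but *absorbs events shared by every cell* — a male X at CN 1,
say. For such designs a `"uniform"` (bin-width) or externally supplied
reference is the correct choice, and the package makes the trade
explicit rather than guessing. No GC/mappability correction is applied
(the synthetic data has none); a per-bin covariate can be passed as the
external reference. Segmentation (CBS/HMM) and subclone discovery are
out of scope — groups are an input.

## Co-accessibility

Candidate pairs are same-chromosome, non-overlapping peaks whose centre
distance is ≤ 2× the local median read length (median over fragments
with midpoints within a 100-kb window around the pair midpoint, falling
back to the global median below 20 fragments — "local" is not pinned
down by prior work, so the window is a parameter). The published idea is
that co-accessibility alters the length distribution of peak-supporting
reads; the concrete statistic here is this package's own formalisation:
condition on fragments with a left end in A, compute the expected number
reaching B from the empirical length CDF,
`λ = Σ_i [F(B.end − s_i) − F(B.start − s_i)]`, and score the observed
spanning count by the Poisson upper tail, BH across candidate pairs. It
is closed-form, directly operationalises "both ends on the same
molecule", and is calibrated on the simulator's null (see the acceptance
tests). `λ = 0` with a positive observation is flagged and given the
smallest representable p rather than zero. Orientation is fixed (left
end in the left peak); the symmetric count is the same molecules, not
extra evidence. Padding defaults to 0: an end must fall strictly inside
the peak. Cicero-style correlation across cells and loop calling are
non-goals.

## Problem sizes and numerical choices

The validation suite runs, as the package's own choice of study
conditions: ASP recovery on 1000 peaks × 10 replicates with ~50
haplotyped reads per peak (2% ASPs at skew 0.9); a flanking-SNP-only
variant of the same design (SNPs inside ASPs removed before
haplotyping); phasing of 100 SNPs/chromosome over 5 chromosomes at ~20×
coverage and 5% base error; 100 planted SVs at 0.5 cell fraction over
100 cells; CNV recovery at ~200 fragments per 1-Mb bin; co-accessibility
null calibration over ~150–250 candidate pairs plus planted pairs at 3×
enrichment; and a 200,000-end uniform background for peak-caller
calibration. Ties and degenerate cases are decided, not left to chance:
ambiguous haplotype ties stay ambiguous, zero-weight phase edges are
dropped, CN 0.5 boundaries round away from zero, and empty inputs return
empty (typed) results or defined sentinels.

## Known limitations

Beyond the simulator's idealisations listed above: the ASP test assumes
haplotyping errors are symmetric (a systematic reference bias would
inflate one direction); the co-accessibility null assumes fragment
lengths are exchangeable across the genome, so strong regional length
structure beyond what the local-median constraint captures could
miscalibrate it; SV genotyping per cell beyond presence/absence, CRAM
input, indel/multi-allelic VCF records and basecalling/alignment itself
are out of scope.
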