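---
title: "Methods: quantifying transcription-factor convergence in a 2x2 cistrome design"
author: "cistromeConverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transcription-factor convergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistromeConverge)
```

## The analytical problem

A glucocorticoid pulse delivered in the light phase recruits the
glucocorticoid receptor (GR) to chromatin in skeletal muscle, and this
recruitment depends on the circadian activator BMAL1. The evidence for such
convergence comes from downstream quantification of ChIP-seq data laid out
on a 2x2 genotype-by-treatment design (BMAL1-WT vs BMAL1-KO muscle, vehicle
vs prednisone), with three immunoprecipitated factors: GR, BMAL1 and RNA
polymerase II. This package implements that downstream quantification as a
reusable, tested pipeline operating on peak calls (BED), coverage tracks
(bedGraph), motif-site tables and a TSS table — the standard outputs of any
upstream aligner/peak-caller combination:

1. **Motif-site occupancy** — mean library-normalized coverage over windows
   centred on GRE or E-box sites, aggregated across sites, contrasted
   drug/vehicle per genotype (with cross-motif profiles: GR on E-box, BMAL1
   on GRE, computed by the same operation with swapped inputs).
2. **Peak-to-TSS annotation** — nearest-TSS assignment with strand-signed
   distances, region classes, and the fraction of peaks closer than 10 kb
   to a TSS, contrasted between treatments.
3. **Inter-factor co-occurrence** — for each GR peak the distance to the
   nearest BMAL1 summit, binned into [0,300], (300,900], (900,5000] and
   (5000,Inf) bp, with per-bin drug/vehicle fraction ratios and a label
   permutation test.
4. **The convergent-gene screen** — RNA polymerase II signal on TSS windows
   per condition, drug/vehicle fold change per genotype, quadrant
   classification (up in WT but not in KO), intersected with drug-driven GR
   and BMAL1 signal gains within 10 kb of the TSS.

Because the underlying sequencing data are not publicly deposited, the
package ships a synthetic cistrome generator that plants each of these
effects with known sizes, so every stage is verified by parameter recovery
rather than by reference to unavailable raw data.

## Coordinate conventions

Files use the BED convention (0-based, half-open); in memory all
coordinates live in `GRanges` (1-based, closed), the Bioconductor standard,
and conversion happens once at the I/O boundary. Printed literature
coordinates such as `chr5:51553620-51554360` are 1-based inclusive and map
onto `GRanges` directly (`printedRegion()`). All distances and derived
statistics are invariant to this choice. Peak summits absent from the input
default to the floor midpoint of the interval, and all distances are
summit-to-TSS or summit-to-summit: the summit is the sharpest localization
a peak call provides, and using edges instead would make distances depend
on peak widths (an edge-gap variant of the interdistance is available
behind a flag). Nearest-TSS ties are broken by the lexicographically
smaller gene identifier so results are deterministic; peaks on chromosomes
without genes receive an infinite distance sentinel rather than an error.

## Quantification choices

**"Relative signal".** Occupancy on a motif site is operationalized as the
length-weighted mean of library-normalized coverage over the window
`center ± halfwidth` (halfwidth default 200 bp, covering the fragment-size
smear around a site). Whether published figures divide by an input track is
usually unstated; both modes are provided and the default is no input
division, which is the more conservative, oracle-checkable choice. The
per-condition aggregate is a 10% trimmed mean over sites, which tames the
handful of sites that sit under unrelated strong peaks without hiding a
genuine genome-wide shift.

**Pseudocounts.** Fold changes use `(x + eps) / (y + eps)` with
`eps = 0.01` normalized units by default. The pseudocount exists to
regularize noisy, near-empty windows in real data; it is configurable, and
exactness statements about noise-free recovery hold at `eps = 0` (with any
`eps > 0` a ratio of the form `(g*a + eps)/(a + eps)` cannot equal `g`
exactly).

**Bin edges.** Published interdistance ranges "0-300 bp" and "300-900 bp"
overlap at 300. The package declares `[0,300]`, `(300,900]` (closed left
bin including both endpoints, then left-open bins) so every distance falls
in exactly one bin; 300 bp falls in the first.

**Direction of the interdistance.** Nearest-neighbour distance from set A
to set B is not symmetric. The default direction is GR to BMAL1 — the
question asked is "does a GR peak have a BMAL1 peak nearby" — and the
reverse direction can be computed by swapping arguments; the pipeline
reports the GR-to-BMAL1 direction.

**"Gain within 10 kb".** The screen's factor gain tiles
`[tss - 10 kb, tss + 10 kb)` into 400 bp windows and takes
`log2((drug + eps)/(vehicle + eps))` at the window maximizing the drug
signal (ties broken by proximity to the TSS). The windowed-max reading
captures a newly appearing peak anywhere in the span, which matches how
promoter-track gains are read by eye; a mean-over-span alternative sits
behind a flag for users who prefer an integrated measure. Gains are
evaluated in the WT genotype only: the KO lacks BMAL1, so a KO BMAL1
"gain" would quantify antibody background.

**Region classes.** The gene model carries only TSS positions, so region
classes are fixed signed-distance windows: promoter `[-1000, +100)`,
5'UTR proxy `[+100, +1000)`, gene body `[+1000, +10000)`, TTS-flank proxy
`[-10000, -1000)`, otherwise intergenic, applied first-match in that
order. The 5'UTR and TTS-flank labels are declared proxies for exon-aware
annotation, which would require a full gene model; the 10 kb
proximal/distal statistic — the quantity the treatment contrast rests on —
does not depend on these labels.

**Screen thresholds.** The RNA polymerase II up-regulation threshold
(1.5-fold) and the factor-gain threshold (log2 1.5) are declared defaults:
published screens of this design rarely state their cutoffs, so the
package makes them explicit parameters, and selection is monotone
decreasing in each (tested).

## The synthetic cistrome generator

`simConfig()` / `simulateCistrome()` emulate the full 2x2x3 design. The
generator's structural choices:

* **Genome layout.** 2 chromosomes x 5 Mb, 200 genes placed uniformly with
  a minimum TSS spacing of 20 kb (so each gene's ±10 kb screen span is
  unambiguous), 300 GRE (12 bp) and 300 E-box (6 bp) sites, half of them
  placed in promoters (−1000..+100 bp of a TSS, strand sense). TSSs and
  motif centres are snapped to the 50 bp track grid.
* **Signal model.** Tracks are step functions at 50 bp resolution: flat
  background 1, plus Gaussian bumps (sd 75 bp, truncated at 4 sd) at peak
  summits — the scale motivated by a typical chromatin shear band of
  roughly 150-600 bp. Multiplicative lognormal noise (sdlog 0.15 by
  default) is applied per step: coverage is nonnegative and overdispersed,
  and multiplicative noise leaves drug/vehicle ratios unbiased. Tracks are
  emitted depth-matched with normalization factor 1.
* **Planted effects are window-multiplicative.** The drug effect
  multiplies the signal over the bin-aligned quantification window: GRE
  windows x3 in WT and x1.3 in KO (GR track), E-box windows x2.5 in WT
  (BMAL1 track), TSS windows by each gene's planted fold (RNA polymerase
  II track), and the core promoter tile of convergent genes by per-gene GR
  and BMAL1 gain folds (2.5-4x). Scaling the whole window rather than only
  the bump peak makes the planted fold the exact expectation of the
  measured ratio, so noise-free recovery is exact and stochastic recovery
  is unbiased.
* **Identifiability constraints.** Random background peaks are kept out of
  motif-site windows and out of convergent-gene neighbourhoods, and
  convergent genes are drawn from genes whose core promoter tile is free
  of motif windows. Without these exclusions, condition-specific random
  peaks would alias into the planted effects and the recovery tests would
  measure placement luck rather than estimator correctness.
* **Paired condition design.** Vehicle and drug share their background
  peak complement; the drug condition adds proximal recruitment (placement
  rate 0.3 under vehicle shifting to 0.7 in WT / 0.4 in KO — the KO shift
  deliberately blunted) and BMAL1 partner peaks at 0-900 bp offsets from
  40% of WT drug GR peaks. Partner host peaks are kept clear of convergent
  spans so partners cannot shadow the planted promoter gains.
* **Gene classes.** 25 convergent, 25 non-convergent WT-only-up, 20
  shared-up, 20 KO-only-up, the rest null. Up-regulated fold changes are
  drawn from U(2, 4) and unaffected ones from U(0.8, 1.2), leaving a clear
  margin on both sides of the 1.5 threshold so class recovery measures the
  pipeline, not threshold luck. BMAL1 in the KO genotype is simulated as
  nonspecific background (the KO has no BMAL1 protein).

What the generator does **not** emulate: read-level artefacts
(mappability, GC bias, duplicate reads), replicate-to-replicate biological
variance, peak-width variation, correlated noise along the genome, and the
true genomic density of motif matches. Passing recovery tests therefore
demonstrates that the estimators measure what they claim on data with the
declared generative structure — not that any particular biological dataset
satisfies that structure.

## Derived assay measures

The accompanying physiology/bioenergetics formulas are implemented exactly
as defined: weight-normalized work `mass_g * distance_m^2 / time_s^2`;
basal oxygen consumption rate (mean of three baseline reads minus mean of
three rotenone/antimycin reads, per microgram protein); respiratory control
ratio (state III over oligomycin state IV, error on a zero denominator);
13C labeling percentage with background subtraction (floored at zero with a
QC flag, since a fraction cannot be negative — the only clamped quantity;
all other negative results are flagged but reported); qPCR quantities with
a configurable amplification efficiency (default 2, perfect doubling, as
no plate-specific efficiency is usually reported); ChIP-qPCR percent input
with the input dilution correction expressed in cycles (a required
parameter, because the input fraction is experiment-specific). The
circadian reporter amplitude detrends with a centred 24 h running mean
(half-open window, so a periodic component integrates to zero on a regular
grid), splits the trace into cycles at ascending zero crossings, and
reports half the max-minus-min height of the third cycle, roughly three
days into the recording; traces with fewer than three full oscillations
are an error, not a zero.

## Problem sizes and verification

The test-suite simulations use the default desk-scale configuration
(10 Mb genome, 200 genes, 400 peaks per condition; seconds per run) and a
reduced variant for I/O-heavy checks. Interval primitives are verified
against per-base and all-pairs brute-force oracles on hundreds of random
instances; noise-free runs must return planted effect sizes exactly (1e-6);
the default stochastic run must recover the planted convergent gene set
with sensitivity and specificity of at least 0.9, occupancy folds within
10%, and placement rates within binomial error; the permutation test is
checked against exact enumeration on eight-observation instances; and the
full pipeline must be byte-identical across reruns under a fixed seed.
`scripts/acceptance.R` recomputes the headline quantities from scratch for
any seed.

## Known limitations

* The pipeline consumes peak and signal files; alignment and peak calling
  quality are upstream concerns it cannot detect.
* The TSS-only gene model makes two region labels proxies (above); supply
  exon-aware labels externally if they matter.
* The permutation test treats distances as exchangeable between
  conditions; strong chromosome-scale structure could violate this.
* Occupancy aggregates assume library-size normalization is adequate;
  composition effects (one condition globally redistributing signal) are
  not corrected.
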