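---
title: "Diagnosing a hybrid diploid genome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing a hybrid diploid genome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaikit)
```

## The problem

Vegetatively diploid microbes — budding yeasts, and as has recently become
clear, some green algae — experience a characteristic set of evolutionary
forces: allodiploid hybridization (fusion of haploid gametes from two
diverged species), mitotic recombination that shuffles the two parental
chromosome sets, loss of heterozygosity (LOH) that progressively
homogenizes the genome, and aneuploidy. Given a phased diploid assembly
and standard read-level observables, all of these forces leave diagnostic
signatures that can be read off with a handful of window statistics:

* **heterozygosity** between the two haplotypes, computed in windows over
  alignable sites, distinguishes hybrid (percent-scale) from ordinary
  (sub-percent) diploids;
* runs with **no heterozygous site over 1 kb or more** are LOH tracts,
  classed as interstitial, terminal or whole-chromosome by whether they
  touch a chromosome end;
* comparing each haplotype window's divergence to each candidate **parent
  reference** paints the genome by parent of origin; boundaries between
  oppositely-painted runs on the two haplotypes are mitotic-recombination
  switches, reciprocal (crossover) or not (LOH);
* **read depth** in 20-kb windows against a robust genome-wide baseline
  yields integer copy-number calls, whole-chromosome or partial;
* **5mC/6mA modification fractions** anchored at transcription start
  sites reveal nucleosome-linker periodicity of promoter/gene-body
  methylation;
* long-read isoform catalogs are curated by explicit **read-support and
  coding-length rules**, including Kozak-model rescue of ORFs truncated
  at internal ATGs, and antisense lncRNA relationships are classified by
  exonic overlap and promoter geometry.

mosaikit implements each of these procedures as a reusable, tested
function, together with a synthetic allodiploid genome generator whose
truth log makes every stage verifiable by planted-event recovery — no
external data needed.

## The generator and what it emulates

`simulateHybridGenome()` draws an ancestral sequence per chromosome
(default GC 0.64, matching a streamlined algal genome), derives parent P
and parent S by independent per-site substitution (`divP`, `divS`,
defaults 0.0135 each so the parents sit ~2.7% apart — the divergence
regime of the hybrid the defaults emulate), and adds a second substitution
layer on one haplotype of each parent for within-parent heterozygosity
(`hetP` = 0.006, `hetS` = 0.0135, the sub-percent vs percent contrast
between the two parental species). The hybrid starts as haplotype A = P1,
haplotype B = S1 and then receives planted events: reciprocal crossovers,
interstitial/terminal/whole-chromosome LOH (one haplotype's interval
copied onto the other), and whole or partial aneuploidies (recorded as
copy number; depth emission multiplies accordingly).

Design choices worth stating:

* **Substitutions only, no indels.** All eight sequences share one
  coordinate system, which is exactly the situation the window statistics
  assume (they operate on aligned sites). Real assemblies add alignment
  uncertainty that this generator deliberately does not model; the
  `AlignabilityMask` plumbing and the variant false-negative /
  false-positive rates are the knobs that let tests probe robustness to
  missing or spurious calls.
* **Depth is negative binomial** with mean `depthMean × copies` and
  dispersion `depthDispersion`, reducing to Poisson at 0 — the standard
  overdispersion model for read depth. Aneuploidy is emitted as extra
  depth, not as a third haplotype in the variant table, matching the fact
  that the copy-number evidence in the motivating setting is
  coverage-only.
* **Methylation template.** Modification fraction as a function of TSS
  offset: near-zero baseline (0.02) upstream, two 6mA peaks at `period`
  and `2·period` (height 0.5 — ApT methylation is sparser and noisier
  than CpG), and 5mC peaks from `3·period` onward with heights rising
  geometrically to `methPlateau` (default 0.95, the called-fraction
  ceiling at gene-body linker peaks). Peaks are Gaussian with sd 20 bp on
  the fraction scale, clipped to [0, 1]. Observed modified counts are
  binomial given per-site Poisson read numbers. This reproduces the
  *shape* a metaprofile estimator must recover; it does not model
  sequence-dependent site density, 5hmC, or mapping bias.
* **Transcripts.** Isoform mixtures instantiate each branch of the filter
  and the primary-isoform cascade with the correct outcome known by
  construction. Kozak transcripts come in three classes — training
  (strong context, no in-frame upstream ATG), extension (weak annotated
  start, one strong in-frame upstream ATG, no intervening in-frame stop)
  and negative controls (the reverse) — built codon-wise so that the
  planted candidate structure is unambiguous. Context strings sample the
  consensus (GCCGCCACC…ATG…GCG) at probability 0.9, giving a strong/weak
  score separation far above the 4-bit level at which recovery is
  asserted.

Because the generator's truth intervals tile each haplotype chromosome
exactly and every planted event is logged once, recovery tests can assert
completeness (every planted tract/switch/aneuploidy found), soundness
(nothing else found) and precision (boundary errors bounded by the local
inter-het gap, switch positions within one window).

## Window statistics

Windows are non-overlapping tiles anchored at 0 (the motivating analyses
plot one value per bin; a sliding step is configurable), 0-based
half-open, never crossing a chromosome end; the last window may be short.
Heterozygosity is qualifying sites / aligned sites; windows with fewer
than 2,000 aligned sites (of 10,000) are excluded rather than reported
noisily. Site quality below 60 is discarded when a quality column exists;
an absent column is treated as passing, with a warning, so that
assembly-vs-assembly variant tables (which have no meaningful per-site
quality) flow through.

Divergence mode applies the half-weight rule: when a strain's reads are
compared to a reference, a site where only one of the strain's two
haplotypes differs contributes 1/2, where both differ, 1. Heterozygosity
mode weights every site 1 — a self-comparison of two haplotypes has only
heterozygous sites, and halving them would halve the statistic. The mode
is explicit in the function called, never inferred from the data.

Degenerate-site classification enumerates, for each codon position, the
nucleotides preserving the encoded amino acid under the standard code:
reported 0 when only the observed base does, else 2, 3 or 4. A trailing
stop codon is tolerated and labeled `NA`; an internal stop is an error.

## LOH tracts

A tract is a maximal interval with *no* heterozygous site: the open
interior between consecutive het sites (both flanks excluded — this makes
the brute-force oracle unambiguous and pins down the off-by-one at the
1-kb boundary: two het sites 1,001 bp apart leave exactly 1,000 bp of
interior and produce a tract; 999 bp apart do not). Chromosomes with no
het site yield one whole-chromosome tract. A callability guard
(`minCallableFraction`, default 0.5) suppresses tracts that are mostly
unalignable — such regions masquerade as homozygous; set it to 0 to apply
the 1-kb rule literally. Under background heterozygosity *h* per bp the
chance of a spurious ≥1-kb gap is ~e^(−1000·h) per site; at *h* = 0.027
the 10-Mb recovery suite asserts zero false tracts, and called boundaries
overshoot planted ones only by the distance to the nearest flanking het
site (median ≈ ln 2 / h ≈ 26 bp).

Between-strain tract comparison uses greedy reciprocal-overlap matching
(≥ 50% of both lengths, best overlap first, each tract matched once) —
symmetric, deterministic, and standard for CNV/LOH set comparison.

## Ancestry painting

The decision statistic is the signed difference `d_S − d_P` of a window's
divergence to the two parental references, with symmetric threshold
`delta` = 0.01 — midway between the within-species regime
(0.006–0.0135) and the between-species regime (~0.027–0.04), so
informative windows separate cleanly. Windows are `ambiguous` inside the
band and `unassigned` when either comparison fails the aligned-site
filter; neither ever seeds a segment, they only join neighbors.
Segmentation smooths: short P/S runs (< 3 windows) flanked by the same
other label are absorbed, ambiguous runs inherit agreeing flanks.
`delta` and `min_run` have no canonical published values; both are
configurable and carried in the output.

Switch classification pairs label-change boundaries across the two
haplotypes: opposite transitions within one window of each other are a
reciprocal crossover; an unpaired boundary at an LOH tract edge (or
bordering a region where both haplotypes share a label) is nonreciprocal
LOH; anything else is left `unclassified` rather than guessed. The A/B
haplotype labels are arbitrary: painting never attempts to name which
physical haplotype came from which parent genome-wide, because mosaicism
makes that correspondence undefined.

## Copy number

Per chromosome the *median* window depth (robust to partial events) is
compared to a genome baseline: the median of per-chromosome medians after
one pruning round that drops chromosomes outside [0.75, 1.25] of the
initial baseline — without pruning, a genome where several chromosomes
are aneuploid drags the baseline toward them. `expectedCopies` is
explicit because the same data can be mapped to a phased diploid assembly
(normal = 1 per haplotype chromosome) or a collapsed haploid reference
(normal = 2). Rounding is half away from zero, symmetric and
deterministic; each call carries a confidence = fraction of windows whose
implied integer equals the call. Partial aneuploidy uses recursive binary
segmentation on window means — each split maximizes the between-segment
sum of squares and is accepted only if both sides span ≥ 5 windows and
the means differ by ≥ 25% of baseline — which matches an exhaustive
best-split search at every recursion level and needs no tuning beyond
those two guards. No GC or mappability correction is attempted, and
non-integer (subclonal) states are out of scope.

## Methylation metaprofiles

Offsets are TSS-anchored with downstream positive regardless of strand.
Sites with fewer than 5 reads are removed first. The profile is the
median modification fraction per offset, pooled over all (gene, site)
pairs — the pooled reading of "median per position across all genes";
a `perGeneMedian` flag implements the alternative (per-gene medians
first). Periodicity is estimated as the autocorrelation-maximizing lag of
the mean-centered, linearly interpolated downstream profile within
50–500 bp, reported only when that autocorrelation reaches 0.2 — a flat
or aperiodic profile returns no period rather than a spurious one.

## Transcript rules

All thresholds are the written rules, with boundaries honored exactly:
isoforms with < 5 reads *or* < 5% of the gene's total reads (total
computed before any removal — the alternative, post-removal totals, is a
documented open choice) are dropped, with the most abundant isoform
rescued if a gene would lose everything. The primary-isoform cascade and
its tie-breaks (read count, then lexicographic id) are spelled out in
`?selectPrimaryIsoform` and tested against an independently coded oracle
over an exhaustive grid. The Kozak model uses window {−9…−1, +3…+5}
around the A of ATG, pseudocount 1, log-odds base 2 against background
frequencies, and the 25th percentile (linear interpolation) of training
scores as the extension threshold; extension goes to the 5'-most
qualifying upstream ATG (maximal extension — the best-scoring alternative
is available via `rule = "best"`), never crosses an in-frame stop, never
shortens a CDS, and is idempotent. Antisense lncRNA calls require ≥ 30%
antisense exonic overlap of the mRNA transcript length ("at least 30%"
read inclusively), with promoter classes assigned from the lncRNA TSS
position relative to the gene body and the nearest sense TSS (300-bp
pairing window).

The Kozak/ORF machinery operates on transcript-coordinate sequences
(each transcript model carries its spliced sequence and CDS start within
the transcript); that is the level at which the scanning rule is defined,
and it keeps the rule independent of exon structure bookkeeping.

## Problem sizes and numerical choices

The recovery suites run at: 10 Mb / 20 planted tracts for LOH; 5 Mb / 10
planted switches for painting; 100 replicate depth simulations (7 Mb
each, Poisson mean 50) for copy number; 2,000 genes for metaprofiles;
and a 120/40/40 training/extension/negative transcript set for the Kozak
rule — sizes chosen so each suite completes in about a minute on one core
while keeping binomial/Poisson sampling error an order of magnitude below
every asserted tolerance. All randomness flows through R's RNG seeded
once per simulation; a fixed seed makes every emitted file
byte-identical.

## Limitations

The generator validates the *procedures*, not the upstream callers: it
emits variant tables and depth directly rather than reads, so mapping
bias, cross-haplotype mis-mapping (which in real data doubles apparent
depth over duplicated near-identical haplotypes), indels and structural
variants other than the planted event classes are all outside what
passing tests demonstrate. Painting assumes the inter-parent divergence
comfortably exceeds within-parent heterozygosity (≥ ~4×); as the two
regimes approach each other the ambiguous band widens and accuracy
degrades gracefully rather than failing loudly. Copy-number calling
assumes the majority of chromosomes are euploid — if more than half the
genome is aneuploid the pruned baseline is undefined and the caller stops
with an error rather than silently rescaling.
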