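# mosaikit

Diagnosing hybrid diploid ("allodiploid") genomes from standard
observables — variant tables, depth tracks, modification calls and
transcript models.

Vegetatively diploid microbes such as budding yeasts and some green algae
experience a distinctive set of evolutionary forces: hybridization between
diverged species, mitotic recombination that shuffles the two parental
chromosome sets, loss of heterozygosity (LOH), and aneuploidy. All of
them leave signatures that can be computed from a phased diploid assembly
with a handful of explicit procedures, and mosaikit implements those
procedures as tested, reusable functions:

* **Windowed heterozygosity and divergence** — per 10-kb window,
  qualifying variant sites over alignable sites, with windows under 2,000
  aligned sites excluded; divergence applies the half-weight rule (a site
  where only one of a strain's two haplotypes differs from the reference
  counts 1/2). Degenerate-site classification (0/2/3/4-fold) and
  per-class heterozygosity.
* **LOH tracts** — maximal runs with no heterozygous site over ≥ 1 kb,
  classed interstitial / terminal / whole-chromosome, with a callability
  guard, per-class summaries and reciprocal-overlap comparison of two
  strains' tract sets.
* **Parent-of-origin painting** — each haplotype window is assigned to
  parent P or S by the signed difference of its divergence to the two
  parental references (threshold δ = 0.01); segments are smoothed runs;
  boundary pairs with opposite transitions on the two haplotypes are
  reciprocal mitotic crossovers, unpaired boundaries at LOH tract edges
  are nonreciprocal LOH.
* **Copy number** — median depth per chromosome in 20-kb windows against
  a pruned-median genome baseline gives integer calls (phased or
  collapsed reference conventions); recursive binary segmentation finds
  partial aneuploidies.
* **Methylation metaprofiles** — strand-aware TSS-anchored medians of
  5mC (CpG) and 6mA (ApT) fractions (sites with < 5 reads removed), plus
  autocorrelation estimation of the nucleosome-linker period.
* **Transcript curation** — decoupling of wrongly merged genes by CDS
  overlap; isoform filtering (< 5 reads or < 5% of gene total); a
  four-branch primary-isoform cascade; a Kozak position-weight model
  (window −9…−1/+3…+5, pseudocount 1, log₂ odds) whose training-score
  25th percentile drives ORF extension to upstream in-frame starts; and
  antisense lncRNA classification (≥ 30% antisense exonic overlap, with
  bidirectional/unidirectional/adjacent promoter classes).
* **A synthetic allodiploid generator** — two parental lineages ~2.7%
  apart with within-parent heterozygosity 0.6% / 1.35%, planted
  crossovers, LOH tracts and aneuploidies, negative-binomial depth,
  a periodic methylation template and designed transcript mixtures, all
  recorded in a truth log so every stage is testable by planted-event
  recovery.

## Worked example

Simulate a 1.2-Mb hybrid with one crossover, one terminal LOH tract and
one duplicated haplotype chromosome, then run the full diagnosis:

```r
library(mosaikit)

cfg <- simulationConfig(
  chromLengths = c(chr01 = 600000L, chr02 = 600000L),
  events = list(
    list(type = "crossover",    chrom = "chr01", pos = 300000),
    list(type = "loh_terminal", chrom = "chr02", start = 450000,
         end = 600000, donor = "B"),
    list(type = "aneuploidy_whole", chrom = "chr02", haplotype = "B",
         copies = 2L)),
  seed = 250L)
sim <- simulateHybridGenome(cfg)
res <- analyzeHybridGenome(sim)

head(res$het_windows[, c("chrom", "start", "end", "value")], 3)
#>   chrom start   end  value
#> 1 chr01     0 10000 0.0272
#> 2 chr01 10000 20000 0.0249
#> 3 chr01 20000 30000 0.0261
```

Heterozygosity runs at ~2.6–2.7% per window, the hybrid regime. The
planted LOH tract is recovered with boundaries at the nearest flanking
heterozygous sites:

```r
subset(res$loh_tracts, length > 10000)
#>   chrom  start    end length n_callable          class
#> 1 chr02 449926 600000 150074     150074 terminal_right
```

Both planted switches are found and correctly typed, and the duplicated
haplotype chromosome is called at two copies:

```r
res$switches
#>   chrom pos_lo pos_hi haplotypes                 type
#> 1 chr01 300000 300000        A,B reciprocal_crossover
#> 2 chr02 450000 450000          A    nonreciprocal_LOH

subset(res$copy_number, copies != 1)
#>     chrom median_depth baseline    ratio copies confidence   mode
#> 4 B_chr02      100.014  50.0074 1.999985      2          1 phased
```

The tract set summarizes to 12.5% of this toy genome homozygous:

```r
summarizeLoh(res$loh_tracts, sum(chromLengths(sim)))$genome_fraction_homozygous
#> [1] 0.1250617
```

## Vignette

`vignettes/hybrid-genome-diagnostics.Rmd` describes the models and
procedures, the generator's assumptions and what passing tests do and do
not show about real data, the tunable parameters with their defaults and
rationale, and known limitations.
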