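---
title: "Mapping EMS-induced recessive mutants from bulked RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping EMS-induced recessive mutants from bulked RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebsrmap)
```

## The genetic model

The package maps single-gene recessive mutations induced by EMS
(ethyl methanesulfonate) in an inbred background, using RNA-seq of two
bulked pools harvested from one selfed, segregating ear: a mutant pool
(kernels showing the recessive phenotype) and a wild-type sibling pool.
Because the mutant parent was heterozygous, the genotype structure at the
causal locus is fixed by Mendelian segregation:

* the mutant pool is homozygous for the mutant allele — its expected
  mutant-read fraction (the **SNP index**) is 1;
* the phenotypically wild-type siblings are a 2:1 mixture of heterozygous
  carriers and homozygous wild type, so the wild-type pool's expected
  mutant-allele frequency is $\tfrac{2}{3} \cdot \tfrac{1}{2} = \tfrac13$
  (index 0.333), while the fraction of *individuals carrying* the allele
  is $\tfrac23$.

The **D-value** at a site is the difference between the two pool indices.
At a fully linked site the allele-level D is $1 - \tfrac13 = 0.667$;
every unlinked heterozygous background mutation segregates identically in
both pools (expected frequency $\tfrac12$ each, D centred on 0). Sites
with high D, a near-1 mutant-pool index and a protein-damaging annotation
localise the causal gene without any genetic map.

## High-confidence SNP filtering

RNA-seq variant calls are noisy at low depth, so three filters are
applied before any linkage statistic (`filter_high_confidence()`):

1. **Per-pool coverage ≥ 5 reads.** The threshold is diagnosed rather
   than assumed: EMS produces almost exclusively C→T and G→A transitions,
   so the fraction of canonical substitutions among retained sites
   (`ems_spectrum_curve()`) rises with the coverage cutoff and plateaus
   once spurious calls are excluded — on both real and generated data the
   plateau starts at 5. We enforce the depth in *each* pool (the stricter
   of the two possible readings) because an allele-frequency estimate
   from four reads is unusable whichever pool it comes from.
2. **Detected in both pools** (≥ 1 alternate read in each). A true causal
   allele must appear in the wild-type sibling pool too, since two-thirds
   of those individuals carry it.
3. **Cross-line blacklist.** In a cohort of independently mutagenised
   lines, a site present in more than 10% of lines is shared background
   (residual heterogeneity or a systematic artefact), not an independent
   EMS hit, and is discarded. Presence is evaluated on the *raw*,
   pre-filter record sets: recurrence is a detection property, and making
   it depend on the coverage filter would let a shared artefact escape
   the blacklist in lines where it happened to be shallowly covered. The
   comparison is strict — with 20 lines, a site in exactly 2 lines (10%)
   survives, 3 lines (15%) does not.

Each removed record is attributed to the first filter it fails, in the
order above, so the drop counts plus survivors always partition the
input.

## Linkage statistics and candidate calling

For each surviving site the per-pool SNP indices, depths and D-value are
computed (`linkage_stats()`). Calling then proceeds in two stages, as the
mapping logic of the method dictates:

1. **Chromosome localization.** Sites with per-pool depth > 10 and
   D > 0.4 are *linked*; the chromosomes carrying linked sites are the
   candidate location (`localize_chromosome()`). Linked SNPs on several
   chromosomes are all reported (`status = "multiple"`) rather than
   electing an arbitrary winner — dispersed peaks are themselves a
   diagnostic of residual false positives.
2. **Candidate genes.** On the called chromosomes, a candidate site must
   have (i) mutant-pool SNP index > 0.9, (ii) D-value > 0.4, and (iii) a
   large-effect annotation. All comparisons are strict (`>`); the
   boundary semantics matter only on a set of measure zero for real
   depth ratios but are fixed and tested. The default large-effect set is
   {stop_gained, missense_variant}; `splice_region_variant` is not
   included by default (splice disruption is a plausible mechanism, so
   the set is configurable) and `synonymous_variant` never qualifies. A
   genome-wide calling mode (`genome_wide = TRUE`) bypasses stage 1 for
   comparison.

When a multi-effect annotation is attached to one site, the most severe
label is kept, using the fixed order stop_gained > splice_region_variant
> missense_variant > synonymous_variant > everything else; collapsing
order is otherwise undefined in annotation tools' output, so it is pinned
and documented here.

### Threshold sweep and the false-positive rate

Every line carries a single recessive mutation, so any line with more
than one candidate gene contains at least one false positive. The
**false-positive rate** at a threshold is the proportion of lines with
more than one candidate gene. `sweep_thresholds()` re-runs the two-stage
calling over a grid of D thresholds; the candidate count is non-
increasing in the threshold (a strict-threshold subset argument, also
verified property-style in the tests), and on cohorts with a clear
planted signal the FPR reaches zero by D = 0.4 — the behaviour that
motivates 0.4 as the default.

## Monte Carlo calibration of the D threshold

Finite pools make observed D-values deviate from theory. The calibration
(`simulate_d_values()`) models one causal SNP and draws, per replicate:

1. the wild-type pool's carrier count $k \sim \mathrm{Bin}(20, \tfrac23)$,
   giving a realised pool allele frequency $\hat p = k/40$;
2. a sequencing depth $d \sim \mathrm{Poisson}(30)$ (re-drawn on zero — a
   replicate with no reads has no D-value; probability $e^{-30}$) and
   mutant reads $\sim \mathrm{Bin}(d, \hat p)$, giving the observed
   wild-type index;
3. the deviation of that index from its expectation $\tfrac13$ is
   subtracted from the model centre and a single Gaussian technical-noise
   term $\mathcal N(0, 0.05)$ is added.

The mutant pool contributes no binomial deviation — its true frequency is
1 and a binomial at $p = 1$ is deterministic — so its technical variation
is folded into the one noise term; applying the stated noise once, not
once per pool, also keeps the variance at its stated minimum. The
reported threshold is the empirical 95th percentile (linear-interpolation
quantile; at $10^5$ replicates the choice of quantile convention moves
the answer only in the fourth decimal).

### The two centres

The genetic model admits two readings of the "theoretical D" for this
design. At allele scale the centre is $1 - \tfrac13 = 0.667$. At
*carrier-fraction* scale — one minus the fraction of wild-type
individuals carrying the allele — it is $1 - \tfrac23 = 0.333$. These are
genuinely different numbers describing the same cross, and the package
keeps both as an explicit option (`d_center_model`): the default
`"carrier"` centre of 0.333 is the parameterization under which the
95th percentile lands at ≈ 0.5, consistent with the calibrated threshold
the candidate rule uses, while `"allelic"` (0.667) is the allele-level
centre. `compare_center_models()` reports both from a shared random
stream, in which case the two thresholds differ by exactly the centre
difference. How the original calibration combined the binomial, Poisson
and Gaussian components into one draw is not fully determined by its
description; the composition above is this package's explicit
reconstruction, and the test suite verifies its variance decomposition
term by term against closed forms.

```{r sim, eval = FALSE}
sim <- simulate_d_values(sim_config(seed = 1))
sim
#> D-value threshold simulation
#>   replicates: 100000, pool size: 20, depth lambda: 30, noise sd: 0.05
#>   center model: carrier (center = 0.3333)
#>   D ~ mean 0.3332, sd 0.1133
#>   threshold (95th percentile): 0.5157
```

## The synthetic-experiment generator

`generate_cohort()` builds complete cohorts — per-line mutant/wild-type
VCFs with AD fields, a GFF3 gene sketch, an effect table, a manifest and
a ground-truth table — so every pipeline stage is testable end to end
without external data. Its defaults are the study conditions the method
assumes, chosen once:

* 20 lines, pools of 20, Poisson(30) per-pool depth;
* 30–80 SNPs per line (uniform), matching the observed per-line range
  with its mean in the mid-50s;
* one causal site per line inside a gene, mutant-pool frequency 1,
  wild-type-pool frequency from a binomial carrier draw at 2:1 het:hom;
* unlinked background EMS sites at frequency 0.5 (heterozygous parent) or
  1.0 (homozygous) in *both* pools — the 1:2:1 structure of selfed
  heterozygous sites makes their expected allele frequency independent of
  the kernel phenotype, which is exactly why the D-value contrast works;
  the het:hom split among background sites (default 2:1) is a free
  parameter of the generator, as real per-line zygosity breakdowns are
  not available;
* 73.33% of non-causal sites exonic, with effect proportions
  30.56/63.63/3.66/1.89 (synonymous/missense/stop-gained/splice-region,
  renormalised to sum to one — the printed proportions sum to 0.9974);
* true EMS sites 100% canonical C→T/G→A; a configurable fraction
  (default 25%) of spurious non-canonical calls forced below 5× per-pool
  depth, which is what gives the generator its rising
  spectrum-vs-coverage curve;
* optional shared sites recurring in 25% of lines to exercise the
  blacklist.

Read counts are drawn $\mathrm{Bin}(\mathrm{Poisson}(\lambda), f)$ per
pool directly; there is no read-level simulation (no FASTQ, no
alignment), so the generator does not emulate alignment artefacts,
allele-specific expression, or the strong expression skew of real
transcriptomes (where a few dozen genes can absorb most of the data and
leave low-expression transcripts under-covered). Passing tests on
generated cohorts therefore validates the statistical logic of
filtering, linkage and calling — not robustness to those upstream
effects. Sites are statistically independent by default: the per-site
statistic does not model recombination distance, so linkage decay around
the causal site is deliberately not simulated.

With the defaults, parameter recovery over 200 generated lines returns
the planted gene as a candidate in every line where the causal site's
sampled depths pass the depth and index rules; misses occur only through
sampling (e.g. a shallow wild-type draw at the causal site), never
through the calling logic, and the truth table makes each miss auditable.

## Numerical and interface choices

* Coordinates are 1-based inclusive internally (VCF/GFF3 convention);
  conversion to 0-based half-open happens only when writing BED.
* Variants are kept on the reference strand; canonical-EMS status is
  defined on (ref, alt) pairs directly, with no complementing.
* Multiallelic VCF lines are split per ALT allele; indel alleles and
  records without a parseable AD for either pool are skipped and counted,
  never silently dropped.
* Pools may be called jointly (one two-sample VCF) or separately (two
  single-sample VCFs, merged on site with zero fill); both input shapes
  are accepted since either calling strategy is legitimate upstream.
* Zero-depth sites raise an error in `snp_index()` rather than returning
  NaN: the coverage filter upstream is the supported way to remove them.
* Ties in chromosome localization are reported, not broken.
* D-values are per-site; no sliding-window smoothing is applied (unlike
  window-based QTL-seq implementations), because candidate calling is
  gene-resolved from the start.

## Problem sizes used in the checks

The shipped test-suite and acceptance checks run the Monte Carlo at its
full $10^5$ replicates, oracle comparisons on 30–50-site fixtures,
sweeps on a 10-line cohort, and parameter recovery on 200 generated
lines (10 cohorts of 20); these sizes give stable statistics for every
quantity asserted while keeping a full run in the order of a minute.

## Known limitations

* The mapping success of the method on real data is bounded by biology
  the package cannot see: transcripts not expressed at sampling time,
  marker deserts in low-mutation-density material, and expression skew
  all reduce usable sites; the package reports stage-by-stage counts so
  such failures are visible, but cannot rescue them.
* The calibration simulates the causal-locus distribution (the design
  models a single causal SNP), not a genome-wide null; the threshold it
  returns is a deviation allowance around full linkage, not a
  false-discovery control.
* Gene assignment is interval-based on `gene` features only; no
  transcript-aware effect prediction is attempted — effects are consumed
  from upstream annotation, not computed.
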