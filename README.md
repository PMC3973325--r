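# gantcscope

Analysis of CcrM-dependent GANTC methylation in *Caulobacter crescentus*
and related *Alphaproteobacteria*: genome-wide motif distribution
statistics, SMRT-kinetics methylome calling, promoter motif conservation
scoring, and methylation-coupled differential-expression enrichment — with
a synthetic-data generator so the whole pipeline is testable offline.

## The science in brief

CcrM is a cell cycle–regulated orphan N6-adenine methyltransferase that
methylates the adenine of 5'-GANTC-3' (a reverse-complement palindrome,
one methylatable adenine per strand). Newly replicated motifs sit
hemi-methylated until CcrM reappears late in the cell cycle, so motifs
near the replication origin spend longer hemi-methylated than motifs near
the terminus. The package implements:

* **Motif statistics.** Observed vs expected counts of GANTC (and the 24
  pentanucleotides of its structural family, including CTNAG) per genome
  partition. The composition null is
  `E = L · f(G)·f(A)·f(T)·f(C)` (the degenerate centre contributes a
  factor of 1); partition expectations allocate the observed genome total
  proportionally to partition length; intergenic counts are
  genome − (coding + rna).
* **Two-state IPD mixing model.** The population-average SMRT
  inter-pulse-duration ratio at a motif adenine is
  `r = f·r_full + (1 − f)·1`, with `r_full` calibrated from a
  constitutively methylated reference (7.68 gives the hemi-methylated
  midpoint `(7.68 + 1)/2 = 4.34`). Strand adenines with `r < 2.4` are
  called under-methylated; sites are classified as fully methylated,
  asymmetric, or under-methylated on both strands. Windowed 20-kb
  profiles are rescaled (reference ↦ 100 %, midpoint ↦ 0 %) and smoothed
  by circular tricube local-linear regression, and the origin-distance
  gradient is tested by a permutation Spearman correlation.
* **Promoters and conservation.** The promoter is the 200 bp upstream of
  the translational start (wrapping circular origins); a motif belongs to
  it when its start coordinate lies inside. Cross-species conservation is
  counted from an ortholog presence panel.
* **DE and enrichment.** Significance at adjusted p < 0.01, strong
  changes at ≥ 2-fold (log2 ≥ 1); exact hypergeometric (Fisher)
  enrichment of regulons, COG classes, promoter motifs and conservation
  strata within the DE sets; the excess-direct-target estimate
  `n·(1 − 1/fold)` (80 genes at 2-fold enrichment → ~40 direct targets);
  and a candidate table of significant, motif-bearing, conserved genes.

See `vignettes/gantcscope-methods.Rmd` for the full model description,
parameter defaults and design choices.

## Worked example

```r
library(gantcscope)

plan <- syntheticPlan(seed = 1)      # the wild-type-like study condition
gen  <- generateGenome(plan)
partitionCounts(gen$genome, gen$features)
#> PartitionCounts for GANTC on 'chr' (1000000 bp)
#>    partition observed  expected  ratio
#> 1     genome     1996 3905.2000 0.5111
#> 2     coding      683  900.5010 0.7585
#> 3        rna       49   64.5826 0.7587
#> 4 intergenic     1264 1030.9200 1.2260
```

The genome carries ~2000 GANTC sites, about half of what its base
composition predicts (`ratio 0.51`, i.e. ~2-fold depleted) and relatively
enriched in intergenic DNA — the planted signature of a CcrM-bearing
alphaproteobacterial genome.

```r
meth  <- generateMethylationPlan(plan, gen$sites)
ref   <- generateIpdDataset(plan, fullyMethylatedPlan(meth), seedOffset = 1000L)
model <- calibrate(ref)
model
#> CalibrationModel: r_full = 7.678, r_hemi = 4.339, tau = 2.4

ipd <- generateIpdDataset(plan, meth)
ad  <- motifAdenines(gen$sites$position0, length(gen$genome))
out <- callSites(callStrands(ipd, ad, model))
out$tally
#>             full       asymmetric under_methylated          no_data
#>             1961               11               24                0

set.seed(1)
originGradientStat(out$calls, 0, 1e6, nPerm = 10000)
#> rho = 0.867, permutation p = 1e-04
```

Calibration recovers the planted fully methylated ratio (7.68) to within
a few hundredths; the caller recovers exactly the 24 bilaterally
under-methylated and 11 asymmetric planted sites; and the site fractions
correlate strongly with origin distance — the replication-timing
hemi-methylation gradient.

`simulateBundle(plan, dir)` writes a complete FASTA/GFF3/TSV bundle and
a config; `runPipeline(config)` runs all four stages over it and writes
per-stage TSVs plus a JSON report. A thin command-line wrapper lives at
`inst/scripts/gantcscope.R` (subcommands `simulate`, `run`,
`motif-stats`).

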