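# methylphase

Two-stage calling of **mutation-specific DNA hypermethylation** from
whole-genome bisulfite sequencing (WGBS) count data, with the analyses
that build on it: 5-hydroxymethylation (5hmC) from paired oxidative
bisulfite tracks, chromatin-state/enhancer annotation with a
permutation null for region-set overlap, superenhancer calling from
ranked H3K27ac signal, and loop-anchor linking of enhancer DMRs to
target-gene expression percentiles.

The package is aimed at tumor epigenomics cohorts — the motivating
setting is AML, where *IDH1/IDH2/TET2* mutations produce focal
hypermethylation that must be separated from the CpG-island
hypermethylation common to all tumors. Because that separation needs
two different comparisons, DMR calling is two-staged:

1. **vs normal** — a beta-binomial Wald test at every CpG (target group
   vs normal cells), BH-adjusted, with a DMC requiring `q < 0.05` *and*
   a methylation difference ≥ 0.2; same-direction DMCs are chained into
   DMRs with **> 10 CpGs** and a pooled difference ≥ 0.2.
2. **vs all other tumors** — each DMR is re-tested with per-sample
   counts aggregated over its span, target vs the pooled remaining
   tumor samples (confounding mutation groups excluded). Regions that
   stay significant, large and same-direction are **group-specific**.

The per-CpG statistic is a Wald ratio on pooled proportions with exact
beta-binomial variance `mu(1-mu) * (T + phi*(S-T)) / T^2`
(`T = sum n`, `S = sum n^2`) and a method-of-moments dispersion
shrunk toward the chromosome median. 5hmC is the per-CpG beta
difference WGBS − oxWGBS at CpGs with coverage > 10× in both assays.
Details, defaults and design rationale are in the methods vignette
(`vignettes/methylphase-methods.Rmd`).

A seeded synthetic cohort generator (`sim_config()`,
`simulate_methylomes()`, `simulate_paired_oxbs()`,
`simulate_annotations()`) produces full cohorts with ground truth —
planted specific/shared hyper-DMRs, planted 5hmC, consistent
annotation tracks — so every stage is testable without controlled-access
patient data.

## Worked example

```r
library(methylphase)

cfg <- sim_config(seed = 42,
  groups = c(CD34 = 6, IDHmut = 7, otherAML = 20),
  reference_group = "CD34",
  planted_dmrs = list(list(target_groups = "IDHmut", n_regions = 100,
                           cpg_range = c(20, 60), delta = 0.4,
                           placement = "enhancer_state")),
  planted_shared = list(list(n_regions = 50, cpg_range = c(20, 60),
                             delta = 0.4, placement = "random")))
sim  <- simulate_methylomes(cfg)
sim$matrix
#> CpGCountMatrix: 52943 CpGs x 33 samples (CD34, IDHmut, otherAML)

dmcs <- dmc_test(sim$matrix, "CD34", "IDHmut")    # stage 1, per CpG
sum(dmcs$is_dmc)
#> [1] 5745

dmrs <- segment_dmrs(dmcs)                         # chain into regions
nrow(dmrs); table(dmrs$direction)
#> [1] 150
#> hyper
#>   150

spec <- call_group_specific(dmrs, sim$matrix,      # stage 2
                            "IDHmut", "otherAML")
nrow(spec)
#> [1] 100
```

The 150 stage-1 regions are the 100 planted IDH-specific plus the 50
planted pan-tumor regions; stage 2 keeps exactly the 100 specific ones
(the shared regions show no target-vs-tumor difference) — all labeled
`hyper`, i.e. hypermethylated relative to CD34.

Downstream, on the same synthetic bundle:

```r
ann <- simulate_annotations(sim$truth, cfg)
cls <- classify_enhancers(spec, ann$k27ac, ann$k4me1, ann$k27me3)
table(cls$class)                       # planted regions are enhancers
links <- map_edmr_targets(spec[cls$class != "none", ],
                          ann$loops, ann$promoters)
expression_percentiles(ann$expression, colnames(ann$expression$tpm),
                       unique(links$gene))$top_quartile_fraction
#> [1] 0.82  (linked genes are drawn from the top expression quartile)
```

`run_all(run_config(...))` executes the whole chain from files on disk
(bedGraphs + sample sheet + BED/BEDPE/TSV annotations) and writes
BED6+/TSV tables plus a JSON manifest; `simulate_cohort(cfg, dir)`
writes a complete input bundle. A thin CLI wrapper lives at
`inst/cli/methylphase.R` (`simulate`, `run-all`).

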