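---
title: "Calling mutation-specific DNA hypermethylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling mutation-specific DNA hypermethylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylphase)
```

# The problem

In acute myeloid leukemia (AML), mutations in *IDH1*, *IDH2* and *TET2*
perturb TET-mediated active demethylation and produce focal DNA
hypermethylation. Distinguishing hypermethylation that is *specific* to
one mutation group from the CpG-island hypermethylation common to many
tumors requires two separate statistical comparisons on whole-genome
bisulfite sequencing (WGBS) count data: first against normal
hematopoietic cells (CD34+), then against all other tumor samples.
`methylphase` implements that two-stage procedure together with the
analyses built on its output: 5-hydroxymethylation (5hmC) estimation
from paired oxidative bisulfite data, chromatin-state and enhancer
annotation with a permutation null for region-set overlap,
superenhancer calling from ranked H3K27ac signal, and linking of
enhancer DMRs to target genes through chromatin-loop anchors.

# The count model and the Wald test

At CpG $c$, sample $s$ contributes methylated and total read counts
$(y_{cs}, n_{cs})$. Within a group $g$ the counts follow a
beta-binomial: the sample-level methylation proportion is
$p_{cs} \sim \mathrm{Beta}$ with mean $\mu_{gc}$ and overdispersion
$\varphi$, parameterized so that

$$\mathrm{Var}(y_{cs}/n_{cs}) = \mu(1-\mu)\left[\frac{1-\varphi}{n_{cs}} + \varphi\right].$$

The group mean is estimated by the pooled proportion
$\hat\mu_g = \sum_s y_{cs} / \sum_s n_{cs}$ over samples with at least
one read. The test statistic for a difference between groups $a$ and
$b$ is the Wald ratio

$$W_c = \frac{\hat\mu_b - \hat\mu_a}{\sqrt{\widehat{\mathrm{Var}}(\hat\mu_a) + \widehat{\mathrm{Var}}(\hat\mu_b)}},
\qquad
\widehat{\mathrm{Var}}(\hat\mu_g) = \hat\mu_g(1-\hat\mu_g)\,\frac{T_g + \hat\varphi\,(S_g - T_g)}{T_g^2},$$

with $T_g = \sum_s n_{cs}$ and $S_g = \sum_s n_{cs}^2$ — the exact
variance of the pooled estimator under a shared dispersion. Two-sided
p-values come from the standard normal, with Benjamini–Hochberg
adjustment across all tested CpGs. A CpG is called differentially
methylated (DMC) only when both $q < 0.05$ *and* the absolute group
difference is at least 0.2 — the difference filter matters as much as
the significance filter at WGBS coverage.

## Dispersion estimation and shrinkage

Each squared standardized beta residual gives a moment estimate
$\hat\varphi_i = (r_i - 1/n_i)/(1 - 1/n_i)$; these are averaged over
the samples of both groups (requiring $n_i \ge 2$) and clamped to
$[0, 0.99]$. Because per-CpG moment estimates at 20–40 samples are
noisy, the raw estimate is shrunk toward the chromosome-wide median
with data weight equal to the number of usable samples and a fixed
prior weight of 20 pseudo-samples:

$$\hat\varphi = \frac{n\,\hat\varphi_{\mathrm{raw}} + 20\,\tilde\varphi_{\mathrm{chrom}}}{n + 20}.$$

The prior weight trades per-CpG adaptivity against stability; 20 makes
the chromosome median dominate at typical cohort sizes while still
letting strongly overdispersed CpGs pull away from it. No local
smoothing of methylation levels across neighboring CpGs is applied:
segmentation (below) already aggregates across CpGs, and smoothing
would entangle the two steps. A CpG is testable when both groups have
at least two covered samples; untestable CpGs are counted and skipped.

# DMR segmentation and the two-stage specificity call

Same-direction DMCs within 1 kb of each other are chained. A chain
becomes a differentially methylated region (DMR) when

* the chained span contains **more than 10** covered CpGs,
* the pooled group difference over *all* CpGs in the span (not only the
  DMCs) is at least 0.2 in the chain's direction, and
* DMCs make up at least half the span's CpGs.

Boundaries are CpG-anchored and half-open, ending at the last CpG
position + 2 (the dinucleotide footprint), which makes downstream
overlap arithmetic exactly reproducible. The 1 kb gap and the 0.5 DMC
share are deliberate defaults where the region definition itself left
them open; both are exposed in `thresholds()` and recorded in every run
manifest.

The second stage re-tests each stage-1 DMR for specificity: per-sample
counts are aggregated over the region span and a single beta-binomial
Wald test compares the target group against all other tumor samples
pooled, with groups carrying confounding mutations (e.g. *DNMT3A*,
*TET2* when testing *IDH*) excluded entirely. BH runs across regions; a
region is group-specific only if it is significant, has an aggregated
difference of at least 0.2, and keeps its stage-1 direction. The same
aggregated test is exposed as `region_group_test()` for cross-genotype
re-testing of a fixed region set.

# 5hmC from paired oxidative bisulfite data

Standard bisulfite conversion reports 5mC + 5hmC; oxidative bisulfite
(oxBS) reports 5mC alone. The per-CpG, per-sample 5hmC estimate is the
beta difference WGBS − oxWGBS, kept only where **both** assays have
coverage strictly above 10 reads. Negative estimates are *retained*:
they are legitimate sampling noise around small true values, and
flooring them at zero would bias every region mean upward. Group
comparisons of region-set means use Welch's t-test on per-sample means
(the sample, not the CpG, is the unit of replication), with BH across
the reported contrasts. Incomplete oxidation leaks 5hmC into the oxBS
signal; the generator models this with a per-group efficiency
$e$, so the expected subtraction is $e \cdot \mathrm{5hmC}$ — at
$e = 0.8$ a planted level of 0.2 is recovered as 0.16, which the
acceptance checks verify by Monte Carlo at coverage 10,000.

# Annotation, permutation null, superenhancers, loops

**Chromatin states.** Each region is assigned the state with maximal
total base-pair overlap in a non-overlapping 15-state tiling (ties go
to the lowest state index). Enrichment is the ratio of assigned-state
fractions between a query and a background set. The equivalent per-bp
counting oracle is enforced in the tests.

**Enhancer classes** follow the histone-mark rule: H3K27ac with
H3K27me3 is *poised*; H3K27ac otherwise is *active* (with or without
H3K4me1); H3K4me1 alone is *weak*; everything else — including
H3K4me1 + H3K27me3 without H3K27ac, which the rule's source does not
cover — is *none*, keeping *weak* a clean K4me1-only class.

**Permutation overlap test.** The null preserves the region universe:
it redraws $|Q|$ regions from the finite set of all DMRs without
replacement and recounts overlaps with the reference, rather than
shuffling coordinates genome-wide. The reported p uses add-one
smoothing, $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, so it is
never zero; an exhaustive-enumeration mode covers toy instances
exactly.

**Superenhancers.** H3K27ac peaks within 12.5 kb are stitched and
their signals summed. With both axes of the ascending rank–signal
curve scaled to the unit square, the cutoff is the tangent point of a
slope-1 line, located as the minimizer of (scaled signal − scaled
rank); regions strictly above the cutoff signal are superenhancers.
An all-equal signal profile is a straight line with no tangent point
distinct from its end, and deliberately yields zero superenhancers.
The TSS-exclusion refinement of the original stitching procedure is
omitted — it needs a transcript annotation the pipeline does not
otherwise require.

**Loops and expression.** A DMR is anchored if it overlaps either
anchor of any loop by ≥ 1 bp. Enhancer-classified DMRs are linked to
every gene whose promoter (TSS ± 2 kb when no promoter track is
supplied) overlaps the partner anchor, deduplicated per (DMR, gene).
Target-gene expression is summarized as mid-rank percentiles,
$100(r - 0.5)/N$, over all *expressed* genes (mean TPM > 0 in the
chosen samples); the headline statistic is the fraction of linked
genes at or above the 75th percentile.

# The synthetic cohort generator

Every stage is validated against cohorts with known ground truth.
The generator emulates the structure the analysis assumes, at desk
scale (defaults: 2 chromosomes × 5 Mb, ~50,000 CpGs):

* **Clustered CpG placement** — dense islands (mean gap 30 bp, 1.5–2 kb
  long, 40/Mb) over a sparse background (mean gap 350 bp), so CpG
  density statistics have real contrast.
* **Bimodal baseline** — islands sit at the low mode (0.15) with
  probability 0.9, background blocks at the high mode (0.85), with
  small per-CpG jitter; this reproduces the observation that focal
  hypermethylation hits regions lowly methylated in normal cells.
* **Planted regions** — runs of 20–60 consecutive island CpGs get
  +δ (default 0.4) added to the target groups' mean track; "shared"
  regions target every tumor group, "specific" regions one group.
  Planting fails loudly if any mean would exceed 1.
* **Counts** — sample proportions are Beta with overdispersion
  φ = 0.05, coverage is negative binomial (mean 30, size 10), reads
  are binomial. Group sizes default to 6 normal, 7 target, 20
  comparison — the shape of the real cohort design.
* **Paired oxBS** — WGBS draws use 5mC + 5hmC, oxBS draws
  5mC + (1 − e)·5hmC; the two assays of one sample are independent
  library draws.
* **Annotations** — a 15-state tiling in which every enhancer-placed
  planted region lies inside an enhancer-state interval; peaks
  consistent with states (planted regions get H3K27ac + H3K4me1);
  loops that put a configurable fraction of enhancer-placed regions
  inside an anchor whose partner contains the promoter of a
  top-quartile expressed gene; a log-normal TPM table.

One seed fans out to fixed per-stage child seeds, so the generator is
bit-reproducible and stages can be rerun independently.

What passing on this generator does *not* show: the generator has
block-constant baselines, position-independent coverage, no SNPs or
mapping artifacts, no correlated biological replicates beyond the
beta-binomial, and planted effects with sharp boundaries. Real DMR
boundaries are fuzzier and real dispersion varies with methylation
level, so recovery rates here are upper bounds on real-data behavior;
the calibration properties (null silence, permutation uniformity,
oracle equivalence) are the transferable guarantees.

# Numerical choices and degenerate inputs

* Counts are reconstructed from bedGraph betas as
  `round(beta × coverage)` half-away-from-zero — deterministic and
  inverse-consistent for betas printed at ≥ 2 decimals.
* Zero-coverage cells are retained in the matrix but excluded from
  every statistic, keeping position universes comparable across
  samples.
* `SE = 0` with zero difference gives statistic 0, p = 1; with nonzero
  difference (one group all-0, the other all-1) it gives an infinite
  statistic and p = 0.
* Raw dispersion estimates are clamped to [0, 0.99] before shrinkage
  and final values to [1e-6, 0.99].
* Regions with no covered CpG are excluded from low-methylation
  denominators and flagged, never silently zeroed.
* Profile windows truncated at chromosome edges simply lack those
  sub-bins.

# Problem sizes used in the tests

The packaged checks run the generator at 1–2 chromosomes of 2–5 Mb
(~20,000–55,000 CpGs), 6–40 samples, 20 null seeds for calibration,
500 replicates for permutation calibration, and 1,000 random count
configurations for oracle agreement at 1e-10 — sizes chosen so the
entire suite completes in a few minutes on one core while every
statistical property is still sharply testable.

# Known limitations

* No covariate adjustment, paired designs, or local-likelihood
  smoothing in the DMC test.
* The second-stage comparison pools all non-excluded tumor samples; a
  per-group mixed model is out of scope.
* 5hmC is subtraction-only; no joint maximum-likelihood estimation of
  (5mC, 5hmC) with conversion-rate parameters.
* Superenhancer calling omits TSS exclusion.
* The permutation universe must be supplied; whether it includes the
  query set is the caller's modeling decision.
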