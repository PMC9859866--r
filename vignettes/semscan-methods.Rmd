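---
title: "Stochastic epigenetic mutation analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic epigenetic mutation analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semscan)
```

## The SEM model

A stochastic epigenetic mutation (SEM) is a per-subject extreme outlier in
DNA methylation: at a CpG probe with reference quartiles Q1 and Q3 (computed
across a designated reference sample set) and IQR = Q3 − Q1, a subject's
beta value is a hypo-methylated SEM when it lies strictly below Q1 − 3·IQR
and a hyper-methylated SEM strictly above Q3 + 3·IQR. The statistic is
deliberately distribution-free: array beta values are bounded, bimodal and
heteroskedastic, and a quartile-based outlier rule is robust to all three.
Thresholds are computed on the beta scale (the scale on which the outlier
rule is conventionally defined for methylation arrays) and are *not*
clamped to [0, 1]; a probe whose lower bound is negative simply cannot
produce hypo calls, which is the honest behaviour for probes with low
methylation and non-trivial spread.

Assumptions worth keeping in mind:

* The reference set characterises "normal" variation at each probe. By
  default the reference is the whole cohort (cases plus controls), so each
  subject is evaluated against thresholds that include itself; with dozens
  of samples a single outlier barely moves a quartile, and the bias is
  conservative (toward fewer calls). An external reference matrix, or a
  leave-one-out mode (the `--loo` switch of the command-line `call`
  subcommand), are available where that bias matters.
* Quartiles use linear interpolation between order statistics at position
  1 + (n − 1)q (`stats::quantile` type 7). This convention is load-bearing:
  the packaged cohort table's group quantile summaries reproduce exactly
  under it, and the package uses it uniformly for thresholds and summaries.
* At least 4 reference samples are required; below that, quartiles are too
  unstable to define an outlier bound at all.
* Probes with any missing reference value are excluded from threshold
  computation entirely (`usable = FALSE`) rather than imputed — the
  simplest defensible rule. Probes with IQR below `iqr_floor`
  (default 1e-6, i.e. only numerically constant probes) are likewise
  unusable, since a 3·IQR band of width ~0 would call measurement noise.

## Burden inference

Per-subject hypo and hyper call counts are modelled on the natural-log
scale, where multiplicative burden differences become additive and the
heavy right tail of counts (an order of magnitude across subjects is
normal) is tamed. Zero counts have no defined log and are excluded from
the log-scale model with a warning — no +1 pseudo-count is added, because
the quantile summaries are reported as ln(count) exactly and a pseudo-count
would silently shift them. In practice cohort-scale burdens are in the
hundreds to tens of thousands and exclusion never triggers.

The group comparison is a linear mixed model,
`ln(burden) ~ group + sex + (1 | family)`, fitted by REML (`lme4`), with a
Wald z test on the group coefficient. A single-coefficient Wald test is
standard practice here and keeps results comparable across fits; the
z (rather than t) reference is slightly anti-conservative at twin-cohort
sizes, which the type-I calibration test quantifies (empirically ~5–7%
rejection at nominal 5% over 200 null cohorts — inside the accepted
2–9% band). When the family random-effect variance estimate hits the zero
boundary the mixed model is exactly an OLS fit, and the implementation
falls back (with a warning) to OLS with family-cluster-robust (CR0)
standard errors, which keeps the family structure in the uncertainty even
when the point estimate of the variance is zero. The default covariate set
is `sex` only; batch can be added where the design includes it.

A Wilcoxon signed-rank companion (`paired_signed_rank`) restricted to
complete discordant pairs gives a nonparametric check; the exact null
distribution is used up to 25 pairs.

## SEM-enriched regions

The region scanner asks, per subject and direction: does some genomic
window hold more same-direction SEMs than the subject's own genome-wide
rate explains? Windows are `window_probes = 10` consecutive *usable* probes
(probe-count windows, not basepair windows, so the test is invariant to
probe density), stepped by one probe. The window count k is tested against
the upper tail of Binomial(m, r_s) with m the window size and r_s the
subject's genome-wide per-probe SEM rate for that direction — an exact
small-sample tail that needs no asymptotics at k of 3–10. BH correction is
applied across all windows of one subject × direction scan; windows with
q ≤ 0.05 and k ≥ `min_sems = 3` are merged when they overlap (adjacent but
non-overlapping windows stay separate), and a merged region keeps its best
window q and the count of distinct SEM probes covered. All three parameters
are exposed; the k ≥ 3 floor exists because a window with 1–2 calls is
indistinguishable from scattered singles regardless of p.

Regions are called per subject, not per group, matching the study design
the package targets (individual epimutation profiles compared across
populations afterwards); direction purity is enforced — hypo and hyper
calls are never pooled into one region.

## Gene sets and the candidate screen

A gene enters a population × direction set when at least one SEM of that
direction in at least one sample of the population lands on a probe
annotated to it (multi-gene probes count for every listed gene; symbol
matching is case-sensitive and exact, with the manifest as the single
authority). "Univocal" genes are those in exactly one population's set for
a direction — implemented as set difference against *both* other
populations. Cross-direction intersections and the "both directions in
cases" list are emitted in two variants (restricted to case-univocal genes
in both directions, and unrestricted), because the restriction is a
genuine ambiguity in how such lists are defined; both are labelled.

The candidate screen is a transparent membership filter of the univocal
sets against a configurable gene list. The packaged default list covers
the dyshormonogenesis and thyroid-development genes plus imprinted loci
relevant to the CH worked example. No external knowledge bases or scoring
are involved, by design.

## Paired differential methylation

This stage is intentionally a simplification of the limma-style
region-hierarchy pipelines: within-pair M-value differences (M =
log2(β/(1−β)), β clamped to [1e-3, 1−1e-3]) over complete discordant pairs,
a one-sample t against zero per probe, BH across probes; at region level,
member-probe M-values are averaged per sample first, with BH within each
region class (gene bodies, promoters = 1500 bp upstream of a gene's first
probe, CpG islands from the manifest, 5 kb tilings). No empirical-Bayes
moderation and no combined-rank scoring are applied: the stage exists to
establish whether broad methylation differences exist at all, and its null
behaviour is what the tests pin down (p < 0.05 fraction within [0.03,
0.07] on 20,000 null probes). One numerical caveat is asserted in its true
form: the M transform is monotone, so each within-pair difference agrees
in sign with its beta-scale counterpart beyond the clamp width, but *mean*
differences across pairs can disagree in sign between scales because the
logit is convex near the boundaries — region and site effect sizes are
therefore reported on both scales.

## The synthetic cohort generator

The generator is first-class, tested code: every stochastic property of
the pipeline is verified against its recorded ground truth. It emulates:

* bimodal array-like beta baselines (45% of probes near 0.1, 45% near
  0.85, 10% intermediate);
* twin/family correlation: a per-pair shared shift (SD 0.02) plus a second
  shared shift of the same SD for MZ pairs, so MZ within-pair correlation
  exceeds DZ, over i.i.d. Gaussian noise (SD 0.03) truncated to [0, 1];
* single-probe epimutations: per-sample Poisson counts (control rate 50
  per sample by default, split half hypo / half hyper), with the hypo rate
  multiplied in cases (default ×2, matching the direction of the group
  effect the package is designed to detect);
* contiguous epimutation clusters for region-scan truth.

Spikes displace a value to at least 0.15 beta units beyond the cohort's
pre-spike outlier bound, then clamp to [0.001, 0.999]; only probes where
the full displacement fits are eligible, so every recorded single-probe
spike is callable by construction. Cluster spans are placed uniformly
among positions where at least 80% of member probes can be displaced past
their bound within the clamp (falling back to the best available stretch),
implementing the same callability guarantee at region scale.

What the generator does *not* emulate — and hence what passing tests do
not show about real arrays: Infinium I/II chemistry differences, batch
effects beyond a label, cell-composition variation, age effects,
cross-reactive probes, and spatial correlation of background noise. The
recovery and calibration results certify the algorithms, not the
biology.

Default desk-scale sizes (chosen once for stable quartiles at interactive
runtimes): 20,000 probes × 20 twin pairs for single-cohort checks; the
Monte-Carlo properties use 1,500–4,000 probes per cohort over 20–200
seeds, and the null calibration of the paired test uses 20,000 probes.

## Determinism and orchestration

All randomness in a pipeline run flows from one config seed: the generator
consumes it directly, and no downstream stage is stochastic, so identical
configs give bit-identical artifacts (verified by MD5 in the run manifest).
Coordinates are 1-based inclusive in manifests and 0-based half-open in
exported BED, converted bijectively. Sex-chromosome handling is the
caller's choice at manifest level; nothing in the pipeline treats
chromosomes asymmetrically.

## Known limitations

* The SEM reference-population question (external panel vs the cohort
  itself) is a genuine degree of freedom; both modes are supported and
  results can differ materially for small cohorts. Neither is asserted as
  canonical.
* The Wald z inference is mildly anti-conservative below ~20 families;
  users with few families should prefer the signed-rank companion.
* The region scanner's binomial null treats probes as exchangeable within
  a subject × direction scan; strong probe-density artefacts could
  inflate enrichment at dense loci (partly mitigated by probe-count
  windows).
* Gene annotation trusts the manifest's symbols verbatim; no aliasing or
  identifier mapping is attempted.
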