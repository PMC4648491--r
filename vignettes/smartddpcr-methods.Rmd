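---
title: "Measuring tumor preferential allelic imbalance with duplexed ddPCR: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tumor preferential allelic imbalance with duplexed ddPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartddpcr)
```

## The problem

Heritable cancer-risk SNPs can be subject to somatic selection: when a
tumor loses or gains copies at a locus carrying a heterozygous risk
variant, the risk allele may be preferentially retained or amplified
relative to the protective allele. This is *preferential allelic
imbalance* (PAI). Detecting it needs an accurate, absolute measurement of
the two allele copy numbers in tumor DNA — which duplexed droplet digital
PCR (ddPCR) provides — plus a calibrated definition of when a sample's
allelic ratio is genuinely imbalanced, a cohort-level test for a
directional excess, and a model of the somatic copy states that produce
imbalance. `smartddpcr` implements that full chain, along with a
simulator to generate ground-truthed cohorts and a scanner that nominates
candidate PAI loci from recurrent somatic copy-number alteration (SCNA)
peaks overlapping GWAS SNPs of a matching cancer type.

## Poisson quantitation of droplet counts

A duplexed well partitions the reaction into $n$ droplets (typically
10--20,000); each droplet is scored positive or negative per fluorescence
channel (FAM carries the risk allele, VIC the protective allele). Target
molecules distribute over droplets as Poisson, so with a fraction
$q = n_\mathrm{neg}/n$ of negative droplets the mean occupancy is
$\hat\lambda = -\ln q$ and the absolute concentration is
$\hat\lambda / V$ copies/µL for droplet volume $V$.

Numerical choices:

* **Droplet volume** defaults to $V = 0.00085$ µL (0.85 nL), the
  QX100-era convention; instruments do not report it and any fixed $V$
  cancels in every *proportion* the package computes, so only absolute
  copies/µL depend on it. It is configurable everywhere.
* **Confidence interval**: a 95% Wilson score interval on the negative
  fraction, pushed through $-\ln(\cdot)/V$. The Wilson interval is
  well-behaved at very low and very high occupancy where the Wald
  interval degenerates; simulation shows ~94% empirical coverage across
  $\lambda \in [0.05, 1]$ at 20,000 droplets.
* **Saturation**: all-positive wells have unbounded concentration and
  raise a dedicated error rather than returning `Inf`; the remedy
  (dilution) is an assay decision, not something to paper over.

The simulator draws each channel's positive count as
$\mathrm{Binomial}(n,\, 1 - e^{-cV})$, which is exactly the marginal of
per-droplet independent Poisson occupancy; channels are independent by
default, with an optional probe cross-reactivity rate (default 0) that
adds a fraction of the other allele's occupancy to a channel's rate. All
randomness descends from one top-level seed through deterministically
spawned per-well substreams, so cohorts are bit-reproducible.

## Allelic-imbalance calling

For a sample measured in replicate (duplicates by default), the
risk-allele proportion is

$$p = \frac{\bar c_\mathrm{risk}}{\bar c_\mathrm{risk} + \bar c_\mathrm{prot}},$$

0.5 in an unaltered heterozygote and invariant to rescaling both
concentrations. Thresholds come from *constitutional* (germline) DNA of
heterozygotes, which cannot carry somatic alterations: with mean $\mu$
and sample SD $s$ ($n-1$ denominator; the choice is ours, it is not
dictated by the method description) of the constitutional proportions,
the AI bounds are $\mu \pm 3s$ (three-sigma rule; the multiplier is
configurable). Calls use strict inequalities — a proportion exactly at a
bound is `no_AI` — matching the "above or below" definition. Samples with
total allele concentration below `min_total_conc` (default 5 copies/µL;
the study excluded low-concentration samples without printing its cutoff)
are `excluded`, and exclusion beats any other status. Thresholds are
calibrated per assay from pooled constitutional measurements; when every
subject has a paired normal, comparing each tumor against its own
constitutional proportion is preferable and can be done by passing that
subject's measurements to `calibrate_thresholds()` directly.

At 15,000 droplets and duplicate wells the measurement SD of $p$ is
roughly 0.003 near $p = 0.5$, so three-sigma thresholds sit near
0.49/0.51 on simulated data and the diploid false-positive rate is well
under the nominal 0.27% of a Gaussian three-sigma rule; clonal one-allele
losses ($p \to 1$ or $0$) are essentially always called.

## The PAI binomial test

Among tumors with AI, under the null each sample is equally likely to
favor either allele. The test is a one-sided exact binomial: with
$k = \max(k_\mathrm{risk}, k_\mathrm{prot})$ out of
$n = k_\mathrm{risk} + k_\mathrm{prot}$,
$p = P(X \ge k)$, $X \sim \mathrm{Binomial}(n, 1/2)$, summed exactly.
The tail is taken from the **majority** direction by default. This single
convention reproduces every published value we encode — including the
cohorts where the protective allele held the majority (4 vs 5 reports
0.5, where a strictly risk-directed tail would give 0.746) — and was
verified against exhaustive enumeration before adoption. A strict
a-priori risk-direction tail remains available via `direction = "risk"`.
Ties report $P(X \ge k) > 0.5$ with a tie flag. No multiple-testing
correction is applied across SNPs; raw per-SNP p-values are reported.

## Somatic copy states and clonal fraction

With a genomic-control assay (a locus not somatically altered in the
tumor type, e.g. an *SLC24A3*-style target), the control-normalized copy
number is $\mathrm{cn} = (\bar c_\mathrm{risk} + \bar
c_\mathrm{prot})/\bar c_\mathrm{ctrl}$, 1.0 for diploid. A tumor sample
is modelled as normal heterozygous cells plus one altered clone at
fraction $f$; each candidate state traces a curve in $(p, \mathrm{cn})$:

| model | cn | $p$ | at $f=1$ |
|---|---|---|---|
| diploid | 1 | 1/2 | (0.5, 1) |
| homozygous deletion | $1-f$ | 1/2 | (0.5, 0) |
| hemizygous deletion (prot lost) | $1-f/2$ | $1/(2-f)$ | (1, 0.5) |
| CN-LOH toward risk | 1 | $(1+f)/2$ | (1, 1) |
| trisomy, risk gained | $(2+f)/2$ | $(1+f)/(2+f)$ | (2/3, 1.5) |
| tetrasomy 3:1 risk | $1+f$ | $(1+2f)/(2+2f)$ | (0.75, 2) |

plus the risk/protective mirrors. The $f=1$ columns are the clusters seen
in hyperdiploid leukemias: 2/3 and 1/3 for diploid→triploid shifts, 0.75
for diploid→tetraploid, and 1/0 for chromosomal LOH arising via
near-haploidy. (Describing the 2:1 copy ratio of a trisomic heterozygote
as "3:2" would give 0.6; the forward model works in copy counts, so the
triploid cluster is at 2/3 ≈ 0.667.)

Classification projects the observed point onto every curve — the
projections have closed forms; the reciprocal-shaped curves reduce to a
quartic solved exactly — and keeps the model with the smallest Euclidean
residual. Two deliberate conventions:

* **Coincident curves.** Every curve passes through (0.5, 1) at $f = 0$,
  and the trisomy curve is exactly the $\mathrm{cn} \le 1.5$ segment of
  the 3:1 tetrasomy curve (trisomy at $f$ = tetrasomy at $f/2$). When
  several models achieve the same minimal residual at the same predicted
  point, the call goes to the simplest model (fewest somatic events), so
  an observation on the shared amplification segment is reported as
  trisomy. Those states are observationally indistinguishable there; no
  classifier could do better from $(p, \mathrm{cn})$ alone.
* **Ambiguity flag.** A call is flagged ambiguous when a model predicting
  a *genuinely different* point fits within `ambiguity_margin` (default
  0.02, on the O(1) scale shared by both axes) of the best residual.
  Observations near the diploid point are therefore routinely ambiguous —
  correctly so, since small subclonal events of several kinds are
  indistinguishable from noise there. Combined states (e.g. homozygous
  loss in one subclone plus CN-LOH in another) are outside the model
  space on purpose; they surface as high-residual or ambiguous calls
  rather than being force-fitted.

The residual metric is unweighted Euclidean distance; both axes are O(1)
and the measurement SDs of $p$ and cn are comparable at the default
simulation depth. Weighting by per-axis variance is a straightforward
user-side extension (scale the inputs), not a package option, to keep
calls comparable across cohorts.

## Agreement statistics

Copy-number estimates can be cross-checked against MLPA probe ratios
(averaged over locus probes per sample) and allele proportions against
Sanger peak heights. Lin's concordance correlation coefficient

$$\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}$$

uses population moments ($n$ denominators) per Lin's definition, with a
Fisher-z CI using Lin's (1989) standard error; $|\rho_c| \le |r|$ always,
with equality only absent location/scale shift. Reported $R^2$ is squared
Pearson correlation (not a regression $R^2$). Bland–Altman limits are
$\bar d \pm 1.96\,\mathrm{sd}(d)$ with the sample SD. Sanger proportions
are per-strand peak-height ratios averaged over forward and reverse
reads; an additive peak-height bias (dye/sequence-context effects) shifts
constitutional Sanger proportions above 0.5, which the tests assert
qualitatively — the direction, not a magnitude — since the bias size is
instrument-specific.

## The SCNA × GWAS scanner

Recurrent SCNA peak regions (GISTIC-style, 1-based inclusive hg19
coordinates; BED input is converted at the reader) are intersected with
GWAS-catalog SNPs: a SNP joins a peak if its position falls inside the
interval (inclusive bounds — the packaged peak table itself uses
start = 1 rows, fixing the dialect) *or* if it maps to a gene listed for
the peak. Trait phrases are mapped to controlled tumor-type codes through
an editable packaged vocabulary TSV — the matching logic never hard-codes
a cancer type — and a locus is a matched PAI candidate when its SCNA
tumor types intersect its SNPs' mapped codes. Summaries count a locus
once per cancer type (and once per reporting group, e.g. "lung" spanning
both lung adenocarcinoma and squamous codes), so per-cancer counts can
sum to more than the number of matched loci. Catalog rows with missing
positions or multi-SNP haplotypes are skipped with a reported count;
unmapped trait phrases warn rather than vanish.

## What the simulator does and does not emulate

`simulate_cohort()` generates constitutional diploid heterozygotes plus a
tumor arm of planted copy states (`"model:f:count"` triples) at a control
concentration of 800 copies/µL, 15,000 droplets, duplicate wells — a
mid-range operating point for 1–20 ng/µL DNA input. It emulates droplet
sampling noise, replicate structure, and clone-mixture copy arithmetic.
It does **not** emulate: fluorescence amplitude and threshold "rain",
probe cross-reactivity (unless enabled), inter-well pipetting variance,
tumor-purity dilution by normal cells beyond what a clone mixture
encodes, or PCR inhibition. A green simulation test therefore
establishes the statistical pipeline's correctness under ideal droplet
statistics, not robustness to instrument-level artifacts; the published
agreement figures against MLPA/Sanger (CCC 0.95, $R^2$ 0.91–0.98) depend
on the study's raw paired data and are deliberately not asserted —
property-based checks of the statistics stand in for them.

## Known limitations

* Single-SNP assays: thresholds and calls are per-assay; cross-assay
  pooling is the caller's decision.
* Solid tumors require a purity correction before the clonal fractions
  are interpretable; none is applied.
* The copy-state model space is single-event; combined subclonal events
  surface as ambiguity, not as calls.
* Absolute copies/µL inherit the droplet-volume convention; only
  proportions and normalized copy numbers are convention-free.
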