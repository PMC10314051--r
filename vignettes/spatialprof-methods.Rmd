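---
title: "Methods: QC, normalization and region-trend analysis for digital spatial profiling"
author: "spatialprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QC, normalization and region-trend analysis for digital spatial profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialprof)
```

# The setting

GeoMx-style digital spatial profiling (DSP) measures a targeted RNA panel in
pathologist-drawn regions of interest (ROIs) on a tissue section. Each ROI is
illuminated twice, once for the pan-cytokeratin-positive (PanCK, epithelial)
compartment and once for the vimentin-positive (Vimentin, stromal)
compartment, producing two *areas of illumination* (AOIs) per ROI. In early
(pT1) colorectal cancer, one lesion contains the full histological
progression — normal mucosa, transition area, low-grade dysplasia, high-grade
dysplasia, carcinoma — so within-sample comparisons along this ordered axis
isolate the transcriptional program of malignant transformation from
inter-patient variation. `spatialprof` implements the complete analysis path
for such a design: probe-level QC, normalization, single-sample gene-set
enrichment, gene-set-based cell-type deconvolution, and the differential and
trend statistics, together with a synthetic-data generator that makes every
stage testable without any download.

The ordinal coding of histology is fixed throughout: normal = 1,
transition = 2, low-grade dysplasia = 3, high-grade dysplasia = 4,
carcinoma = 5 (`histology_rank()`).

# Quality control

**AOI flags.** Seven technical rules flag low-performing AOIs, each a strict
inequality against its threshold (`qc_thresholds()` defaults in
parentheses, an AOI exactly at a threshold is *not* flagged): raw reads
(< 1000), percent aligned reads (< 80), sequencing saturation (< 50),
negative-probe count geometric mean (< 10), no-template-control count
(> 60), nuclei (< 100), surface area (< 600 µm²). Flags are advisory —
the AOI is annotated, not removed — because background-comparable signal,
not any single sequencing metric, is the evidence that an AOI is
unusable. A `drop_flagged` switch in `run_qc()` enables hard filtering.

**Probe QC.** Targets are carried by several probes (five in the cancer
transcriptome panel emulated here). For every multi-probe target,
`probe_qc()` applies two rules:

* *Local (per AOI):* a two-sided single-outlier Grubbs test at
  $\alpha = 0.05$ on the target's probe values. The rejected probe is
  excluded from that AOI's target count only. The test runs on
  $\log_2$ counts: probe noise is multiplicative, and Grubbs assumes
  approximate normality, which holds far better on the log scale. The
  critical value is $\frac{n-1}{\sqrt{n}}
  \sqrt{t^2_{\alpha/2n,\,n-2}\big/\big(n-2+t^2_{\alpha/2n,\,n-2}\big)}$;
  with $n < 3$ probes the test is undefined and the target is exempt.
  (With $n = 3$ the critical value, 1.1543, sits just below the largest
  attainable statistic $2/\sqrt{3} \approx 1.1547$, so three-probe panels
  essentially cannot fail a probe — one reason panels carry five probes.)
* *Global:* a probe is removed from all AOIs when its geometric mean
  across AOIs is at most 0.1 of its target's overall probe geometric
  mean **and** it fails the Grubbs test in at least 20% of AOIs.

The last retained probe of a target is never excluded. Zeros entering any
geometric statistic are replaced by 0.5 — half the smallest observable
count.

**Limit of quantitation.** Per AOI, the negative probes (panel probes with
no genomic target) estimate nonspecific binding. The LOQ is defined on the
geometric scale: $\mathrm{LOQ}_j = \mathrm{GeoMean}(\mathrm{neg}_j) \cdot
\mathrm{GeoSD}(\mathrm{neg}_j)^{2}$, with $\mathrm{GeoSD} =
\exp(\mathrm{sd}(\log x))$ (sample sd). The multiplicative ("geomean times
geoSD squared") reading of "two SDs of the geomean" follows the vendor
convention for these log-normal-like background counts; an additive reading
would mix scales.

**Background-based dropping.** An AOI whose third-quartile target signal is
below `background_min_ratio` (default 2) times its negative-probe geomean
is dropped: its on-target signal is not separable from background. The
ratio 2 is a package choice — the underlying guideline is qualitative
("comparable to background") — and is exposed in the configuration for
sensitivity analysis.

# Normalization

`collapse_targets()` summarizes each target per AOI as the geometric mean
of its retained probes. `q3_normalize()` then computes each AOI's 75th
percentile over target values (type-7, linear-interpolation quantile — Q3
conventions differ between software, so the choice is fixed and recorded),
takes the geometric mean of those quartiles as the common reference $R$,
and rescales AOI $j$ by $R/q3_j$. Q3 normalization addresses the dominant
technical column effects — segment area, amount of targetable mRNA,
hybridisation efficiency — while being robust to the lower half of the
count distribution where background dominates. Q3 is computed over all
targets (an above-LOQ-only variant exists as a configuration switch);
negative probes are never included. `log2_transform()` (pseudocount 1)
prepares the matrix for enrichment scoring and statistics.

`merge_and_renormalize()` joins two raw cohorts (for example, the study
cohort and a healthy-colon reference atlas) on their shared targets and
re-runs Q3 on the merged matrix, so columns from both cohorts become
directly comparable. The intersection-only merge keeps downstream columns
complete.

# Enrichment scoring and deconvolution

`ssgsea_score()` implements single-sample gene-set enrichment as a
rank walk. Genes are sorted by decreasing expression (ties resolved by
stable input order). Let the gene at sorted position $i$ of $N$ carry the
rank statistic $r_i = N - i + 1$. The score of set $S$ is

$$\mathrm{ES}(S) = \sum_{i=1}^{N} \left[ P_{\mathrm{in}}(i) -
P_{\mathrm{out}}(i) \right], \quad
P_{\mathrm{in}}(i) = \frac{\sum_{k \le i,\, k \in S} r_k^{\alpha}}
{\sum_{k \in S} r_k^{\alpha}}, \quad
P_{\mathrm{out}}(i) = \frac{\#\{k \le i,\, k \notin S\}}{N - |S|}.$$

The exponent defaults to $\alpha = 0.25$, the weighting of the original
single-sample enrichment method. Weights use rank positions, not raw
expression, so scores are invariant under any strictly increasing
transform of a sample's expression — normalization scale cannot leak into
the scores. No cross-sample rescaling is applied by default (correlation
and clustering downstream are unaffected); `rescale = TRUE` enables
min-max rescaling.

**Panel-applicability filter.** A targeted panel cannot faithfully score
every gene set. `filter_sets_by_panel()` scores each set on a
full-transcriptome reference cohort twice — once on all genes, once
restricted to the panel — and keeps the set only when the Pearson
correlation between the two per-sample score vectors is at least 0.6.
Sets with fewer than 2 panel genes are removed; a manual exclusion list
and explicit redundancy groups (keep the highest-correlation member per
group) implement the curation steps that cannot be inferred from data.

**Deconvolution.** `deconvolve()` scores cell-type marker gene sets with
the same engine, giving per-AOI relative abundance scores per cell type
(consensus tumour-microenvironment style). Scores are comparable across
AOIs within a cell type, not between cell types. The package ships
`inst/extdata/immune_markers_synthetic.gmt`, a small hand-assembled
collection of canonical immune and stromal markers, as a synthetic
stand-in example; any marker GMT is accepted.

# Differential and trend statistics

All result tables share one schema (`unit_id`, `contrast`, `segment`,
`effect`, `p_value`, `fdr`, `direction`) and all FDR adjustment is
Benjamini–Hochberg (`bh_fdr()`), computed within segment and contrast
family.

* `paired_segment_de()`: paired t-test per gene across complete ROI pairs,
  effect = mean paired $\log_2$ difference (PanCK − Vimentin).
* `stepwise_de()`: Welch t-tests for the four adjacent histology pairs
  within one segment; a gene is called at $p < 0.05$ **and**
  $|\log_2\mathrm{FC}| > 0.5$. The pooled-variance variant is available
  (`var_equal = TRUE`); Welch is the default because group variances
  along the progression axis have no reason to be equal.
* `ordinal_trend()`: Spearman correlation (mid-ranks) between expression
  and the ordinal histology rank, two-sided p by the t-approximation, per
  segment.
* `region_anova()`: classic one-way F across histology groups, applied to
  genes or to deconvolution scores.

Zero-variance units are reported with $p = 1$ ("no evidence") rather than
`NA`, so the BH input is always complete; such units are flagged
`degenerate` where relevant.

# The synthetic-data generator

`simulate_dsp()` emulates the study design: 8 samples × 9 ROIs × 2
segments (144 AOIs), 500 targets × 5 probes, 30 negative probes. For AOI
$j$ (scale $s_j$, segment $g$, rank $r$) and target $t$:

$$\mu_{tj} = \mathrm{base}_t \cdot s_j \cdot 2^{\beta_t (r-1)} \cdot
2^{\gamma_t \,[g = \mathrm{PanCK}]},$$

with each probe drawing $\mathrm{NB}(\mu_{tj}\pi_p,\ \theta = 10)$ and
probe factor $\pi_p = 1$ except planted outlier probes
($\pi_p = 1/20$). Negative probes draw log-normal background around a
per-AOI level uniform in 12–28 counts, independent of $s_j$ (nonspecific
binding does not scale with target mRNA). Defaults: 10% trend genes at
±0.5 $\log_2$ per rank step (signs alternating), 30% segment genes at
±1 $\log_2$, AOI scale factors log-normal(0, 0.4), 5% of AOIs planted to
trip exactly one QC threshold, two planted 15-gene sets (one rising, one
falling with rank) drawn from the trend genes. Baseline means are
log2-normal(7, 1) floored at 32 counts: a panel target must be
quantifiable above the ~10–30-count background for a 20×-attenuated
outlier probe to be a measurable phenomenon at all. Outlier probes are
planted only on targets without trend or segment effects, so every
ground-truth label isolates a single mechanism. Everything is reproducible
from one seed, and `fixture_small()` provides a deterministic 6-AOI,
20-target miniature (with one planted outlier probe and one
background-level AOI) for unit tests.

What the generator does *not* emulate: spatial autocorrelation between
neighbouring ROIs, patient-level random effects, probe-specific
efficiencies beyond the planted outliers, gene–gene correlation beyond
what shared scale factors induce, and segment-dependent background. Tests
passing on this generator therefore demonstrate the pipeline's
correctness under its stated noise model, not robustness to every
property of real tissue data.

# Numerical and design choices

* Quantile type 7 for Q3; geometric statistics with the 0.5 zero shift;
  sample (n−1) sd everywhere, including `zscore_rows()` (recorded in the
  output's `sd_type` attribute).
* Grubbs on $\log_2$ counts, $\alpha = 0.05$, per-AOI granularity: each
  illuminated segment of an ROI is one "segment" in the probe-QC sense.
* Spearman p-values use the t-approximation with mid-ranks; at such AOI
  counts (≥ 70 per segment) the approximation is accurate to well below
  the decision thresholds used.
* Ties in the enrichment walk are resolved by stable input order, making
  scores deterministic; a fully constant sample is scored, not erroneous.
* Problem sizes in tests: oracle comparisons at 10⁴ random BH vectors,
  Grubbs decisions over $n \in 3..30$, 10³ random enrichment instances;
  calibration at 1000 null genes; recovery at the default 500-target
  design. These sizes give Monte Carlo error comfortably below every
  asserted margin.

# Known limitations

**Composition bias of Q3 normalization.** When a sizeable fraction of the
panel changes several-fold along the histology axis, the 75th percentile
itself drifts with histology even under sign-balanced changes, because the
expression distribution is log-normal-like: more genes sit below Q3 than
above it, so symmetric migration across the quartile is asymmetric in
effect. Dividing by a drifting Q3 imprints a small compensatory
*anti-trend* on every unchanged gene (in the default generator,
~0.02–0.03 $\log_2$ per rank step). With ≥ 70 AOIs per segment the
Spearman trend test has power against even this small artifact, so
discovery lists at BH 0.05 contain genuinely null genes whose apparent
trend is a normalization echo, and apparent "down" regulation is
systematically overrepresented when true changes skew upward (and vice
versa). This is the classic composition problem that motivates
median-of-ratios and trimmed-mean size factors in sequencing analysis;
quartile normalization is retained here because it is the established
convention for this platform, but trend discovery lists should be read
with the bias in mind, and effect sizes near the detection floor
(|rho| ≲ 0.3 at these AOI counts) should not be over-interpreted.
`scripts/acceptance.R` quantifies the effect (`trend_truth_level_fdr`)
on every run.

**Other limitations.** The paired segment test conditions on complete ROI
pairs; no patient-nested or mixed-effects structure is modelled; the
deposited-data reproduction (`reproduce_deposited()`) requires the user to
download the study matrices and is exercised in tests only on a synthetic
stand-in; heatmap clustering defaults (Euclidean, average linkage) in
report layers are display conventions, not validated analysis.
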