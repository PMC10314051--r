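# spatialprof

Quality control, normalization, enrichment and region-trend analysis for
GeoMx-style digital spatial profiling (DSP) of tissues with ordered
histology — built for the early-colorectal-cancer design in which one pT1
lesion contains the whole progression from normal mucosa through dysplasia
to carcinoma, profiled separately in its epithelial (PanCK) and stromal
(Vimentin) compartments.

## Who this is for

Analysts working with probe-level DSP count matrices (probes × areas of
illumination) who need a reproducible, scriptable path from raw counts to
statistics, instead of a point-and-click analysis suite: spatial
transcriptomics of tumour progression, marker discovery along an ordinal
histology axis, and gene-set-level characterization of the tumour
microenvironment.

## What it computes

- **AOI QC**: seven advisory flags with strict thresholds (raw reads
  < 1000, aligned < 80 %, saturation < 50 %, negative-probe geomean < 10,
  NTC count > 60, nuclei < 100, area < 600 µm²), plus background-based
  dropping of AOIs whose Q3 signal is within 2× of the negative-probe
  geometric mean.
- **Probe QC**: per-AOI two-sided single-outlier Grubbs test (α = 0.05, on
  log2 counts) for local exclusions; global exclusion when
  geomean(probe)/geomean(target) ≤ 0.1 *and* Grubbs failure in ≥ 20 % of
  AOIs.
- **Limit of quantitation**: LOQ = GeoMean(neg) · GeoSD(neg)², per AOI.
- **Normalization**: probe → target collapse by geometric mean, Q3
  (third-quartile) normalization `v′ᵢⱼ = vᵢⱼ · R / q3ⱼ` with
  `R = GeoMean(q3)`, log2 transform, and raw-cohort merging with joint
  renormalization.
- **ssGSEA**: rank-walk enrichment score
  `ES(S) = Σᵢ [P_in(i) − P_out(i)]` with rank-statistic weights
  `r^α` (α = 0.25), a panel-applicability filter (keep sets whose
  full-vs-panel score correlation is ≥ 0.6 on a reference cohort), and
  gene-set-based immune cell deconvolution.
- **Statistics**: paired segment t-tests, stepwise Welch t-tests between
  adjacent histologies (gates p < 0.05 and |log2FC| > 0.5), Spearman
  ordinal trend along normal(1) → carcinoma(5), one-way region ANOVA, all
  with Benjamini–Hochberg FDR.
- **Synthetic data**: a negative-binomial generator with planted trend /
  segment genes, outlier probes, QC violators and gene sets, so the whole
  pipeline is testable offline with known ground truth.

## Worked example

```r
library(spatialprof)

sim <- simulate_dsp(sim_config(), seed = 7)   # 144 AOIs, 500 targets
qc  <- run_qc(sim$counts, sim$annotation)
qc
#> qc_report: 144 AOIs; 7 flagged; 0 dropped; 50 probes globally excluded; 3457 local probe exclusions

nm    <- normalize_pipeline(sim$counts, qc)   # collapse -> Q3 -> log2
trend <- ordinal_trend(nm$log2, sim$annotation, segment = "PanCK")
head(trend[order(trend$fdr), c("unit_id", "effect", "p_value", "fdr", "direction")], 5)
#>     unit_id     effect      p_value          fdr direction
#> 421   G0421 -0.9569205 2.517283e-39 6.293206e-37      down
#> 487   G0487 -0.9570533 2.264556e-39 6.293206e-37      down
#> 29    G0029  0.9547961 1.309334e-38 1.309334e-36        up
#> 81    G0081 -0.9549289 1.183889e-38 1.309334e-36      down
#> 441   G0441 -0.9551944 9.670199e-39 1.309334e-36      down

count_significant(trend, fdr_cut = 0.05)
#>  n_up n_down
#>    25     54
```

The seven flagged AOIs are exactly the generator's planted QC violators and
the 50 globally excluded probes are exactly its planted outlier probes
(`sim$truth`). The top trend genes are planted ±0.5 log2-per-step genes
whose Spearman rho against the histology rank approaches ±1. The
up/down asymmetry among discoveries (25 up vs 54 down, with 25 planted in
each direction) is the composition bias of quartile normalization — a
known limitation discussed in the methods vignette
(`vignettes/spatialprof-methods.Rmd`).

Real data enter through `read_probe_counts()` / `read_aoi_annotation()`
(TSV/CSV) and `read_gmt()`; `reproduce_deposited()` re-runs
QC → normalization → contrasts on a downloaded raw/normalized matrix pair
and reports per-AOI concordance.

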