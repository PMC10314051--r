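# Synthetic GeoMx-like probe-count generator with planted ground truth:
# negative-binomial target counts with segment and histology-trend effects,
# log-normal negative-probe background, occasional outlier probes, and AOI
# technical covariates spanning the QC thresholds.

#' Simulation configuration
#'
#' Defaults emulate the study design: 8 samples, 9 ROIs per sample spanning
#' the histology axis, each ROI illuminated once per segment (144 AOIs),
#' a targeted panel with 5 probes per target, 30 negative probes.
#'
#' @param n_samples Number of tissue samples (default 8).
#' @param rois_per_sample ROIs per sample (default 9).
#' @param histology_profile Integer ranks (1..5) assigned to the ROIs of
#'   each sample; default one normal, one transition, two low-grade, two
#'   high-grade, three carcinoma.
#' @param n_targets Number of panel targets (default 500).
#' @param probes_per_target Probes per target (default 5, panel-style;
#'   1-10 supported).
#' @param n_negative_probes Negative probes (default 30).
#' @param base_log2_mean,base_log2_sd Log2-normal distribution of baseline
#'   target means (defaults 7 and 1: counts centred near 128).
#' @param base_min Floor on baseline target means (default 32, about twice
#'   the negative-probe background: panel targets are quantifiable above
#'   background, so an attenuated outlier probe still registers counts).
#' @param dispersion Negative-binomial size parameter theta (default 10).
#' @param frac_trend_genes Fraction of targets with a histology trend
#'   (default 0.1; signs alternate so half go up, half down).
#' @param trend_effect Log2 change per ordinal step (default 0.5).
#' @param frac_segment_genes Fraction of targets with a segment effect
#'   (default 0.3, signs alternating).
#' @param segment_effect Log2 difference PanCK vs Vimentin (default 1).
#' @param outlier_probe_frac Fraction of target probes attenuated
#'   (default 0.02).
#' @param outlier_attenuation Attenuation factor of outlier probes
#'   (default 20, i.e. outliers sit at 5 percent of their siblings).
#' @param aoi_scale_sdlog SD of the log-normal per-AOI technical scale
#'   factors (default 0.4).
#' @param qc_violation_frac Fraction of AOIs engineered to trip one random
#'   QC threshold (default 0.05).
#' @param neg_level_range Range of the per-AOI negative-probe geometric
#'   mean (default c(12, 28), inside the passing band above 10).
#' @param neg_sdlog Log-normal spread of negative-probe counts
#'   (default 0.35).
#' @param n_planted_sets Number of planted gene sets with histology-tied
#'   activity (default 2: one rising, one falling).
#' @param planted_set_size Genes per planted set (default 15).
#' @param seed Default seed used by [simulate_dsp] when none is given.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 8, rois_per_sample = 9,
                       histology_profile = c(1L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 5L),
                       n_targets = 500, probes_per_target = 5,
                       n_negative_probes = 30,
                       base_log2_mean = 7, base_log2_sd = 1,
                       base_min = 32, dispersion = 10,
                       frac_trend_genes = 0.1, trend_effect = 0.5,
                       frac_segment_genes = 0.3, segment_effect = 1,
                       outlier_probe_frac = 0.02, outlier_attenuation = 20,
                       aoi_scale_sdlog = 0.4, qc_violation_frac = 0.05,
                       neg_level_range = c(12, 28), neg_sdlog = 0.35,
                       n_planted_sets = 2, planted_set_size = 15,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (length(histology_profile) != rois_per_sample)
    stop("histology_profile must have rois_per_sample entries")
  if (!all(histology_profile %in% 1:5))
    stop("histology ranks must lie in 1..5")
  if (length(unique(histology_profile)) < 2)
    stop("at least 2 distinct histology ranks are required")
  fr <- c(frac_trend_genes, frac_segment_genes, outlier_probe_frac,
          qc_violation_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (probes_per_target < 1 || probes_per_target > 10)
    stop("probes_per_target must lie in 1..10")
  if (!all(is.finite(c(trend_effect, segment_effect))))
    stop("effects must be finite")
  structure(cfg, class = "sim_config")
}

RANK_LABELS <- names(HISTOLOGY_RANKS)

.alternating_signs <- function(n) rep_len(c(1, -1), n)

#' Simulate a GeoMx-like dataset with known ground truth
#'
#' For AOI j with technical scale s_j, segment g and histology rank r, a
#' target t has mean mu = base_t * s_j * 2^(beta_t (r-1)) * 2^(gamma_t
#' [g = PanCK]); each of its probes draws a negative binomial with mean
#' mu * pi_p (probe factor; outlier probes pi = 1/attenuation) and size
#' `dispersion`. Negative probes draw a log-normal background independent
#' of s_j (nonspecific binding does not scale with target RNA). Technical
#' annotations are drawn to pass QC except for planted violators, each of
#' which trips exactly one threshold.
#'
#' @param cfg A [sim_config].
#' @param seed Integer seed; the output is fully reproducible from it.
#' @return A list of class `dsp_simulation`: `counts` ([probe_counts]),
#'   `annotation` (AOI data frame), `truth` (planted ground truth:
#'   trend/segment gene effects, outlier probe ids, AOI scale factors, QC
#'   violators and their violated threshold, planted gene sets), and
#'   `config`.
#' @export
simulate_dsp <- function(cfg = sim_config(), seed = cfg$seed) {
  set.seed(seed)
  n_roi <- cfg$n_samples * cfg$rois_per_sample
  samples <- rep(sprintf("S%02d", seq_len(cfg$n_samples)),
                 each = cfg$rois_per_sample)
  rois <- rep(sprintf("R%02d", seq_len(cfg$rois_per_sample)),
              times = cfg$n_samples)
  roi_rank <- rep(cfg$histology_profile, times = cfg$n_samples)

  # two AOIs per ROI, one per segment
  aoi <- data.frame(
    sample_id = rep(samples, each = 2),
    roi_id = rep(rois, each = 2),
    segment = rep(SEGMENT_LEVELS, times = n_roi),
    histology_rank = rep(roi_rank, each = 2),
    stringsAsFactors = FALSE
  )
  aoi$histology <- RANK_LABELS[aoi$histology_rank]
  aoi$aoi_id <- paste(aoi$sample_id, aoi$roi_id, aoi$segment, sep = "_")
  n_aoi <- nrow(aoi)

  scale_factors <- stats::rlnorm(n_aoi, 0, cfg$aoi_scale_sdlog)

  targets <- sprintf("G%04d", seq_len(cfg$n_targets))
  base <- pmax(2^stats::rnorm(cfg$n_targets, cfg$base_log2_mean,
                              cfg$base_log2_sd), cfg$base_min)

  n_trend <- round(cfg$frac_trend_genes * cfg$n_targets)
  trend_idx <- if (n_trend) sample.int(cfg$n_targets, n_trend) else integer(0)
  beta <- numeric(cfg$n_targets)
  beta[trend_idx] <- cfg$trend_effect * .alternating_signs(n_trend)

  n_seg <- round(cfg$frac_segment_genes * cfg$n_targets)
  seg_idx <- if (n_seg) sample.int(cfg$n_targets, n_seg) else integer(0)
  gamma <- numeric(cfg$n_targets)
  gamma[seg_idx] <- cfg$segment_effect * .alternating_signs(n_seg)

  # probe layout
  ppt <- cfg$probes_per_target
  probe_target <- rep(targets, each = ppt)
  probe_id <- paste0(probe_target, ".p", rep(seq_len(ppt), cfg$n_targets))
  n_probes <- length(probe_id)
  pi_p <- rep(1, n_probes)
  n_out <- round(cfg$outlier_probe_frac * n_probes)
  outlier_idx <- integer(0)
  if (n_out && ppt >= 3) {
    # at most one outlier per target (siblings stay a clean majority), and
    # only on targets without trend/segment effects so each ground-truth
    # label isolates a single planted mechanism
    pool <- setdiff(seq_len(cfg$n_targets), union(trend_idx, seg_idx))
    out_targets <- sample(pool, min(n_out, length(pool)))
    outlier_idx <- (out_targets - 1L) * ppt +
      sample.int(ppt, length(out_targets), replace = TRUE)
    pi_p[outlier_idx] <- 1 / cfg$outlier_attenuation
  }

  # planted QC violators: each trips exactly one threshold
  n_viol <- round(cfg$qc_violation_frac * n_aoi)
  viol_idx <- if (n_viol) sample.int(n_aoi, n_viol) else integer(0)
  viol_type <- if (n_viol) sample(AOI_FLAGS, n_viol, replace = TRUE)
               else character(0)

  # annotations drawn safely inside the passing region
  ann <- data.frame(
    aoi_id = aoi$aoi_id, sample_id = aoi$sample_id, roi_id = aoi$roi_id,
    segment = aoi$segment, histology = aoi$histology,
    nuclei = round(stats::runif(n_aoi, 150, 3000)),
    area = round(stats::runif(n_aoi, 15000, 350000)),
    raw_reads = round(stats::runif(n_aoi, 5e4, 5e5)),
    pct_aligned = stats::runif(n_aoi, 85, 99),
    seq_saturation = stats::runif(n_aoi, 60, 95),
    ntc_count = round(stats::runif(n_aoi, 0, 20)),
    stringsAsFactors = FALSE
  )
  neg_level <- stats::runif(n_aoi, cfg$neg_level_range[1],
                            cfg$neg_level_range[2])
  for (k in seq_along(viol_idx)) {
    i <- viol_idx[k]
    switch(viol_type[k],
           low_reads       = { ann$raw_reads[i] <- 500 },
           low_aligned     = { ann$pct_aligned[i] <- 70 },
           low_saturation  = { ann$seq_saturation[i] <- 40 },
           low_neg_geomean = { neg_level[i] <- 5 },
           high_ntc        = { ann$ntc_count[i] <- 100 },
           low_nuclei      = { ann$nuclei[i] <- 50 },
           low_area        = { ann$area[i] <- 400 })
  }

  # target probe counts
  log2mu_rank <- outer(beta, aoi$histology_rank - 1)      # targets x AOIs
  log2mu_seg <- outer(gamma, as.numeric(aoi$segment == "PanCK"))
  mu_t <- base * 2^(log2mu_rank + log2mu_seg) *
    rep(scale_factors, each = cfg$n_targets)
  mu_p <- mu_t[rep(seq_len(cfg$n_targets), each = ppt), , drop = FALSE] * pi_p
  counts_t <- matrix(
    stats::rnbinom(length(mu_p), mu = as.vector(mu_p), size = cfg$dispersion),
    nrow = n_probes, dimnames = list(probe_id, aoi$aoi_id))

  # negative probes: log-normal background around the per-AOI level
  neg_id <- sprintf("NegProbe.%02d", seq_len(cfg$n_negative_probes))
  counts_n <- matrix(
    round(stats::rlnorm(cfg$n_negative_probes * n_aoi,
                        rep(log(neg_level), each = cfg$n_negative_probes),
                        cfg$neg_sdlog)),
    nrow = cfg$n_negative_probes, dimnames = list(neg_id, aoi$aoi_id))

  # one NTC control row mirroring the annotation counts
  counts_c <- matrix(ann$ntc_count, nrow = 1,
                     dimnames = list("NTC.01", aoi$aoi_id))

  meta <- data.frame(
    probe_id = c(probe_id, neg_id, "NTC.01"),
    target = c(probe_target, neg_id, "NTC.01"),
    probe_class = c(rep("target", n_probes),
                    rep("negative", cfg$n_negative_probes), "ntc"),
    stringsAsFactors = FALSE
  )
  pc <- probe_counts(rbind(counts_t, counts_n, counts_c), meta)
  ann <- validate_aoi_annotation(ann)

  # planted gene sets tied to histology: one per sign, drawn from the
  # planted trend genes
  sets <- list()
  if (cfg$n_planted_sets > 0 && n_trend > 0) {
    up <- targets[trend_idx][beta[trend_idx] > 0]
    dn <- targets[trend_idx][beta[trend_idx] < 0]
    pools <- rep_len(list(up, dn), cfg$n_planted_sets)
    dirs <- rep_len(c("rising", "falling"), cfg$n_planted_sets)
    for (s in seq_len(cfg$n_planted_sets)) {
      pool <- pools[[s]]
      size <- min(cfg$planted_set_size, length(pool))
      if (size >= 2)
        sets[[sprintf("planted_%s_%d", dirs[s], s)]] <- sample(pool, size)
    }
  }
  planted_sets <- if (length(sets))
    gene_set_collection(sets, source = "simulation") else NULL

  truth <- list(
    trend_genes = data.frame(gene = targets[trend_idx],
                             effect = beta[trend_idx],
                             stringsAsFactors = FALSE),
    segment_genes = data.frame(gene = targets[seg_idx],
                               effect = gamma[seg_idx],
                               stringsAsFactors = FALSE),
    outlier_probe_ids = probe_id[outlier_idx],
    aoi_scale_factors = stats::setNames(scale_factors, aoi$aoi_id),
    qc_violations = data.frame(aoi_id = aoi$aoi_id[viol_idx],
                               flag = viol_type,
                               stringsAsFactors = FALSE),
    planted_sets = planted_sets,
    neg_level = stats::setNames(neg_level, aoi$aoi_id)
  )
  structure(list(counts = pc, annotation = ann, truth = truth, config = cfg,
                 seed = seed),
            class = "dsp_simulation")
}

#' @export
print.dsp_simulation <- function(x, ...) {
  cat("dsp_simulation: ", nrow(x$counts$counts), " probes x ",
      ncol(x$counts$counts), " AOIs; ",
      NROW(x$truth$trend_genes), " trend genes, ",
      NROW(x$truth$segment_genes), " segment genes, ",
      length(x$truth$outlier_probe_ids), " outlier probes, ",
      NROW(x$truth$qc_violations), " QC violators (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes `counts.tsv`, `aois.tsv` and `truth.json` to a directory.
#'
#' @param sim A `dsp_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_probe_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_aoi_annotation(sim$annotation, file.path(dir, "aois.tsv"))
  truth <- sim$truth
  truth$planted_sets <- if (!is.null(truth$planted_sets))
    truth$planted_sets$sets else NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Tiny deterministic fixture for unit tests
#'
#' 3 ROIs (ranks 1, 3, 5) x 2 segments, 20 targets (19 with 2 probes, one
#' with 5 probes of which one is a planted 20x-attenuated outlier), 5
#' negative probes, and one planted background-level AOI whose target
#' signal sits at the negative-probe level. Deterministic: an internal
#' fixed seed is used and the caller's RNG state is untouched.
#'
#' @return A `dsp_simulation`-like list with `counts`, `annotation`,
#'   `truth`.
#' @export
fixture_small <- function() {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(20220)

  ranks <- c(1L, 3L, 5L)
  aoi <- expand.grid(segment = SEGMENT_LEVELS, roi = sprintf("R%02d", 1:3),
                     stringsAsFactors = FALSE)
  aoi$sample_id <- "S01"
  aoi$rank <- rep(ranks, each = 2)
  aoi$aoi_id <- paste(aoi$sample_id, aoi$roi, aoi$segment, sep = "_")
  n_aoi <- nrow(aoi)

  targets <- sprintf("T%02d", 1:20)
  ppt <- c(5L, rep(2L, 19))  # T01 carries the 5-probe outlier target
  probe_target <- rep(targets, times = ppt)
  probe_id <- unlist(lapply(seq_along(targets), function(i)
    paste0(targets[i], ".p", seq_len(ppt[i]))))
  pi_p <- rep(1, length(probe_id))
  outlier_probe <- "T01.p5"
  pi_p[probe_id == outlier_probe] <- 1 / 30

  base <- 2^stats::runif(20, 6, 8)
  background_aoi <- aoi$aoi_id[n_aoi]
  aoi_scale <- rep(1, n_aoi)
  aoi_scale[n_aoi] <- 0.08  # drives Q3 down to the background level

  mu <- outer(base[match(probe_target, targets)] * pi_p, aoi_scale)
  counts_t <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = 40),
                     nrow = length(probe_id),
                     dimnames = list(probe_id, aoi$aoi_id))

  neg_id <- sprintf("NegProbe.%02d", 1:5)
  counts_n <- matrix(round(stats::rlnorm(5 * n_aoi, log(14), 0.25)),
                     nrow = 5, dimnames = list(neg_id, aoi$aoi_id))

  meta <- data.frame(
    probe_id = c(probe_id, neg_id),
    target = c(probe_target, neg_id),
    probe_class = c(rep("target", length(probe_id)), rep("negative", 5)),
    stringsAsFactors = FALSE
  )
  pc <- probe_counts(rbind(counts_t, counts_n), meta)

  ann <- data.frame(
    aoi_id = aoi$aoi_id, sample_id = aoi$sample_id, roi_id = aoi$roi,
    segment = aoi$segment, histology = RANK_LABELS[aoi$rank],
    nuclei = round(stats::runif(n_aoi, 200, 2000)),
    area = round(stats::runif(n_aoi, 20000, 200000)),
    raw_reads = round(stats::runif(n_aoi, 1e5, 4e5)),
    pct_aligned = stats::runif(n_aoi, 88, 98),
    seq_saturation = stats::runif(n_aoi, 65, 90),
    ntc_count = round(stats::runif(n_aoi, 0, 10)),
    stringsAsFactors = FALSE
  )
  ann <- validate_aoi_annotation(ann)

  structure(list(
    counts = pc, annotation = ann,
    truth = list(outlier_probe_ids = outlier_probe,
                 background_aoi = background_aoi,
                 aoi_scale_factors = stats::setNames(aoi_scale, aoi$aoi_id)),
    config = NULL, seed = 20220
  ), class = "dsp_simulation")
}
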