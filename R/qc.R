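# AOI- and probe-level quality control: threshold flags on the technical
# metrics, Grubbs/ratio probe filtering, negative-probe limit of
# quantitation, and background-based AOI dropping.

#' AOI QC thresholds
#'
#' Thresholds for flagging low-performing areas of illumination and for
#' probe QC / LOQ. All flag comparisons are strict inequalities: an AOI
#' sitting exactly at a threshold is not flagged.
#'
#' @param min_raw_reads Flag below this raw read count (default 1000).
#' @param min_pct_aligned Flag below this percent aligned (default 80).
#' @param min_seq_saturation Flag below this sequencing saturation percent
#'   (default 50).
#' @param min_neg_geomean Flag below this negative-probe count geometric
#'   mean (default 10).
#' @param max_ntc_count Flag above this no-template-control count
#'   (default 60).
#' @param min_nuclei Flag below this nucleus count (default 100).
#' @param min_area_um2 Flag below this surface area in square micrometres
#'   (default 600).
#' @param probe_ratio_max Global probe exclusion when
#'   geomean(probe)/geomean(target probes) is at or below this (default 0.1).
#' @param grubbs_fail_fraction Global probe exclusion requires Grubbs
#'   failure in at least this fraction of AOIs (default 0.20).
#' @param loq_n_sd Number of geometric SDs above the negative-probe geomean
#'   defining the limit of quantitation (default 2).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_raw_reads = 1000, min_pct_aligned = 80,
                          min_seq_saturation = 50, min_neg_geomean = 10,
                          max_ntc_count = 60, min_nuclei = 100,
                          min_area_um2 = 600, probe_ratio_max = 0.1,
                          grubbs_fail_fraction = 0.20, loq_n_sd = 2) {
  th <- list(min_raw_reads = min_raw_reads, min_pct_aligned = min_pct_aligned,
             min_seq_saturation = min_seq_saturation,
             min_neg_geomean = min_neg_geomean, max_ntc_count = max_ntc_count,
             min_nuclei = min_nuclei, min_area_um2 = min_area_um2,
             probe_ratio_max = probe_ratio_max,
             grubbs_fail_fraction = grubbs_fail_fraction, loq_n_sd = loq_n_sd)
  if (any(unlist(th[names(th) != "loq_n_sd"]) <= 0))
    stop("all thresholds must be positive")
  if (grubbs_fail_fraction > 1) stop("grubbs_fail_fraction must be in (0, 1]")
  if (probe_ratio_max >= 1) stop("probe_ratio_max must be in (0, 1)")
  if (loq_n_sd < 0) stop("loq_n_sd must be >= 0")
  structure(th, class = "qc_thresholds")
}

# Zero-handling policy: geometric statistics replace exact zeros by 0.5
# (half the smallest observable count), messaged once per call site that
# opts into reporting.
.shift_zeros <- function(x) {
  x[x == 0] <- 0.5
  x
}

#' Geometric mean
#'
#' Zero values are replaced by 0.5 before taking logs (counts are integers,
#' so 0.5 is half the smallest observable positive count).
#'
#' @param x Numeric vector of non-negative values.
#' @return `exp(mean(log(x)))`.
#' @examples
#' geomean(c(4, 9)) # 6
#' @export
geomean <- function(x) {
  if (!length(x)) stop("geomean of empty input")
  if (any(!is.finite(x) | x < 0)) stop("geomean requires finite values >= 0")
  exp(mean(log(.shift_zeros(x))))
}

#' Geometric standard deviation
#'
#' `exp(sd(log(x)))` with the sample (n-1) standard deviation and the same
#' zero policy as [geomean].
#'
#' @param x Numeric vector of non-negative values, length >= 2.
#' @return Geometric SD (>= 1 for any input).
#' @export
geosd <- function(x) {
  if (length(x) < 2) stop("geosd requires >= 2 values")
  if (any(!is.finite(x) | x < 0)) stop("geosd requires finite values >= 0")
  exp(stats::sd(log(.shift_zeros(x))))
}

#' Two-sided single-outlier Grubbs test
#'
#' Computes G = max |x_i - mean| / sd and compares it with the critical
#' value ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2)), where t is the upper
#' alpha/(2n) quantile of Student's t with n - 2 degrees of freedom.
#'
#' @param x Numeric vector, length >= 3.
#' @param alpha Significance level (default 0.05).
#' @return A list with `outlier` (index of the rejected value, or
#'   `NA_integer_` if none), `G`, `critical`, `n` and `alpha`. Zero-variance
#'   input returns no outlier.
#' @export
grubbs_test <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 3) stop("Grubbs test undefined for n < 3")
  s <- stats::sd(x)
  if (s == 0)
    return(list(outlier = NA_integer_, G = 0, critical = NA_real_,
                n = n, alpha = alpha))
  dev <- abs(x - mean(x))
  i <- which.max(dev)
  G <- dev[i] / s
  tcrit <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  list(outlier = if (G > crit) i else NA_integer_,
       G = G, critical = crit, n = n, alpha = alpha)
}

.neg_counts <- function(x) {
  x$counts[x$probes$probe_class == "negative", , drop = FALSE]
}

.target_counts <- function(x) {
  x$counts[x$probes$probe_class == "target", , drop = FALSE]
}

#' Per-AOI negative-probe geometric mean
#' @param x A [probe_counts] object.
#' @return Named numeric vector over AOIs.
#' @export
neg_geomean <- function(x) {
  apply(.neg_counts(x), 2, geomean)
}

AOI_FLAGS <- c("low_reads", "low_aligned", "low_saturation",
               "low_neg_geomean", "high_ntc", "low_nuclei", "low_area")

#' Flag low-performing AOIs
#'
#' Applies the seven AOI QC rules. Every comparison is strict, matching the
#' thresholds as printed: e.g. raw reads below 1000 flag, exactly 1000 does
#' not. Flags are advisory: AOIs are only removed by
#' [drop_background_aois] (or an explicit `drop_flagged` policy).
#'
#' @param x A [probe_counts] object.
#' @param ann AOI annotation data frame covering every AOI of `x`.
#' @param thresholds A [qc_thresholds] object.
#' @return Data frame: `aoi_id`, one logical column per flag
#'   (`low_reads`, `low_aligned`, `low_saturation`, `low_neg_geomean`,
#'   `high_ntc`, `low_nuclei`, `low_area`), `n_flags`, `flags` (collapsed
#'   label string) and the derived `neg_geomean`.
#' @export
flag_aois <- function(x, ann, thresholds = qc_thresholds()) {
  ids <- aoi_ids(x)
  missing_ann <- setdiff(ids, ann$aoi_id)
  if (length(missing_ann))
    stop("missing annotation for AOI(s): ", paste(missing_ann, collapse = ", "))
  ann <- ann[match(ids, ann$aoi_id), ]
  ng <- neg_geomean(x)
  th <- thresholds
  fl <- data.frame(
    aoi_id          = ids,
    low_reads       = ann$raw_reads      < th$min_raw_reads,
    low_aligned     = ann$pct_aligned    < th$min_pct_aligned,
    low_saturation  = ann$seq_saturation < th$min_seq_saturation,
    low_neg_geomean = ng                 < th$min_neg_geomean,
    high_ntc        = ann$ntc_count      > th$max_ntc_count,
    low_nuclei      = ann$nuclei         < th$min_nuclei,
    low_area        = ann$area           < th$min_area_um2,
    stringsAsFactors = FALSE
  )
  fl$n_flags <- rowSums(fl[AOI_FLAGS])
  fl$flags <- apply(fl[AOI_FLAGS], 1, function(z)
    paste(AOI_FLAGS[z], collapse = ";"))
  fl$neg_geomean <- unname(ng)
  rownames(fl) <- NULL
  fl
}

#' Probe QC: local and global probe exclusion
#'
#' For every target carried by more than one probe: (a) per AOI, a
#' two-sided single-outlier Grubbs test on the target's probe counts
#' (log2 scale, zeros shifted to 0.5) marks the rejected probe as locally
#' excluded in that AOI; (b) a probe is globally excluded when its
#' geometric-mean ratio to the whole target (across all AOIs) is at or
#' below `probe_ratio_max` *and* it failed the Grubbs test in at least
#' `grubbs_fail_fraction` of the AOIs. Single-probe targets are exempt, and
#' the last retained probe of a target is never excluded.
#'
#' @param x A [probe_counts] object.
#' @param thresholds A [qc_thresholds] object (uses `probe_ratio_max` and
#'   `grubbs_fail_fraction`).
#' @param alpha Grubbs significance level (default 0.05).
#' @return A list with `global_excluded` (probe ids), `local_excluded`
#'   (data frame `probe_id`, `aoi_id`), and `probe_stats` (per multi-probe
#'   probe: geomean ratio and Grubbs failure fraction).
#' @export
probe_qc <- function(x, thresholds = qc_thresholds(), alpha = 0.05) {
  meta <- x$probes
  tgt_rows <- which(meta$probe_class == "target")
  counts <- x$counts
  ids <- aoi_ids(x)
  n_aoi <- length(ids)

  stats_list <- list()
  local_list <- list()
  global <- character(0)

  for (tg in unique(meta$target[tgt_rows])) {
    rows <- tgt_rows[meta$target[tgt_rows] == tg]
    p <- length(rows)
    if (p < 2) next  # single-probe targets exempt from both rules
    sub <- counts[rows, , drop = FALSE]
    lsub <- log2(.shift_zeros(sub))
    fails <- matrix(FALSE, p, n_aoi)
    if (p >= 3) {
      mu <- colMeans(lsub)
      dev <- lsub - rep(mu, each = p)
      s <- sqrt(colSums(dev^2) / (p - 1))
      tcrit <- stats::qt(1 - alpha / (2 * p), df = p - 2)
      crit <- (p - 1) / sqrt(p) * sqrt(tcrit^2 / (p - 2 + tcrit^2))
      ok <- s > 0
      if (any(ok)) {
        adev <- abs(dev[, ok, drop = FALSE])
        G <- apply(adev, 2, max) / s[ok]
        imax <- apply(adev, 2, which.max)
        rej <- G > crit
        cols_ok <- which(ok)
        for (k in which(rej)) fails[imax[k], cols_ok[k]] <- TRUE
      }
    }
    probe_gm <- apply(sub, 1, geomean)
    target_gm <- geomean(as.vector(sub))
    ratio <- probe_gm / target_gm
    fail_frac <- rowSums(fails) / n_aoi
    glob <- ratio <= thresholds$probe_ratio_max &
      fail_frac >= thresholds$grubbs_fail_fraction
    # never exclude the last remaining probe of a target
    if (all(glob)) {
      warning("probe QC would exclude all probes of target '", tg,
              "'; retaining the probe with the highest ratio", call. = FALSE)
      glob[which.max(ratio)] <- FALSE
    }
    pid <- meta$probe_id[rows]
    global <- c(global, pid[glob])
    # local exclusions only meaningful for probes not globally excluded;
    # also never empty a target within an AOI
    loc <- fails & !glob
    for (j in seq_len(n_aoi)) {
      retained <- !glob & !loc[, j]
      if (!any(retained)) {
        # keep the locally-failing probe closest to the target geomean
        cand <- which(!glob)
        keep <- cand[which.min(abs(log(ratio[cand])))]
        loc[keep, j] <- FALSE
      }
    }
    if (any(loc)) {
      idx <- which(loc, arr.ind = TRUE)
      local_list[[tg]] <- data.frame(probe_id = pid[idx[, 1]],
                                     aoi_id = ids[idx[, 2]],
                                     stringsAsFactors = FALSE)
    }
    stats_list[[tg]] <- data.frame(probe_id = pid, target = tg,
                                   ratio = unname(ratio),
                                   grubbs_fail_fraction = unname(fail_frac),
                                   global_excluded = unname(glob),
                                   stringsAsFactors = FALSE)
  }
  local <- if (length(local_list)) do.call(rbind, c(local_list, list(make.row.names = FALSE)))
           else data.frame(probe_id = character(0), aoi_id = character(0))
  probe_stats <- if (length(stats_list)) do.call(rbind, c(stats_list, list(make.row.names = FALSE)))
                 else data.frame(probe_id = character(0), target = character(0),
                                 ratio = numeric(0), grubbs_fail_fraction = numeric(0),
                                 global_excluded = logical(0))
  list(global_excluded = global, local_excluded = local,
       probe_stats = probe_stats)
}

#' Negative-probe limit of quantitation
#'
#' Per AOI, LOQ = GeoMean(negatives) * GeoSD(negatives)^n_sd, where GeoSD is
#' the geometric standard deviation `exp(sd(log(x)))` (sample sd).
#'
#' @param x A [probe_counts] object with >= 2 negative probes.
#' @param n_sd Number of geometric SDs (default 2).
#' @return Named numeric vector of LOQ values per AOI.
#' @export
compute_loq <- function(x, n_sd = 2) {
  neg <- .neg_counts(x)
  if (nrow(neg) < 2) stop("LOQ requires >= 2 negative probes")
  apply(neg, 2, function(v) geomean(v) * geosd(v)^n_sd)
}

#' Drop AOIs whose signal is comparable to background
#'
#' An AOI is dropped when its third-quartile (Q3) target signal is less
#' than `min_ratio` times its negative-probe geometric mean, i.e. when
#' on-target signal is not separable from nonspecific binding.
#'
#' @param q3_per_aoi Named positive vector: per-AOI 75th percentile of
#'   target values (negatives excluded).
#' @param neg_geomean_per_aoi Named positive vector: per-AOI negative-probe
#'   geomean, same AOIs.
#' @param min_ratio Minimum Q3/background ratio to retain (default 2; the
#'   comparison is strict: an AOI exactly at the ratio is retained).
#' @return Character vector of dropped AOI ids.
#' @export
drop_background_aois <- function(q3_per_aoi, neg_geomean_per_aoi,
                                 min_ratio = 2) {
  if (any(q3_per_aoi <= 0) || any(neg_geomean_per_aoi <= 0) || min_ratio <= 0)
    stop("drop_background_aois requires positive inputs")
  ids <- names(q3_per_aoi)
  if (is.null(ids)) ids <- as.character(seq_along(q3_per_aoi))
  if (!is.null(names(neg_geomean_per_aoi)))
    neg_geomean_per_aoi <- neg_geomean_per_aoi[ids]
  ids[q3_per_aoi / neg_geomean_per_aoi < min_ratio]
}

#' Run the full QC stage
#'
#' Bundles AOI flagging, probe QC, LOQ computation and background-based
#' AOI dropping into one report.
#'
#' @param x A [probe_counts] object.
#' @param ann AOI annotation data frame.
#' @param thresholds A [qc_thresholds] object.
#' @param alpha Grubbs significance level.
#' @param background_min_ratio Q3/background retention ratio (default 2).
#' @param drop_flagged If `TRUE`, flagged AOIs are dropped as well
#'   (default `FALSE`: flags are advisory).
#' @return An object of class `qc_report`: list with `aoi_flags`,
#'   `probe_qc`, `loq`, `dropped_aois` (data frame `aoi_id`, `reason`).
#' @export
run_qc <- function(x, ann, thresholds = qc_thresholds(), alpha = 0.05,
                   background_min_ratio = 2, drop_flagged = FALSE) {
  fl <- flag_aois(x, ann, thresholds)
  pq <- probe_qc(x, thresholds, alpha)
  loq <- compute_loq(x, n_sd = thresholds$loq_n_sd)
  tgt <- .target_counts(x)
  q3 <- apply(tgt, 2, stats::quantile, probs = 0.75, type = 7, names = FALSE)
  q3 <- pmax(q3, 0.5)  # degenerate all-zero AOI still comparable to background
  bg_drop <- drop_background_aois(q3, neg_geomean(x), background_min_ratio)
  dropped <- data.frame(aoi_id = bg_drop,
                        reason = rep("background", length(bg_drop)),
                        stringsAsFactors = FALSE)
  if (drop_flagged) {
    extra <- setdiff(fl$aoi_id[fl$n_flags > 0], dropped$aoi_id)
    if (length(extra))
      dropped <- rbind(dropped,
                       data.frame(aoi_id = extra, reason = "flagged",
                                  stringsAsFactors = FALSE))
  }
  structure(list(aoi_flags = fl, probe_qc = pq, loq = loq,
                 dropped_aois = dropped, thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", nrow(x$aoi_flags), "AOIs;",
      sum(x$aoi_flags$n_flags > 0), "flagged;",
      nrow(x$dropped_aois), "dropped;",
      length(x$probe_qc$global_excluded), "probes globally excluded;",
      nrow(x$probe_qc$local_excluded), "local probe exclusions\n")
  invisible(x)
}
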