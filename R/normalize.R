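# Probe -> target collapse, Q3 normalization, log2 transform, and
# cross-cohort merging with joint renormalization.

.new_target_matrix <- function(values, scale, q3_reference = NULL,
                               q3_factors = NULL) {
  structure(values, scale = scale, q3_reference = q3_reference,
            q3_factors = q3_factors,
            class = c("target_matrix", class(values)))
}

#' Construct a target expression matrix
#'
#' Wraps a plain numeric matrix (targets x AOIs, dimnames required) as a
#' `target_matrix` carrying its normalization scale, e.g. for external
#' cohorts entering [merge_and_renormalize].
#'
#' @param values Numeric matrix with target row names and AOI column names.
#' @param scale One of `"raw"`, `"q3_normalized"`, `"log2_q3"`.
#' @return A `target_matrix`.
#' @export
target_matrix <- function(values, scale = "raw") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry target row names and AOI column names")
  scale <- match.arg(scale, c("raw", "q3_normalized", "log2_q3"))
  if (any(!is.finite(values))) stop("values must be finite")
  .new_target_matrix(values, scale = scale)
}

#' Normalization scale of a target matrix
#' @param m A target expression matrix produced by [collapse_targets],
#'   [q3_normalize] or [log2_transform].
#' @return One of `"raw"`, `"q3_normalized"`, `"log2_q3"`.
#' @export
tm_scale <- function(m) {
  sc <- attr(m, "scale")
  if (is.null(sc)) stop("matrix carries no normalization scale attribute")
  sc
}

#' Collapse probes to target-level counts
#'
#' Per target and AOI, the collapsed value is the geometric mean of the
#' target's retained probes in that AOI. Probe exclusions from [probe_qc]
#' are honored: globally excluded probes are removed everywhere, locally
#' excluded probes only in their AOI. Negative and NTC probes are never
#' collapsed into targets. AOIs dropped by QC are removed.
#'
#' @param x A [probe_counts] object.
#' @param qc Optional `qc_report` from [run_qc] (or a list with elements
#'   `probe_qc` and `dropped_aois`).
#' @return A `target_matrix` (targets x AOIs) with scale `"raw"`.
#' @export
collapse_targets <- function(x, qc = NULL) {
  meta <- x$probes
  counts <- x$counts
  keep_aoi <- aoi_ids(x)
  global <- character(0)
  local <- data.frame(probe_id = character(0), aoi_id = character(0))
  if (!is.null(qc)) {
    global <- qc$probe_qc$global_excluded
    local <- qc$probe_qc$local_excluded
    if (nrow(qc$dropped_aois))
      keep_aoi <- setdiff(keep_aoi, qc$dropped_aois$aoi_id)
  }
  counts <- counts[, keep_aoi, drop = FALSE]
  tgt_rows <- which(meta$probe_class == "target" & !(meta$probe_id %in% global))
  targets <- unique(meta$target[tgt_rows])
  out <- matrix(NA_real_, length(targets), length(keep_aoi),
                dimnames = list(targets, keep_aoi))
  local_by_probe <- split(local$aoi_id, local$probe_id)
  for (ti in seq_along(targets)) {
    rows <- tgt_rows[meta$target[tgt_rows] == targets[ti]]
    pid <- meta$probe_id[rows]
    sub <- counts[rows, , drop = FALSE]
    use <- matrix(TRUE, length(rows), length(keep_aoi))
    for (k in seq_along(pid)) {
      ex <- local_by_probe[[pid[k]]]
      if (!is.null(ex)) use[k, keep_aoi %in% ex] <- FALSE
    }
    bad <- !colSums(use)
    if (any(bad))
      stop("target '", targets[ti], "' has no retained probe in AOI(s): ",
           paste(keep_aoi[bad], collapse = ", "))
    lsub <- log(.shift_zeros(sub))
    lsub[!use] <- NA
    out[ti, ] <- exp(colMeans(lsub, na.rm = TRUE))
  }
  .new_target_matrix(out, scale = "raw")
}

#' Q3 (third-quartile) normalization
#'
#' Computes the 75th percentile of each AOI's target values
#' (linear-interpolation, quantile type 7), takes the geometric mean of
#' those quartiles as the common reference R, and rescales each AOI by
#' R / q3_j. Removes technical column effects (segment area, RNA amount,
#' hybridisation efficiency) while preserving within-AOI structure.
#'
#' @param m A raw (or already Q3-normalized) `target_matrix` with >= 4
#'   targets.
#' @return A `target_matrix` with scale `"q3_normalized"`,
#'   `attr(, "q3_reference")` = R and `attr(, "q3_factors")` the per-AOI
#'   multipliers.
#' @export
q3_normalize <- function(m) {
  sc <- tm_scale(m)
  if (sc == "log2_q3")
    stop("q3_normalize expects linear-scale values, got log2_q3")
  if (nrow(m) < 4) stop("Q3 normalization requires >= 4 targets")
  q3 <- apply(m, 2, stats::quantile, probs = 0.75, type = 7, names = FALSE)
  if (any(q3 == 0))
    stop("Q3 is zero for AOI(s): ",
         paste(colnames(m)[q3 == 0], collapse = ", "),
         " (should have been background-dropped)")
  R <- exp(mean(log(q3)))
  factors <- R / q3
  out <- sweep(unclass(m), 2, factors, "*")
  names(factors) <- colnames(m)
  .new_target_matrix(out, scale = "q3_normalized", q3_reference = R,
                     q3_factors = factors)
}

#' Log2 transform of normalized expression
#'
#' @param m A Q3-normalized `target_matrix`.
#' @param pseudocount Added before the log (default 1).
#' @return A `target_matrix` with scale `"log2_q3"`.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  if (tm_scale(m) != "q3_normalized")
    stop("log2_transform expects a q3_normalized matrix, got ", tm_scale(m))
  if (any(m < 0)) stop("negative values cannot be log-transformed")
  out <- log2(unclass(m) + pseudocount)
  .new_target_matrix(out, scale = "log2_q3",
                     q3_reference = attr(m, "q3_reference"),
                     q3_factors = attr(m, "q3_factors"))
}

#' Merge two raw cohorts and renormalize jointly
#'
#' Restricts both matrices to their shared targets, concatenates the AOIs,
#' and applies Q3 normalization to the merged matrix, so the two cohorts
#' become directly comparable.
#'
#' @param a,b Raw-scale `target_matrix` objects (e.g. study cohort and a
#'   reference atlas). AOI ids must not collide.
#' @return A Q3-normalized `target_matrix` over the shared targets and the
#'   union of AOIs.
#' @export
merge_and_renormalize <- function(a, b) {
  if (tm_scale(a) != "raw" || tm_scale(b) != "raw")
    stop("merge_and_renormalize expects raw-scale matrices")
  shared <- intersect(rownames(a), rownames(b))
  if (!length(shared)) stop("no shared targets between the two matrices")
  if (length(common_aoi <- intersect(colnames(a), colnames(b))))
    stop("AOI id collision: ", paste(utils::head(common_aoi, 3), collapse = ", "))
  message("merging on ", length(shared), " shared targets")
  merged <- cbind(unclass(a)[shared, , drop = FALSE],
                  unclass(b)[shared, , drop = FALSE])
  q3_normalize(.new_target_matrix(merged, scale = "raw"))
}

#' Run collapse + Q3 + log2 in one step
#'
#' @param x A [probe_counts] object.
#' @param qc Optional `qc_report` from [run_qc].
#' @param pseudocount Log2 pseudocount (default 1).
#' @return A list with `raw`, `q3` and `log2` target matrices.
#' @export
normalize_pipeline <- function(x, qc = NULL, pseudocount = 1) {
  raw <- collapse_targets(x, qc)
  q3 <- q3_normalize(raw)
  list(raw = raw, q3 = q3, log2 = log2_transform(q3, pseudocount))
}
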