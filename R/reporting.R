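# Summary artifacts: significant-gene counts, row z-scoring for heatmap
# inputs, run summaries, and the deposited-data reproduction workflow.

#' Count significant up/down units in a result table
#'
#' Strict inequality: a unit with FDR exactly at the cut is not counted.
#'
#' @param results A result table with `fdr` and `direction` columns.
#' @param fdr_cut FDR threshold (default 0.05).
#' @return Named integer vector `c(n_up, n_down)`.
#' @export
count_significant <- function(results, fdr_cut = 0.05) {
  if (!"fdr" %in% names(results)) stop("result table has no fdr column")
  sig <- results$fdr < fdr_cut
  c(n_up = sum(sig & results$direction == "up"),
    n_down = sum(sig & results$direction == "down"))
}

#' Row z-scores, optionally within column groups
#'
#' Per row (within each group of columns if `groups` is given): subtract
#' the mean and divide by the sample (n-1) standard deviation. Zero-sd
#' rows become all-zero and are flagged in `attr(, "constant_rows")`.
#'
#' @param m Numeric matrix.
#' @param groups Optional factor/character vector over columns (e.g.
#'   segment labels) scoping the standardization.
#' @return Matrix of z-scores; `attr(, "sd_type")` records the denominator
#'   convention.
#' @export
zscore_rows <- function(m, groups = NULL) {
  m <- as.matrix(m)
  if (is.null(groups)) groups <- rep("all", ncol(m))
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) stop("groups must match the columns")
  out <- m
  constant <- rep(FALSE, nrow(m))
  for (g in unique(groups)) {
    cols <- groups == g
    if (sum(cols) < 2)
      stop("z-scoring requires >= 2 columns per group (group '", g, "')")
    sub <- m[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    s <- sqrt(rowSums((sub - mu)^2) / (ncol(sub) - 1))
    zero <- s == 0
    s[zero] <- 1
    out[, cols] <- (sub - mu) / s
    constant <- constant | zero
  }
  attr(out, "constant_rows") <- rownames(m)[constant]
  attr(out, "sd_type") <- "sample (n-1)"
  out
}

#' Summarize a full pipeline run
#'
#' @param qc A `qc_report` from [run_qc].
#' @param expr Final expression matrix (targets x retained AOIs).
#' @param results Named list of result tables.
#' @param fdr_cut FDR threshold for the significant counts (default 0.05).
#' @return A list of class `run_summary`: AOI/target tallies and
#'   per-contrast up/down counts, recomputable from the inputs.
#' @export
run_summary <- function(qc, expr, results = list(), fdr_cut = 0.05) {
  counts <- lapply(results, count_significant, fdr_cut = fdr_cut)
  structure(list(
    n_aois_in = nrow(qc$aoi_flags),
    n_aois_flagged = sum(qc$aoi_flags$n_flags > 0),
    n_aois_dropped = nrow(qc$dropped_aois),
    n_aois_retained = ncol(expr),
    n_targets = nrow(expr),
    n_probes_global_excluded = length(qc$probe_qc$global_excluded),
    significant = counts,
    fdr_cut = fdr_cut
  ), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("run_summary: ", x$n_aois_in, " AOIs in; ", x$n_aois_flagged,
      " flagged; ", x$n_aois_dropped, " dropped; matrix ", x$n_targets,
      " targets x ", x$n_aois_retained, " AOIs; ",
      x$n_probes_global_excluded, " probes excluded\n", sep = "")
  for (nm in names(x$significant)) {
    v <- x$significant[[nm]]
    cat(sprintf("  %-28s up=%d down=%d (FDR<%g)\n", nm, v["n_up"],
                v["n_down"], x$fdr_cut))
  }
  invisible(x)
}

.read_deposited_matrix <- function(path, what) {
  df <- utils::read.table(path, header = TRUE, sep = .infer_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  if (!any(num) || all(num))
    stop(what, " matrix must have one gene-id column plus numeric AOI ",
         "columns; found columns: ", paste(names(df), collapse = ", "))
  id_col <- which(!num)[1]
  m <- as.matrix(df[num])
  rownames(m) <- df[[id_col]]
  m
}

#' Reproduce the analysis from deposited raw/normalized matrices
#'
#' Runs the QC and normalization stages on a deposited raw counts table,
#' compares the result against the deposited normalized matrix (per-AOI
#' Spearman correlation over shared targets), runs the main contrasts, and
#' returns the summary counts. Deposited files are never downloaded
#' automatically: point the path arguments at local copies.
#'
#' @param raw_path Path to the raw probe counts table (see
#'   [read_probe_counts] for the expected schema).
#' @param ann_path Path to the AOI annotation table.
#' @param norm_path Path to the deposited normalized matrix (one gene-id
#'   column plus one numeric column per AOI).
#' @param background_min_ratio Q3/background retention ratio (default 2).
#' @param fdr_cut FDR threshold for the summary counts.
#' @return A list with `summary` (a [run_summary]), `concordance` (per-AOI
#'   Spearman correlation between pipeline and deposited normalized
#'   values), and `results` (paired/trend result tables).
#' @export
reproduce_deposited <- function(raw_path, ann_path, norm_path,
                                background_min_ratio = 2, fdr_cut = 0.05) {
  for (p in c(raw_path, ann_path, norm_path)) {
    if (!file.exists(p))
      stop("deposited file not found: ", p,
           " (the study data is available from FigShare, ",
           "doi 10.6084/m9.figshare.16818415)")
  }
  x <- read_probe_counts(raw_path)
  ann <- read_aoi_annotation(ann_path)
  qc <- run_qc(x, ann, background_min_ratio = background_min_ratio)
  norm <- normalize_pipeline(x, qc)
  deposited <- .read_deposited_matrix(norm_path, "normalized")

  shared_genes <- intersect(rownames(norm$q3), rownames(deposited))
  shared_aois <- intersect(colnames(norm$q3), colnames(deposited))
  if (!length(shared_genes) || !length(shared_aois))
    stop("no overlap between pipeline output and deposited matrix; ",
         "pipeline targets: ", paste(utils::head(rownames(norm$q3), 3),
                                     collapse = ", "),
         "...; deposited rows: ", paste(utils::head(rownames(deposited), 3),
                                        collapse = ", "), "...")
  concordance <- vapply(shared_aois, function(a)
    stats::cor(norm$q3[shared_genes, a], deposited[shared_genes, a],
               method = "spearman"), numeric(1))

  results <- list(paired_segment = paired_segment_de(norm$log2, ann))
  for (seg in SEGMENT_LEVELS) {
    results[[paste0("trend_", seg)]] <-
      tryCatch(ordinal_trend(norm$log2, ann, seg), error = function(e) NULL)
  }
  results <- Filter(Negate(is.null), results)
  list(summary = run_summary(qc, norm$log2, results, fdr_cut),
       concordance = concordance, results = results)
}
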