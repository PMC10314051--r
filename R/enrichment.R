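# Single-sample gene-set enrichment scoring (ssGSEA), the
# panel-applicability filter for gene-set collections, and gene-set-based
# immune cell deconvolution.

#' ssGSEA score of one gene set in one sample
#'
#' Genes are ranked by decreasing expression (ties broken by stable input
#' order). Walking down the ranked list, the score accumulates the
#' difference between a weighted empirical CDF over in-set genes (weight =
#' rank statistic^alpha, where the statistic of the gene at sorted position
#' i among N genes is N - i + 1, normalized to sum one over the set) and
#' the unweighted ECDF over out-of-set genes:
#' score = sum_i (P_in(i) - P_out(i)).
#' The score is rank-based: any strictly increasing transform of the
#' expression leaves it unchanged.
#'
#' @param expr Named numeric vector: expression of every gene in one
#'   sample (log2 scale in the standard pipeline; only ranks matter).
#' @param gene_set Character vector of gene symbols.
#' @param alpha Rank-weighting exponent (default 0.25; 0 gives the
#'   unweighted Kolmogorov-Smirnov-style running sum).
#' @return A single numeric enrichment score.
#' @examples
#' e <- c(A = 3, B = 2, C = 1)
#' ssgsea_score(e, "A", alpha = 0) # 1.5
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  genes <- names(expr)
  if (is.null(genes)) stop("expr must be a named vector")
  n <- length(expr)
  in_set <- genes %in% gene_set
  k <- sum(in_set)
  if (k == 0) stop("no gene of the set is present in the expression vector")
  if (k == n) stop("gene set covers the whole gene universe")
  ord <- order(-expr, seq_len(n))  # decreasing, stable in input order
  in_ord <- in_set[ord]
  stat <- as.numeric(n:1)          # rank statistic: top gene gets N
  w <- ifelse(in_ord, stat^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_ord) / (n - k)
  sum(p_in - p_out)
}

#' ssGSEA scores for a collection of sets over all AOIs
#'
#' @param expr Numeric matrix genes x AOIs (log2-scale expression in the
#'   standard pipeline).
#' @param sets A [gene_set_collection].
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param min_genes Sets with fewer genes present in `expr` are dropped
#'   with a warning (default 2).
#' @param rescale If `TRUE`, min-max rescale the score matrix to [0, 1]
#'   (off by default; downstream correlation and clustering are unaffected).
#' @return Numeric matrix sets x AOIs of class `enrichment_matrix` with
#'   attributes `alpha` and `normalized`.
#' @export
ssgsea <- function(expr, sets, alpha = 0.25, min_genes = 2,
                   rescale = FALSE) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expr must have gene row names")
  set_list <- sets$sets
  present <- vapply(set_list, function(g) sum(rownames(expr) %in% g),
                    integer(1))
  drop <- present < min_genes
  if (any(drop)) {
    warning("dropping ", sum(drop), " set(s) with < ", min_genes,
            " genes present: ",
            paste(utils::head(names(set_list)[drop], 5), collapse = ", "),
            call. = FALSE)
    set_list <- set_list[!drop]
  }
  if (!length(set_list)) stop("no gene set with enough genes present")
  n <- nrow(expr)
  stat_pow <- as.numeric(n:1)^alpha
  in_mat <- vapply(set_list, function(g) rownames(expr) %in% g,
                   logical(n))  # genes x sets
  scores <- matrix(NA_real_, length(set_list), ncol(expr),
                   dimnames = list(names(set_list), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], seq_len(n))
    io <- in_mat[ord, , drop = FALSE]
    for (s in seq_along(set_list)) {
      ins <- io[, s]
      w <- stat_pow * ins
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!ins) / (n - sum(ins))
      scores[s, j] <- sum(p_in - p_out)
    }
  }
  if (rescale) {
    rng <- range(scores)
    scores <- (scores - rng[1]) / diff(rng)
  }
  structure(scores, alpha = alpha, normalized = rescale,
            class = c("enrichment_matrix", class(scores)))
}

#' Panel-applicability filter for gene-set collections
#'
#' A targeted panel measures only a subset of the transcriptome, so some
#' gene sets cannot be scored faithfully from panel data. For each set,
#' ssGSEA scores are computed per reference sample twice — on the full
#' reference matrix and on the same matrix restricted to the panel genes —
#' and the Pearson correlation between the two score vectors is the set's
#' applicability. Sets with r below `r_min` are removed, as are sets with
#' fewer than `min_genes` panel genes, sets on the manual exclusion list,
#' and, within each declared redundancy group, every set but the one with
#' the highest correlation.
#'
#' @param reference_expr Full-transcriptome matrix genes x samples (>= 3
#'   samples), e.g. a TCGA cohort on log2 scale.
#' @param panel_genes Character vector of panel gene symbols (subset of the
#'   reference genes).
#' @param sets A [gene_set_collection].
#' @param r_min Minimum Pearson correlation to keep a set (default 0.6;
#'   sets are kept when r >= r_min).
#' @param min_genes Minimum panel genes per set (default 2).
#' @param exclusion_list Set names removed by manual curation.
#' @param redundancy_groups Optional named list: group -> set names; only
#'   the highest-correlation member of each group is kept.
#' @param alpha ssGSEA exponent (default 0.25).
#' @return The filtered [gene_set_collection]; `attr(, "filter_report")`
#'   holds a data frame with per-set r, panel gene counts, and the
#'   keep/remove decision with its reason.
#' @export
filter_sets_by_panel <- function(reference_expr, panel_genes, sets,
                                 r_min = 0.6, min_genes = 2,
                                 exclusion_list = NULL,
                                 redundancy_groups = NULL, alpha = 0.25) {
  reference_expr <- as.matrix(reference_expr)
  if (ncol(reference_expr) < 3)
    stop("panel filter requires >= 3 reference samples")
  missing_panel <- setdiff(panel_genes, rownames(reference_expr))
  if (length(missing_panel))
    stop("panel gene(s) absent from the reference: ",
         paste(utils::head(missing_panel, 5), collapse = ", "))
  if (length(panel_genes) > nrow(reference_expr))
    stop("panel cannot exceed the reference gene universe")
  panel_expr <- reference_expr[panel_genes, , drop = FALSE]

  nm <- names(sets$sets)
  n_panel <- vapply(sets$sets, function(g) sum(panel_genes %in% g),
                    integer(1))
  n_full <- vapply(sets$sets, function(g) sum(rownames(reference_expr) %in% g),
                   integer(1))
  r <- rep(NA_real_, length(nm))
  names(r) <- nm
  scorable <- n_panel >= 1 & n_full >= 1 & n_panel < length(panel_genes)
  if (any(scorable)) {
    sub <- gene_set_collection(sets$sets[scorable], source = sets$source)
    full_scores <- ssgsea(reference_expr, sub, alpha = alpha, min_genes = 1)
    panel_scores <- ssgsea(panel_expr, sub, alpha = alpha, min_genes = 1)
    for (s in rownames(full_scores))
      r[s] <- stats::cor(full_scores[s, ], panel_scores[s, ])
  }

  reason <- rep("", length(nm))
  names(reason) <- nm
  keep <- rep(TRUE, length(nm))
  names(keep) <- nm
  keep[n_panel == 0] <- FALSE
  reason[n_panel == 0] <- "no panel genes"
  idx <- keep & n_panel < min_genes
  keep[idx] <- FALSE
  reason[idx] <- paste0("fewer than ", min_genes, " panel genes")
  idx <- keep & (is.na(r) | r < r_min)
  keep[idx] <- FALSE
  reason[idx] <- paste0("correlation below ", r_min)
  idx <- keep & nm %in% exclusion_list
  keep[idx] <- FALSE
  reason[idx] <- "manual exclusion"
  if (!is.null(redundancy_groups)) {
    for (g in names(redundancy_groups)) {
      members <- intersect(redundancy_groups[[g]], nm[keep])
      if (length(members) > 1) {
        best <- members[which.max(r[members])]
        losers <- setdiff(members, best)
        keep[losers] <- FALSE
        reason[losers] <- paste0("redundant with ", best)
      }
    }
  }
  report <- data.frame(set = nm, r = unname(r), n_panel_genes = unname(n_panel),
                       kept = unname(keep), reason = unname(reason),
                       stringsAsFactors = FALSE)
  if (!any(keep)) stop("no gene set survives the panel filter")
  out <- gene_set_collection(sets$sets[keep],
                             source = paste0(sets$source, " (panel-filtered)"))
  attr(out, "filter_report") <- report
  out
}

#' Gene-set-based immune cell deconvolution
#'
#' Scores cell-type marker gene sets with the ssGSEA engine, yielding one
#' relative-abundance score per cell type per AOI (consensus
#' tumour-microenvironment style: scores are comparable across AOIs for a
#' given cell type, not across cell types).
#'
#' @param expr Numeric matrix genes x AOIs, log2 scale.
#' @param cell_type_sets A [gene_set_collection] of marker sets. The
#'   package ships a synthetic example collection of canonical immune and
#'   stromal markers (see
#'   `system.file("extdata", "immune_markers_synthetic.gmt", package =
#'   "spatialprof")`); any marker GMT is accepted.
#' @param alpha ssGSEA exponent (default 0.25).
#' @param min_genes Minimum marker genes present (default 2).
#' @return An `enrichment_matrix`, cell types x AOIs.
#' @export
deconvolve <- function(expr, cell_type_sets, alpha = 0.25, min_genes = 2) {
  ssgsea(expr, cell_type_sets, alpha = alpha, min_genes = min_genes)
}
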