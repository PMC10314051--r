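# Differential and trend statistics across segments and ordered histology:
# paired segment comparison, stepwise adjacent-histology tests, Spearman
# ordinal trend, one-way region ANOVA, and Benjamini-Hochberg FDR control.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_(i) = min_{j >= i} (p_(j) * n / j), capped at
#' one and mapped back to input order.
#'
#' @param p Numeric vector of p-values in [0, 1] (no missing values).
#' @return Adjusted values in [0, 1].
#' @export
bh_fdr <- function(p) {
  if (anyNA(p)) stop("missing p-values must be handled upstream")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

.direction <- function(effect) {
  ifelse(effect > 0, "up", ifelse(effect < 0, "down", "none"))
}

.result_table <- function(unit_id, contrast, segment, effect, p_value, fdr,
                          effect_type, extra = NULL) {
  res <- data.frame(unit_id = unit_id, contrast = contrast, segment = segment,
                    effect = effect, p_value = p_value, fdr = fdr,
                    direction = .direction(effect),
                    effect_type = effect_type, stringsAsFactors = FALSE)
  if (!is.null(extra)) res <- cbind(res, extra)
  rownames(res) <- NULL
  res
}

.scope_ann <- function(expr, ann, segment = NULL) {
  ann <- ann[match(colnames(expr), ann$aoi_id), ]
  if (anyNA(ann$aoi_id))
    stop("annotation missing for AOI(s): ",
         paste(colnames(expr)[is.na(ann$aoi_id)], collapse = ", "))
  if (!is.null(segment) && segment != "both") {
    keep <- ann$segment == segment
    list(expr = expr[, keep, drop = FALSE], ann = ann[keep, ])
  } else list(expr = expr, ann = ann)
}

# Vectorized two-sided one-sample t on the rows of a difference matrix.
# Zero-variance rows get p = 1 (no-evidence convention).
.row_t_onesample <- function(d) {
  k <- ncol(d)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (k - 1))
  p <- rep(1, nrow(d))
  ok <- s > 0
  tt <- m[ok] / (s[ok] / sqrt(k))
  p[ok] <- 2 * stats::pt(-abs(tt), df = k - 1)
  list(effect = m, p = p)
}

#' Paired differential expression between segments
#'
#' Each ROI is illuminated once per segment, so the PanCK and Vimentin AOIs
#' of one ROI form a natural pair. Per gene: mean paired log2 difference
#' (PanCK - Vimentin), two-sided paired t-test, BH FDR across genes.
#' ROIs lacking either member are excluded with a message. Genes with
#' zero-variance differences get p = 1 (no evidence).
#'
#' @param expr Log2-scale expression matrix genes x AOIs.
#' @param ann AOI annotation data frame.
#' @return A result table: `unit_id`, `contrast`, `segment`, `effect`
#'   (mean paired log2 difference; up = higher in PanCK), `p_value`, `fdr`,
#'   `direction`.
#' @export
paired_segment_de <- function(expr, ann) {
  sc <- .scope_ann(expr, ann)
  ann <- sc$ann; expr <- sc$expr
  roi <- paste(ann$sample_id, ann$roi_id, sep = "|")
  panck <- ann$segment == "PanCK"
  vim <- ann$segment == "Vimentin"
  complete <- intersect(roi[panck], roi[vim])
  incomplete <- setdiff(unique(roi), complete)
  if (length(incomplete))
    message("excluding ", length(incomplete),
            " ROI(s) lacking a segment pair")
  if (length(complete) < 2) stop("fewer than 2 complete ROI pairs")
  ip <- match(complete, ifelse(panck, roi, NA))
  iv <- match(complete, ifelse(vim, roi, NA))
  d <- expr[, ip, drop = FALSE] - expr[, iv, drop = FALSE]
  tt <- .row_t_onesample(d)
  .result_table(rownames(expr), "PanCK_vs_Vimentin", "both",
                tt$effect, tt$p, bh_fdr(tt$p), "log2FC")
}

# Vectorized two-sample t on rows; Welch by default.
.row_t_twosample <- function(x1, x2, var_equal = FALSE) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  effect <- m2 - m1
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- rep(1, length(effect))
  ok <- se > 0
  p[ok] <- 2 * stats::pt(-abs(effect[ok] / se[ok]), df = df[ok])
  deg <- !ok & effect != 0   # zero variance but different means
  p[deg] <- 0
  list(effect = effect, p = p)
}

STEPWISE_CONTRASTS <- data.frame(
  lower = c("normal", "transition", "low_grade_dysplasia",
            "high_grade_dysplasia"),
  upper = c("transition", "low_grade_dysplasia", "high_grade_dysplasia",
            "carcinoma"),
  stringsAsFactors = FALSE
)

#' Stepwise differential expression between adjacent histologies
#'
#' Unpaired t-tests (Welch by default) for the four adjacent pairs along
#' the progression axis (transition vs normal, LGD vs transition, HGD vs
#' LGD, carcinoma vs HGD), within one segment. A gene is called
#' significant when p < `p_cut` and |log2FC| > `log2fc_cut`.
#'
#' @param expr Log2-scale expression matrix genes x AOIs.
#' @param ann AOI annotation data frame.
#' @param segment `"PanCK"` or `"Vimentin"`.
#' @param p_cut P-value cut-off (default 0.05).
#' @param log2fc_cut Absolute log2 fold-change cut-off (default 0.5).
#' @param var_equal Use the pooled-variance (Student) t instead of Welch.
#' @return Result table with one block per contrast; `effect` is the
#'   difference of group means on the log2 scale (higher histology minus
#'   lower), `significant` the joint call, `fdr` the BH adjustment within
#'   each contrast. Contrasts with fewer than 2 AOIs in either group are
#'   skipped with a warning.
#' @export
stepwise_de <- function(expr, ann, segment, p_cut = 0.05, log2fc_cut = 0.5,
                        var_equal = FALSE) {
  sc <- .scope_ann(expr, ann, segment)
  blocks <- list()
  for (i in seq_len(nrow(STEPWISE_CONTRASTS))) {
    lo <- STEPWISE_CONTRASTS$lower[i]; hi <- STEPWISE_CONTRASTS$upper[i]
    x1 <- sc$expr[, sc$ann$histology == lo, drop = FALSE]
    x2 <- sc$expr[, sc$ann$histology == hi, drop = FALSE]
    if (ncol(x1) < 2 || ncol(x2) < 2) {
      warning("skipping contrast ", hi, "_vs_", lo, " in ", segment,
              ": group with < 2 AOIs", call. = FALSE)
      next
    }
    tt <- .row_t_twosample(x1, x2, var_equal)
    blocks[[i]] <- .result_table(
      rownames(sc$expr), paste0(hi, "_vs_", lo), segment,
      tt$effect, tt$p, bh_fdr(tt$p), "log2FC",
      extra = data.frame(
        significant = tt$p < p_cut & abs(tt$effect) > log2fc_cut))
  }
  if (!length(blocks)) stop("no stepwise contrast could be computed")
  do.call(rbind, blocks)
}

#' Spearman ordinal trend across histologies
#'
#' Per gene, the Spearman correlation (mid-ranks for ties) between
#' expression and the histology ordinal rank (normal = 1 ... carcinoma =
#' 5), with the two-sided t-approximation p-value and BH FDR across genes
#' within the segment. Constant genes are reported with rho = 0, p = 1 and
#' `degenerate = TRUE`.
#'
#' @param expr Log2-scale expression (or score) matrix, units x AOIs.
#' @param ann AOI annotation data frame.
#' @param segment `"PanCK"` or `"Vimentin"`.
#' @return Result table with `effect` = Spearman rho,
#'   `direction` = sign of rho.
#' @export
ordinal_trend <- function(expr, ann, segment) {
  sc <- .scope_ann(expr, ann, segment)
  ranks <- sc$ann$histology_rank
  if (is.null(ranks)) ranks <- histology_rank(sc$ann$histology)
  if (length(unique(ranks)) < 3)
    stop("ordinal trend requires >= 3 distinct histology ranks in scope")
  n_units <- nrow(sc$expr)
  rho <- numeric(n_units); p <- numeric(n_units)
  degenerate <- logical(n_units)
  for (g in seq_len(n_units)) {
    y <- sc$expr[g, ]
    if (stats::sd(y) == 0) {
      rho[g] <- 0; p[g] <- 1; degenerate[g] <- TRUE
    } else {
      ct <- suppressWarnings(
        stats::cor.test(y, ranks, method = "spearman", exact = FALSE))
      rho[g] <- unname(ct$estimate)
      p[g] <- ct$p.value
    }
  }
  .result_table(rownames(sc$expr), "ordinal_trend", segment,
                rho, p, bh_fdr(p), "spearman_rho",
                extra = data.frame(degenerate = degenerate))
}

#' One-way ANOVA across histology regions
#'
#' Per unit (gene or deconvolution score), the classic one-way F test
#' across histology groups within a segment, with BH FDR. Requires at
#' least two groups with at least two AOIs each; smaller groups are
#' dropped with a warning.
#'
#' @param expr Matrix units x AOIs (log2 expression or enrichment scores).
#' @param ann AOI annotation data frame.
#' @param segment `"PanCK"`, `"Vimentin"` or `"both"`.
#' @return Result table with `effect` = F statistic.
#' @export
region_anova <- function(expr, ann, segment = "both") {
  sc <- .scope_ann(expr, ann, segment)
  g <- factor(sc$ann$histology, levels = names(HISTOLOGY_RANKS))
  sizes <- table(g[!is.na(g)])
  small <- names(sizes)[sizes > 0 & sizes < 2]
  if (length(small)) {
    warning("dropping group(s) with < 2 AOIs: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(as.character(g) %in% small)
    sc$expr <- sc$expr[, keep, drop = FALSE]
    g <- droplevels(g[keep])
  } else g <- droplevels(g)
  k <- nlevels(g)
  if (k < 2) stop("ANOVA requires >= 2 histology groups with >= 2 AOIs")
  n <- length(g)
  X <- sc$expr
  gm <- rowMeans(X)
  ss_tot <- rowSums((X - gm)^2)
  ss_within <- 0
  for (lev in levels(g)) {
    sub <- X[, g == lev, drop = FALSE]
    ss_within <- ss_within + rowSums((sub - rowMeans(sub))^2)
  }
  ss_between <- ss_tot - ss_within
  df1 <- k - 1; df2 <- n - k
  Fs <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(Fs, df1, df2, lower.tail = FALSE)
  zero_w <- ss_within == 0
  Fs[zero_w] <- ifelse(ss_between[zero_w] > 0, Inf, 0)
  p[zero_w] <- ifelse(ss_between[zero_w] > 0, 0, 1)
  .result_table(rownames(X), "region_anova", segment,
                Fs, p, bh_fdr(p), "F")
}

#' Ordinal trend on enrichment scores
#'
#' [ordinal_trend] applied to an enrichment (or deconvolution) score
#' matrix, with gene sets as the units.
#'
#' @param scores An `enrichment_matrix` (sets x AOIs).
#' @param ann AOI annotation data frame.
#' @param segment `"PanCK"` or `"Vimentin"`.
#' @return Result table with `effect` = Spearman rho per set.
#' @export
trend_on_scores <- function(scores, ann, segment) {
  ordinal_trend(unclass(scores), ann, segment)
}
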