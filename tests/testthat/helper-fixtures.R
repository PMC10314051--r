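# Shared helpers: tiny in-code fixtures and independent oracle
# implementations used across test files.

# minimal probe_counts: n_targets targets x probes_per_target probes,
# n_neg negatives, counts supplied or constant
tiny_counts <- function(counts_target, counts_neg, aoi = NULL,
                        probes_per_target = NULL, targets = NULL) {
  counts_target <- as.matrix(counts_target)
  counts_neg <- as.matrix(counts_neg)
  if (is.null(aoi)) aoi <- paste0("A", seq_len(ncol(counts_target)))
  colnames(counts_target) <- aoi
  colnames(counts_neg) <- aoi
  if (is.null(targets)) {
    stopifnot(!is.null(probes_per_target))
    n_t <- nrow(counts_target) / probes_per_target
    targets <- rep(paste0("T", seq_len(n_t)), each = probes_per_target)
  }
  probe_id <- paste0(targets, ".p", stats::ave(seq_along(targets), targets,
                                               FUN = seq_along))
  neg_id <- paste0("Neg", seq_len(nrow(counts_neg)))
  meta <- data.frame(
    probe_id = c(probe_id, neg_id),
    target = c(targets, neg_id),
    probe_class = c(rep("target", length(targets)),
                    rep("negative", nrow(counts_neg))),
    stringsAsFactors = FALSE
  )
  probe_counts(rbind(counts_target, counts_neg), meta)
}

# annotation covering given AOIs, all passing QC
tiny_ann <- function(aoi, segment = rep("PanCK", length(aoi)),
                     histology = rep("normal", length(aoi)),
                     sample_id = rep("S01", length(aoi)),
                     roi_id = paste0("R", seq_along(aoi))) {
  validate_aoi_annotation(data.frame(
    aoi_id = aoi, sample_id = sample_id, roi_id = roi_id,
    segment = segment, histology = histology,
    nuclei = 500, area = 50000, raw_reads = 2e5, pct_aligned = 95,
    seq_saturation = 80, ntc_count = 5, stringsAsFactors = FALSE
  ))
}

# --- independent oracles -------------------------------------------------

# BH step-up, written as a direct loop over the definition
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min((n / seq(i, n)) * ps[seq(i, n)]))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Grubbs decision through an independent route: convert each candidate's
# deviation to the p-value of the max-|t| statistic and compare with alpha
grubbs_bruteforce <- function(x, alpha) {
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) return(NA_integer_)
  G <- max(abs(x - mean(x))) / s
  # invert G -> t and compute the Bonferroni-corrected tail probability
  num <- G^2 * n * (n - 2)
  den <- (n - 1)^2 - G^2 * n
  if (den <= 0) return(which.max(abs(x - mean(x))))  # beyond the support: reject
  tstat <- sqrt(num / den)
  p <- 2 * n * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  if (p < alpha) which.max(abs(x - mean(x))) else NA_integer_
}

# naive ssGSEA: explicit walk down the ranked list
ssgsea_naive <- function(expr, gene_set, alpha) {
  n <- length(expr)
  ord <- order(-expr, seq_len(n))
  genes <- names(expr)[ord]
  in_set <- genes %in% gene_set
  stat <- n - seq_len(n) + 1
  wsum <- sum(stat[in_set]^alpha)
  n_out <- sum(!in_set)
  p_in <- 0; p_out <- 0; score <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) p_in <- p_in + stat[i]^alpha / wsum
    else p_out <- p_out + 1 / n_out
    score <- score + (p_in - p_out)
  }
  score
}

rand_expr <- function(n_genes, n_aoi, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * n_aoi, 6, 1.5), n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              paste0("A", seq_len(n_aoi))))
  m
}

# 8-AOI flag fixture: one violator per QC flag + one boundary-exact AOI
make_flag_fixture <- function() {
  # 8 AOIs: one violator per flag plus one boundary-exact AOI
  aoi <- paste0("A", 1:8)
  ann <- tiny_ann(aoi)
  ann$raw_reads[1] <- 900
  ann$pct_aligned[2] <- 70
  ann$seq_saturation[3] <- 40
  # A4 gets a low negative geomean via the counts below
  ann$ntc_count[5] <- 100
  ann$nuclei[6] <- 50
  ann$area[7] <- 400
  # A8 sits exactly at every threshold
  ann$raw_reads[8] <- 1000; ann$pct_aligned[8] <- 80
  ann$seq_saturation[8] <- 50; ann$ntc_count[8] <- 60
  ann$nuclei[8] <- 100; ann$area[8] <- 600
  neg <- matrix(20, 3, 8)
  neg[, 4] <- c(9, 10, 11)   # geomean 9.97 < 10
  neg[, 8] <- 10             # geomean exactly 10
  tgt <- matrix(100, 4, 8)
  x <- tiny_counts(tgt, neg, aoi = aoi, probes_per_target = 1)
  list(x = x, ann = ann)
}

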