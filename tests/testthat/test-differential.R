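# BH FDR, paired/stepwise t-tests, ordinal trend, region ANOVA.

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, NA)), "missing")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # brute-force agreement on random vectors (full grid in acceptance)
  set.seed(1)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_bruteforce(p))
  }
})

make_paired_data <- function(n_genes = 30, n_roi = 8, shift_gene = NULL,
                             shift = 0, seed = 1) {
  set.seed(seed)
  aoi <- c(outer(c("PanCK", "Vimentin"), paste0("R", 1:n_roi),
                 function(s, r) paste(r, s, sep = "_")))
  seg <- rep(c("PanCK", "Vimentin"), n_roi)
  roi <- rep(paste0("R", 1:n_roi), each = 2)
  ann <- tiny_ann(aoi, segment = seg, roi_id = roi,
                  histology = rep("normal", length(aoi)))
  m <- matrix(rnorm(n_genes * length(aoi), 6, 0.3), n_genes,
              dimnames = list(paste0("G", 1:n_genes), aoi))
  if (!is.null(shift_gene))
    m[shift_gene, seg == "PanCK"] <- m[shift_gene, seg == "PanCK"] + shift
  list(m = m, ann = ann)
}

test_that("paired segment test recovers shifts and respects conventions", {
  d <- make_paired_data(shift_gene = "G1", shift = 1)
  res <- paired_segment_de(d$m, d$ann)
  r1 <- res[res$unit_id == "G1", ]
  expect_lt(r1$p_value, 0.01)
  expect_identical(r1$direction, "up")
  expect_equal(r1$effect, 1, tolerance = 0.3)
  # agreement with t.test on a single gene
  pk <- d$ann$aoi_id[d$ann$segment == "PanCK"]
  vm <- d$ann$aoi_id[d$ann$segment == "Vimentin"]
  tt <- t.test(d$m["G2", pk], d$m["G2", vm], paired = TRUE)
  r2 <- res[res$unit_id == "G2", ]
  expect_equal(r2$p_value, tt$p.value)
  expect_equal(r2$effect, unname(tt$estimate))

  # identical values in both members of every pair: effect 0, p 1
  d2 <- d
  d2$m["G3", vm] <- d2$m["G3", pk]
  res2 <- paired_segment_de(d2$m, d2$ann)
  expect_equal(res2$effect[res2$unit_id == "G3"], 0)
  expect_equal(res2$p_value[res2$unit_id == "G3"], 1)

  # swapping segment labels negates effects, preserves p
  ann_sw <- d$ann
  ann_sw$segment <- ifelse(ann_sw$segment == "PanCK", "Vimentin", "PanCK")
  res_sw <- paired_segment_de(d$m, ann_sw)
  expect_equal(res_sw$effect, -res$effect)
  expect_equal(res_sw$p_value, res$p_value)
})

test_that("incomplete ROI pairs are excluded with a message", {
  d <- make_paired_data()
  keep <- d$ann$aoi_id != d$ann$aoi_id[1]   # drop one PanCK AOI
  expect_message(res <- paired_segment_de(d$m[, d$ann$aoi_id[keep]],
                                          d$ann[keep, ]),
                 "lacking")
  expect_s3_class(res, "data.frame")
})

make_stepwise_data <- function(n_genes = 20, n_per = 8, sdv = 0.3,
                               shift_gene = NULL, shift = 0, seed = 2) {
  set.seed(seed)
  hist <- rep(names(spatialprof:::HISTOLOGY_RANKS), each = n_per)
  aoi <- paste0("A", seq_along(hist))
  ann <- tiny_ann(aoi, segment = rep("PanCK", length(aoi)), histology = hist,
                  roi_id = paste0("R", seq_along(aoi)))
  m <- matrix(rnorm(n_genes * length(aoi), 6, sdv), n_genes,
              dimnames = list(paste0("G", 1:n_genes), aoi))
  if (!is.null(shift_gene))
    m[shift_gene, ] <- m[shift_gene, ] +
      shift * (histology_rank(hist) - 1)
  list(m = m, ann = ann)
}

test_that("stepwise contrasts test adjacent histologies with joint gates", {
  d <- make_stepwise_data(shift_gene = "G1", shift = 1)
  res <- stepwise_de(d$m, d$ann, "PanCK")
  expect_identical(sort(unique(res$contrast)),
                   sort(c("transition_vs_normal",
                          "low_grade_dysplasia_vs_transition",
                          "high_grade_dysplasia_vs_low_grade_dysplasia",
                          "carcinoma_vs_high_grade_dysplasia")))
  g1 <- res[res$unit_id == "G1", ]
  expect_true(all(g1$significant))
  expect_equal(g1$effect, rep(1, 4), tolerance = 0.45)
  # identical distributions: not significant
  g2 <- res[res$unit_id == "G2", ]
  expect_false(any(g2$significant))
  # Welch identity vs t.test
  x1 <- d$m["G3", d$ann$histology == "normal"]
  x2 <- d$m["G3", d$ann$histology == "transition"]
  tt <- t.test(x2, x1)
  r3 <- res[res$unit_id == "G3" & res$contrast == "transition_vs_normal", ]
  expect_equal(r3$p_value, tt$p.value)

  # the fold-change gate blocks small effects regardless of p
  d4 <- make_stepwise_data(n_per = 200, shift_gene = "G4", shift = 0.4,
                           sdv = 0.2, seed = 4)
  res4 <- stepwise_de(d4$m, d4$ann, "PanCK")
  g4 <- res4[res4$unit_id == "G4" & res4$contrast == "transition_vs_normal", ]
  expect_lt(g4$p_value, 0.001)
  expect_false(g4$significant)
})

test_that("a planted 1-log2 shift is detected in >= 95% of simulations", {
  set.seed(5)
  hits <- 0
  for (rep in 1:200) {
    x1 <- rnorm(8, 0, 0.3); x2 <- rnorm(8, 1, 0.3)
    tt <- t.test(x2, x1)
    hits <- hits + (tt$p.value < 0.05 && abs(mean(x2) - mean(x1)) > 0.5)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("small groups are skipped with a warning", {
  d <- make_stepwise_data(n_per = 8)
  keep <- d$ann$histology != "normal" |
    d$ann$aoi_id %in% d$ann$aoi_id[d$ann$histology == "normal"][1]
  expect_warning(res <- stepwise_de(d$m[, d$ann$aoi_id[keep]], d$ann[keep, ],
                                    "PanCK"),
                 "transition_vs_normal")
  expect_false("transition_vs_normal" %in% res$contrast)
})

test_that("ordinal trend follows the Spearman contract", {
  hist <- names(spatialprof:::HISTOLOGY_RANKS)
  aoi <- paste0("A", 1:5)
  ann <- tiny_ann(aoi, segment = rep("Vimentin", 5), histology = hist,
                  roi_id = paste0("R", 1:5))
  m <- rbind(G1 = 1:5, G2 = c(2, 1, 4, 3, 5), G3 = rep(7, 5))
  colnames(m) <- aoi
  res <- ordinal_trend(m, ann, "Vimentin")
  expect_equal(res$effect[res$unit_id == "G1"], 1)
  expect_identical(res$direction[res$unit_id == "G1"], "up")
  # agreement with cor.test
  ct <- suppressWarnings(cor.test(m["G2", ], 1:5, method = "spearman",
                                  exact = FALSE))
  expect_equal(res$effect[res$unit_id == "G2"], unname(ct$estimate))
  expect_equal(res$p_value[res$unit_id == "G2"], ct$p.value)
  # constant unit: rho 0, p 1, degenerate flag
  expect_equal(res$p_value[res$unit_id == "G3"], 1)
  expect_true(res$degenerate[res$unit_id == "G3"])
  # negating values negates rho
  resn <- ordinal_trend(-m[1:2, ], ann, "Vimentin")
  expect_equal(resn$effect, -res$effect[1:2])
  # fewer than 3 distinct ranks is an error
  ann2 <- ann; ann2$histology <- rep(c("normal", "carcinoma"), c(2, 3))
  ann2$histology_rank <- histology_rank(ann2$histology)
  expect_error(ordinal_trend(m, ann2, "Vimentin"), "3 distinct")
})

test_that("trend p-values are calibrated under label-independent data", {
  set.seed(6)
  hist <- rep(names(spatialprof:::HISTOLOGY_RANKS), each = 10)
  aoi <- paste0("A", seq_along(hist))
  ann <- tiny_ann(aoi, segment = rep("PanCK", length(aoi)), histology = hist,
                  roi_id = paste0("R", seq_along(aoi)))
  m <- matrix(rnorm(1000 * length(aoi)), 1000,
              dimnames = list(paste0("G", 1:1000), aoi))
  res <- ordinal_trend(m, ann, "PanCK")
  frac <- mean(res$p_value < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
})

test_that("region ANOVA matches classical identities and detects shifts", {
  d <- make_stepwise_data(n_per = 6, seed = 7)
  res <- region_anova(d$m, d$ann, "PanCK")
  # identity with oneway.test on one gene
  g <- factor(d$ann$histology)
  ow <- oneway.test(d$m["G1", ] ~ g, var.equal = TRUE)
  r1 <- res[res$unit_id == "G1", ]
  expect_equal(r1$effect, unname(ow$statistic))
  expect_equal(r1$p_value, ow$p.value)

  # two groups: F equals the square of the pooled t statistic
  keep <- d$ann$histology %in% c("normal", "carcinoma")
  res2 <- region_anova(d$m[, d$ann$aoi_id[keep]], d$ann[keep, ], "PanCK")
  tt <- t.test(d$m["G2", d$ann$aoi_id[keep][1:6]],
               d$m["G2", d$ann$aoi_id[keep][7:12]], var.equal = TRUE)
  expect_equal(res2$effect[res2$unit_id == "G2"], unname(tt$statistic)^2)

  # a strongly shifted group is detected
  d$m["G5", d$ann$histology == "carcinoma"] <-
    d$m["G5", d$ann$histology == "carcinoma"] + 3
  res3 <- region_anova(d$m, d$ann, "PanCK")
  expect_lt(res3$p_value[res3$unit_id == "G5"], 1e-6)
})

test_that("trend on scores shares the ordinal_trend contract", {
  set.seed(8)
  hist <- rep(names(spatialprof:::HISTOLOGY_RANKS), each = 8)
  aoi <- paste0("A", seq_along(hist))
  ann <- tiny_ann(aoi, segment = rep("PanCK", length(aoi)), histology = hist,
                  roi_id = paste0("R", seq_along(aoi)))
  rk <- histology_rank(hist)
  sc <- rbind(rising = rk + rnorm(length(rk), 0, 0.3),
              flat = rnorm(length(rk)))
  colnames(sc) <- aoi
  scores <- structure(sc, class = c("enrichment_matrix", "matrix", "array"))
  res <- trend_on_scores(scores, ann, "PanCK")
  expect_lt(res$fdr[res$unit_id == "rising"], 0.05)
  expect_gt(res$effect[res$unit_id == "rising"], 0.8)
})

test_that("results are invariant to AOI ordering", {
  d <- make_stepwise_data(seed = 9)
  perm <- sample(ncol(d$m))
  res_a <- ordinal_trend(d$m, d$ann, "PanCK")
  res_b <- ordinal_trend(d$m[, perm], d$ann, "PanCK")
  expect_equal(res_a, res_b)
  expect_equal(region_anova(d$m, d$ann, "PanCK"),
               region_anova(d$m[, perm], d$ann, "PanCK"))
})
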