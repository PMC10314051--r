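# ssGSEA scoring, panel-applicability filter, deconvolution.

test_that("ssGSEA score matches the hand-walked accumulation", {
  e <- c(A = 3, B = 2, C = 1)
  # set = top gene, alpha 0: running differences 1, 0.5, 0
  expect_equal(ssgsea_score(e, "A", alpha = 0), 1.5)
  # set = bottom gene: mirror image
  expect_equal(ssgsea_score(e, "C", alpha = 0), -1.5)
  # rank invariance under strictly increasing transforms
  set.seed(1)
  x <- rnorm(30); names(x) <- paste0("G", 1:30)
  gs <- sample(names(x), 6)
  expect_equal(ssgsea_score(exp(x), gs, 0.25), ssgsea_score(x, gs, 0.25))
  expect_error(ssgsea_score(e, "Z"), "no gene")
  expect_error(ssgsea_score(e, c("A", "B", "C")), "universe")
})

test_that("ssGSEA agrees exactly with a naive re-walk on random instances", {
  set.seed(2)
  for (rep in 1:200) {
    n <- sample(5:50, 1)
    x <- rnorm(n); names(x) <- paste0("G", seq_len(n))
    if (rep %% 4 == 0) x[sample(n, 2)] <- x[1]  # plant ties
    k <- sample(1:min(10, n - 1), 1)
    gs <- sample(names(x), k)
    alpha <- sample(c(0, 0.25, 1), 1)
    expect_equal(ssgsea_score(x, gs, alpha), ssgsea_naive(x, gs, alpha))
  }
})

test_that("reversing the ranking negates the alpha = 0 score", {
  set.seed(3)
  for (rep in 1:20) {
    n <- 25
    x <- rnorm(n); names(x) <- paste0("G", 1:n)
    gs <- sample(names(x), 5)
    expect_equal(ssgsea_score(-x, gs, 0), -ssgsea_score(x, gs, 0))
  }
})

test_that("ssgsea matrix scoring is columnwise and handles degenerate ties", {
  m <- rand_expr(40, 6, seed = 4)
  sets <- gene_set_collection(list(S1 = rownames(m)[1:5],
                                   S2 = rownames(m)[6:10]))
  sc <- ssgsea(m, sets, alpha = 0.25)
  expect_equal(dim(sc), c(2L, 6L))
  # per-column: matches the single-sample scorer
  expect_equal(sc["S1", 3], ssgsea_score(m[, 3], sets$sets$S1, 0.25))
  # duplicated AOI column duplicates its score column
  m2 <- cbind(m, dup = m[, 1])
  sc2 <- ssgsea(m2, sets, alpha = 0.25)
  expect_equal(sc2[, "dup"], sc2[, 1])
  # constant column: all-tied ranks resolved by stable input order, so
  # the score is well-defined and matches the naive walk
  mc <- m; mc[, 2] <- 5
  scc <- ssgsea(mc, gene_set_collection(list(S1 = rownames(m)[1:5],
                                             S2 = rownames(m)[11:15])), 0.25)
  expect_equal(scc["S1", 2], ssgsea_naive(mc[, 2], rownames(m)[1:5], 0.25))
  expect_equal(scc["S2", 2], ssgsea_naive(mc[, 2], rownames(m)[11:15], 0.25))
  # sets below min_genes are dropped with a warning
  expect_warning(
    ssgsea(m, gene_set_collection(list(S1 = rownames(m)[1:5], tiny = "nope")),
           min_genes = 2),
    "dropping")
})

test_that("planted set activity raises ssGSEA scores in shifted AOIs", {
  set.seed(5)
  wins <- 0
  for (rep in 1:50) {
    m <- rand_expr(60, 2)
    gs <- sample(rownames(m), 8)
    m[gs, 1] <- m[gs, 1] + 2   # active AOI in column 1
    sc <- ssgsea(m, gene_set_collection(list(S = gs)), alpha = 0.25)
    wins <- wins + (sc[1, 1] > sc[1, 2])
  }
  expect_equal(wins, 50)
})

test_that("panel filter keeps faithful sets and removes panel-orphans", {
  set.seed(6)
  ref <- rand_expr(300, 12)
  inside <- rownames(ref)[1:10]          # set fully inside the panel
  orphan <- rownames(ref)[291:300]       # set with zero panel overlap
  panel <- rownames(ref)[1:150]
  sets <- gene_set_collection(list(inside = inside, orphan = orphan))
  filt <- filter_sets_by_panel(ref, panel, sets, r_min = 0.6)
  rep_df <- attr(filt, "filter_report")
  expect_true("inside" %in% names(filt$sets))
  expect_false("orphan" %in% names(filt$sets))
  expect_identical(rep_df$reason[rep_df$set == "orphan"], "no panel genes")
  expect_gt(rep_df$r[rep_df$set == "inside"], 0.6)

  # panel = full universe: r = 1 for every set, all kept
  all_filt <- filter_sets_by_panel(ref, rownames(ref), sets, r_min = 0.6)
  rep_all <- attr(all_filt, "filter_report")
  expect_true(all(rep_all$kept))
  expect_gt(min(rep_all$r, na.rm = TRUE), 0.999)

  # r_min = 0: only structural filters act
  f0 <- filter_sets_by_panel(ref, panel, sets, r_min = 1e-9)
  expect_true("inside" %in% names(f0$sets))
  expect_error(filter_sets_by_panel(ref[, 1:2], panel, sets), ">= 3")
})

test_that("redundancy groups keep the highest-correlation member", {
  set.seed(7)
  ref <- rand_expr(200, 10)
  panel <- rownames(ref)[1:120]
  sets <- gene_set_collection(list(
    proc_a1 = rownames(ref)[1:10],            # fully in panel: high r
    proc_a2 = c(rownames(ref)[1:5], rownames(ref)[121:125]),  # half outside
    other = rownames(ref)[11:20]))
  filt <- filter_sets_by_panel(ref, panel, sets, r_min = 0,
                               redundancy_groups = list(a = c("proc_a1",
                                                              "proc_a2")))
  kept <- names(filt$sets)
  expect_true("other" %in% kept)
  expect_identical(sum(c("proc_a1", "proc_a2") %in% kept), 1L)
  rep_df <- attr(filt, "filter_report")
  winner <- rep_df$set[rep_df$kept & grepl("^proc", rep_df$set)]
  expect_identical(winner, rep_df$set[which.max(ifelse(grepl("^proc", rep_df$set),
                                                       rep_df$r, -Inf))])
})

test_that("deconvolution ranks planted marker activity on top", {
  markers <- read_gmt(system.file("extdata", "immune_markers_synthetic.gmt",
                                  package = "spatialprof"))
  set.seed(8)
  universe <- unique(unlist(markers$sets))
  filler <- sprintf("FILL%03d", 1:300)
  m <- matrix(rnorm((length(universe) + 300) * 4, 6, 1),
              ncol = 4,
              dimnames = list(c(universe, filler), paste0("A", 1:4)))
  m[markers$sets$Macrophages, 1] <- m[markers$sets$Macrophages, 1] + 3
  sc <- deconvolve(m, markers, alpha = 0.25)
  expect_identical(rownames(sc)[which.max(sc[, 1])], "Macrophages")

  # immune-low (epithelial-like) AOIs score below immune-high (stromal-like)
  m2 <- m
  immune <- setdiff(names(markers$sets), c("Fibroblasts", "Endothelial_cells"))
  for (ct in immune) m2[markers$sets[[ct]], 4] <- m2[markers$sets[[ct]], 4] + 2
  sc2 <- deconvolve(m2, markers, alpha = 0.25)
  expect_true(all(sc2[immune, 4] > sc2[immune, 2]))

  # identical marker sets give identical score rows
  twin <- gene_set_collection(list(x = markers$sets$B_cells,
                                   y = markers$sets$B_cells))
  sct <- deconvolve(m, twin)
  expect_equal(unname(sct["x", ]), unname(sct["y", ]))
})

test_that("deconvolution is invariant to monotone per-column rescaling", {
  markers <- read_gmt(system.file("extdata", "immune_markers_synthetic.gmt",
                                  package = "spatialprof"))
  set.seed(9)
  genes <- c(unique(unlist(markers$sets)), sprintf("FILL%03d", 1:100))
  m <- matrix(rnorm(length(genes) * 3, 6, 1), ncol = 3,
              dimnames = list(genes, paste0("A", 1:3)))
  sc <- deconvolve(m, markers)
  m2 <- m
  m2[, 1] <- exp(m2[, 1]); m2[, 2] <- 3 * m2[, 2] + 7
  expect_equal(unclass(deconvolve(m2, markers)), unclass(sc))
})
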