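test_that("largest-remainder allocation is exact and deterministic", {
  expect_equal(
    allocate_counts(400, c(CO = 0.25, OC = 0.25, PO = 0.25, PC = 0.25)),
    c(CO = 100L, OC = 100L, PO = 100L, PC = 100L))
  # remainder goes to largest fractional parts, ties by order
  expect_equal(allocate_counts(10, c(a = 1/3, b = 1/3, c = 1/3)),
               c(a = 4L, b = 3L, c = 3L))
  expect_equal(sum(allocate_counts(97, c(x = 0.93, y = 0.03, z = 0.04))),
               97L)
  expect_error(allocate_counts(10, c(a = 0.5, b = 0.6)), "sum to 1")
  expect_error(allocate_counts(10, c(0.5, 0.5)), "named")
})

test_that("CAD simulator plants exact label counts and is seed-stable", {
  gm <- genome_model(c("chrA", "chrB"), c(2e6, 2e6))
  sm <- five_stage_map(1)
  d1 <- simulate_cad_dataset(gm, 400,
                             c(CO = .25, OC = .25, PO = .25, PC = .25),
                             sm, seed = 7)
  expect_equal(unname(table(d1$truth$labels)[c("CO", "OC", "PO", "PC")]),
               rep(100L, 4), ignore_attr = TRUE)
  d2 <- simulate_cad_dataset(gm, 400,
                             c(CO = .25, OC = .25, PO = .25, PC = .25),
                             sm, seed = 7)
  expect_identical(unclass(d1$peaks)[, ], unclass(d2$peaks)[, ])
  expect_identical(unclass(d1$background)[, ], unclass(d2$background)[, ])

  # degenerate proportions: all permanently open above the planted signal
  d3 <- simulate_cad_dataset(gm, 100, c(PO = 1.0), sm, seed = 1)
  expect_true(all(unclass(d3$peaks) >
                    stats::qexp(0.999, d3$truth$lambda_bg)))
  expect_error(
    simulate_cad_dataset(gm, 10, c(CO = 0.5, OC = 0.6), sm, seed = 1),
    "sum to 1")
})

test_that("bulk signature simulator plants stage effects", {
  stages <- c("s1", "s2")
  genes <- sprintf("gene_%05d", 1:10)
  sig <- list(up = list(genes = genes,
                        effect = c(s1 = 1, s2 = 8)))
  b <- simulate_bulk_signatures(500, 3, stages, sig, seed = 9)
  m <- unclass(b$fpkm)
  s2_cols <- grepl("^s2_", colnames(m))
  # sample-mean oracle on the generated table
  expect_gt(mean(m[genes, s2_cols]), mean(m[genes, !s2_cols]))
  expect_gt(mean(m[genes, s2_cols]),
            mean(m[setdiff(rownames(m), genes), s2_cols]))

  # null case: multiplier 1 everywhere makes members exchangeable
  sig0 <- list(up = list(genes = genes, effect = c(s1 = 1, s2 = 1)))
  b0 <- simulate_bulk_signatures(500, 3, stages, sig0, seed = 9)
  m0 <- unclass(b0$fpkm)
  pv <- stats::wilcox.test(as.vector(m0[genes, ]),
                           as.vector(m0[sample(setdiff(rownames(m0),
                                                       genes), 50), ]))$p.value
  expect_gt(pv, 1e-4)

  b2 <- simulate_bulk_signatures(500, 3, stages, sig, seed = 9)
  expect_identical(unclass(b$fpkm)[, ], unclass(b2$fpkm)[, ])
  expect_error(
    simulate_bulk_signatures(5, 2, stages,
                             list(x = list(genes = "gene_99999",
                                           effect = c(s1 = 1, s2 = 1)))),
    "outside the universe")
})

test_that("marker panel construction guarantees recovery margins", {
  mp <- simulate_marker_panel(50, 10, seed = 3)
  got <- select_tsc_markers(mp$panel)
  expect_setequal(got$genes, mp$truth)
  # margin >= 0.5 log2 units on every condition for true markers
  r <- attr(got, "ratios")
  tm <- r[r$gene %in% mp$truth, ]
  expect_true(all(tm$log2_nTSC_vs_hES >= 3.5))
  expect_true(all(tm$log2_nTSC_vs_pTSC >= 3.0))
  expect_true(all(tm$log2_EVT_vs_nTSC <= -2.0))
  expect_true(all(tm$log2_ST_vs_nTSC <= -2.0))

  # no planted markers -> empty selection
  mp0 <- simulate_marker_panel(30, 0, seed = 5)
  expect_length(select_tsc_markers(mp0$panel)$genes, 0)

  mpa <- simulate_marker_panel(50, 10, seed = 3)
  expect_identical(unclass(mp$panel)[, ], unclass(mpa$panel)[, ])
})

test_that("cell simulator plants separable lineages and QC failures", {
  msets <- default_lineage_markers(10)
  sc <- simulate_cell_matrix(300, 4000,
                             c(naive = .4, primed = .3, TE = .2, PrE = .1),
                             msets, elevation = 50, frac_fail_qc = 0,
                             seed = 21)
  m <- unclass(sc$counts)
  # separability limit: argmax of marker-set mean identifies the lineage
  means <- vapply(msets, function(s) colMeans(m[s$genes, ]),
                  numeric(ncol(m)))
  called <- colnames(means)[max.col(means)]
  expect_equal(called, unname(sc$truth$lineage[colnames(m)]))

  sc2 <- simulate_cell_matrix(300, 4000,
                              c(naive = .4, primed = .3, TE = .2, PrE = .1),
                              msets, elevation = 50, frac_fail_qc = 0,
                              seed = 21)
  expect_identical(m[, ], unclass(sc2$counts)[, ])

  # planted failing fraction is exact and flagged
  sc3 <- simulate_cell_matrix(200, 4000,
                              c(naive = 1, primed = 0, TE = 0, PrE = 0),
                              msets, frac_fail_qc = 0.1, seed = 2)
  expect_equal(sum(sc3$truth$fail_qc), 20)
})

test_that("temporal pattern generator plants six distinct shapes", {
  p <- simulate_temporal_patterns(genes_per_pattern = 10, seed = 4)
  expect_equal(dim(unclass(p$fpkm)), c(60, 5))
  expect_equal(p$labels, rep(1:6, each = 10))
  p2 <- simulate_temporal_patterns(genes_per_pattern = 10, seed = 4)
  expect_identical(unclass(p$fpkm)[, ], unclass(p2$fpkm)[, ])
  # planted shapes are pairwise distinct after z-scoring
  z <- t(scale(t(log2(unclass(p$fpkm) + 1))))
  cent <- apply(z, 2, function(col) tapply(col, p$labels, mean))
  d <- as.matrix(dist(cent))
  expect_true(all(d[upper.tri(d)] > 1))
})
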