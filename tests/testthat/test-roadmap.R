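make_qc_fixture <- function(n_genes = 3500, n_cells = 60, lambda = 1.9,
                            seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_cells, lambda), n_genes,
                dimnames = list(
                  c(sprintf("MT-G%02d", 1:10), sprintf("RPL%02d", 1:10),
                    sprintf("gene_%05d", seq_len(n_genes - 20))),
                  sprintf("cell_%03d", seq_len(n_cells))))
  })
  m
}

test_that("QC thresholds are strict and ordered cells-then-genes", {
  m <- make_qc_fixture(seed = 2)
  # boundary cell: exactly 2500 detected genes -> removed (strict >);
  # rows avoid gene_00001 (row 21), which is zeroed below
  m[, 1] <- 0
  m[c(1:20, 22:2501), 1] <- 1
  # comfortable cell: nFeature 3000, nCount 5000, low pctMT -> retained
  m[, 2] <- 0
  m[21:3020, 2] <- 1
  m[21:2020, 2] <- 2
  # gene detected in exactly 9 retained cells -> removed
  m["gene_00001", ] <- 0
  res0 <- qc_filter_cells(value_matrix(m, "COUNT"), qc = default_qc)
  retained <- res0$cells$cell_id[res0$cells$pass]
  m["gene_00001", retained[1:9]] <- 1

  res <- qc_filter_cells(value_matrix(m, "COUNT"), qc = default_qc)
  expect_false("cell_001" %in% colnames(res$counts))
  expect_equal(res$cells$nFeature[1], 2500)
  expect_true("cell_002" %in% colnames(res$counts))
  expect_false("gene_00001" %in% rownames(res$counts))
  expect_equal(
    res$genes$n_cells_detected[res$genes$gene_id == "gene_00001"], 9)
  # ribosomal genes removed even when broadly detected
  expect_false(any(grepl("^RP[LS]", rownames(res$counts))))
  expect_error(qc_filter_cells(tiny_matrix(matrix(0.5, 1), scale = "COUNT")),
               "integers")
})

test_that("QC filter equals brute-force rule scan on random fixtures", {
  for (seed in 1:6) {
    m <- make_qc_fixture(n_genes = 3000, n_cells = 50,
                         lambda = runif(1, 1.6, 2.2), seed = seed)
    res <- qc_filter_cells(value_matrix(m, "COUNT"), qc = default_qc)
    orc <- oracle_qc(m, default_qc)
    expect_setequal(as.character(colnames(res$counts)), orc$cells)
    expect_setequal(as.character(rownames(res$counts)), orc$genes)
  }
})

test_that("lineage assignment is argmax with tie and margin rules", {
  sc <- rbind(c1 = c(naive = 0.9, primed = 0.1, TE = 0.1, PrE = 0.1),
              c2 = c(naive = 0.5, primed = 0.5, TE = 0.1, PrE = 0.1),
              c3 = c(naive = 0.30, primed = 0.25, TE = 0.1, PrE = 0.1))
  a <- assign_lineage(sc)
  expect_equal(as.character(a$label), c("naive", "unassigned", "naive"))
  a2 <- assign_lineage(sc, min_margin = 0.1)
  expect_equal(as.character(a2$label[3]), "unassigned")
  expect_equal(a$margin[1], 0.8)
})

test_that("lineage proportions sum to 1 and ignore cell order", {
  withr::with_seed(17, {
    n <- 300
    labels <- sample(c("naive", "primed", "TE", "PrE"), n, replace = TRUE,
                     prob = c(.7, .1, .1, .1))
    stage <- sample(c("day8", "nESC"), n, replace = TRUE)
  })
  sc <- matrix(0, n, 4, dimnames = list(sprintf("c%03d", 1:n),
                                        c("naive", "primed", "TE", "PrE")))
  sc[cbind(1:n, match(labels, colnames(sc)))] <- 1
  a <- assign_lineage(sc)
  props <- lineage_proportions(a, stats::setNames(stage, a$cell_id),
                               stage_order = c("day8", "nESC"))
  expect_equal(unname(rowSums(props)), c(1, 1), tolerance = 1e-9)
  # permutation invariance
  perm <- withr::with_seed(1, sample(n))
  a_perm <- assign_lineage(sc[perm, ])
  props2 <- lineage_proportions(a_perm,
                                stats::setNames(stage, a$cell_id),
                                stage_order = c("day8", "nESC"))
  expect_equal(props2, props)
  # degenerate: every cell naive
  sc1 <- sc; sc1[] <- 0; sc1[, "naive"] <- 1
  p1 <- lineage_proportions(assign_lineage(sc1),
                            stats::setNames(stage, a$cell_id),
                            stage_order = c("day8", "nESC"))
  expect_equal(unname(p1[, "naive"]), c(1, 1))
  # renormalization after dropping unassigned is explicit
  sc2 <- sc; sc2[1, ] <- 0.5
  a3 <- assign_lineage(sc2)
  p3 <- lineage_proportions(a3, stats::setNames(stage, a$cell_id),
                            stage_order = c("day8", "nESC"),
                            drop_unassigned = TRUE)
  expect_equal(unname(rowSums(p3)), c(1, 1), tolerance = 1e-9)
})

test_that("pipeline runner writes deterministic outputs end-to-end", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  man1 <- run_pipeline(out_dir = out1, seed = 42, n_regions = 300,
                       n_cells = 300, n_genes_bulk = 500)
  man2 <- run_pipeline(out_dir = out2, seed = 42, n_regions = 300,
                       n_cells = 300, n_genes_bulk = 500)
  expect_true(all(file.exists(file.path(out1, names(man1$outputs)))))
  expect_identical(man1$outputs, man2$outputs)  # byte-identical digests
  expect_lte(man1$threshold$efdr, man1$threshold$alpha)
})
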