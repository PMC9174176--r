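test_that("RPKM arithmetic matches the definition", {
  cnt <- tiny_matrix(matrix(c(100, 0), 2), scale = "COUNT")
  rpkm <- compute_rpkm(cnt, region_lengths = c(1000, 1000),
                       library_sizes = 1e7)
  expect_equal(unclass(rpkm)[1, 1], 10.0)  # 100 * 1e9 / (1000 * 1e7)
  expect_equal(unclass(rpkm)[2, 1], 0.0)

  # doubling library size halves every value
  withr::with_seed(1, {
    cnt2 <- tiny_matrix(matrix(rpois(20, 50), 5), scale = "COUNT")
  })
  a <- compute_rpkm(cnt2, rep(500, 5), rep(1e6, 4))
  b <- compute_rpkm(cnt2, rep(500, 5), rep(2e6, 4))
  expect_equal(unclass(a)[, ] / 2, unclass(b)[, ])
  expect_error(compute_rpkm(cnt2, rep(500, 5), rep(0, 4)), "library")
  expect_equal(vm_scale(a), "RPKM")
})

test_that("background shuffle conserves counts/lengths and never overlaps", {
  gm <- genome_model("chr1", 10000)
  pk <- region_set("chr1", 5000, 5100, id = "p1", genome = gm)
  bg <- shuffle_background(pk, gm, seed = 1)
  expect_equal(nrow(bg), 1)
  expect_equal(bg$end - bg$start, 100)
  expect_equal(oracle_any_overlap(bg, pk), 0L)

  gm2 <- genome_model(c("chr1", "chr2"), c(5e5, 5e5))
  withr::with_seed(5, {
    start <- sort(sample(seq(0, 4.9e5, by = 1200), 200))
  })
  pk2 <- region_set(rep(c("chr1", "chr2"), each = 100), start[1:200],
                    start[1:200] + 300, genome = gm2)
  bg2 <- shuffle_background(pk2, gm2, seed = 2)
  expect_equal(nrow(bg2), nrow(pk2))
  expect_equal(bg2$end - bg2$start, pk2$end - pk2$start)
  expect_equal(bg2$chrom, pk2$chrom)
  # brute-force all-pairs interval oracle: bg vs peaks, bg vs bg
  expect_equal(oracle_any_overlap(bg2, pk2), 0L)
  self <- oracle_any_overlap(bg2, bg2)
  expect_equal(self, nrow(bg2))  # only self-hits
  expect_identical(shuffle_background(pk2, gm2, seed = 2), bg2)
  # impossible placement errors with the region name
  gm3 <- genome_model("chrX", 250)
  pk3 <- region_set("chrX", 0, 200, id = "wide", genome = gm3)
  expect_error(shuffle_background(pk3, gm3, seed = 1, max_attempts = 50),
               "wide")
})

test_that("threshold calibration matches the exhaustive sweep", {
  pk <- tiny_matrix(matrix(c(20, 30, 40, 50), 2), scale = "RPKM")
  bg <- tiny_matrix(matrix(c(1, 2, 3, 3), 2), scale = "RPKM")
  thr <- calibrate_open_threshold(pk, bg, alpha = 0.01)
  expect_equal(thr$t_star, 20)
  expect_equal(thr$efdr_at_t, 0)
  orc <- oracle_threshold(c(20, 30, 40, 50), c(1, 2, 3, 3), 0.01)
  expect_equal(thr$t_star, orc$t_star)
  expect_equal(thr$efdr_at_t, orc$efdr)

  # all-zero background: smallest positive peak value wins
  pk2 <- tiny_matrix(matrix(c(7, 3, 9, 5), 2), scale = "RPKM")
  bg2 <- tiny_matrix(matrix(rep(0, 4), 2), scale = "RPKM")
  expect_equal(calibrate_open_threshold(pk2, bg2, 0.01)$t_star, 3)

  # inseparable distributions error rather than return a bogus threshold
  same <- tiny_matrix(matrix(1:4, 2), scale = "RPKM")
  expect_error(calibrate_open_threshold(same, same, 0.01), "eFDR")
})

test_that("replicate merging averages columns per stage in order", {
  sm <- stage_map(c("early", "late"),
                  c(a1 = "early", a2 = "early", b1 = "late"))
  m <- tiny_matrix(matrix(c(10, 20, 6), 1), genes = "r1",
                   samples = c("a1", "a2", "b1"), scale = "RPKM")
  merged <- merge_replicates(m, sm)
  expect_equal(colnames(merged), c("early", "late"))
  expect_equal(unname(unclass(merged)["r1", ]), c(15, 6))

  m3 <- tiny_matrix(matrix(c(1, 2, 6), 1), genes = "r1",
                    samples = c("a1", "a2", "a3"), scale = "RPKM")
  sm3 <- stage_map("only", c(a1 = "only", a2 = "only", a3 = "only"))
  expect_equal(unname(unclass(merge_replicates(m3, sm3))[1, 1]), 3.0)
  expect_error(merge_replicates(m, sm3), "no stage assignment")
})

test_that("binarization uses >= at the threshold and is monotone", {
  thr <- structure(list(t_star = 14.22), class = "open_threshold")
  m <- tiny_matrix(matrix(c(14.22 - 1e-9, 14.22, 15, 1), 2),
                   scale = "RPKM")
  calls <- binarize_accessibility(m, thr)
  expect_false(calls[1, 1])  # just below -> closed
  expect_true(calls[2, 1])   # equality -> open
  # raising any single value never flips open -> closed
  m2 <- unclass(m)
  m2[1, 1] <- m2[1, 1] + 5
  calls2 <- binarize_accessibility(tiny_matrix(m2, scale = "RPKM"), thr)
  expect_true(all(calls2 >= calls))
})

test_that("dynamics classes match run-length oracle over all patterns", {
  for (S in 2:5) {
    pats <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), S)))
    dimnames(pats) <- list(sprintf("r%02d", seq_len(nrow(pats))),
                           paste0("stage", seq_len(S)))
    got <- classify_dynamics(pats)
    want <- apply(pats, 1, oracle_dynamics)
    expect_equal(as.character(got), unname(want))
    # stage reversal maps CO <-> OC and fixes PO/PC/COMPLEX
    rev_got <- classify_dynamics(pats[, S:1, drop = FALSE])
    map <- c(CO = "OC", OC = "CO", PO = "PO", PC = "PC",
             COMPLEX = "COMPLEX")
    expect_equal(as.character(rev_got), unname(map[as.character(got)]))
  }
  # the canonical examples
  expect_equal(as.character(classify_dynamics(
    matrix(c(FALSE, FALSE, TRUE, TRUE), 1,
           dimnames = list("r", NULL)))), "CO")
  expect_equal(as.character(classify_dynamics(
    matrix(c(TRUE, TRUE, TRUE), 1, dimnames = list("r", NULL)))), "PO")
  expect_equal(as.character(classify_dynamics(
    matrix(c(TRUE, FALSE, TRUE), 1, dimnames = list("r", NULL)))),
    "COMPLEX")
  expect_error(classify_dynamics(matrix(TRUE, 1, 1)), "2 stages")
})

test_that("promoter windows are half-open TSS +/- w intervals", {
  gm <- genome_model("chr1", 1e6)
  tss <- data.frame(gene = c("GENE1", "GENE2"), chrom = "chr1",
                    tss = c(10000, 500000), strand = c("+", "-"))
  rs <- region_set(rep("chr1", 3), c(6500, 13000, 499999),
                   c(7200, 14000, 500001),
                   id = c("pkA", "pkB", "pkC"), genome = gm)
  asg <- assign_promoters(rs, tss, w = 3000)
  expect_equal(asg$pkA, "GENE1")      # overlaps [7000, 13000)
  expect_equal(asg$pkB, character(0)) # [13000, 14000) misses half-open edge
  expect_equal(asg$pkC, "GENE2")
  # w = 0: only regions containing the TSS base
  asg0 <- assign_promoters(rs, tss, w = 0)
  expect_equal(asg0$pkA, character(0))
  expect_equal(asg0$pkC, "GENE2")     # contains position 500000
})
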