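# shared fixture builders and independent oracles

tiny_matrix <- function(values, genes = NULL, samples = NULL,
                        scale = "FPKM") {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  value_matrix(m, scale)
}

five_stage_map <- function(reps = 2) {
  stages <- c("pESC", "day6", "day8", "day10", "nESC")
  stage_map(stages, stats::setNames(
    rep(stages, each = reps),
    paste0(rep(stages, each = reps), "_rep", seq_len(reps))))
}

# exhaustive sweep over candidate thresholds (independent of the
# implementation's findInterval path)
oracle_threshold <- function(pk, bg, alpha) {
  for (t in sort(unique(c(pk, bg)))) {
    npk <- sum(pk >= t)
    if (npk == 0) next
    efdr <- (sum(bg >= t) * length(pk) / length(bg)) / npk
    if (efdr <= alpha) return(list(t_star = t, efdr = efdr))
  }
  NULL
}

# run-length based dynamics labelling, independent of the switch-count path
oracle_dynamics <- function(open) {
  r <- rle(as.logical(open))
  if (length(r$values) == 1) return(if (r$values[1]) "PO" else "PC")
  if (length(r$values) == 2) return(if (r$values[1]) "OC" else "CO")
  "COMPLEX"
}

# all-pairs half-open interval intersection
oracle_any_overlap <- function(a, b) {
  hits <- 0L
  for (i in seq_len(nrow(a))) {
    same <- b$chrom == a$chrom[i]
    hits <- hits + sum(same & a$start[i] < b$end & b$start < a$end[i])
  }
  hits
}

# per-cell / per-gene QC rule scan with explicit loops
oracle_qc <- function(m, qc) {
  pass <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    nfeat <- sum(v > 0)
    ncnt <- sum(v)
    mt <- grepl("^MT-", rownames(m))
    pmt <- if (ncnt > 0) 100 * sum(v[mt]) / ncnt else 0
    pass[j] <- nfeat > qc$min_features && ncnt > qc$min_count &&
      ncnt < qc$max_count && pmt < qc$max_pct_mt
  }
  keep_gene <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    ndet <- sum(m[i, pass] >= 1)
    keep_gene[i] <- ndet >= qc$min_cells_per_gene &&
      !grepl("^RP[LS]", rownames(m)[i])
  }
  list(cells = colnames(m)[pass], genes = rownames(m)[keep_gene])
}

default_qc <- list(min_features = 2500, min_count = 1000,
                   max_count = 100000, max_pct_mt = 10,
                   min_cells_per_gene = 10)

# six planted canonical temporal patterns with small jitter, FPKM scale
planted_pattern_matrix <- function(genes_per_cluster = 50, seed = 11) {
  simulate_temporal_patterns(genes_per_pattern = genes_per_cluster,
                             seed = seed)
}
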