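#' Min-max scale a gene set over a sample panel
#'
#' For each retained gene g and sample j,
#' `s_gj = (x_gj - min_g) / (max_g - min_g)`, with min/max taken over
#' exactly the samples of the panel passed in, so every scaled value lies
#' in \[0, 1\] and each retained gene attains both 0 and 1 somewhere on the
#' panel. Genes are retained only if they reach the expression floor
#' (`FPKM >= tau` in at least one panel sample); genes absent from the
#' matrix are ignored with a warning, and constant genes (max = min, where
#' the formula is undefined) are dropped with a warning.
#'
#' @param matrix A [value_matrix()] (FPKM), genes x samples, `>= 2`
#'   samples.
#' @param gset A [gene_set()].
#' @param tau Expression floor (default 5 FPKM).
#' @return Numeric matrix of scaled values (retained genes x samples) with
#'   attributes `dropped_absent`, `dropped_floor`, `dropped_constant`.
#' @export
minmax_scale_genes <- function(matrix, gset, tau = 5) {
  stopifnot(inherits(gset, "gene_set"))
  if (ncol(matrix) < 2) stop("panel needs >= 2 samples", call. = FALSE)
  present <- intersect(gset$genes, rownames(matrix))
  absent <- setdiff(gset$genes, present)
  if (length(absent)) {
    warning("signature '", gset$name, "': ", length(absent),
            " gene(s) absent from matrix (e.g. ", absent[1], ")",
            call. = FALSE)
  }
  m <- unclass(matrix)[present, , drop = FALSE]
  mx <- apply(m, 1, max)
  mn <- apply(m, 1, min)
  keep_floor <- mx >= tau
  keep_range <- mx > mn
  dropped_floor <- present[!keep_floor]
  dropped_constant <- present[keep_floor & !keep_range]
  if (length(dropped_constant)) {
    warning("signature '", gset$name, "': ", length(dropped_constant),
            " constant gene(s) dropped", call. = FALSE)
  }
  keep <- keep_floor & keep_range
  if (!any(keep)) {
    stop("signature '", gset$name,
         "': no genes retained after FPKM floor / range filters",
         call. = FALSE)
  }
  s <- (m[keep, , drop = FALSE] - mn[keep]) / (mx[keep] - mn[keep])
  structure(s, dropped_absent = absent, dropped_floor = dropped_floor,
            dropped_constant = dropped_constant)
}

#' Score bulk samples against gene signatures
#'
#' The signature score of a sample is the mean of its min-max-scaled
#' expression (see [minmax_scale_genes()]) over the signature's retained
#' genes; scores are therefore bounded in \[0, 1\] and are relative to the
#' sample panel being compared.
#'
#' @param matrix A [value_matrix()] (FPKM), genes x samples.
#' @param gene_sets List of [gene_set()] objects.
#' @param tau Expression floor passed to [minmax_scale_genes()].
#' @return Numeric matrix samples x signatures of scores in \[0, 1\], with
#'   attribute `retained`: a named list of the genes each score averages.
#' @export
bulk_signature_score <- function(matrix, gene_sets, tau = 5) {
  if (inherits(gene_sets, "gene_set")) gene_sets <- list(gene_sets)
  nm <- vapply(gene_sets, `[[`, "", "name")
  retained <- stats::setNames(vector("list", length(gene_sets)), nm)
  scores <- matrix(NA_real_, ncol(matrix), length(gene_sets),
                   dimnames = list(colnames(matrix), nm))
  for (k in seq_along(gene_sets)) {
    s <- minmax_scale_genes(matrix, gene_sets[[k]], tau = tau)
    retained[[k]] <- rownames(s)
    scores[, k] <- colMeans(s)
  }
  structure(scores, retained = retained)
}

#' Control-set module score for single cells
#'
#' A per-cell expression score of a gene set against a size-matched random
#' control, in the style of control-gene-set module scoring: counts are
#' log-normalized per cell (`log(1 + count / cell_total * 1e4)`), genes are
#' binned into `n_bins` equal-frequency bins of average expression, and for
#' each set gene `n_ctrl` control genes are drawn from its bin. The score
#' is the cell's mean log-normalized expression over the set genes minus
#' its mean over the pooled (deduplicated) control genes, so under the null
#' it is centered at zero.
#'
#' @param counts A [value_matrix()] of scale COUNT, genes x cells.
#' @param gset A [gene_set()]; its intersection with the matrix must be
#'   nonempty.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes drawn per set gene (default 100).
#' @param seed Integer seed; same seed gives identical scores.
#' @return Named numeric vector of per-cell scores.
#' @export
cell_module_score <- function(counts, gset, n_bins = 24, n_ctrl = 100,
                              seed = 1L) {
  stopifnot(inherits(gset, "gene_set"))
  m <- unclass(counts)
  totals <- colSums(m)
  if (any(totals <= 0)) stop("cell with zero total counts", call. = FALSE)
  lognorm <- log1p(sweep(m, 2, totals, "/") * 1e4)
  set_genes <- intersect(gset$genes, rownames(m))
  if (!length(set_genes)) {
    stop("gene set '", gset$name, "' has no genes in the matrix",
         call. = FALSE)
  }
  avg <- rowMeans(lognorm)
  n_bins <- min(n_bins, nrow(m))
  bin <- as.integer(cut(rank(avg, ties.method = "first"), breaks = n_bins))
  names(bin) <- rownames(m)
  withr::with_seed(seed, {
    ctrl <- unlist(lapply(set_genes, function(g) {
      pool <- names(bin)[bin == bin[g]]
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }), use.names = FALSE)
    ctrl <- unique(ctrl)
    colMeans(lognorm[set_genes, , drop = FALSE]) -
      colMeans(lognorm[ctrl, , drop = FALSE])
  })
}

#' Select trophoblast stem-cell markers by expression log-ratios
#'
#' A gene is kept as a TSC marker iff all four strict inequalities hold
#' (with a +1 pseudocount):
#' `log2((nTSC+1)/(hES+1)) > 3`, `log2((nTSC+1)/(pTSC+1)) > 2.5`,
#' `log2((EVT+1)/(nTSC+1)) < -1.5`, and `log2((ST+1)/(nTSC+1)) < -1.5` —
#' i.e. markedly higher in naive-derived TSC than in either pluripotent
#' state, and markedly lower in both differentiated trophoblast
#' derivatives.
#'
#' @param panel A [value_matrix()] (FPKM) with columns `nTSC`, `hES`,
#'   `pTSC`, `EVT`, `ST`.
#' @param thresholds Numeric `(r1, r2, r3, r4)` log2-ratio cutoffs.
#' @param pseudocount Pseudocount added to every FPKM before the ratio.
#' @return A [gene_set()] named `TSC_markers`; attribute `ratios` holds the
#'   per-gene log2 ratios and the four pass flags.
#' @export
select_tsc_markers <- function(panel,
                               thresholds = c(r1 = 3, r2 = 2.5,
                                              r3 = -1.5, r4 = -1.5),
                               pseudocount = 1) {
  need <- c("nTSC", "hES", "pTSC", "EVT", "ST")
  if (!all(need %in% colnames(panel))) {
    stop("panel must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(length(thresholds) == 4)
  pc <- pseudocount
  m <- unclass(panel)
  l2 <- function(a, b) log2((m[, a] + pc) / (m[, b] + pc))
  r_hes <- l2("nTSC", "hES")
  r_ptsc <- l2("nTSC", "pTSC")
  r_evt <- l2("EVT", "nTSC")
  r_st <- l2("ST", "nTSC")
  keep <- r_hes > thresholds[[1]] & r_ptsc > thresholds[[2]] &
    r_evt < thresholds[[3]] & r_st < thresholds[[4]]
  ratios <- data.frame(gene = rownames(m),
                       log2_nTSC_vs_hES = r_hes,
                       log2_nTSC_vs_pTSC = r_ptsc,
                       log2_EVT_vs_nTSC = r_evt,
                       log2_ST_vs_nTSC = r_st,
                       kept = keep, row.names = NULL)
  out <- gene_set("TSC_markers", rownames(m)[keep])
  attr(out, "ratios") <- ratios
  out
}
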