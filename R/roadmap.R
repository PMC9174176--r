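#' Quality-control filter for single-cell count matrices
#'
#' Applies the per-cell thresholds first — a cell is retained iff all three
#' strict inequalities hold: `nFeature > min_features`,
#' `min_count < nCount < max_count`, and `pctMT < max_pct_mt`, where
#' nFeature is the number of genes with count > 0, nCount the total count,
#' and pctMT the percentage of counts on mitochondrial (`MT-` prefixed)
#' genes. Among the retained cells, genes detected (count >= 1) in fewer
#' than `min_cells_per_gene` cells are then discarded, and ribosomal genes
#' (`RPL`/`RPS` prefixes) are removed from downstream analysis. The order —
#' cells, then genes — is fixed because it changes the result.
#'
#' @param counts A [value_matrix()] of scale COUNT, genes x cells.
#' @param qc Named list of cutoffs; see [pipeline_config()] for the
#'   defaults (2500 / 1000 / 100000 / 10 / 10).
#' @param mt_pattern,ribo_pattern Regexes identifying mitochondrial and
#'   ribosomal gene symbols (standard human prefixes by default).
#' @return List with `counts` (the filtered [value_matrix()]), `cells`
#'   (per-cell data.frame: `nFeature`, `nCount`, `pctMT`, per-criterion
#'   pass flags, overall `pass`), and `genes` (per-gene data.frame over the
#'   input genes: `n_cells_detected` among retained cells, `ribosomal`,
#'   `kept`).
#' @export
qc_filter_cells <- function(counts,
                            qc = list(min_features = 2500,
                                      min_count = 1000,
                                      max_count = 100000,
                                      max_pct_mt = 10,
                                      min_cells_per_gene = 10),
                            mt_pattern = "^MT-",
                            ribo_pattern = "^RP[LS]") {
  m <- unclass(counts)
  if (any(m != floor(m))) stop("counts must be integers", call. = FALSE)
  n_count <- colSums(m)
  n_feature <- colSums(m > 0)
  mt <- grepl(mt_pattern, rownames(m))
  pct_mt <- ifelse(n_count > 0,
                   100 * colSums(m[mt, , drop = FALSE]) / n_count, 0)
  pass_feature <- n_feature > qc$min_features
  pass_count <- n_count > qc$min_count & n_count < qc$max_count
  pass_mt <- pct_mt < qc$max_pct_mt
  pass <- pass_feature & pass_count & pass_mt
  cells <- data.frame(cell_id = colnames(m), nFeature = n_feature,
                      nCount = n_count, pctMT = pct_mt,
                      pass_feature = pass_feature, pass_count = pass_count,
                      pass_mt = pass_mt, pass = pass, row.names = NULL)
  kept_cells <- m[, pass, drop = FALSE]
  n_det <- rowSums(kept_cells >= 1)
  ribo <- grepl(ribo_pattern, rownames(m))
  keep_gene <- n_det >= qc$min_cells_per_gene & !ribo
  genes <- data.frame(gene_id = rownames(m), n_cells_detected = n_det,
                      ribosomal = ribo, kept = keep_gene, row.names = NULL)
  kept <- kept_cells[keep_gene, , drop = FALSE]
  # zero-row/column subsets lose dimnames; restore them explicitly
  dimnames(kept) <- list(rownames(m)[keep_gene], colnames(m)[pass])
  list(counts = value_matrix(kept, "COUNT"),
       cells = cells, genes = genes)
}

#' Assign cells to lineages from signature scores
#'
#' Each cell receives the label of its highest-scoring lineage signature
#' (naive / primed / TE / PrE when scored with the default marker sets).
#' A cell whose top two scores are exactly tied, or whose winning margin
#' (best minus second-best) is below `min_margin`, is left `unassigned`.
#'
#' @param scores Numeric matrix, cells x lineages; column names are the
#'   lineage labels.
#' @param min_margin Minimum winning margin (default 0: only exact ties
#'   are unassigned).
#' @return data.frame with `cell_id`, `label` (factor over the lineages
#'   plus `unassigned`) and `margin`.
#' @export
assign_lineage <- function(scores, min_margin = 0) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stop("need >= 2 lineage score columns",
                             call. = FALSE)
  if (anyNA(scores)) stop("missing scores", call. = FALSE)
  labs <- colnames(scores)
  best_i <- max.col(scores, ties.method = "first")
  best <- scores[cbind(seq_len(nrow(scores)), best_i)]
  second <- apply(scores, 1, function(x) sort(x, decreasing = TRUE)[2])
  margin <- best - second
  label <- labs[best_i]
  label[margin == 0 | margin < min_margin] <- "unassigned"
  data.frame(cell_id = rownames(scores),
             label = factor(label, levels = c(labs, "unassigned")),
             margin = margin, row.names = NULL)
}

#' Per-stage lineage proportions
#'
#' Tabulates, for each transition stage, the proportion of its cells
#' carrying each lineage label (including `unassigned`). Rows sum to 1.
#' This is the cell-fate tracking underlying the observation that the
#' naive-like fraction climbs along the transition and dominates the
#' endpoint.
#'
#' @param assignment data.frame from [assign_lineage()].
#' @param stages Either a [stage_map()] or a named character vector
#'   `cell_id -> stage`; every cell must be staged.
#' @param stage_order Optional explicit stage order (taken from the stage
#'   map when given one).
#' @param drop_unassigned If `TRUE`, unassigned cells are removed and the
#'   remaining proportions renormalized.
#' @return Numeric matrix stages x labels; every row sums to 1.
#' @export
lineage_proportions <- function(assignment, stages, stage_order = NULL,
                                drop_unassigned = FALSE) {
  if (inherits(stages, "stage_map")) {
    stage_order <- stages$stages
    stages <- stages$assignment
  }
  missing <- setdiff(assignment$cell_id, names(stages))
  if (length(missing)) {
    stop("cell(s) with no stage: ", paste(utils::head(missing, 3),
                                          collapse = ", "), call. = FALSE)
  }
  st <- stages[assignment$cell_id]
  if (is.null(stage_order)) stage_order <- unique(st)
  lab <- assignment$label
  if (drop_unassigned) {
    keep <- lab != "unassigned"
    st <- st[keep]
    lab <- droplevels(lab[keep])
  }
  tab <- table(factor(st, levels = stage_order), lab)
  totals <- rowSums(tab)
  if (any(totals == 0)) {
    stop("stage(s) with no cells: ",
         paste(stage_order[totals == 0], collapse = ", "), call. = FALSE)
  }
  props <- sweep(unclass(tab), 1, totals, "/")
  dimnames(props) <- list(stage = stage_order, label = colnames(tab))
  props
}
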