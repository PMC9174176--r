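#' Run the full synthetic roadmap pipeline
#'
#' Wires every stage end-to-end on seeded synthetic data: accessibility
#' simulation, background shuffling, empirical-FDR threshold calibration,
#' replicate merging, binarization and dynamics classification; bulk
#' signature simulation, min-max scoring and temporal clustering; marker
#' panel simulation and log-ratio selection; single-cell simulation, QC,
#' module scoring, lineage assignment and per-stage proportions. All
#' tabular outputs are written under `out_dir` and summarised in a JSON
#' manifest with MD5 digests, so identical seed and configuration
#' reproduce identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; defaults to `config$rng_seed`.
#' @param n_regions,n_cells,n_genes_bulk Problem sizes for the synthetic
#'   stages.
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json` when jsonlite is available).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = ".",
                         seed = config$rng_seed, n_regions = 2000,
                         n_cells = 1000, n_genes_bulk = 2000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  stages <- c("pESC", "day6", "day8", "day10", "nESC")
  smap <- stage_map(stages, stats::setNames(
    rep(stages, each = 2), paste0(rep(stages, each = 2), "_rep", 1:2)))

  # -- chromatin accessibility dynamics ---------------------------------
  gm <- genome_model(paste0("chr", 1:4), rep(3e6, 4))
  cad <- simulate_cad_dataset(
    gm, n_regions,
    c(CO = 0.25, OC = 0.25, PO = 0.25, PC = 0.25),
    smap, seed = seed)
  bg_regions <- shuffle_background(cad$regions, gm, seed = seed + 1)
  thr <- calibrate_open_threshold(cad$peaks, cad$background,
                                  alpha = config$fdr_alpha)
  merged <- merge_replicates(cad$peaks, smap)
  calls <- binarize_accessibility(merged, thr)
  labels <- classify_dynamics(calls)
  write_bed_regions(cad$regions, p("peaks.bed"))
  write_bed_regions(bg_regions, p("background.bed"))
  utils::write.table(
    data.frame(region_id = names(labels), label = as.character(labels),
               truth = as.character(cad$truth$labels[names(labels)])),
    p("cad_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  # -- bulk signatures and temporal clustering --------------------------
  sig_genes <- sprintf("gene_%05d", 1:40)
  signatures <- list(
    naive = list(genes = sig_genes[1:20],
                 effect = stats::setNames(c(1, 1, 2, 4, 8), stages)),
    primed = list(genes = sig_genes[21:40],
                  effect = stats::setNames(c(8, 4, 2, 1, 1), stages)))
  bulk <- simulate_bulk_signatures(n_genes_bulk, 2, stages, signatures,
                                   seed = seed + 2)
  sets <- lapply(names(signatures), function(nm)
    gene_set(nm, signatures[[nm]]$genes))
  scores <- bulk_signature_score(bulk$fpkm, sets,
                                 tau = config$expression_floor)
  utils::write.table(
    data.frame(sample_id = rownames(scores), scores, check.names = FALSE),
    p("signature_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  expressed <- filter_expressed_genes(bulk$fpkm, config$expression_floor)
  clust <- cluster_temporal_profiles(merge_replicates(expressed,
                                                      bulk$stage_map),
                                     k = config$kmeans_k, seed = seed + 3)
  utils::write.table(
    data.frame(gene_id = names(clust$cluster), cluster = clust$cluster),
    p("temporal_clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # -- TSC marker selection ---------------------------------------------
  mp <- simulate_marker_panel(50, 10, thresholds = config$marker_thresholds,
                              pseudocount = config$pseudocount,
                              seed = seed + 4)
  markers <- select_tsc_markers(mp$panel,
                                thresholds = config$marker_thresholds,
                                pseudocount = config$pseudocount)
  write_gmt_genesets(list(markers), p("tsc_markers.gmt"))

  # -- single-cell roadmap ----------------------------------------------
  msets <- default_lineage_markers()
  sc <- simulate_cell_matrix(
    n_cells, 4000,
    c(naive = 0.93, primed = 0.03, TE = 0.02, PrE = 0.02),
    msets, seed = seed + 5)
  qc <- qc_filter_cells(sc$counts, qc = config$qc)
  sc_scores <- vapply(msets, function(s)
    cell_module_score(qc$counts, s, seed = seed + 6),
    numeric(ncol(qc$counts)))
  assignment <- assign_lineage(sc_scores)
  cell_stage <- stats::setNames(rep("nESC", nrow(assignment)),
                                assignment$cell_id)
  props <- lineage_proportions(assignment, cell_stage,
                               stage_order = "nESC")
  utils::write.table(
    data.frame(stage = rownames(props), props, check.names = FALSE),
    p("lineage_proportions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  outputs <- c("peaks.bed", "background.bed", "cad_labels.tsv",
               "signature_scores.tsv", "temporal_clusters.tsv",
               "tsc_markers.gmt", "lineage_proportions.tsv")
  manifest <- list(
    version = as.character(utils::packageVersion("pluroadmap")),
    seed = seed,
    config = unclass(config),
    threshold = list(t_star = thr$t_star, efdr = thr$efdr_at_t,
                     alpha = thr$alpha),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(manifest)
}
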