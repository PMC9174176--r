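#' Deterministic largest-remainder allocation
#'
#' Splits `n` items over categories so that counts match the target
#' proportions exactly up to integer rounding: each category gets
#' `floor(n * p)` and remaining items go to the largest fractional parts
#' (ties broken by category order). Used by every generator so that planted
#' class sizes are exact rather than multinomial draws.
#'
#' @param n Total number of items.
#' @param proportions Named numeric vector summing to 1 (tolerance 1e-9).
#' @return Named integer vector of counts summing to `n`.
#' @export
allocate_counts <- function(n, proportions) {
  if (is.null(names(proportions))) {
    stop("proportions must be named", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", sum(proportions), ")",
         call. = FALSE)
  }
  if (any(proportions < 0)) stop("negative proportion", call. = FALSE)
  quota <- n * proportions
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- quota - counts
    take <- order(-frac, seq_along(frac))[seq_len(rem)]
    counts[take] <- counts[take] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

#' Simulate a staged accessibility dataset with planted dynamics
#'
#' Generates a peak set tiled over the genome, a region-by-sample RPKM-scale
#' peak matrix, and a size-matched background matrix, with each region
#' planted as one of the four accessibility dynamics classes: CO
#' (closed-to-open), OC (open-to-closed), PO (permanently open), PC
#' (permanently closed). Background and closed-state entries are drawn from
#' an exponential null `Exp(lambda_bg)`; open-state entries from a normal
#' `N(mu_open, sigma_open)` truncated at zero. CO/OC regions switch state at
#' one planted stage (uniform over stages 2..S). Label counts follow
#' [allocate_counts()], so planted proportions are exact.
#'
#' The default separation (`mu_open = 50`, `lambda_bg = 1`) puts the open
#' mean at roughly ten times the background 99th percentile, emulating the
#' clear bimodality that an empirical-FDR threshold exploits on real
#' ATAC-seq peak-vs-background matrices.
#'
#' @param genome A [genome_model()].
#' @param n_regions Number of peak regions.
#' @param label_proportions Named proportions over `CO`, `OC`, `PO`, `PC`
#'   summing to 1.
#' @param stages A [stage_map()]; its samples become matrix columns.
#' @param mu_open,sigma_open Mean and sd of the open-state RPKM signal.
#' @param lambda_bg Rate of the exponential background distribution.
#' @param region_length Peak width in bp.
#' @param noiseless If `TRUE`, open entries are exactly `mu_open` and
#'   closed/background entries exactly `mu_open / 100`: a fully separable
#'   construction for exact-recovery tests.
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return List with `regions` ([region_set()]), `peaks` and `background`
#'   ([value_matrix()] RPKM), and `truth` (planted labels, switch stages,
#'   distribution parameters).
#' @export
simulate_cad_dataset <- function(genome, n_regions, label_proportions,
                                 stages, mu_open = 50, sigma_open = 5,
                                 lambda_bg = 1, region_length = 500,
                                 noiseless = FALSE, seed = 1L) {
  stopifnot(inherits(stages, "stage_map"), n_regions >= 1)
  classes <- c("CO", "OC", "PO", "PC")
  props <- stats::setNames(rep(0, 4), classes)
  unknown <- setdiff(names(label_proportions), classes)
  if (length(unknown)) {
    stop("unknown dynamics class: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  props[names(label_proportions)] <- label_proportions
  counts <- allocate_counts(n_regions, props)

  # tile peaks along the genome, leaving 3x-length gaps for backgrounds
  pitch <- 4 * region_length
  per_chrom <- pmax(floor((unclass(genome) - region_length) / pitch), 0)
  if (sum(per_chrom) < n_regions) {
    stop("genome too small to tile ", n_regions, " regions of ",
         region_length, " bp", call. = FALSE)
  }
  chrom <- rep(names(genome), per_chrom)[seq_len(n_regions)]
  idx_in_chrom <- sequence(per_chrom)[seq_len(n_regions)]
  start <- (idx_in_chrom - 1) * pitch
  regions <- region_set(chrom, start, start + region_length,
                        id = sprintf("peak_%05d", seq_len(n_regions)),
                        genome = genome)

  samples <- names(stages$assignment)
  stage_of <- stages$assignment[samples]
  stage_idx <- match(stage_of, stages$stages)
  S <- length(stages$stages)
  if (S < 2) stop("need at least 2 stages", call. = FALSE)

  withr::with_seed(seed, {
    labels <- rep(classes, counts)
    labels <- sample(labels)  # interleave classes across the tiling
    switch_stage <- rep(NA_integer_, n_regions)
    dyn <- labels %in% c("CO", "OC")
    switch_stage[dyn] <- sample(2:S, sum(dyn), replace = TRUE)

    # open[i, s] = TRUE if region i is in the open state at stage s
    open_at <- matrix(FALSE, n_regions, S)
    open_at[labels == "PO", ] <- TRUE
    for (i in which(dyn)) {
      if (labels[i] == "CO") {
        open_at[i, switch_stage[i]:S] <- TRUE
      } else {
        open_at[i, seq_len(switch_stage[i] - 1)] <- TRUE
      }
    }

    open_entry <- open_at[, stage_idx, drop = FALSE]
    n_entries <- n_regions * length(samples)
    if (noiseless) {
      vals <- matrix(mu_open / 100, n_regions, length(samples))
      vals[open_entry] <- mu_open
      bg <- matrix(mu_open / 100, n_regions, length(samples))
    } else {
      vals <- matrix(stats::rexp(n_entries, rate = lambda_bg),
                     n_regions, length(samples))
      n_open <- sum(open_entry)
      vals[open_entry] <- pmax(
        stats::rnorm(n_open, mean = mu_open, sd = sigma_open), 0)
      bg <- matrix(stats::rexp(n_entries, rate = lambda_bg),
                   n_regions, length(samples))
    }
    dimnames(vals) <- list(regions$id, samples)
    dimnames(bg) <- list(sprintf("bg_%05d", seq_len(n_regions)), samples)

    truth <- list(
      labels = stats::setNames(factor(labels, levels = c(classes, "COMPLEX")),
                               regions$id),
      switch_stage = stats::setNames(switch_stage, regions$id),
      mu_open = mu_open, sigma_open = sigma_open, lambda_bg = lambda_bg,
      noiseless = noiseless, stages = stages
    )
    list(regions = regions,
         peaks = value_matrix(vals, "RPKM"),
         background = value_matrix(bg, "RPKM"),
         truth = truth)
  })
}

#' Simulate a bulk FPKM matrix with planted stage-wise signature effects
#'
#' Baseline expression is log-normal, `FPKM = exp(N(baseline_meanlog,
#' baseline_sdlog))`, drawn independently per gene and sample. Genes that
#' belong to a planted signature are multiplied by that signature's effect
#' for the sample's stage, emulating signatures that switch on along the
#' primed-to-naive transition.
#'
#' @param n_genes Size of the simulated gene universe (ids `gene_<n>`).
#' @param samples_per_stage Replicates per stage (samples named
#'   `<stage>_rep<j>`).
#' @param stages Character vector of stage names in temporal order.
#' @param signatures Named list; each element is
#'   `list(genes = <ids within the universe>, effect = <named multiplier per
#'   stage, all >= 1>)`.
#' @param baseline_meanlog,baseline_sdlog Log-scale baseline parameters.
#' @param seed Integer seed.
#' @return List with `fpkm` ([value_matrix()] FPKM), `stage_map`
#'   ([stage_map()]) and `truth` (the signature definitions and baseline
#'   parameters).
#' @export
simulate_bulk_signatures <- function(n_genes, samples_per_stage, stages,
                                     signatures,
                                     baseline_meanlog = log(10),
                                     baseline_sdlog = 1, seed = 1L) {
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  for (nm in names(signatures)) {
    sg <- signatures[[nm]]
    if (!all(sg$genes %in% genes)) {
      stop("signature '", nm, "' references genes outside the universe",
           call. = FALSE)
    }
    if (!all(stages %in% names(sg$effect))) {
      stop("signature '", nm, "' lacks an effect for every stage",
           call. = FALSE)
    }
    if (any(sg$effect < 1)) {
      stop("effect multipliers must be >= 1", call. = FALSE)
    }
  }
  samples <- as.vector(t(outer(stages, seq_len(samples_per_stage),
                               function(s, j) paste0(s, "_rep", j))))
  stage_of <- rep(stages, each = samples_per_stage)

  withr::with_seed(seed, {
    vals <- matrix(exp(stats::rnorm(n_genes * length(samples),
                                    baseline_meanlog, baseline_sdlog)),
                   n_genes, length(samples),
                   dimnames = list(genes, samples))
    for (nm in names(signatures)) {
      sg <- signatures[[nm]]
      eff <- sg$effect[stage_of]
      vals[sg$genes, ] <- vals[sg$genes, , drop = FALSE] *
        rep(eff, each = length(sg$genes))
    }
    list(fpkm = value_matrix(vals, "FPKM"),
         stage_map = stage_map(stages,
                               stats::setNames(stage_of, samples)),
         truth = list(signatures = signatures,
                      baseline_meanlog = baseline_meanlog,
                      baseline_sdlog = baseline_sdlog))
  })
}

#' Simulate a five-condition trophoblast marker panel
#'
#' Builds an FPKM panel over conditions `nTSC`, `hES`, `pTSC`, `EVT`, `ST`
#' in which planted true markers satisfy all four selection log2-ratios
#' (see [select_tsc_markers()]) with a margin of at least `margin` log2
#' units, and every non-marker violates at least one of the four by at
#' least the same margin. Exact recovery by the filter is therefore
#' guaranteed by construction.
#'
#' @param n_genes Total genes in the panel.
#' @param n_true_markers Number of planted markers (`<= n_genes`).
#' @param margin Construction margin in log2 units.
#' @param thresholds,pseudocount Selection constants; defaults match
#'   [pipeline_config()].
#' @param seed Integer seed.
#' @return List with `panel` ([value_matrix()] FPKM, columns
#'   nTSC/hES/pTSC/EVT/ST) and `truth` (character vector of marker ids).
#' @export
simulate_marker_panel <- function(n_genes, n_true_markers, margin = 0.5,
                                  thresholds = c(r1 = 3, r2 = 2.5,
                                                 r3 = -1.5, r4 = -1.5),
                                  pseudocount = 1, seed = 1L) {
  stopifnot(n_true_markers <= n_genes, n_true_markers >= 0, margin > 0)
  r1 <- thresholds[[1]]; r2 <- thresholds[[2]]
  r3 <- thresholds[[3]]; r4 <- thresholds[[4]]
  pc <- pseudocount
  genes <- sprintf("gene_%04d", seq_len(n_genes))

  withr::with_seed(seed, {
    marker_idx <- if (n_true_markers > 0) {
      sort(sample.int(n_genes, n_true_markers))
    } else integer(0)
    is_marker <- seq_len(n_genes) %in% marker_idx

    ntsc <- stats::runif(n_genes, 100, 500)
    # values satisfying each condition with the margin
    pass_hes <- function(n) stats::runif(length(n), 0,
                                         pmax((n + pc) / 2^(r1 + margin) - pc, 0))
    pass_ptsc <- function(n) stats::runif(length(n), 0,
                                          pmax((n + pc) / 2^(r2 + margin) - pc, 0))
    pass_low <- function(n, r) stats::runif(length(n), 0,
                                            pmax((n + pc) * 2^(r - margin) - pc, 0))
    # values violating each condition with the margin
    fail_hes <- function(n) (n + pc) / 2^(r1 - margin) - pc +
      stats::runif(length(n), 0, n)
    fail_ptsc <- function(n) (n + pc) / 2^(r2 - margin) - pc +
      stats::runif(length(n), 0, n)
    fail_low <- function(n, r) (n + pc) * 2^(r + margin) - pc +
      stats::runif(length(n), 0, n)

    hes <- pass_hes(ntsc)
    ptsc <- pass_ptsc(ntsc)
    evt <- pass_low(ntsc, r3)
    st <- pass_low(ntsc, r4)

    nm <- which(!is_marker)
    if (length(nm)) {
      # each non-marker violates >= 1 condition, chosen at random
      broken <- sample.int(4, length(nm), replace = TRUE)
      hes[nm[broken == 1]] <- fail_hes(ntsc[nm[broken == 1]])
      ptsc[nm[broken == 2]] <- fail_ptsc(ntsc[nm[broken == 2]])
      evt[nm[broken == 3]] <- fail_low(ntsc[nm[broken == 3]], r3)
      st[nm[broken == 4]] <- fail_low(ntsc[nm[broken == 4]], r4)
    }

    panel <- cbind(nTSC = ntsc, hES = hes, pTSC = ptsc, EVT = evt, ST = st)
    rownames(panel) <- genes
    list(panel = value_matrix(panel, "FPKM"),
         truth = genes[is_marker])
  })
}

#' Simulate a single-cell count matrix with planted lineages
#'
#' Generates a genes-by-cells negative-binomial count matrix in which each
#' cell carries one planted lineage label (naive, primed, TE, PrE by
#' default); the cell's lineage marker genes are elevated by a
#' multiplicative factor. The gene universe contains the supplied marker
#' sets, `MT-` prefixed mitochondrial genes, `RPL`/`RPS` prefixed ribosomal
#' genes, optional planted rare genes (count 1 in fewer than ten cells, so
#' the detection filter removes them), and background genes. A planted
#' fraction of cells fails quality control: half by a collapsed library
#' (low nFeature and nCount) and half by an inflated mitochondrial
#' fraction.
#'
#' Lineage and QC-failure counts use [allocate_counts()], so planted
#' proportions are exact. Defaults (`base_mu = 3`, `nb_size = 2`,
#' `n_genes >= 4000`) put healthy cells far inside the QC acceptance region
#' (around 3400 detected genes, around 13,000 counts, around 3\% pctMT).
#'
#' @param n_cells,n_genes Matrix dimensions (`n_genes` must cover markers,
#'   mito, ribo and rare genes).
#' @param lineage_proportions Named proportions over the marker-set names,
#'   summing to 1.
#' @param marker_sets Named list of [gene_set()], one per lineage, pairwise
#'   disjoint.
#' @param elevation Multiplicative elevation of a cell's own lineage
#'   markers (> 1).
#' @param base_mu Mean expression of a background gene in a library-factor-1
#'   cell.
#' @param nb_size Negative-binomial size (inverse dispersion).
#' @param libsize_sdlog Log-normal sd of the per-cell library factor.
#' @param mito_factor Expression multiplier of mitochondrial genes
#'   (healthy cells).
#' @param ribo_factor Expression multiplier of ribosomal genes.
#' @param frac_fail_qc Planted fraction of QC-failing cells.
#' @param n_mt,n_ribo,n_rare Counts of mitochondrial / ribosomal / planted
#'   rare genes.
#' @param seed Integer seed.
#' @return List with `counts` ([value_matrix()] COUNT, genes x cells) and
#'   `truth` (per-cell lineage labels, QC-failure flags and modes, rare
#'   gene ids, parameters).
#' @export
simulate_cell_matrix <- function(n_cells, n_genes, lineage_proportions,
                                 marker_sets, elevation = 8,
                                 base_mu = 3, nb_size = 2,
                                 libsize_sdlog = 0.2,
                                 mito_factor = 12, ribo_factor = 4,
                                 frac_fail_qc = 0.05,
                                 n_mt = 10, n_ribo = 20, n_rare = 5,
                                 seed = 1L) {
  lineages <- names(marker_sets)
  if (is.null(lineages) || !setequal(names(lineage_proportions), lineages)) {
    stop("lineage_proportions names must match marker_sets names",
         call. = FALSE)
  }
  marker_genes <- lapply(marker_sets, `[[`, "genes")
  all_markers <- unlist(marker_genes, use.names = FALSE)
  if (anyDuplicated(all_markers)) {
    stop("marker sets must be pairwise disjoint", call. = FALSE)
  }
  n_special <- length(all_markers) + n_mt + n_ribo + n_rare
  if (n_genes < n_special) {
    stop("n_genes too small for markers + MT + ribosomal + rare genes",
         call. = FALSE)
  }
  mt_genes <- sprintf("MT-G%02d", seq_len(n_mt))
  ribo_genes <- c(sprintf("RPL%02d", seq_len(ceiling(n_ribo / 2))),
                  sprintf("RPS%02d", seq_len(floor(n_ribo / 2))))
  rare_genes <- if (n_rare > 0) sprintf("RARE%02d", seq_len(n_rare)) else
    character(0)
  bg_genes <- sprintf("gene_%05d",
                      seq_len(n_genes - n_special))
  genes <- c(all_markers, mt_genes, ribo_genes, rare_genes, bg_genes)

  withr::with_seed(seed, {
    lin_counts <- allocate_counts(n_cells, lineage_proportions[lineages])
    lineage <- sample(rep(lineages, lin_counts))
    cells <- sprintf("cell_%05d", seq_len(n_cells))

    n_fail <- round(frac_fail_qc * n_cells)
    fail_idx <- if (n_fail > 0) sample.int(n_cells, n_fail) else integer(0)
    fail_mode <- rep("pass", n_cells)
    if (n_fail > 0) {
      modes <- rep(c("low_library", "high_mito"), length.out = n_fail)
      fail_mode[fail_idx] <- modes
    }

    lib <- exp(stats::rnorm(n_cells, 0, libsize_sdlog))
    lib[fail_mode == "low_library"] <- lib[fail_mode == "low_library"] * 0.03

    base <- rep(base_mu, length(genes))
    names(base) <- genes
    base[mt_genes] <- base_mu * mito_factor
    base[ribo_genes] <- base_mu * ribo_factor
    base[rare_genes] <- 0  # filled deterministically below

    # genes x cells expected counts
    mu <- outer(base, lib)
    mito_boost <- which(fail_mode == "high_mito")
    if (length(mito_boost)) {
      mu[mt_genes, mito_boost] <- mu[mt_genes, mito_boost] * 20
    }
    for (ln in lineages) {
      idx <- which(lineage == ln)
      mu[marker_genes[[ln]], idx] <-
        mu[marker_genes[[ln]], idx, drop = FALSE] * elevation
    }
    counts <- matrix(stats::rnbinom(length(mu), size = nb_size,
                                    mu = as.vector(mu)),
                     nrow = length(genes),
                     dimnames = list(genes, cells))
    # rare genes: a single read in < min_cells_per_gene healthy cells
    healthy <- which(fail_mode == "pass")
    for (g in rare_genes) {
      hit <- healthy[sample.int(length(healthy), min(5, length(healthy)))]
      counts[g, hit] <- 1L
    }
    storage.mode(counts) <- "double"
    list(counts = value_matrix(counts, "COUNT"),
         truth = list(
           lineage = stats::setNames(lineage, cells),
           fail_qc = stats::setNames(fail_mode != "pass", cells),
           fail_mode = stats::setNames(fail_mode, cells),
           rare_genes = rare_genes,
           marker_sets = marker_sets,
           params = list(elevation = elevation, base_mu = base_mu,
                         nb_size = nb_size, frac_fail_qc = frac_fail_qc)))
  })
}

#' Default synthetic lineage marker sets
#'
#' Small disjoint marker sets for the four blastocyst-stage identities
#' tracked during the primed-to-naive transition, for use with
#' [simulate_cell_matrix()] and [cell_module_score()].
#'
#' @param n_per_set Markers per lineage.
#' @return Named list of [gene_set()]: `naive`, `primed`, `TE`, `PrE`.
#' @export
default_lineage_markers <- function(n_per_set = 25) {
  lin <- c("naive", "primed", "TE", "PrE")
  stats::setNames(lapply(lin, function(l) {
    gene_set(l, sprintf("%s_M%02d", toupper(l), seq_len(n_per_set)))
  }), lin)
}

#' Simulate genes following planted temporal expression patterns
#'
#' Generates an FPKM matrix whose genes follow six canonical stage
#' trajectories — monotone up, monotone down, early transient peak, late
#' transient peak, U-shaped, and inverted-U — with independent Gaussian
#' jitter on the log2 scale. The shapes are deterministic and pairwise
#' distinct after per-gene z-scoring, so temporal clustering at k = 6 has
#' a well-defined planted partition to recover.
#'
#' @param genes_per_pattern Genes generated per pattern.
#' @param stages Character vector of stage names (>= 3 stages; shapes are
#'   interpolated to the stage count).
#' @param noise_sd Jitter sd in log2 units.
#' @param amplitude Peak-to-trough pattern amplitude in log2 units.
#' @param baseline_log2 Log2 expression the patterns oscillate around.
#' @param seed Integer seed.
#' @return List with `fpkm` ([value_matrix()]) and `labels` (planted
#'   pattern index per gene, 1..6).
#' @export
simulate_temporal_patterns <- function(genes_per_pattern = 50,
                                       stages = c("pESC", "day6", "day8",
                                                  "day10", "nESC"),
                                       noise_sd = 0.1, amplitude = 4,
                                       baseline_log2 = 4, seed = 1L) {
  S <- length(stages)
  if (S < 3) stop("need >= 3 stages", call. = FALSE)
  shapes <- rbind(
    up = c(-1, -0.5, 0, 0.5, 1),
    down = c(1, 0.5, 0, -0.5, -1),
    early_peak = c(-1, 1, 0, -0.5, -1),
    late_peak = c(-1, -0.5, 0, 1, -1),
    u = c(1, -0.5, -1, -0.5, 1),
    inverted_u = c(-1, 0.5, 1, 0.5, -1))
  shapes <- t(apply(shapes, 1, function(v) {
    stats::approx(seq(0, 1, length.out = 5), v,
                  xout = seq(0, 1, length.out = S))$y
  }))
  lab <- rep(seq_len(nrow(shapes)), each = genes_per_pattern)
  withr::with_seed(seed, {
    log2m <- baseline_log2 + (amplitude / 2) * shapes[lab, , drop = FALSE] +
      matrix(stats::rnorm(length(lab) * S, sd = noise_sd), length(lab), S)
    m <- 2^log2m
    dimnames(m) <- list(sprintf("g%04d", seq_along(lab)), stages)
    list(fpkm = value_matrix(m, "FPKM"), labels = lab)
  })
}
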