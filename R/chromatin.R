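#' RPKM-normalize a count matrix over regions
#'
#' `RPKM = count * 1e9 / (region_length_bp * library_size)`: reads per
#' kilobase of region per million mapped reads.
#'
#' @param counts A [value_matrix()] of scale `COUNT`, regions x samples.
#' @param region_lengths Numeric vector of region lengths in bp, named by
#'   region id or in row order; all `> 0`.
#' @param library_sizes Numeric vector of mapped reads per sample, named by
#'   sample id or in column order; all `> 0`.
#' @return A [value_matrix()] of scale `RPKM`.
#' @export
compute_rpkm <- function(counts, region_lengths, library_sizes) {
  if (!is.null(names(region_lengths))) {
    missing <- setdiff(rownames(counts), names(region_lengths))
    if (length(missing)) {
      stop("no region length for: ", missing[1], call. = FALSE)
    }
    region_lengths <- region_lengths[rownames(counts)]
  }
  if (!is.null(names(library_sizes))) {
    missing <- setdiff(colnames(counts), names(library_sizes))
    if (length(missing)) {
      stop("no library size for: ", missing[1], call. = FALSE)
    }
    library_sizes <- library_sizes[colnames(counts)]
  }
  stopifnot(length(region_lengths) == nrow(counts),
            length(library_sizes) == ncol(counts))
  if (any(region_lengths <= 0)) stop("region lengths must be > 0",
                                     call. = FALSE)
  if (any(library_sizes <= 0)) stop("library sizes must be > 0",
                                    call. = FALSE)
  rpkm <- unclass(counts) * 1e9 /
    outer(as.numeric(region_lengths), as.numeric(library_sizes))
  dimnames(rpkm) <- dimnames(counts)
  value_matrix(rpkm, "RPKM")
}

#' Shuffle background regions avoiding the peak set
#'
#' For each peak, places one background region of the same length on the
#' same chromosome, uniformly at random by rejection sampling, with zero
#' overlap with any peak and with previously placed background regions
#' (mirroring an exclusion-list genomic shuffle). Deterministic under
#' `seed`.
#'
#' @param peaks A [region_set()] of peak regions.
#' @param genome A [genome_model()].
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling attempts per region before
#'   erroring.
#' @param same_chrom If `FALSE`, a background may land on any chromosome
#'   long enough (chromosome drawn length-weighted).
#' @return A [region_set()] of background regions, ids `bg_<peak id>`.
#' @export
shuffle_background <- function(peaks, genome, seed = 1L,
                               max_attempts = 1000L, same_chrom = TRUE) {
  glen <- unclass(genome)
  occ_start <- split(peaks$start, peaks$chrom)
  occ_end <- split(peaks$end, peaks$chrom)
  for (ch in names(glen)) {
    if (is.null(occ_start[[ch]])) {
      occ_start[[ch]] <- numeric(0)
      occ_end[[ch]] <- numeric(0)
    }
  }
  n <- nrow(peaks)
  out_chrom <- character(n)
  out_start <- numeric(n)
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      len <- peaks$end[i] - peaks$start[i]
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        ch <- if (same_chrom) peaks$chrom[i] else {
          ok <- names(glen)[glen >= len]
          sample(ok, 1, prob = glen[ok])
        }
        L <- glen[[ch]]
        if (L < len) next
        s <- floor(stats::runif(1, 0, L - len + 1))
        if (s > L - len) s <- L - len  # guard the open upper edge
        e <- s + len
        if (!any(s < occ_end[[ch]] & occ_start[[ch]] < e)) {
          out_chrom[i] <- ch
          out_start[i] <- s
          occ_start[[ch]] <- c(occ_start[[ch]], s)
          occ_end[[ch]] <- c(occ_end[[ch]], e)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place background for region ", peaks$id[i],
             " after ", max_attempts, " attempts", call. = FALSE)
      }
    }
  })
  region_set(out_chrom, out_start,
             out_start + (peaks$end - peaks$start),
             id = paste0("bg_", peaks$id), genome = genome)
}

#' Calibrate the open/closed RPKM threshold by empirical FDR
#'
#' Pools all entries of the peak matrix and of the size-matched background
#' matrix and computes, for every candidate threshold `t` (the sorted
#' distinct observed values across both matrices), the empirical false
#' discovery rate
#' \deqn{eFDR(t) = \frac{\#\{bg \ge t\} \cdot N_{peak}/N_{bg}}{\#\{peak \ge t\}}}
#' i.e. background exceedances rescaled to the peak-matrix size, divided by
#' peak exceedances. The calibrated threshold is the smallest candidate
#' with at least one peak exceedance and `eFDR <= alpha`. Because eFDR is a
#' step function changing only at observed values, restricting candidates
#' to observed values is lossless.
#'
#' On the staged ATAC-seq matrices this procedure models, the analogous
#' genome-wide calibration at a 1\% FDR yields an RPKM threshold in the
#' low tens; everything downstream (open/closed calls, dynamics classes)
#' keys off this single value.
#'
#' @param peak_matrix,background_matrix [value_matrix()] objects (RPKM).
#' @param alpha Target FDR level in (0,1).
#' @return Object of class `open_threshold`: list with `t_star`, `alpha`,
#'   `efdr_at_t`, `n_peak_entries`, `n_background_entries`.
#' @export
calibrate_open_threshold <- function(peak_matrix, background_matrix,
                                     alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  pk <- as.vector(unclass(peak_matrix))
  bg <- as.vector(unclass(background_matrix))
  if (!length(pk) || !length(bg)) {
    stop("both matrices must be nonempty", call. = FALSE)
  }
  cand <- sort(unique(c(pk, bg)))
  sp <- sort(pk)
  sb <- sort(bg)
  np <- length(pk)
  nb <- length(bg)
  # number of entries >= t, via count of entries strictly below t
  n_peak_ge <- np - findInterval(cand, sp, left.open = TRUE)
  n_bg_ge <- nb - findInterval(cand, sb, left.open = TRUE)
  efdr <- ifelse(n_peak_ge > 0,
                 (n_bg_ge * np / nb) / n_peak_ge, Inf)
  ok <- which(n_peak_ge > 0 & efdr <= alpha)
  if (!length(ok)) {
    stop("no threshold achieves eFDR <= ", alpha,
         "; peak and background distributions overlap too much ",
         "(increase alpha or signal separation)", call. = FALSE)
  }
  i <- ok[1]
  structure(list(t_star = cand[i], alpha = alpha, efdr_at_t = efdr[i],
                 n_peak_entries = np, n_background_entries = nb),
            class = "open_threshold")
}

#' @export
print.open_threshold <- function(x, ...) {
  cat(sprintf(
    "open/closed threshold: %.4g RPKM (eFDR %.4g at alpha %.3g; %d peak / %d background entries)\n",
    x$t_star, x$efdr_at_t, x$alpha, x$n_peak_entries,
    x$n_background_entries))
  invisible(x)
}

#' Merge replicate columns into one column per stage
#'
#' Per-stage value is the arithmetic mean of the stage's replicate columns,
#' a matrix-level analogue of pooling replicate alignments before
#' quantification. Column order follows the stage map's temporal order.
#'
#' @param matrix A [value_matrix()].
#' @param stages A [stage_map()] assigning every column of `matrix`.
#' @return A [value_matrix()] with one column per stage.
#' @export
merge_replicates <- function(matrix, stages) {
  stopifnot(inherits(stages, "stage_map"))
  missing <- setdiff(colnames(matrix), names(stages$assignment))
  if (length(missing)) {
    stop("sample(s) with no stage assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ghost <- setdiff(names(stages$assignment), colnames(matrix))
  if (length(ghost)) {
    stop("assigned sample(s) absent from matrix: ",
         paste(ghost, collapse = ", "), call. = FALSE)
  }
  m <- unclass(matrix)
  out <- vapply(stages$stages, function(st) {
    cols <- names(stages$assignment)[stages$assignment == st]
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m))  # vapply drops dim for 1-row input
  dimnames(out) <- list(rownames(m), stages$stages)
  value_matrix(out, vm_scale(matrix))
}

#' Binarize a stage matrix into open/closed calls
#'
#' A locus is called open at a stage iff its (stage-merged) RPKM value is
#' `>= t_star`; values strictly below the threshold are closed. Equality
#' counts as open: the calibrated threshold is itself an observed value at
#' which the eFDR guarantee holds, so the value attaining it is treated as
#' signal.
#'
#' @param stage_matrix A [value_matrix()], regions x stages.
#' @param threshold An `open_threshold` from [calibrate_open_threshold()],
#'   or a single numeric RPKM cutoff.
#' @return Logical matrix (`TRUE` = open) with the input dimnames.
#' @export
binarize_accessibility <- function(stage_matrix, threshold) {
  t_star <- if (inherits(threshold, "open_threshold")) threshold$t_star
            else as.numeric(threshold)
  stopifnot(is.finite(t_star))
  calls <- unclass(stage_matrix) >= t_star
  dimnames(calls) <- dimnames(stage_matrix)
  calls
}

#' Classify per-region accessibility dynamics
#'
#' Given open/closed calls over temporally ordered stages, each region is
#' assigned one dynamics class: `PO` (open at every stage), `PC` (closed at
#' every stage), `CO` (exactly one closed-to-open switch: closed at the
#' first stage, open at the last), `OC` (exactly one open-to-closed
#' switch), or `COMPLEX` for every other pattern (multiple switches).
#' Reversing the stage order exchanges CO and OC and fixes the other
#' classes.
#'
#' @param calls Logical region-by-stage matrix from
#'   [binarize_accessibility()]; columns in temporal order; `>= 2` stages.
#' @return Factor of labels (`CO`, `OC`, `PO`, `PC`, `COMPLEX`) named by
#'   region id.
#' @export
classify_dynamics <- function(calls) {
  if (ncol(calls) < 2) stop("need >= 2 stages", call. = FALSE)
  S <- ncol(calls)
  n_open <- rowSums(calls)
  n_switch <- rowSums(calls[, -1, drop = FALSE] !=
                        calls[, -S, drop = FALSE])
  first_open <- calls[, 1]
  lab <- rep("COMPLEX", nrow(calls))
  lab[n_open == S] <- "PO"
  lab[n_open == 0] <- "PC"
  lab[n_switch == 1 & !first_open] <- "CO"
  lab[n_switch == 1 & first_open] <- "OC"
  stats::setNames(factor(lab, levels = c("CO", "OC", "PO", "PC", "COMPLEX")),
                  rownames(calls))
}

#' Assign peak regions to gene promoter windows
#'
#' The promoter window of a gene is `[TSS - w, TSS + w)` in 0-based
#' half-open coordinates (always covering at least the TSS base itself, so
#' `w = 0` degenerates to the single TSS position), clipped at the
#' chromosome start. A region is assigned to every gene whose window it
#' overlaps. The TSS position supplied for a minus-strand gene must be the
#' annotated transcript end coordinate. Overlap is computed with IRanges.
#'
#' @param regions A [region_set()].
#' @param tss_table data.frame with columns `gene`, `chrom`, `tss`
#'   (0-based position), `strand` (`"+"`/`"-"`).
#' @param w Window half-width in bp (default 3000, i.e. TSS +/- 3 kb).
#' @return Named list: `region id -> character vector of overlapping
#'   genes` (empty vectors for unassigned regions); attribute `w` records
#'   the half-width.
#' @export
assign_promoters <- function(regions, tss_table, w = 3000) {
  stopifnot(all(c("gene", "chrom", "tss", "strand") %in% names(tss_table)),
            w >= 0)
  win_start <- pmax(tss_table$tss - w, 0)
  win_end <- pmax(tss_table$tss + w, tss_table$tss + 1)
  out <- stats::setNames(vector("list", nrow(regions)), regions$id)
  for (i in seq_along(out)) out[[i]] <- character(0)
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    gi <- which(tss_table$chrom == ch)
    if (!length(gi)) next
    # 0-based half-open -> 1-based closed for IRanges
    rr <- IRanges::IRanges(start = regions$start[ri] + 1,
                           end = regions$end[ri])
    gw <- IRanges::IRanges(start = win_start[gi] + 1, end = win_end[gi])
    hits <- IRanges::findOverlaps(rr, gw)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      for (j in seq_along(qh)) {
        id <- regions$id[ri[qh[j]]]
        out[[id]] <- c(out[[id]], tss_table$gene[gi[sh[j]]])
      }
    }
  }
  attr(out, "w") <- w
  out
}
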