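#' Construct a genome model
#'
#' A genome model is the ordered set of chromosomes with their lengths, used
#' to validate region coordinates and to bound background shuffling. All
#' coordinates in this package follow the BED convention: 0-based, half-open
#' `[start, end)`.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Integer vector of chromosome lengths in bp (positive).
#' @return An object of class `genome_model`: a named numeric vector of
#'   chromosome lengths, ordered as given.
#' @examples
#' gm <- genome_model(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_model <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) {
    stop("chrom and length must have equal length", call. = FALSE)
  }
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome names: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive and finite", call. = FALSE)
  }
  structure(stats::setNames(length, chrom), class = "genome_model")
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a tab-delimited file with columns chromosome name and
#'   length (no header), the layout produced by `samtools faidx` /
#'   UCSC `fetchChromSizes`.
#' @return A [genome_model()].
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric"),
                          col.names = c("chrom", "length"))
  genome_model(df$chrom, df$length)
}

#' Construct a region set
#'
#' @param chrom,start,end Region coordinates (BED convention, 0-based
#'   half-open).
#' @param id Region identifiers; unique. Defaults to `region_<n>`.
#' @param genome Optional [genome_model()]; when supplied, chromosomes and
#'   bounds are validated against it.
#' @return A `data.frame` of class `region_set` with columns
#'   `chrom`, `start`, `end`, `id`.
#' @export
region_set <- function(chrom, start, end, id = NULL, genome = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(chrom)
  if (is.null(id)) id <- paste0("region_", seq_len(n))
  id <- as.character(id)
  stopifnot(length(start) == n, length(end) == n, length(id) == n)
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop("invalid interval (need 0 <= start < end) for region ",
         id[bad[1]], ": [", start[bad[1]], ", ", end[bad[1]], ")",
         call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("duplicate region ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(genome)) {
    unknown <- setdiff(chrom, names(genome))
    if (length(unknown)) {
      stop("chromosome(s) not in genome: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    oob <- which(end > unclass(genome)[chrom])
    if (length(oob)) {
      stop("region ", id[oob[1]], " exceeds length of ", chrom[oob[1]],
           call. = FALSE)
    }
  }
  structure(
    data.frame(chrom = chrom, start = start, end = end, id = id,
               stringsAsFactors = FALSE),
    class = c("region_set", "data.frame")
  )
}

#' Read regions from a BED file
#'
#' Accepts BED3 or wider; column 4, when present, supplies region ids,
#' otherwise ids `region_<n>` are generated. Coordinates are validated
#' against the genome; errors report the offending line.
#'
#' @param path Path to a BED file (tab-delimited, no header).
#' @param genome A [genome_model()].
#' @return A [region_set()].
#' @export
read_bed_regions <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty BED file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("BED line ", which(nf < 3)[1], " has fewer than 3 fields",
         call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric coordinate at BED line ",
         which(is.na(start) | is.na(end))[1], call. = FALSE)
  }
  id <- if (all(nf >= 4)) vapply(fields, `[[`, "", 4L) else NULL
  out <- try(region_set(chrom, start, end, id, genome = genome),
             silent = TRUE)
  if (inherits(out, "try-error")) {
    # re-validate line by line so the error names a line number
    for (i in seq_along(chrom)) {
      res <- try(region_set(chrom[i], start[i], end[i],
                            if (is.null(id)) NULL else id[i],
                            genome = genome), silent = TRUE)
      if (inherits(res, "try-error")) {
        stop("BED line ", i, ": ",
             conditionMessage(attr(res, "condition")), call. = FALSE)
      }
    }
    stop(conditionMessage(attr(out, "condition")), call. = FALSE)
  }
  out
}

#' Write a region set to BED4
#'
#' @param regions A [region_set()].
#' @param path Output path.
#' @export
write_bed_regions <- function(regions, path) {
  utils::write.table(
    data.frame(regions$chrom, format(regions$start, scientific = FALSE,
                                     trim = TRUE),
               format(regions$end, scientific = FALSE, trim = TRUE),
               regions$id),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.valid_scales <- c("RPKM", "FPKM", "COUNT")

#' Construct a value matrix
#'
#' The central quantification container: a nonnegative numeric matrix with
#' features (peaks or genes) as rows and samples (or cells) as columns, plus
#' a tag recording the scale of the values.
#'
#' @param values Numeric matrix with unique rownames (feature ids) and
#'   unique colnames (sample ids); all entries finite and `>= 0`.
#' @param scale One of `"RPKM"`, `"FPKM"`, `"COUNT"`.
#' @return The matrix with attribute `scale` set and class `value_matrix`
#'   prepended.
#' @export
value_matrix <- function(values, scale = c("RPKM", "FPKM", "COUNT")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("value matrix requires feature rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature id: ",
         rownames(values)[duplicated(rownames(values))][1], call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1], call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("value matrix contains missing or non-finite entries", call. = FALSE)
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative value at feature ", rownames(values)[bad[1]],
         ", sample ", colnames(values)[bad[2]], call. = FALSE)
  }
  structure(values, scale = scale,
            class = c("value_matrix", class(values)))
}

#' Scale tag of a value matrix
#' @param x A [value_matrix()].
#' @return `"RPKM"`, `"FPKM"`, or `"COUNT"` (`NA` if untagged).
#' @export
vm_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) NA_character_ else s
}

#' Read a features-by-samples TSV matrix
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' Duplicate ids, non-numeric cells and negative values are rejected with an
#' error naming the offending row or column.
#'
#' @param path Path to a tab-delimited matrix.
#' @param scale Scale tag for the values; see [value_matrix()].
#' @return A [value_matrix()].
#' @export
read_value_matrix <- function(path, scale = c("RPKM", "FPKM", "COUNT")) {
  scale <- match.arg(scale)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "")
  if (ncol(df) < 2) stop("matrix file has no sample columns: ", path,
                         call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate feature id in ", path, ": ",
         ids[duplicated(ids)][1], call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at feature ", ids[bad[1]], ", sample ",
         colnames(vals)[bad[2]], call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(vals))
  value_matrix(num, scale)
}

#' Write a value matrix as TSV
#'
#' Inverse of [read_value_matrix()]: feature ids in the first column
#' (header `feature_id`), sample ids as the remaining header fields. Values
#' are written with full precision so that a write/read round-trip is exact.
#'
#' @param x A [value_matrix()] (or plain named matrix).
#' @param path Output path.
#' @export
write_value_matrix <- function(x, path) {
  df <- data.frame(feature_id = rownames(x),
                   format(unclass(x), digits = 17, scientific = TRUE,
                          trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a stage map
#'
#' Associates each sample of a matrix with one ordered transition stage
#' (e.g. primed ESC, day 6, day 8, ..., naive ESC). The stage order given
#' here defines the temporal axis used by replicate merging and dynamics
#' classification.
#'
#' @param stages Character vector of stage names in temporal order.
#' @param assignment Named character vector: `sample_id -> stage name`.
#' @return A list of class `stage_map` with elements `stages` and
#'   `assignment`.
#' @export
stage_map <- function(stages, assignment) {
  stages <- as.character(stages)
  if (anyDuplicated(stages)) stop("duplicate stage names", call. = FALSE)
  assignment <- stats::setNames(as.character(assignment), names(assignment))
  if (is.null(names(assignment)) || any(!nzchar(names(assignment)))) {
    stop("assignment must be a named vector sample_id -> stage",
         call. = FALSE)
  }
  unknown <- setdiff(unique(assignment), stages)
  if (length(unknown)) {
    stop("assignment references unknown stage(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  empty <- setdiff(stages, assignment)
  if (length(empty)) {
    stop("stage(s) with no samples: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  structure(list(stages = stages, assignment = assignment),
            class = "stage_map")
}

#' Construct a gene set
#' @param name Signature name.
#' @param genes Character vector of gene symbols; duplicates are dropped.
#' @return A list of class `gene_set` with elements `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) genes <- unique(genes)
  structure(list(name = as.character(name)[1], genes = genes),
            class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated fields
#' `name`, `description`, then gene symbols. Within-line duplicate symbols
#' are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of [gene_set()] objects.
#' @export
read_gmt_genesets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("GMT line ", which(nf < 3)[1],
         " has fewer than 3 fields (name, description, >=1 gene)",
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate symbols in gene set '", f[1], "' dropped",
              call. = FALSE)
    }
    gene_set(f[1], genes)
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#' @param sets List of [gene_set()] objects.
#' @param path Output path.
#' @param description Description field written for every set.
#' @export
write_gmt_genesets <- function(sets, path, description = "na") {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one place. Defaults
#' are the thresholds used throughout the staged primed-to-naive analyses:
#' 1\% empirical FDR for the open/closed RPKM threshold, an FPKM floor of 5
#' for expressed-gene retention, k = 6 temporal clusters, TSS +/- 3 kb
#' promoter windows, the 2000 most variable features, the four trophoblast
#' stem-cell marker log2-ratio thresholds (3, 2.5, -1.5, -1.5, with a +1
#' pseudocount), and the single-cell QC cutoffs (nFeature > 2500,
#' 1000 < nCount < 100000, pctMT < 10, genes detected in >= 10 cells).
#'
#' @param fdr_alpha Empirical FDR level for threshold calibration, in (0,1).
#' @param expression_floor FPKM floor for expressed-gene retention.
#' @param kmeans_k Number of temporal expression clusters.
#' @param promoter_halfwidth Promoter window half-width in bp.
#' @param top_variance_k Number of top-variance features retained.
#' @param marker_thresholds Numeric vector `(r1, r2, r3, r4)` of log2-ratio
#'   cutoffs for marker selection.
#' @param pseudocount Pseudocount added before log2 ratios.
#' @param qc Named list of single-cell QC cutoffs.
#' @param rng_seed Integer seed recorded for reproducibility.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fdr_alpha = 0.01,
                            expression_floor = 5,
                            kmeans_k = 6,
                            promoter_halfwidth = 3000,
                            top_variance_k = 2000,
                            marker_thresholds = c(r1 = 3, r2 = 2.5,
                                                  r3 = -1.5, r4 = -1.5),
                            pseudocount = 1,
                            qc = list(min_features = 2500,
                                      min_count = 1000,
                                      max_count = 100000,
                                      max_pct_mt = 10,
                                      min_cells_per_gene = 10),
                            rng_seed = 1L) {
  stopifnot(is.numeric(fdr_alpha), fdr_alpha > 0, fdr_alpha < 1,
            promoter_halfwidth >= 0, kmeans_k >= 1,
            length(marker_thresholds) == 4,
            all(is.finite(marker_thresholds)))
  structure(list(fdr_alpha = fdr_alpha,
                 expression_floor = expression_floor,
                 kmeans_k = as.integer(kmeans_k),
                 promoter_halfwidth = promoter_halfwidth,
                 top_variance_k = as.integer(top_variance_k),
                 marker_thresholds = marker_thresholds,
                 pseudocount = pseudocount,
                 qc = qc,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields absent from the file keep their [pipeline_config()] defaults.
#'
#' @param path Path to a YAML file mapping configuration fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- utils::modifyList(unclass(defaults), raw)
  do.call(pipeline_config, args)
}
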