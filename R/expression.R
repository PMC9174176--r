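#' Filter to expressed genes
#'
#' Keeps genes with `FPKM >= tau` in at least one sample (the floor is
#' inclusive). Idempotent.
#'
#' @param matrix A [value_matrix()] (FPKM), genes x samples.
#' @param tau Expression floor (default 5 FPKM).
#' @return The filtered [value_matrix()].
#' @export
filter_expressed_genes <- function(matrix, tau = 5) {
  m <- unclass(matrix)
  keep <- apply(m, 1, max) >= tau
  value_matrix(m[keep, , drop = FALSE], vm_scale(matrix))
}

# k-means++ seeding: first center uniform, later centers drawn with
# probability proportional to squared distance from the nearest chosen one
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      idx[j] <- sample.int(n, 1)
    } else {
      idx[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(
      (x - matrix(x[idx[j], ], n, ncol(x), byrow = TRUE))^2))
  }
  x[idx, , drop = FALSE]
}

#' Cluster temporal expression profiles
#'
#' Clusters the *shape* of each gene's trajectory over the stage-ordered
#' samples: expression is transformed to `log2(FPKM + 1)` and z-scored per
#' gene, then partitioned by k-means (k-means++ seeding into Lloyd
#' iterations, `n_init` restarts, best within-cluster sum of squares kept;
#' deterministic under `seed`). Genes constant across samples have no profile shape and are
#' dropped with a warning before clustering. Apply
#' [filter_expressed_genes()] first to restrict to expressed genes.
#'
#' @param matrix A [value_matrix()] (FPKM), genes x samples.
#' @param k Number of clusters (default 6).
#' @param seed Integer seed.
#' @param n_init Random restarts (default 10).
#' @return Object of class `profile_clustering`: list with `cluster` (named
#'   integer vector), `k`, `centers` (k x samples matrix in transformed
#'   space), `transform`, `tot_withinss`, `seed`.
#' @export
cluster_temporal_profiles <- function(matrix, k = 6, seed = 1L,
                                      n_init = 10) {
  m <- log2(unclass(matrix) + 1)
  z <- t(scale(t(m)))
  const <- rowSums(!is.finite(z)) > 0
  if (any(const)) {
    warning(sum(const), " constant gene(s) dropped before clustering",
            call. = FALSE)
    z <- z[!const, , drop = FALSE]
  }
  if (nrow(z) < k) {
    stop("fewer genes (", nrow(z), ") than clusters (", k, ")",
         call. = FALSE)
  }
  km <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      centers <- kmeanspp_centers(z, k)
      # individual Lloyd restarts may hit an empty cluster; only the kept
      # best solution is checked below
      fit <- withCallingHandlers(
        stats::kmeans(z, centers = centers, iter.max = 100,
                      algorithm = "Lloyd"),
        warning = function(w) {
          if (grepl("empty cluster", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) {
        best <- fit
      }
    }
    best
  })
  if (any(km$size == 0)) warning("empty cluster produced", call. = FALSE)
  structure(list(cluster = stats::setNames(km$cluster, rownames(z)),
                 k = k, centers = km$centers,
                 transform = "per-gene z-score of log2(FPKM + 1)",
                 tot_withinss = km$tot.withinss, seed = seed),
            class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(sprintf("temporal profile clustering: %d genes in k = %d clusters (%s)\n",
              length(x$cluster), x$k, x$transform))
  print(table(x$cluster))
  invisible(x)
}

#' Top-variance feature selection
#'
#' Ranks features by the sample variance of `log2(value + 1)` and returns
#' the top `k` ids. Ties are broken by lexicographic feature id so the
#' selection is deterministic.
#'
#' @param matrix A [value_matrix()].
#' @param k Number of features to return (`<=` feature count; default
#'   2000).
#' @return Character vector of `k` feature ids, most variable first.
#' @export
top_variance_features <- function(matrix, k = 2000) {
  if (k > nrow(matrix)) {
    stop("k (", k, ") exceeds feature count (", nrow(matrix), ")",
         call. = FALSE)
  }
  m <- log2(unclass(matrix) + 1)
  v <- apply(m, 1, stats::var)
  ord <- order(-v, rownames(m))
  rownames(m)[ord][seq_len(k)]
}

#' Pairwise sample correlation
#'
#' Pearson correlation between samples over `log2(FPKM + 1)` of the
#' expressed genes (those passing [filter_expressed_genes()] at `tau`).
#'
#' @param matrix A [value_matrix()] (FPKM).
#' @param tau Expression floor applied before correlating.
#' @return Symmetric samples x samples correlation matrix with unit
#'   diagonal.
#' @export
sample_correlation <- function(matrix, tau = 5) {
  f <- filter_expressed_genes(matrix, tau)
  if (nrow(f) < 2) {
    stop("fewer than 2 genes pass the expression floor", call. = FALSE)
  }
  stats::cor(log2(unclass(f) + 1))
}
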