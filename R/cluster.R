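#' PCA / UMAP embedding of filtered cells
#'
#' Embeds the cells of a scaled, log1p-transformed count matrix (the
#' QC/embedding branch), typically restricted beforehand to the peaks the
#' differential z-score selected. The matrix is reduced to `n_components`
#' principal components, a `n_neighbors`-nearest-neighbour graph is built and
#' a 2-D UMAP is computed. Coordinates are for visualisation only; the
#' numeric contract of this function is determinism for a fixed seed.
#'
#' @param x A [binned_counts] object, scaled and log1p-transformed.
#' @param selected_peaks Optional character vector of peak ids to restrict
#'   the feature space to (columns of other peaks are dropped).
#' @param n_components Number of principal components (default 10).
#' @param n_neighbors Neighbourhood size (default 25); must be < number of
#'   cells.
#' @param seed Integer seed; required.
#' @return Tibble `barcode`, `condition`, `umap1`, `umap2`.
#' @export
embed_cells <- function(x, selected_peaks = NULL, n_components = 10L,
                        n_neighbors = 25L, seed) {
  stopifnot(inherits(x, "binned_counts"))
  if (missing(seed)) abort("embed_cells: an explicit seed is required")
  if (!x$scaled || !x$log_transformed) {
    abort("embed_cells expects scaled, log1p-transformed counts")
  }
  m <- x$counts
  if (!is.null(selected_peaks)) {
    keep <- x$peak_ids %in% selected_peaks
    if (!any(keep)) abort("embed_cells: no selected peak is present in the matrix")
    cols <- rep(keep, each = x$n_bins)
    m <- m[, cols, drop = FALSE]
  }
  n <- nrow(m)
  if (n < n_neighbors + 1) {
    abort(sprintf("embed_cells: %d cells but n_neighbors = %d (need n_neighbors + 1 cells)",
                  n, n_neighbors))
  }
  n_components <- min(n_components, n - 1L, ncol(m))
  pcs <- prcomp(as.matrix(m), center = TRUE, scale. = FALSE,
                rank. = n_components)$x
  set.seed(seed)
  coords <- uwot::umap(pcs, n_neighbors = n_neighbors, n_threads = 1,
                       n_sgd_threads = 1, batch = TRUE)
  tibble(barcode = x$cell_ids, condition = x$condition,
         umap1 = coords[, 1], umap2 = coords[, 2])
}

#' Jaccard index of two id sets
#'
#' `|A intersect B| / |A union B|`; two empty sets give 0 by convention
#' (with a warning, since the ratio is undefined).
#'
#' @param set_a,set_b Vectors of ids (duplicates ignored).
#' @return Fraction in `[0, 1]`.
#' @export
jaccard_index <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0) {
    warn("jaccard_index: both sets empty; returning 0 by convention")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Cluster stability by subsampled re-clustering
#'
#' Scores each cluster of a full-data clustering against re-clusterings of
#' subsamples (the standard recipe: 20 subsamples of 80% of the cells drawn
#' without replacement, re-clustered each time). For every original cluster
#' and every run, the cluster is restricted to the subsampled cells and the
#' best-match Jaccard index against the run's clusters is taken; the
#' per-cluster median across runs must exceed `threshold` (strictly) for the
#' cluster to be called stable. Matching is by best Jaccard independently
#' per original cluster, so the report is invariant to cluster-label
#' renaming. A cluster with no member sampled in a run scores 0 for that
#' run.
#'
#' Clustering itself is injected: each run supplies its own cell-to-cluster
#' map (any community-detection method).
#'
#' @param full_labels Tibble `barcode`, `cluster`: the full-data clustering.
#' @param subsample_runs List of tibbles `barcode`, `cluster`, one per run;
#'   each run's barcodes must be a subset of `full_labels$barcode`.
#' @param threshold Stability cutoff on the median Jaccard (default 0.75,
#'   strict).
#' @return Tibble `cluster`, `median_jaccard`, `stable`, plus the list
#'   column `jaccard_values` (one value per run).
#' @export
cluster_stability <- function(full_labels, subsample_runs, threshold = 0.75) {
  stopifnot(all(c("barcode", "cluster") %in% names(full_labels)),
            is.list(subsample_runs), length(subsample_runs) > 0)
  for (run in subsample_runs) {
    if (nrow(run) == 0) abort("cluster_stability: empty subsample run")
    extra <- setdiff(run$barcode, full_labels$barcode)
    if (length(extra) > 0) {
      abort(sprintf("cluster_stability: subsample cell '%s' not in the full set",
                    extra[1]))
    }
  }
  clusters <- sort(unique(full_labels$cluster))
  per_cluster <- lapply(clusters, function(cl) {
    members <- full_labels$barcode[full_labels$cluster == cl]
    vapply(subsample_runs, function(run) {
      kept <- intersect(members, run$barcode)
      if (length(kept) == 0) return(0)
      best <- 0
      for (rc in unique(run$cluster)) {
        j <- jaccard_index(kept, run$barcode[run$cluster == rc])
        if (j > best) best <- j
      }
      best
    }, 0)
  })
  med <- vapply(per_cluster, median, 0)
  tibble(cluster = clusters,
         median_jaccard = med,
         stable = med > threshold,
         jaccard_values = per_cluster)
}
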