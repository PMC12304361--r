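#' Binned per-cell count matrices
#'
#' A `binned_counts` object holds the cells x (peak, bin) count matrix for
#' one condition: a sparse non-negative matrix whose rows are cells and whose
#' columns are the `n_peaks * n_bins` (peak, bin) features in peak-major
#' order, together with the cell barcodes, peak ids, bin count, and flags
#' recording whether per-cell scaling and the log(x + 1) transform have been
#' applied.
#'
#' @param counts Sparse (or dense, coerced) numeric matrix, cells x features.
#' @param cell_ids Character vector of barcodes (row names).
#' @param peak_ids Character vector of peak ids.
#' @param n_bins Bins per peak window.
#' @param condition Condition label.
#' @param scaled,log_transformed Processing flags.
#' @return A `binned_counts` object.
#' @name binned_counts
#' @export
new_binned_counts <- function(counts, cell_ids, peak_ids, n_bins,
                              condition = NA_character_,
                              scaled = FALSE, log_transformed = FALSE) {
  counts <- as(counts, "CsparseMatrix")
  if (!is(counts, "dsparseMatrix")) counts <- as(counts, "dsparseMatrix")
  counts <- as(counts, "generalMatrix")
  n_bins <- as.integer(n_bins)
  stopifnot(nrow(counts) == length(cell_ids),
            ncol(counts) == length(peak_ids) * n_bins,
            !anyDuplicated(cell_ids), !anyDuplicated(peak_ids))
  if (length(counts@x) > 0 && min(counts@x) < 0) {
    abort("binned_counts: negative counts are not allowed")
  }
  rownames(counts) <- cell_ids
  structure(
    list(counts = counts, cell_ids = as.character(cell_ids),
         peak_ids = as.character(peak_ids), n_bins = n_bins,
         condition = as.character(condition),
         scaled = isTRUE(scaled), log_transformed = isTRUE(log_transformed)),
    class = "binned_counts")
}

#' @export
dim.binned_counts <- function(x) dim(x$counts)

#' @method print binned_counts
#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf(
    "<binned_counts> %d cells x %d peaks x %d bins (condition: %s)%s%s\n",
    nrow(x$counts), length(x$peak_ids), x$n_bins, x$condition,
    if (x$scaled) ", scaled" else "",
    if (x$log_transformed) ", log1p" else ""))
  invisible(x)
}

#' Per-cell total counts and non-zero peak numbers
#'
#' @param x A [binned_counts] object.
#' @return A tibble with `barcode`, `total` (reads in windows) and
#'   `nonzero_peaks` (peaks with at least one count in the cell).
#' @export
cell_totals <- function(x) {
  stopifnot(inherits(x, "binned_counts"))
  per_peak <- peak_cell_sums(x)
  tibble(barcode = x$cell_ids,
         total = unname(Matrix::rowSums(x$counts)),
         nonzero_peaks = unname(Matrix::rowSums(per_peak > 0)))
}

#' Per-cell, per-peak read sums
#'
#' Collapses the bin axis: returns the sparse cells x peaks matrix of reads
#' per cell per peak window. The peak test statistic depends on the data
#' only through this matrix, which makes it the natural input for
#' permutation-based checks.
#'
#' @param x A [binned_counts] object.
#' @return A sparse matrix, cells x peaks.
#' @export
peak_cell_sums <- function(x) {
  np <- length(x$peak_ids)
  agg <- sparseMatrix(
    i = seq_len(ncol(x$counts)),
    j = rep(seq_len(np), each = x$n_bins),
    x = 1, dims = c(ncol(x$counts), np))
  out <- x$counts %*% agg
  colnames(out) <- x$peak_ids
  out
}

#' Build per-condition binned count matrices from fragments
#'
#' Accumulates [assign_fragments()] weights into one [binned_counts] matrix
#' per condition in the design, with identical column ordering across
#' conditions. Fragments whose barcode is absent from the design are dropped
#' and reported. Cells present in the design but without any in-window
#' fragment appear as all-zero rows.
#'
#' @param fragments Fragment tibble, or a path to a fragments TSV (processed
#'   in chunks without loading the whole file).
#' @param windows A `peak_windows` object.
#' @param design Design tibble (`barcode`, `condition`) with exactly the
#'   cells to keep.
#' @param mode Fragment assignment mode, see [assign_fragments()].
#' @return A list with `matrices` (named list of [binned_counts], one per
#'   condition), `qc` (a [cell_qc_report()] tibble) and `n_unknown_barcode`
#'   (fragment records dropped for barcodes not in the design).
#' @export
build_matrix <- function(fragments, windows, design,
                         mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  validate_design(design)
  nb <- attr(windows, "n_bins")
  peak_ids <- windows$peak
  ncol_total <- length(peak_ids) * nb
  col_of <- setNames(seq_along(peak_ids), peak_ids)
  row_of <- setNames(seq_len(nrow(design)), design$barcode)

  trip <- list(); n_unknown <- 0L
  take <- function(chunk) {
    known <- chunk$barcode %in% design$barcode
    n_unknown <<- n_unknown + sum(!known)
    hits <- assign_fragments(chunk[known, , drop = FALSE], windows, mode = mode)
    if (nrow(hits) > 0) {
      trip[[length(trip) + 1L]] <<- tibble(
        i = unname(row_of[hits$barcode]),
        j = (unname(col_of[hits$peak]) - 1L) * nb + hits$bin + 1L,
        x = hits$weight)
    }
    invisible(NULL)
  }
  if (is.character(fragments) && length(fragments) == 1) {
    read_fragments_chunked(fragments, take)
  } else {
    take(fragments)
  }
  if (n_unknown > 0) {
    warn(sprintf("%d fragment record(s) with barcodes absent from the design were dropped",
                 n_unknown))
  }
  trip <- if (length(trip) > 0) dplyr::bind_rows(trip) else
    tibble(i = integer(), j = integer(), x = double())
  full <- sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                       dims = c(nrow(design), ncol_total))

  conditions <- unique(design$condition)
  mats <- lapply(conditions, function(cond) {
    rows <- which(design$condition == cond)
    new_binned_counts(full[rows, , drop = FALSE],
                      cell_ids = design$barcode[rows],
                      peak_ids = peak_ids, n_bins = nb, condition = cond)
  })
  names(mats) <- conditions
  list(matrices = mats,
       qc = dplyr::bind_rows(lapply(mats, cell_qc_report)),
       n_unknown_barcode = n_unknown)
}

#' Per-cell QC report
#'
#' @param x A [binned_counts] object.
#' @param min_reads Read-count threshold used for the `passed_read_filter`
#'   flag (strictly greater than; default 250).
#' @param lower,upper Quantile-filter fractions for the
#'   `passed_quantile_filter` flag (defaults 0.15 and 0.05).
#' @return Tibble: `barcode`, `condition`, `total_reads_in_windows`,
#'   `nonzero_peaks`, `passed_read_filter`, `passed_quantile_filter`.
#' @export
cell_qc_report <- function(x, min_reads = 250, lower = 0.15, upper = 0.05) {
  ct <- cell_totals(x)
  q <- nonzero_quantile_bounds(ct$nonzero_peaks, lower, upper)
  tibble(barcode = ct$barcode, condition = x$condition,
         total_reads_in_windows = ct$total,
         nonzero_peaks = as.integer(ct$nonzero_peaks),
         passed_read_filter = ct$total > min_reads,
         passed_quantile_filter =
           ct$nonzero_peaks >= q[1] & ct$nonzero_peaks <= q[2])
}

nonzero_quantile_bounds <- function(nz, lower, upper) {
  if (lower < 0 || upper < 0 || lower + upper >= 1) {
    abort(sprintf("quantile filter fractions invalid: lower = %g, upper = %g (need lower + upper < 1)",
                  lower, upper))
  }
  c(quantile(nz, lower, names = FALSE, type = 7),
    quantile(nz, 1 - upper, names = FALSE, type = 7))
}

#' Select cells by total reads in peak windows
#'
#' Retains cells with strictly more than `min_reads` reads falling in peak
#' windows (the default keeps cells with 251+ reads).
#'
#' @param x An unscaled [binned_counts] object.
#' @param min_reads Threshold (strict; default 250).
#' @return The filtered [binned_counts].
#' @export
filter_cells_by_reads <- function(x, min_reads = 250) {
  stopifnot(inherits(x, "binned_counts"))
  if (x$scaled) abort("filter_cells_by_reads expects unscaled counts")
  if (nrow(x$counts) == 0) abort("filter_cells_by_reads: matrix has no cells")
  keep <- Matrix::rowSums(x$counts) > min_reads
  if (!any(keep)) {
    abort(sprintf(
      "no cell exceeds %g reads in windows (max %g); review the threshold",
      min_reads, max(Matrix::rowSums(x$counts))))
  }
  subset_cells(x, which(keep))
}

#' Remove cells in the tails of the non-zero-peak distribution
#'
#' Computes each cell's number of peaks with non-zero counts and removes
#' cells falling strictly below the `lower` quantile or strictly above the
#' `1 - upper` quantile of that distribution (defaults: lower 15% and upper
#' 5% removed; quantiles by linear interpolation, boundary cells kept).
#'
#' @param x A [binned_counts] object.
#' @param lower Fraction removed from the bottom (default 0.15).
#' @param upper Fraction removed from the top (default 0.05).
#' @return The filtered [binned_counts].
#' @export
quantile_filter_cells <- function(x, lower = 0.15, upper = 0.05) {
  stopifnot(inherits(x, "binned_counts"))
  nz <- cell_totals(x)$nonzero_peaks
  q <- nonzero_quantile_bounds(nz, lower, upper)
  subset_cells(x, which(nz >= q[1] & nz <= q[2]))
}

subset_cells <- function(x, rows) {
  new_binned_counts(x$counts[rows, , drop = FALSE],
                    cell_ids = x$cell_ids[rows], peak_ids = x$peak_ids,
                    n_bins = x$n_bins, condition = x$condition,
                    scaled = x$scaled, log_transformed = x$log_transformed)
}

#' Scale each cell's counts to a common total
#'
#' Multiplies every non-empty cell's counts by `target / total`, so each
#' non-empty cell sums to `target` (default 10,000). All-zero cells are left
#' at zero with a warning.
#'
#' @param x An unscaled [binned_counts] object.
#' @param target Per-cell total after scaling (default 10000).
#' @return The scaled [binned_counts] (flag `scaled` set).
#' @export
normalize_total <- function(x, target = 10000) {
  stopifnot(inherits(x, "binned_counts"))
  if (x$scaled) abort("normalize_total: counts are already scaled")
  if (target <= 0) abort("normalize_total: target must be positive")
  tot <- Matrix::rowSums(x$counts)
  if (any(tot == 0)) {
    warn(sprintf("%d all-zero cell(s) left unscaled", sum(tot == 0)))
  }
  f <- ifelse(tot > 0, target / tot, 0)
  scaled <- Diagonal(x = f) %*% x$counts
  new_binned_counts(scaled, x$cell_ids, x$peak_ids, x$n_bins, x$condition,
                    scaled = TRUE, log_transformed = x$log_transformed)
}

#' Natural log(x + 1) transform
#'
#' Elementwise `log(x + 1)`; used on the QC/embedding branch only, never
#' before the differential z-score. Applying it twice is an error.
#'
#' @param x A [binned_counts] object.
#' @return The transformed [binned_counts] (flag `log_transformed` set).
#' @export
log1p_transform <- function(x) {
  stopifnot(inherits(x, "binned_counts"))
  if (x$log_transformed) abort("log1p_transform: already log-transformed")
  m <- x$counts
  m@x <- log1p(m@x)
  new_binned_counts(m, x$cell_ids, x$peak_ids, x$n_bins, x$condition,
                    scaled = x$scaled, log_transformed = TRUE)
}

#' Fraction of reads in peaks (FRiP)
#'
#' Fraction of fragment records overlapping at least one peak, weighted by
#' duplicate count; each fragment counts once no matter how many peaks it
#' hits. Reported per cell and pooled over all cells.
#'
#' @param fragments Fragment tibble.
#' @param peaks Peak tibble.
#' @return A list with `pooled` (scalar in `[0, 1]`) and `per_cell` (tibble:
#'   `barcode`, `total`, `in_peaks`, `frip`).
#' @export
frip <- function(fragments, peaks) {
  if (nrow(fragments) == 0 || sum(fragments$count) == 0) {
    abort("frip: no reads")
  }
  if (nrow(peaks) == 0) {
    hit <- rep(FALSE, nrow(fragments))
  } else {
    fgr <- GenomicRanges::GRanges(
      fragments$chrom, IRanges::IRanges(fragments$start + 1L, fragments$end))
    pgr <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
    hit <- GenomicRanges::countOverlaps(fgr, pgr) > 0
  }
  per_cell <- fragments |>
    mutate(hit = hit) |>
    group_by(.data$barcode) |>
    summarise(total = sum(.data$count),
              in_peaks = sum(.data$count[.data$hit]),
              frip = .data$in_peaks / .data$total, .groups = "drop")
  list(pooled = sum(fragments$count[hit]) / sum(fragments$count),
       per_cell = per_cell)
}
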