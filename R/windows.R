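#' Filter peaks by score
#'
#' Retains peaks whose narrowPeak column-5 score is at least `min_score`
#' (score >= threshold, so the default keeps peaks scoring exactly 1000).
#' Input order is preserved.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `name`, `score`), e.g.
#'   from [read_narrowpeak()].
#' @param min_score Minimum retained score. Default 1000, the threshold used
#'   for high-confidence transcription-factor peak sets. Note some peak
#'   callers cap column 5 at 1000, in which case this retains only
#'   saturated-score peaks; lower it for uncapped scores.
#' @return The filtered peak tibble. Empty output triggers a warning, not an
#'   error.
#' @export
filter_peaks <- function(peaks, min_score = 1000) {
  stopifnot(is.numeric(min_score), length(min_score) == 1)
  out <- dplyr::filter(peaks, .data$score >= min_score)
  if (nrow(out) == 0 && nrow(peaks) > 0) {
    warn(sprintf("no peaks with score >= %g (max observed %g)",
                 min_score, max(peaks$score)))
  }
  out
}

#' Build fixed-size binned analysis windows around peak centres
#'
#' Each retained peak contributes one window of `2 * flank` bp centred on the
#' interval midpoint (`floor((start + end) / 2)`), divided into contiguous
#' bins of `bin_width` bp. Defaults give the standard geometry: +/- 2.5 kb
#' around the centre, 100 bins of 50 b. Every window has the same bin count;
#' peaks whose window would run off the chromosome (start < 0, or past the
#' length in `chrom_sizes` when given) are dropped and reported rather than
#' clamped, because the downstream statistic assumes one fixed bin count.
#'
#' @param peaks Peak tibble.
#' @param flank Half-window size in bp (default 2500).
#' @param bin_width Bin size in bp (default 50); must divide `2 * flank`.
#' @param chrom_sizes Optional named vector of chromosome lengths used to drop
#'   windows crossing the right boundary.
#' @return A `peak_windows` tibble (`peak`, `chrom`, `start`, `end`) with
#'   attributes `n_bins`, `bin_width`, `flank`, and `dropped` (names of peaks
#'   whose windows were discarded).
#' @examples
#' pk <- tibble::tibble(chrom = "chr1", start = 9950L, end = 10050L,
#'                      name = "p1", score = 1000)
#' w <- make_windows(pk)
#' n_bins(w)  # 100
#' @export
make_windows <- function(peaks, flank = 2500L, bin_width = 50L,
                         chrom_sizes = NULL) {
  flank <- as.integer(flank); bin_width <- as.integer(bin_width)
  if (flank <= 0 || bin_width <= 0 || (2L * flank) %% bin_width != 0L) {
    abort(sprintf("bin_width (%d) must be positive and divide 2 * flank (%d)",
                  bin_width, 2L * flank))
  }
  n_bins <- (2L * flank) %/% bin_width
  centre <- (peaks$start + peaks$end) %/% 2L
  win <- tibble(peak = peaks$name, chrom = peaks$chrom,
                start = centre - flank, end = centre + flank)
  keep <- win$start >= 0L
  if (!is.null(chrom_sizes)) {
    len <- unname(chrom_sizes[win$chrom])
    keep <- keep & !is.na(len) & win$end <= len
  }
  dropped <- win$peak[!keep]
  if (length(dropped) > 0) {
    warn(sprintf("dropped %d window(s) crossing a chromosome boundary: %s",
                 length(dropped),
                 paste(head(dropped, 5), collapse = ", ")))
  }
  out <- win[keep, , drop = FALSE]
  structure(out, n_bins = n_bins, bin_width = bin_width, flank = flank,
            dropped = dropped,
            class = c("peak_windows", class(out)))
}

#' @rdname make_windows
#' @param x A `peak_windows` object.
#' @export
n_bins <- function(x) attr(x, "n_bins")

#' Assign fragments to (peak, bin) coordinates
#'
#' Maps each fragment onto the binned windows. In `midpoint` mode (default)
#' the fragment midpoint `floor((start + end) / 2)` is located within each
#' window containing it, contributing its whole duplicate count to exactly
#' one bin per matched window — totals are conserved for non-overlapping
#' windows. In `overlap` mode the fragment contributes its count to every bin
#' its interval intersects, emulating per-bin interval-coverage counting
#' (which multi-counts straddling fragments). Overlapping peak windows each
#' receive the fragment independently.
#'
#' @param fragments Fragment tibble (`chrom`, `start`, `end`, `barcode`,
#'   `count`).
#' @param windows A `peak_windows` object from [make_windows()].
#' @param mode `"midpoint"` or `"overlap"`.
#' @return Tibble with one row per (fragment, window, bin) hit: `barcode`,
#'   `peak`, `bin` (0-based), `weight`. Fragments outside every window
#'   contribute no rows.
#' @export
assign_fragments <- function(fragments, windows,
                             mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(windows, "peak_windows"))
  bw <- attr(windows, "bin_width")
  nb <- attr(windows, "n_bins")
  if (nrow(fragments) == 0 || nrow(windows) == 0) {
    return(tibble(barcode = character(), peak = character(),
                  bin = integer(), weight = double()))
  }
  wgr <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start + 1L, windows$end))
  if (mode == "midpoint") {
    mid <- (fragments$start + fragments$end) %/% 2L
    fgr <- GenomicRanges::GRanges(fragments$chrom,
                                  IRanges::IRanges(mid + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(fgr, wgr)
    fi <- S4Vectors::queryHits(hits); wi <- S4Vectors::subjectHits(hits)
    tibble(barcode = fragments$barcode[fi],
           peak = windows$peak[wi],
           bin = (mid[fi] - windows$start[wi]) %/% bw,
           weight = as.double(fragments$count[fi]))
  } else {
    fgr <- GenomicRanges::GRanges(
      fragments$chrom, IRanges::IRanges(fragments$start + 1L, fragments$end))
    hits <- GenomicRanges::findOverlaps(fgr, wgr)
    fi <- S4Vectors::queryHits(hits); wi <- S4Vectors::subjectHits(hits)
    # clip the fragment to the window, then enumerate covered bins
    lo <- pmax(fragments$start[fi], windows$start[wi])
    hi <- pmin(fragments$end[fi], windows$end[wi])
    b0 <- (lo - windows$start[wi]) %/% bw
    b1 <- (hi - 1L - windows$start[wi]) %/% bw
    nrep <- b1 - b0 + 1L
    idx <- rep.int(seq_along(fi), nrep)
    bin <- sequence(nrep, from = b0, by = 1L)
    stopifnot(all(bin >= 0L), all(bin < nb))
    tibble(barcode = fragments$barcode[fi][idx],
           peak = windows$peak[wi][idx],
           bin = bin,
           weight = as.double(fragments$count[fi][idx]))
  }
}
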