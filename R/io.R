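#' Read a MACS2 narrowPeak / BED6+ peak file
#'
#' Parses a tab-separated peak file (narrowPeak, BED6+4, or any BED6-like file
#' with at least six columns) into a peak tibble. Coordinates follow the BED
#' convention used throughout this package: 0-based starts, half-open ends.
#' Plain-text and gzip-compressed files are both accepted (sniffed by
#' extension).
#'
#' @param path Path to the peak file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   one row per peak, in file order. Peaks named `.` receive auto-generated
#'   names (`peak_00001`, ...). Columns beyond the standard ten narrowPeak
#'   columns are ignored with a warning.
#' @examples
#' p <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t600\tp1\t1000\t.", p)
#' read_narrowpeak(p)
#' @export
read_narrowpeak <- function(path) {
  raw <- read_tsv_lines(path)
  if (nrow(raw) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double()))
  }
  if (ncol(raw) < 6) {
    abort(sprintf("narrowPeak file '%s' has %d column(s); at least 6 required",
                  path, ncol(raw)))
  }
  if (ncol(raw) > 10) {
    warn(sprintf("'%s': ignoring %d column(s) beyond the 10 narrowPeak columns",
                 path, ncol(raw) - 10L))
  }
  start <- parse_coord(raw[[2]], path, "start")
  end   <- parse_coord(raw[[3]], path, "end")
  score <- suppressWarnings(as.numeric(raw[[5]]))
  bad <- which(is.na(score) | score < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s, line %d: score '%s' is not a non-negative number",
                  path, bad[1], raw[[5]][bad[1]]))
  }
  bad <- which(start < 0 | end <= start)
  if (length(bad) > 0) {
    abort(sprintf("%s, line %d: invalid interval [%d, %d) (need 0 <= start < end)",
                  path, bad[1], start[bad[1]], end[bad[1]]))
  }
  name <- as.character(raw[[4]])
  anon <- is.na(name) | name == "."
  if (any(anon)) {
    name[anon] <- sprintf("peak_%05d", which(anon))
  }
  if (anyDuplicated(name)) {
    abort(sprintf("%s: duplicated peak name '%s'", path,
                  name[anyDuplicated(name)]))
  }
  tibble(chrom = as.character(raw[[1]]), start = start, end = end,
         name = name, score = score)
}

#' Read per-cell fragment records
#'
#' Reads a fragments TSV (`chrom`, `start`, `end`, `barcode` and an optional
#' fifth duplicate-multiplicity column) into a tibble. Missing counts default
#' to 1. Fragments need not be coordinate-sorted. Gzip-compressed files are
#' accepted.
#'
#' @param path Path to the fragments file.
#' @return A tibble with columns `chrom`, `start`, `end`, `barcode`, `count`.
#' @seealso [read_fragments_chunked()] for streaming over large files.
#' @export
read_fragments <- function(path) {
  raw <- read_tsv_lines(path)
  parse_fragment_chunk(raw, path, offset = 0L)
}

#' Stream fragment records in chunks
#'
#' Iterates over a fragments file without loading it whole, invoking
#' `callback(chunk)` on each parsed tibble of fragments. Yields the same
#' multiset of records as [read_fragments()].
#'
#' @param path Path to the fragments file.
#' @param callback Function of one argument, called with each chunk tibble.
#' @param chunk_size Number of lines per chunk.
#' @return Invisibly, the total number of fragment records streamed.
#' @export
read_fragments_chunked <- function(path, callback, chunk_size = 100000L) {
  total <- 0L
  cb <- function(x, pos) {
    chunk <- parse_fragment_chunk(x, path, offset = pos - 1L)
    total <<- total + nrow(chunk)
    callback(chunk)
    invisible(NULL)
  }
  readr::read_tsv_chunked(
    path,
    callback = readr::SideEffectChunkCallback$new(cb),
    chunk_size = chunk_size, col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  invisible(total)
}

#' Read a cell-to-condition design table
#'
#' @param path TSV with columns `barcode` and `condition` (header optional;
#'   detected by whether the first line literally starts with "barcode").
#' @return A tibble with columns `barcode`, `condition`. Barcodes must be
#'   unique and every condition level must contain at least one cell.
#' @export
read_design <- function(path) {
  raw <- read_tsv_lines(path)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    abort(sprintf("design file '%s' needs >= 2 columns (barcode, condition)", path))
  }
  if (raw[[1]][1] == "barcode") raw <- raw[-1, , drop = FALSE]
  out <- tibble(barcode = as.character(raw[[1]]),
                condition = as.character(raw[[2]]))
  validate_design(out)
  out
}

validate_design <- function(design) {
  stopifnot(all(c("barcode", "condition") %in% names(design)))
  if (anyDuplicated(design$barcode)) {
    abort(sprintf("design: duplicated barcode '%s'",
                  design$barcode[anyDuplicated(design$barcode)]))
  }
  if (nrow(design) == 0 || any(table(design$condition) < 1)) {
    abort("design: every condition needs at least one cell")
  }
  invisible(design)
}

#' Write / read a binned count matrix directory
#'
#' Serialises a [binned_counts] object as a plain-text directory: a
#' MatrixMarket triplet file `matrix.mtx` (rows = cells, columns = (peak, bin)
#' features), `cells.tsv` (barcodes), `features.tsv` (peak id, 0-based bin
#' index) and `meta.tsv` (n_bins, condition, scaled/log flags). The round trip
#' is exact.
#'
#' @param x A [binned_counts] object.
#' @param dir Directory to create/write into.
#' @return `write_binned_counts` returns `dir` invisibly;
#'   `read_binned_counts` returns the reconstructed [binned_counts] object.
#' @export
write_binned_counts <- function(x, dir) {
  stopifnot(inherits(x, "binned_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(x$counts, "generalMatrix"), file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(barcode = x$cell_ids), file.path(dir, "cells.tsv"))
  readr::write_tsv(
    tibble(peak = rep(x$peak_ids, each = x$n_bins),
           bin = rep.int(seq_len(x$n_bins) - 1L, length(x$peak_ids))),
    file.path(dir, "features.tsv")
  )
  readr::write_tsv(
    tibble(key = c("n_bins", "condition", "scaled", "log_transformed"),
           value = c(x$n_bins, x$condition, x$scaled, x$log_transformed)),
    file.path(dir, "meta.tsv")
  )
  invisible(dir)
}

#' @rdname write_binned_counts
#' @export
read_binned_counts <- function(dir) {
  need <- c("matrix.mtx", "cells.tsv", "features.tsv", "meta.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    abort(sprintf("'%s' is not a binned-counts directory: missing %s",
                  dir, paste(missing, collapse = ", ")))
  }
  m <- tryCatch(Matrix::readMM(file.path(dir, "matrix.mtx")),
                error = function(e) abort(sprintf(
                  "malformed triplet file in '%s': %s", dir, conditionMessage(e))))
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"), col_types = "c",
                           progress = FALSE)
  feats <- readr::read_tsv(file.path(dir, "features.tsv"), col_types = "ci",
                           progress = FALSE)
  meta <- readr::read_tsv(file.path(dir, "meta.tsv"), col_types = "cc",
                          progress = FALSE)
  meta <- setNames(meta$value, meta$key)
  n_bins <- as.integer(meta[["n_bins"]])
  if (nrow(cells) != nrow(m) || nrow(feats) != ncol(m)) {
    abort(sprintf(
      "'%s': matrix is %d x %d but cells.tsv has %d rows and features.tsv %d",
      dir, nrow(m), ncol(m), nrow(cells), nrow(feats)))
  }
  peak_ids <- unique(feats$peak)
  if (nrow(feats) != length(peak_ids) * n_bins) {
    abort(sprintf("'%s': features.tsv inconsistent with n_bins = %d", dir, n_bins))
  }
  new_binned_counts(
    counts = as(m, "CsparseMatrix"),
    cell_ids = cells$barcode, peak_ids = peak_ids, n_bins = n_bins,
    condition = meta[["condition"]],
    scaled = as.logical(meta[["scaled"]]),
    log_transformed = as.logical(meta[["log_transformed"]])
  )
}

#' Write a differential occupancy results table
#'
#' Fixed-column TSV: `peak`, `zbar_a`, `zbar_b`, `var_a`, `var_b`, `z`,
#' `pvalue`, `padj`, `selected` (plus `status`).
#'
#' @param results Tibble as returned by [tidy()] on an [occupancy_test] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  cols <- c("peak", "zbar_a", "zbar_b", "var_a", "var_b", "z",
            "pvalue", "padj", "selected", "status")
  missing <- setdiff(cols, names(results))
  if (length(missing) > 0) {
    abort(sprintf("results table missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  readr::write_tsv(results[cols], path)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT file: one set per line — name, description, then member
#'   gene ids, tab-separated.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(sprintf("%s, line %d: GMT lines need name, description and >= 1 gene",
                  path, bad[1]))
  }
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, "", 1L))
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

## -- internal parsing helpers -------------------------------------------------

read_tsv_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  readr::read_tsv(path, col_names = FALSE,
                  col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, comment = "#")
}

parse_coord <- function(x, path, what, offset = 0L) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad) > 0) {
    abort(sprintf("%s, line %d: %s '%s' is not an integer coordinate",
                  path, bad[1] + offset, what, x[bad[1]]))
  }
  as.integer(v)
}

parse_fragment_chunk <- function(raw, path, offset = 0L) {
  if (nrow(raw) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  barcode = character(), count = integer()))
  }
  if (ncol(raw) < 4) {
    abort(sprintf("fragments file '%s' needs >= 4 columns (chrom, start, end, barcode)",
                  path))
  }
  if (ncol(raw) > 5) {
    warn(sprintf("'%s': ignoring %d extra column(s) beyond the 5 known",
                 path, ncol(raw) - 5L))
  }
  start <- parse_coord(raw[[2]], path, "start", offset)
  end   <- parse_coord(raw[[3]], path, "end", offset)
  bad <- which(end <= start)
  if (length(bad) > 0) {
    abort(sprintf("%s, line %d: invalid fragment [%d, %d)", path,
                  bad[1] + offset, start[bad[1]], end[bad[1]]))
  }
  if (ncol(raw) >= 5 && !all(is.na(raw[[5]]))) {
    cnt <- parse_coord(raw[[5]], path, "count", offset)
    bad <- which(cnt <= 0)
    if (length(bad) > 0) {
      abort(sprintf("%s, line %d: fragment count %d must be >= 1", path,
                    bad[1] + offset, cnt[bad[1]]))
    }
  } else {
    cnt <- rep.int(1L, nrow(raw))
  }
  tibble(chrom = as.character(raw[[1]]), start = start, end = end,
         barcode = as.character(raw[[4]]), count = cnt)
}
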