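#' Strand-oriented promoter windows around transcription start sites
#'
#' Builds the promoter interval used to quantify bulk occupancy per gene:
#' `upstream` bp before and `downstream` bp after the TSS in the direction of
#' transcription (defaults 1000 and 250, a 1250 bp window). On the `+`
#' strand the window is `[tss - upstream, tss + downstream)`; on `-` it is
#' mirrored. Windows running past the chromosome start are clamped to 0 with
#' a warning.
#'
#' @param genes Tibble with columns `gene`, `chrom`, `tss` (bp) and `strand`
#'   (`"+"` or `"-"`).
#' @param upstream,downstream Window extents in bp.
#' @return Tibble `gene`, `chrom`, `tss`, `strand`, `start`, `end`.
#' @export
make_tss_windows <- function(genes, upstream = 1000L, downstream = 250L) {
  stopifnot(all(c("gene", "chrom", "tss", "strand") %in% names(genes)))
  bad <- setdiff(unique(genes$strand), c("+", "-"))
  if (length(bad) > 0) {
    abort(sprintf("make_tss_windows: unknown strand symbol '%s'", bad[1]))
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end   <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  if (any(start < 0)) {
    warn(sprintf("%d window(s) clamped at chromosome start", sum(start < 0)))
    start <- pmax(start, 0L)
  }
  tibble(gene = genes$gene, chrom = genes$chrom, tss = genes$tss,
         strand = genes$strand, start = as.integer(start), end = as.integer(end))
}

#' Occupancy ratio and paired t-test for one gene set
#'
#' Compares per-gene promoter occupancy between two conditions over the
#' genes of a set: genes with a zero count in either condition are excluded
#' (no division by zero), per-gene ratios a/b are formed, the mean of the
#' per-gene log2 ratios is reported, and a two-sided paired t-test is run on
#' the per-gene differences. With `on_log = TRUE` the t-test uses the
#' per-gene log2-ratio differences instead of raw count differences.
#'
#' @param counts Tibble with columns `gene`, `count_a`, `count_b` (one row
#'   per quantified gene; non-negative).
#' @param gene_set Character vector of gene ids; ids absent from `counts`
#'   are dropped and counted in `n_genes_missing`.
#' @param orientation `"a_vs_b"` (ratio a/b, default) or `"b_vs_a"`.
#' @param on_log Run the t-test on log2 ratios rather than raw differences.
#' @return One-row tibble: `n_genes_used`, `n_genes_excluded_zero`,
#'   `n_genes_missing`, `mean_log2_ratio`, `t_stat`, `df`, `pvalue`,
#'   `minus_log10_p`. Fewer than two usable genes, or all-zero differences,
#'   give `NA` statistics with the reason in `note`.
#' @examples
#' counts <- tibble::tibble(gene = c("g1", "g2", "g3"),
#'                          count_a = c(10, 20, 30), count_b = c(5, 10, 15))
#' occupancy_ratio_test(counts, counts$gene)
#' @export
occupancy_ratio_test <- function(counts, gene_set,
                                 orientation = c("a_vs_b", "b_vs_a"),
                                 on_log = FALSE) {
  orientation <- match.arg(orientation)
  stopifnot(all(c("gene", "count_a", "count_b") %in% names(counts)))
  rows <- counts[counts$gene %in% gene_set, , drop = FALSE]
  n_missing <- length(setdiff(gene_set, counts$gene))
  a <- rows$count_a; b <- rows$count_b
  if (orientation == "b_vs_a") { tmp <- a; a <- b; b <- tmp }
  nonzero <- a > 0 & b > 0
  n_excl <- sum(!nonzero)
  a <- a[nonzero]; b <- b[nonzero]
  n_used <- length(a)

  base <- tibble(n_genes_used = n_used, n_genes_excluded_zero = n_excl,
                 n_genes_missing = n_missing,
                 mean_log2_ratio = if (n_used > 0) mean(log2(a / b)) else NA_real_,
                 t_stat = NA_real_, df = NA_real_, pvalue = NA_real_,
                 minus_log10_p = NA_real_, note = NA_character_)
  if (n_used < 2) {
    base$note <- "fewer than 2 usable genes"
    return(base)
  }
  d <- if (on_log) log2(a / b) else a - b
  s <- stats::sd(d)
  if (s == 0) {
    base$note <- "zero variance of paired differences"
    return(base)
  }
  t_stat <- mean(d) / (s / sqrt(n_used))
  df <- n_used - 1
  p <- 2 * pt(-abs(t_stat), df = df)
  base$t_stat <- t_stat; base$df <- df; base$pvalue <- p
  base$minus_log10_p <- -log10(p)
  base
}

#' Occupancy ratios across many gene sets
#'
#' Applies [occupancy_ratio_test()] to every set of a named list (e.g. from
#' [read_gmt()]), returning one row per (factor, pathway) suitable for the
#' bubble-matrix display (colour = log2 ratio, size = -log10 p). P-values
#' are deliberately not multiplicity-corrected, matching the convention for
#' modest-size curated gene sets.
#'
#' @param counts Per-gene count tibble, see [occupancy_ratio_test()].
#' @param gene_sets Named list of gene-id vectors.
#' @param factor_id Label for the profiled factor (recycled into the output).
#' @inheritParams occupancy_ratio_test
#' @return Tibble with `factor`, `pathway` and the per-set test columns.
#' @export
pathway_occupancy <- function(counts, gene_sets, factor_id = "TF",
                              orientation = c("a_vs_b", "b_vs_a"),
                              on_log = FALSE) {
  orientation <- match.arg(orientation)
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  purrr::imap(gene_sets, function(set, nm) {
    res <- occupancy_ratio_test(counts, set, orientation, on_log)
    dplyr::bind_cols(tibble(factor = factor_id, pathway = nm), res)
  }) |>
    dplyr::bind_rows()
}

#' GSEA pre-ranking score
#'
#' Ranks transcripts for pre-ranked gene-set enrichment by
#' `log2fc * (-log10(padj))`, carrying the sign of the fold change so the
#' score captures both magnitude and significance of differential
#' expression.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param padj Adjusted p-values in `(0, 1]`; an exact zero is an error
#'   (infinite score) — floor p-values upstream.
#' @return Numeric score vector.
#' @export
gsea_rank_score <- function(log2fc, padj) {
  if (any(is.na(padj)) || any(padj <= 0) || any(padj > 1)) {
    abort("gsea_rank_score: padj must lie in (0, 1]; floor zero p-values first")
  }
  log2fc * (-log10(padj))
}

#' Filter a differential-expression table to significant genes
#'
#' Retains genes with `|log2fc| > 0.5` and `padj < 0.1` (both strict) — the
#' thresholds used for duplicate-level single-nucleus RNA-seq, where the
#' relaxed adjusted-p cut compensates for limited statistical power.
#'
#' @param table Tibble with columns `gene`, `log2fc`, `padj`.
#' @param min_abs_log2fc,max_padj Thresholds (strict inequalities).
#' @return The filtered tibble.
#' @export
de_gene_filter <- function(table, min_abs_log2fc = 0.5, max_padj = 0.1) {
  missing <- setdiff(c("gene", "log2fc", "padj"), names(table))
  if (length(missing) > 0) {
    abort(sprintf("de_gene_filter: missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  dplyr::filter(table, abs(.data$log2fc) > min_abs_log2fc,
                .data$padj < max_padj)
}
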