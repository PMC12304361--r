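#' Log2 bin-averaged, cell-summed peak signal
#'
#' For one peak's cells x bins count block `c`, computes
#' \deqn{\bar z = \log_2\!\Big(\frac{1}{n_b}\sum_{i=1}^{n}\sum_{j=1}^{n_b} c_{ij}\Big),}
#' the log2 of the total signal in the window averaged over its `n_b` bins.
#' A block with zero total has no finite log signal and returns `NA` (callers
#' carry a `zero_total` status).
#'
#' @param c Numeric matrix (cells x bins), non-negative; may be sparse.
#' @return Scalar `zbar`, or `NA_real_` when the block total is zero.
#' @export
peak_mean_log_signal <- function(c) {
  if (length(c) == 0) abort("peak_mean_log_signal: empty count block")
  total <- sum(c)
  if (total < 0) abort("peak_mean_log_signal: negative counts")
  if (total == 0) return(NA_real_)
  log2(total / ncol(c))
}

#' Variance of the log2 peak signal
#'
#' The variance estimate attached to [peak_mean_log_signal()]'s statistic:
#' \deqn{\sigma^2 = \frac{1}{\ln(2)\, n_b}\cdot
#'   \frac{\sum_{k,l=1}^{n_b}\sum_{m=1}^{n} (c_{mk}-\hat\mu_k)(c_{ml}-\hat\mu_l)}
#'        {\sum_{i,j} c_{ij}},}
#' with per-bin cell means \eqn{\hat\mu_j = \frac1n \sum_i c_{ij}}. The
#' numerator sums the full bin-by-bin covariance, so correlated signal across
#' the bins of a window inflates the variance as it should. It collapses
#' algebraically to \eqn{\sum_m (r_m - \bar r)^2} where \eqn{r_m} is cell
#' m's row sum; the implementation uses that O(n) form (the quadratic form
#' with the all-ones vector), which equals the literal double bin sum
#' exactly.
#'
#' `mode = "printed"` (default) is this estimator as stated, with a single
#' `ln 2` factor and the raw block total in the denominator.
#' `mode = "delta"` is the textbook first-order delta-method variance of
#' log2 of the total, \eqn{n\,s_r^2 / (\ln 2\, T)^2} with \eqn{s_r^2} the
#' unbiased variance of the cell row sums — provided for sensitivity
#' analysis, not the default.
#'
#' @param c Numeric matrix (cells x bins), non-negative; may be sparse.
#' @param mode `"printed"` or `"delta"`.
#' @return Scalar `sigma2 >= 0`.
#' @examples
#' peak_log_variance(rbind(c(0, 0), c(2, 2)))  # 1 / ln(2)
#' @export
peak_log_variance <- function(c, mode = c("printed", "delta")) {
  mode <- match.arg(mode)
  total <- sum(c)
  if (total <= 0) abort("peak_log_variance: block total must be positive",
                        class = "occupeak_zero_total")
  r <- if (is(c, "Matrix")) Matrix::rowSums(c) else rowSums(c)
  ssq <- sum((r - mean(r))^2)
  if (mode == "printed") {
    ssq / (log(2) * ncol(c) * total)
  } else {
    n <- length(r)
    if (n < 2) return(0)
    n * (ssq / (n - 1)) / (log(2)^2 * total^2)
  }
}

#' Per-condition peak summary
#'
#' @param c Cells x bins count block for one peak in one condition.
#' @param mode Variance mode, see [peak_log_variance()].
#' @return A list: `zbar`, `var`, `total`, `n_cells`, `bin_means` (per-bin
#'   cell averages) and `status` (`"ok"` or `"zero_total"`).
#' @export
peak_condition_summary <- function(c, mode = c("printed", "delta")) {
  mode <- match.arg(mode)
  total <- sum(c)
  bin_means <- if (is(c, "Matrix")) Matrix::colMeans(c) else colMeans(c)
  if (total == 0) {
    return(list(zbar = NA_real_, var = NA_real_, total = 0,
                n_cells = nrow(c), bin_means = bin_means,
                status = "zero_total"))
  }
  list(zbar = peak_mean_log_signal(c), var = peak_log_variance(c, mode),
       total = total, n_cells = nrow(c), bin_means = bin_means, status = "ok")
}

#' Two-condition peak z-score
#'
#' \deqn{z = \frac{\bar z_A - \bar z_B}{\sqrt{\sigma^2_A + \sigma^2_B}}.}
#' Positive z means higher occupancy in the first (A) condition. When both
#' variances are zero the score is 0 if the means agree and undefined
#' otherwise (status `zero_variance`); zero-total summaries propagate their
#' status.
#'
#' @param summary_a,summary_b Summaries from [peak_condition_summary()].
#' @return A list: `z` and `status` (`ok`, `zero_total_a`, `zero_total_b`,
#'   `zero_variance`).
#' @export
peak_zscore <- function(summary_a, summary_b) {
  if (summary_a$status == "zero_total") {
    return(list(z = NA_real_, status = "zero_total_a"))
  }
  if (summary_b$status == "zero_total") {
    return(list(z = NA_real_, status = "zero_total_b"))
  }
  se2 <- summary_a$var + summary_b$var
  if (se2 == 0) {
    if (summary_a$zbar == summary_b$zbar) {
      return(list(z = 0, status = "zero_variance"))
    }
    return(list(z = NA_real_, status = "zero_variance"))
  }
  list(z = (summary_a$zbar - summary_b$zbar) / sqrt(se2), status = "ok")
}

#' Two-sided normal p-value for a z-score
#'
#' `p = 2 * (1 - Phi(|z|))`, the two-sided standard-normal tail. Undefined
#' (`NA`) scores give `NA` p-values, which downstream adjustment excludes.
#'
#' @param z Numeric vector of z-scores.
#' @return P-values in `(0, 1]`.
#' @export
zscore_pvalues <- function(z) {
  2 * pnorm(-abs(z))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment across peaks (wraps [stats::p.adjust()] with
#' `method = "BH"`). `NA` entries are passed through and do not count
#' towards the number of tests.
#'
#' @param pvalues Numeric vector in `(0, 1]`, `NA` allowed.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Differential peak occupancy test between two conditions
#'
#' For every peak, summarises each condition's cells x bins block (log2
#' bin-averaged cell-summed signal and its variance), forms the z-score of
#' the A - B difference, converts to two-sided normal p-values, adjusts by
#' Benjamini-Hochberg across the peaks with a computable score, and flags
#' peaks with `padj < alpha` as differentially occupied. Peaks with zero
#' total in either condition are reported with an explicit status and
#' excluded from the number of tests.
#'
#' Both matrices must share peak ids, bin count and column ordering, and be
#' at the same processing stage (the standard pipeline scales each cell to a
#' common total first; the log1p transform belongs to the embedding branch
#' and is rejected here).
#'
#' @param matrix_a,matrix_b [binned_counts] for conditions A and B.
#' @param alpha Selection threshold on the adjusted p-value (default 0.001,
#'   strict).
#' @param variance_mode `"printed"` (default) or `"delta"`, see
#'   [peak_log_variance()].
#' @return An `occupancy_test` object; [tidy()] extracts the per-peak
#'   results tibble (`peak`, `zbar_a`, `zbar_b`, `var_a`, `var_b`, `z`,
#'   `pvalue`, `padj`, `selected`, `status`), [glance()] the one-row
#'   summary.
#' @examples
#' a <- toy_binned_counts(rbind(c(0, 0), c(2, 2)), "A")
#' b <- toy_binned_counts(rbind(c(2, 2), c(2, 2)), "B")
#' tidy(run_differential(a, b))
#' @export
run_differential <- function(matrix_a, matrix_b, alpha = 0.001,
                             variance_mode = c("printed", "delta")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(matrix_a, "binned_counts"),
            inherits(matrix_b, "binned_counts"))
  if (!identical(matrix_a$peak_ids, matrix_b$peak_ids) ||
      matrix_a$n_bins != matrix_b$n_bins) {
    abort("run_differential: the two matrices have different (peak, bin) columns")
  }
  if (matrix_a$scaled != matrix_b$scaled) {
    abort("run_differential: one matrix is scaled and the other is not")
  }
  if (matrix_a$log_transformed || matrix_b$log_transformed) {
    abort("run_differential: the z-score operates on (scaled) counts, not log1p values")
  }
  nb <- matrix_a$n_bins
  np <- length(matrix_a$peak_ids)

  stat_one <- function(m) {
    # zbar and the printed variance depend on the block only through the
    # per-cell row sums and the total, so compute them peak-wise in bulk
    r <- peak_cell_sums(m)                       # cells x peaks
    tot <- unname(Matrix::colSums(r))
    n <- nrow(r)
    ssq <- unname(Matrix::colSums(r^2)) - n * (tot / n)^2
    ssq <- pmax(ssq, 0)                          # guard fp round-off
    var <- switch(variance_mode,
      printed = ifelse(tot > 0, ssq / (log(2) * nb * tot), NA_real_),
      delta = if (n < 2) rep(0, np) else
        ifelse(tot > 0, n * (ssq / (n - 1)) / (log(2)^2 * tot^2), NA_real_))
    list(zbar = ifelse(tot > 0, log2(tot / nb), NA_real_), var = var,
         total = tot, n_cells = n)
  }
  a <- stat_one(matrix_a)
  b <- stat_one(matrix_b)

  status <- rep("ok", np)
  status[a$total == 0] <- "zero_total_a"
  status[b$total == 0 & status == "ok"] <- "zero_total_b"
  se2 <- a$var + b$var
  zero_var <- status == "ok" & se2 == 0
  status[zero_var] <- "zero_variance"
  z <- rep(NA_real_, np)
  ok <- status == "ok"
  z[ok] <- (a$zbar[ok] - b$zbar[ok]) / sqrt(se2[ok])
  z[zero_var & a$zbar == b$zbar] <- 0

  pvalue <- rep(NA_real_, np)
  pvalue[ok] <- zscore_pvalues(z[ok])
  padj <- rep(NA_real_, np)
  padj[ok] <- bh_adjust(pvalue[ok])
  selected <- !is.na(padj) & padj < alpha & ok

  results <- tibble(
    peak = matrix_a$peak_ids,
    zbar_a = a$zbar, zbar_b = b$zbar, var_a = a$var, var_b = b$var,
    total_a = a$total, total_b = b$total,
    z = z, pvalue = pvalue, padj = padj,
    selected = selected, status = status)
  structure(
    list(results = results, alpha = alpha, variance_mode = variance_mode,
         n_cells_a = a$n_cells, n_cells_b = b$n_cells,
         condition_a = matrix_a$condition, condition_b = matrix_b$condition,
         n_bins = nb),
    class = "occupancy_test")
}

#' @method print occupancy_test
#' @export
print.occupancy_test <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<occupancy_test> %s vs %s: %d peaks (%d tested), %d selected at padj < %g\n",
    x$condition_a, x$condition_b, g$n_peaks, g$n_tested, g$n_selected, x$alpha))
  invisible(x)
}

#' @rdname run_differential
#' @param x An `occupancy_test` object.
#' @param ... Unused.
#' @export
tidy.occupancy_test <- function(x, ...) x$results

#' @rdname run_differential
#' @export
glance.occupancy_test <- function(x, ...) {
  tibble(n_peaks = nrow(x$results),
         n_tested = sum(x$results$status == "ok"),
         n_selected = sum(x$results$selected),
         alpha = x$alpha, variance_mode = x$variance_mode,
         n_cells_a = x$n_cells_a, n_cells_b = x$n_cells_b,
         condition_a = x$condition_a, condition_b = x$condition_b)
}

#' Build a single-peak [binned_counts] from a plain matrix
#'
#' Convenience for worked examples and tests: wraps one cells x bins block
#' as a one-peak `binned_counts` object.
#'
#' @param block Numeric matrix, cells x bins.
#' @param condition Condition label.
#' @param peak Peak id.
#' @return A [binned_counts] with one peak.
#' @export
toy_binned_counts <- function(block, condition = "A", peak = "peak_1") {
  new_binned_counts(block,
                    cell_ids = sprintf("%s_cell%d", condition, seq_len(nrow(block))),
                    peak_ids = peak, n_bins = ncol(block),
                    condition = condition)
}
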