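# shared fixtures and independent oracles

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# literal evaluation of the variance's quadruple sum:
# (1 / (ln2 * n_b)) * sum_{k,l} sum_m (c_mk - mu_k)(c_ml - mu_l) / total
# kept as an explicit bin-pair loop, independent of the row-sum identity
naive_sigma2 <- function(c) {
  c <- as.matrix(c)
  n <- nrow(c); nb <- ncol(c)
  mu <- colMeans(c)
  quad <- 0
  for (k in seq_len(nb)) {
    for (l in seq_len(nb)) {
      quad <- quad + sum((c[, k] - mu[k]) * (c[, l] - mu[l]))
    }
  }
  quad / (log(2) * nb * sum(c))
}

random_count_block <- function(n, nb, lambda = 2) {
  matrix(rpois(n * nb, lambda), n, nb)
}

# per-cell per-peak sums of a binned_counts, as a dense matrix
cell_peak_sums <- function(x) {
  as.matrix(peak_cell_sums(x))
}

# z-scores for an arbitrary condition labelling of a combined
# cells x peaks row-sum matrix (oracle for permutation tests)
zscores_from_rowsums <- function(R, lab, nb) {
  st <- function(M) {
    tot <- colSums(M)
    ssq <- pmax(colSums(M^2) - tot^2 / nrow(M), 0)
    list(zbar = log2(tot / nb), s2 = ssq / (log(2) * nb * tot))
  }
  a <- st(R[lab, , drop = FALSE])
  b <- st(R[!lab, , drop = FALSE])
  unname((a$zbar - b$zbar) / sqrt(a$s2 + b$s2))
}

# small simulated experiment shared across tests (built once per test run)
tiny_sim <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- simulate_experiment(
        sim_config(n_peaks = 30, cells_per_condition = 40, seed = 42))
    }
    memo
  }
})
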