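#' Configuration for the two-state tagmentation simulator
#'
#' Collects and validates the generative parameters for
#' [simulate_experiment()]. Defaults describe the standard recovery
#' scenario: 500 peaks on one synthetic chromosome, 10% of them
#' differentially occupied at |log2FC| = 2, 150 cells per condition, an
#' expected 0.4 reads per peak per cell before the per-cell depth factor
#' (about 60 reads per peak per condition summed over cells, and roughly
#' 200 in-window reads per cell), lognormal depth variation, a Gaussian
#' within-window enrichment profile, and 50 background fragments per cell
#' outside the windows.
#'
#' @param n_peaks Number of peaks.
#' @param frac_diff Fraction of peaks with a nonzero effect.
#' @param effect_log2fc Effect magnitude, applied to condition B intensity
#'   as `2^(true_log2fc)`.
#' @param effect_sign `"both"` (half up, half down), `"up"` or `"down"`.
#' @param cells_per_condition Cells per condition.
#' @param depth_lognormal_mu,depth_lognormal_sigma Parameters of the
#'   per-cell lognormal depth factor.
#' @param mean_peak_reads Expected reads per peak per cell at depth 1,
#'   before the peak-to-peak intensity spread.
#' @param peak_intensity_sigma Lognormal spread of per-peak base intensity
#'   (meanlog offset keeps the mean at `mean_peak_reads`).
#' @param profile_sigma_bins Standard deviation, in bins, of the Gaussian
#'   enrichment profile centred mid-window.
#' @param background_rate Expected fragments per cell placed uniformly
#'   outside all windows (controls FRiP).
#' @param flank,bin_width Window geometry in bp (defaults 2500 / 50, i.e.
#'   100 bins).
#' @param peak_gap Minimum bp between adjacent window edges (default 1000,
#'   so windows never overlap).
#' @param conditions Two condition labels.
#' @param seed Integer seed; mandatory.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_peaks = 500L, frac_diff = 0.1, effect_log2fc = 2,
                       effect_sign = c("both", "up", "down"),
                       cells_per_condition = 150L,
                       depth_lognormal_mu = 0, depth_lognormal_sigma = 0.5,
                       mean_peak_reads = 0.4, peak_intensity_sigma = 0.5,
                       profile_sigma_bins = 10, background_rate = 50,
                       flank = 2500L, bin_width = 50L, peak_gap = 1000L,
                       conditions = c("A", "B"), seed) {
  effect_sign <- match.arg(effect_sign)
  if (missing(seed)) abort("sim_config: a seed is mandatory")
  cfg <- list(n_peaks = as.integer(n_peaks), frac_diff = frac_diff,
              effect_log2fc = effect_log2fc, effect_sign = effect_sign,
              cells_per_condition = as.integer(cells_per_condition),
              depth_lognormal_mu = depth_lognormal_mu,
              depth_lognormal_sigma = depth_lognormal_sigma,
              mean_peak_reads = mean_peak_reads,
              peak_intensity_sigma = peak_intensity_sigma,
              profile_sigma_bins = profile_sigma_bins,
              background_rate = background_rate,
              flank = as.integer(flank), bin_width = as.integer(bin_width),
              peak_gap = as.integer(peak_gap),
              conditions = as.character(conditions),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_peaks >= 1, frac_diff >= 0, frac_diff <= 1,
              cells_per_condition >= 1, mean_peak_reads > 0,
              peak_intensity_sigma >= 0, profile_sigma_bins > 0,
              background_rate >= 0, flank > 0, bin_width > 0,
              peak_gap >= 0, length(conditions) == 2,
              conditions[1] != conditions[2])
  })
  if ((2L * cfg$flank) %% cfg$bin_width != 0L) {
    abort("sim_config: bin_width must divide 2 * flank")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a two-condition single-cell tagmentation experiment
#'
#' Generative model, per peak p and condition g: intensity
#' `lambda_pg = base_p * 2^(true_log2fc_p * [g == B])` with lognormal
#' peak-to-peak base intensities; per cell i a lognormal depth factor `d_i`;
#' the cell's read count for the peak is Poisson(`d_i * lambda_pg`), and each
#' read falls into a window bin drawn from a discretised Gaussian profile
#' centred mid-window. Reads are materialised as fragments of 30-120 bp
#' whose midpoint lies in the assigned bin, so midpoint and overlap counting
#' are both exercised. Background fragments are placed uniformly outside all
#' windows. Peaks sit on one synthetic chromosome (`chrS`) spaced so windows
#' do not overlap. Output is reproducible for a fixed seed and parses
#' cleanly with the package readers.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, writes
#'   `fragments_<condition>.tsv.gz`, `peaks.narrowPeak`, `design.tsv`,
#'   `truth.tsv` and `provenance.json` there.
#' @return A list: `peaks` (peak tibble, narrowPeak-style scores of 1000),
#'   `fragments` (one tibble per condition, named), `design`, `truth`
#'   (`peak`, `true_log2fc`, `base_intensity`) and `config`.
#' @export
simulate_experiment <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_rng(config$seed, {
    cfg <- config
    nb <- (2L * cfg$flank) %/% cfg$bin_width

    # geometry: evenly spaced peaks, windows separated by >= peak_gap
    spacing <- 2L * cfg$flank + cfg$peak_gap
    centre <- cfg$flank + cfg$peak_gap + spacing * (seq_len(cfg$n_peaks) - 1L)
    chrom_len <- centre[cfg$n_peaks] + cfg$flank + cfg$peak_gap
    if (chrom_len > 2^31 - 1) {
      abort("simulate_experiment: peaks x window size exceed the synthetic chromosome")
    }
    peaks <- tibble(chrom = "chrS", start = centre - 250L, end = centre + 250L,
                    name = sprintf("peak_%04d", seq_len(cfg$n_peaks)),
                    score = 1000)

    # ground truth
    k <- round(cfg$frac_diff * cfg$n_peaks)
    fc <- rep(0, cfg$n_peaks)
    if (k > 0) {
      hit <- sample(cfg$n_peaks, k)
      sgn <- switch(cfg$effect_sign,
                    up = rep(1, k), down = rep(-1, k),
                    both = sample(rep(c(1, -1), length.out = k)))
      fc[hit] <- sgn * cfg$effect_log2fc
    }
    base <- cfg$mean_peak_reads *
      rlnorm(cfg$n_peaks, meanlog = -cfg$peak_intensity_sigma^2 / 2,
             sdlog = cfg$peak_intensity_sigma)
    truth <- tibble(peak = peaks$name, true_log2fc = fc, base_intensity = base)

    # within-window bin profile (discretised Gaussian, unit mass)
    bin_centre <- (seq_len(nb) - 0.5) * cfg$bin_width - cfg$flank
    w <- stats::dnorm(bin_centre, 0, cfg$profile_sigma_bins * cfg$bin_width)
    w <- w / sum(w)

    win_start <- centre - cfg$flank
    design <- tibble(
      barcode = c(sprintf("%s_%04d", cfg$conditions[1], seq_len(cfg$cells_per_condition)),
                  sprintf("%s_%04d", cfg$conditions[2], seq_len(cfg$cells_per_condition))),
      condition = rep(cfg$conditions, each = cfg$cells_per_condition))

    frag_one_condition <- function(cond) {
      is_b <- cond == cfg$conditions[2]
      lam_peak <- base * 2^(fc * is_b)
      depth <- rlnorm(cfg$cells_per_condition, cfg$depth_lognormal_mu,
                      cfg$depth_lognormal_sigma)
      barcodes <- design$barcode[design$condition == cond]
      # per (cell, peak) read totals, then vectorised fragment materialisation
      n_ip <- rpois(cfg$cells_per_condition * cfg$n_peaks,
                    rep(depth, times = cfg$n_peaks) *
                      rep(lam_peak, each = cfg$cells_per_condition))
      cell_idx <- rep(rep(seq_len(cfg$cells_per_condition), times = cfg$n_peaks), n_ip)
      peak_idx <- rep(rep(seq_len(cfg$n_peaks), each = cfg$cells_per_condition), n_ip)
      total <- length(cell_idx)
      bin <- sample.int(nb, total, replace = TRUE, prob = w)
      mid <- win_start[peak_idx] + (bin - 1L) * cfg$bin_width +
        sample.int(cfg$bin_width, total, replace = TRUE) - 1L
      len <- sample(30:120, total, replace = TRUE)
      start <- mid - len %/% 2L

      # background: uniform over the complement of the windows
      nbg <- rpois(cfg$cells_per_condition, cfg$background_rate)
      gaps_start <- c(0L, centre + cfg$flank)
      gaps_end <- c(centre - cfg$flank, chrom_len)
      gw <- gaps_end - gaps_start
      tb <- sum(nbg)
      gi <- sample.int(length(gw), tb, replace = TRUE, prob = gw)
      bmid <- gaps_start[gi] + floor(runif(tb) * gw[gi])
      blen <- sample(30:120, tb, replace = TRUE)
      bstart <- pmax(bmid - blen %/% 2L, 0L)

      all_start <- c(start, bstart)
      all_end <- c(start + len, bstart + blen)
      out <- tibble(
        chrom = "chrS",
        start = all_start,
        end = all_end,
        barcode = c(barcodes[cell_idx], rep(barcodes, nbg)),
        count = 1L)
      out[order(out$start, out$barcode), , drop = FALSE]
    }
    fragments <- setNames(lapply(cfg$conditions, frag_one_condition),
                          cfg$conditions)

    res <- list(peaks = peaks, fragments = fragments, design = design,
                truth = truth, config = cfg)
    if (!is.null(dir)) write_simulation(res, dir)
    res
  })
}

#' @rdname simulate_experiment
#' @details `simulate_null()` forces `frac_diff = 0`, making the two
#'   conditions exchangeable at every peak.
#' @export
simulate_null <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  config$frac_diff <- 0
  simulate_experiment(config, dir = dir)
}

write_simulation <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in names(res$fragments)) {
    readr::write_tsv(res$fragments[[cond]],
                     file.path(dir, sprintf("fragments_%s.tsv.gz", cond)),
                     col_names = FALSE)
  }
  pk <- res$peaks
  np <- tibble(chrom = pk$chrom, start = pk$start, end = pk$end,
               name = pk$name, score = pk$score, strand = ".",
               signal = 0, p = -1, q = -1, summit = -1)
  readr::write_tsv(np, file.path(dir, "peaks.narrowPeak"), col_names = FALSE)
  readr::write_tsv(res$design, file.path(dir, "design.tsv"))
  readr::write_tsv(res$truth, file.path(dir, "truth.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(unclass(res$config),
                         file.path(dir, "provenance.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Simulate bulk promoter-occupancy fixtures with gene sets
#'
#' Builds paired per-gene count tables for two conditions plus gene sets
#' with known truth: `n_affected_sets` sets whose genes have condition-A
#' counts elevated by `2^log2_ratio`, and `n_null_sets` exchangeable sets.
#' A fraction of genes is forced to zero in one condition to exercise the
#' zero-exclusion rule downstream.
#'
#' @param genes_per_set Genes in each set (sets are disjoint).
#' @param n_affected_sets,n_null_sets Number of affected / null sets.
#' @param log2_ratio True log2 occupancy ratio (A over B) in affected sets.
#' @param base_mean Mean per-gene count in condition B.
#' @param zero_fraction Fraction of genes zeroed out in one condition.
#' @param seed Integer seed.
#' @return A list: `counts` (`gene`, `count_a`, `count_b`), `gene_sets`
#'   (named list), `truth` (`set`, `true_log2_ratio`).
#' @export
simulate_bulk_fixture <- function(genes_per_set = 200L, n_affected_sets = 2L,
                                  n_null_sets = 3L, log2_ratio = 1,
                                  base_mean = 500, zero_fraction = 0.02,
                                  seed) {
  if (missing(seed)) abort("simulate_bulk_fixture: a seed is mandatory")
  stopifnot(genes_per_set >= 2, n_affected_sets >= 0, n_null_sets >= 0,
            n_affected_sets + n_null_sets >= 1, base_mean > 0,
            zero_fraction >= 0, zero_fraction < 1)
  with_sim_rng(seed, {
    n_sets <- n_affected_sets + n_null_sets
    n_genes <- n_sets * genes_per_set
    gene <- sprintf("gene_%05d", seq_len(n_genes))
    set_of <- rep(seq_len(n_sets), each = genes_per_set)
    affected <- set_of <= n_affected_sets
    mu_b <- rlnorm(n_genes, log(base_mean) - 0.125, 0.5)
    mu_a <- mu_b * ifelse(affected, 2^log2_ratio, 1)
    count_a <- rpois(n_genes, mu_a)
    count_b <- rpois(n_genes, mu_b)
    nz <- sample(n_genes, round(zero_fraction * n_genes))
    if (length(nz) > 0) {
      side <- sample(c(TRUE, FALSE), length(nz), replace = TRUE)
      count_a[nz[side]] <- 0L
      count_b[nz[!side]] <- 0L
    }
    set_names <- sprintf("set_%02d", seq_len(n_sets))
    list(
      counts = tibble(gene = gene, count_a = count_a, count_b = count_b),
      gene_sets = setNames(split(gene, set_of), set_names),
      truth = tibble(set = set_names,
                     true_log2_ratio = ifelse(seq_len(n_sets) <= n_affected_sets,
                                              log2_ratio, 0)))
  })
}

# run expr under a locally seeded RNG, restoring any prior global state
with_sim_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
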