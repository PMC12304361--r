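make_toy_setup <- function() {
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(9950L, 29950L), end = c(10050L, 30050L),
                          name = c("pA", "pB"), score = 1000)
  windows <- make_windows(peaks)
  design <- tibble::tibble(barcode = c("c1", "c2", "c3"),
                           condition = c("X", "X", "Y"))
  # midpoints chosen to land in known windows
  fragments <- tibble::tibble(
    chrom = "chr1",
    start = c(7500L, 10000L, 29980L, 500000L, 10000L),
    end = c(7560L, 10060L, 30040L, 500060L, 10060L),
    barcode = c("c1", "c2", "c3", "c1", "zz"),
    count = 1L)
  list(peaks = peaks, windows = windows, design = design,
       fragments = fragments)
}

test_that("matrix building conserves counts and splits by condition", {
  s <- make_toy_setup()
  expect_warning(bm <- build_matrix(s$fragments, s$windows, s$design),
                 "absent from the design")
  expect_equal(bm$n_unknown_barcode, 1L)
  expect_named(bm$matrices, c("X", "Y"))
  # 3 in-window fragments with known barcodes, 1 outside all windows
  expect_equal(sum(bm$matrices$X$counts) + sum(bm$matrices$Y$counts), 3)
  expect_identical(bm$matrices$X$peak_ids, bm$matrices$Y$peak_ids)
  expect_equal(dim(bm$matrices$X), c(2L, 200L))
  # c1's fragment midpoint 7530 -> pA bin 0 -> column 1
  expect_equal(as.numeric(bm$matrices$X$counts["c1", 1]), 1)
  # cells without in-window fragments stay as all-zero rows
  d2 <- dplyr::bind_rows(s$design, tibble::tibble(barcode = "c4", condition = "Y"))
  expect_warning(bm2 <- build_matrix(s$fragments, s$windows, d2))
  expect_equal(unname(Matrix::rowSums(bm2$matrices$Y$counts)["c4"]), 0)
})

test_that("matrix building streams from a fragments file identically", {
  s <- make_toy_setup()
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(s$fragments, path, col_names = FALSE)
  expect_warning(bm_mem <- build_matrix(s$fragments, s$windows, s$design))
  expect_warning(bm_file <- build_matrix(path, s$windows, s$design))
  expect_equal(as.matrix(bm_file$matrices$X$counts),
               as.matrix(bm_mem$matrices$X$counts))
})

test_that("read filter is strict at the threshold", {
  m <- new_binned_counts(rbind(rep(25, 10), rep(25.1, 10)), c("A", "B"),
                         "p1", 10L)
  # totals 250 and 251
  kept <- filter_cells_by_reads(m, min_reads = 250)
  expect_equal(kept$cell_ids, "B")
  # idempotent: filtering the filtered matrix changes nothing
  expect_equal(filter_cells_by_reads(kept, min_reads = 250)$cell_ids, "B")
  m2 <- new_binned_counts(rbind(rep(0, 10), rep(1, 10)), c("A", "B"), "p1", 10L)
  expect_equal(filter_cells_by_reads(m2, min_reads = 0)$cell_ids, "B")
  expect_error(filter_cells_by_reads(m, min_reads = 1e6), "review the threshold")
  empty <- new_binned_counts(matrix(0, 0, 10), character(), "p1", 10L)
  expect_error(filter_cells_by_reads(empty), "no cells")
})

test_that("quantile filter removes tails of the non-zero-peak distribution", {
  # 100 cells with distinct non-zero-peak values 1..100: one fragment-count
  # per distinct peak
  nb <- 1L
  m <- matrix(0, 100, 100)
  for (i in 1:100) m[i, seq_len(i)] <- 1
  x <- new_binned_counts(m, sprintf("c%03d", 1:100),
                         sprintf("p%03d", 1:100), nb)
  kept <- quantile_filter_cells(x)          # lower 15%, upper 5%
  expect_equal(nrow(kept$counts), 80)
  expect_equal(kept$cell_ids, sprintf("c%03d", 16:95))
  expect_equal(quantile_filter_cells(x, 0, 0)$cell_ids, x$cell_ids)
  expect_error(quantile_filter_cells(x, 0.6, 0.5), "invalid")
  # idempotence within a pass: reapplying to the kept set with 0/0 is identity
  expect_equal(quantile_filter_cells(kept, 0, 0)$cell_ids, kept$cell_ids)
})

test_that("per-cell scaling hits the target total exactly", {
  m <- new_binned_counts(rbind(c(3, 497), c(2, 2), c(0, 0)),
                         c("a", "b", "z"), "p1", 2L)
  expect_warning(s <- normalize_total(m), "all-zero")
  expect_equal(as.numeric(s$counts["a", ]), c(60, 9940))
  tot <- Matrix::rowSums(s$counts)
  expect_equal(unname(tot[c("a", "b")]), c(10000, 10000), tolerance = 1e-9)
  expect_equal(unname(tot["z"]), 0)
  expect_true(s$scaled)
  expect_error(normalize_total(s), "already scaled")
  expect_error(normalize_total(m, target = -1), "positive")
  # a cell whose total already equals the target is unchanged
  m2 <- new_binned_counts(matrix(c(4000, 6000), 1), "a", "p1", 2L)
  expect_equal(as.numeric(normalize_total(m2)$counts), c(4000, 6000))
})

test_that("log1p transform is the natural log and refuses double application", {
  m <- new_binned_counts(matrix(c(0, exp(1) - 1), 1), "a", "p1", 2L)
  lg <- log1p_transform(m)
  expect_equal(as.numeric(lg$counts), c(0, 1))
  expect_error(log1p_transform(lg), "already")
})

test_that("FRiP counts each fragment once and moves with the peak set", {
  fr <- tibble::tibble(chrom = "chr1",
                       start = c(seq(100, 800, by = 100), 5000L, 6000L),
                       end = c(seq(150, 850, by = 100), 5050L, 6050L),
                       barcode = rep(c("c1", "c2"), 5), count = 1L)
  peaks <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L,
                          name = "p1", score = 1000)
  f <- frip(fr, peaks)
  expect_equal(f$pooled, 0.8)
  expect_true(all(f$per_cell$frip >= 0 & f$per_cell$frip <= 1))
  # no peaks -> 0; fragment spanning two peaks still counts once
  expect_equal(frip(fr, peaks[0, ])$pooled, 0)
  two <- dplyr::bind_rows(peaks,
                          tibble::tibble(chrom = "chr1", start = 120L,
                                         end = 140L, name = "p2", score = 1))
  expect_equal(frip(fr, two)$pooled, 0.8)
  expect_error(frip(fr[0, ], peaks), "no reads")
  # monotone non-decreasing as peaks are added
  far <- tibble::tibble(chrom = "chr1", start = 4990L, end = 5100L,
                        name = "p3", score = 1)
  expect_gte(frip(fr, dplyr::bind_rows(peaks, far))$pooled, f$pooled)
})

test_that("qc report flags agree with the standalone filters", {
  sim <- tiny_sim()
  w <- make_windows(sim$peaks)
  bm <- build_matrix(dplyr::bind_rows(sim$fragments), w, sim$design)
  x <- bm$matrices[[1]]
  rep <- cell_qc_report(x, min_reads = 10)
  kept <- filter_cells_by_reads(x, min_reads = 10)
  expect_setequal(rep$barcode[rep$passed_read_filter], kept$cell_ids)
  keptq <- quantile_filter_cells(x)
  expect_setequal(rep$barcode[rep$passed_quantile_filter], keptq$cell_ids)
})
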