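test_that("partition coefficient follows the area-weighted signal formula", {
  expect_equal(partition_coefficient(1, 1, 1, 1), 0.5)
  expect_equal(partition_coefficient(2, 1, 1, 2), 0.5)
  expect_equal(partition_coefficient(3, 1, 1, 1), 0.75)
  expect_error(partition_coefficient(0, 1, 0, 1), "both zero")

  # invariant under rescaling all intensities; monotone in each channel
  set.seed(21)
  for (k in 1:20) {
    r <- runif(4, 0.1, 10)
    p <- partition_coefficient(r[1], r[2], r[3], r[4])
    expect_equal(partition_coefficient(7 * r[1], r[2], 7 * r[3], r[4]), p)
    expect_gt(partition_coefficient(r[1] * 1.5, r[2], r[3], r[4]), p)
    expect_lt(partition_coefficient(r[1], r[2], r[3] * 1.5, r[4]), p)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("enrichment ratio divides chromosome by cytosolic intensity", {
  expect_equal(enrichment_ratio(29, 10), 2.9)
  expect_equal(enrichment_ratio(5, 5), 1)
  expect_equal(enrichment_ratio(0, 3), 0)
  expect_error(enrichment_ratio(1, 0), "cytosolic")
})

test_that("fold change normalizes to the cell's reference-stage mean", {
  rows <- data.frame(
    cell_id = "c1",
    timepoint = 1:4,
    stage = c("metaphase", "metaphase", "anaphase", "telophase"),
    i_chr = c(1, 3, 4, 4), a_chr = 1, i_cyt = 1, a_cyt = 1)
  fc <- fold_change_series(rows)
  # reference mean (1+3)/2 = 2; row at 4 -> 2.0; reference rows average 1
  expect_equal(fc$fold_change, c(0.5, 1.5, 2, 2))
  expect_equal(mean(fc$fold_change[fc$stage == "metaphase"]), 1)

  const <- rows; const$i_chr <- 5
  expect_equal(fold_change_series(const)$fold_change, rep(1, 4))

  # doubling telophase intensity doubles its fold change
  dbl <- rows; dbl$i_chr <- c(2, 2, 2, 4)
  expect_equal(fold_change_series(dbl)$fold_change[4], 2)

  noref <- rows; noref$stage <- "telophase"
  expect_error(fold_change_series(noref), "c1")

  # partition-metric normalization uses the partition column
  fp <- fold_change_series(rows, metric = "partition")
  ref <- mean(fp$partition[fp$stage == "metaphase"])
  expect_equal(fp$fold_change, fp$partition / ref)
})

test_that("negative intensities clamp to zero with a warning", {
  rows <- data.frame(cell_id = "c1", timepoint = 1:2, stage = "metaphase",
                     i_chr = c(-0.5, 2), a_chr = 1, i_cyt = 1, a_cyt = 1)
  expect_warning(fc <- fold_change_series(rows), "clamped")
  expect_equal(fc$i_chr[1], 0)
  bad <- rows; bad$a_chr <- 0
  expect_error(suppressWarnings(fold_change_series(bad)), "positive")
})

test_that("stage summary reproduces the Welch t-test oracle", {
  mk <- function(cell, stage, p) {
    i_chr <- p / (1 - p)  # areas and i_cyt all 1
    data.frame(cell_id = cell, timepoint = 1, stage = stage,
               i_chr = i_chr, a_chr = 1, i_cyt = 1, a_cyt = 1)
  }
  meta <- c(0.20, 0.25, 0.30)
  telo <- c(0.50, 0.60, 0.58)
  rows <- do.call(rbind, c(
    lapply(1:3, function(k) mk(sprintf("m%d", k), "metaphase", meta[k])),
    lapply(1:3, function(k) mk(sprintf("m%d", k), "telophase", telo[k]))))
  out <- summarize_by_stage(rows)
  expect_equal(out$summary$mean, c(mean(meta), mean(telo)), tolerance = 1e-9)
  expect_equal(out$summary$sd, c(sd(meta), sd(telo)), tolerance = 1e-9)
  expect_equal(out$p_value, oracle_welch_p(meta, telo), tolerance = 1e-9)

  # identical cells: zero sd; equal stages: p ~= 1
  same <- do.call(rbind, c(
    lapply(1:3, function(k) mk(sprintf("m%d", k), "metaphase", 0.3)),
    lapply(1:3, function(k) mk(sprintf("m%d", k), "telophase", 0.3))))
  out2 <- summarize_by_stage(same)
  expect_equal(out2$summary$sd, c(0, 0))
  expect_equal(out2$p_value, 1)

  expect_error(summarize_by_stage(rows[c(1, 4), ]), "at least 2 cells")
})

test_that("ROI CSV round-trips through the reader with validation", {
  rois <- make_roi_series(n_cells = 3, noise_cv = 0.05, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(rois, f, row.names = FALSE)
  back <- read_roi_csv(f)
  expect_equal(back$i_chr, rois$i_chr, tolerance = 1e-12)
  expect_equal(back$stage, rois$stage)

  broken <- rois; broken$i_cyt <- NULL
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken, f2, row.names = FALSE)
  expect_error(read_roi_csv(f2), "i_cyt")
})
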