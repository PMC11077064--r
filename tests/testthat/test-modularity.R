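# Unit and property tests for the segmentation pipeline; the 50-run
# calibration and recovery simulations live with the whole-method checks.

test_that("boundary profile handles flat, split and random inputs", {
  prof <- boundary_profile(strrep("A", 200), window = 30)
  expect_equal(prof$position, 30:170)
  expect_true(all(prof$score == 0))

  twoseg <- paste0(strrep("A", 100), strrep("Q", 100))
  prof <- boundary_profile(twoseg, window = 30)
  expect_equal(prof$score[prof$position == 100], 1)

  rec <- sample_sequence(idr_composition(), 400, seed = 12)
  prof <- boundary_profile(rec, window = 30)
  expect_true(all(prof$score < 1))
  expect_true(all(prof$score >= 0))
  expect_gt(stats::sd(prof$score), 0)

  expect_error(boundary_profile("ACDEFG", window = 30), "2\\*window")
})

test_that("candidate detection respects spacing and the tie rule", {
  flat <- data.frame(position = 10:60, score = 0)
  expect_length(detect_candidates(flat, 10), 0L)

  single <- data.frame(position = 10:60,
                       score = dnorm(10:60, mean = 35, sd = 5))
  expect_equal(detect_candidates(single, 10), 35L)

  # two equal peaks 5 apart with min_module 10: smaller wins
  sc <- rep(0, 51)
  sc[c(16, 21)] <- 0.8
  twopeak <- data.frame(position = 10:60, score = sc)
  expect_equal(detect_candidates(twopeak, 10), 25L)

  # far enough apart both are kept
  sc <- rep(0, 51)
  sc[c(6, 36)] <- 0.8
  expect_equal(detect_candidates(data.frame(position = 10:60, score = sc),
                                 10), c(15L, 45L))
})

test_that("boundary optimization homes in on the true junction", {
  mod <- make_modular(list(list(biased_composition("A", 0.9), 200),
                           list(biased_composition("Q", 0.9), 200)),
                      seed = 21)
  # candidate offset +8 from the truth
  opt <- optimize_boundaries(mod$record, 208L, window = 30, min_module = 30)
  expect_lte(abs(opt - 200L), 2L)

  # a fixed point stays put
  expect_equal(optimize_boundaries(mod$record, opt, 30, 30), opt)

  # clamping: a candidate near the end never crosses min_module
  L <- length(mod$record)
  opt_end <- optimize_boundaries(mod$record, L - 31L, window = 30,
                                 min_module = 30)
  expect_lte(opt_end, L - 30L)
  expect_gte(opt_end, 30L)
})

test_that("homopolymers and structureless inputs yield no boundaries", {
  p <- modularity_params(seed = 3, n_perm = 250)
  seg <- suppressMessages(segment_modules(strrep("A", 200), p))
  expect_equal(nrow(seg$boundaries), 0L)
  expect_equal(seg$modules, data.frame(start = 1L, end = 200L))
})

test_that("segmentation tiles the sequence and is deterministic", {
  mod <- make_modular(list(list(biased_composition("A"), 150),
                           list(biased_composition("Q"), 120),
                           list(biased_composition("E"), 150)),
                      seed = 33)
  p <- modularity_params(seed = 5, n_perm = 250)
  seg <- suppressMessages(segment_modules(mod$record, p))

  expect_equal(seg$modules$start[1], 1L)
  expect_equal(seg$modules$end[nrow(seg$modules)], length(mod$record))
  expect_equal(seg$modules$start[-1], seg$modules$end[-nrow(seg$modules)] + 1L)
  expect_equal(nrow(seg$modules), nrow(seg$boundaries) + 1L)

  # concatenating module subsequences reproduces the input
  pieces <- mapply(substr, seg$modules$start, seg$modules$end,
                   MoreArgs = list(x = mod$record$residues))
  expect_equal(paste(pieces, collapse = ""), mod$record$residues)

  seg2 <- suppressMessages(segment_modules(mod$record, p))
  expect_identical(seg$boundaries, seg2$boundaries)

  # both true junctions recovered on this strongly biased input
  expect_equal(nrow(seg$boundaries), 2L)
  expect_true(all(abs(seg$boundaries$position - mod$boundaries) <= 10))
})

test_that("raising the confidence threshold never adds boundaries", {
  mod <- make_modular(list(list(biased_composition("A", 0.6), 200),
                           list(biased_composition("Q", 0.6), 200)),
                      seed = 44)
  counts <- vapply(c(1.0, 1.645, 3.0, 6.0), function(z) {
    p <- modularity_params(seed = 7, n_perm = 250, z_threshold = z)
    nrow(suppressMessages(segment_modules(mod$record, p))$boundaries)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_gte(counts[1], 1L)
})

test_that("validation reports null moments consistent with the z-score", {
  mod <- make_modular(list(list(biased_composition("A"), 200),
                           list(biased_composition("Q"), 200)),
                      seed = 55)
  p <- modularity_params(seed = 9, n_perm = 250)
  seg <- suppressMessages(segment_modules(mod$record, p))
  b <- seg$boundaries
  expect_equal(b$z, (b$flank_score - b$null_mean) / b$null_sd)
  expect_true(all(b$percentile >= seg$conf_test))
  expect_equal(seg$conf_family, pnorm(p$z_threshold))
})
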