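test_that("NCPR track averages signed charges over a centered window", {
  expect_equal(ncpr_track("KKKKK", 3), rep(1, 5))
  expect_equal(ncpr_track("DDDDD", 3), rep(-1, 5))
  expect_equal(ncpr_track("KDKDK", 5)[3], 1 / 5)
  # truncated edges: first position of KKDDD with window 3 averages K,K
  expect_equal(ncpr_track("KKDDD", 3)[1], 1)
  expect_error(ncpr_track("KKKK", 2), "odd")
  tr <- ncpr_track(random_sequence(120, seed = 2), 25)
  expect_true(all(tr >= -1 & tr <= 1))
  expect_length(tr, 120L)
})

test_that("FCR counts exactly the four charged residues", {
  expect_equal(fcr("KRDE"), 1)
  expect_equal(fcr("GGGG"), 0)
  expect_equal(fcr("KAAA"), 0.25)
  expect_equal(fcr("HHHH"), 0)  # histidine uncharged by convention
})

test_that("isoelectric point is the root of the charge curve", {
  for (k in 1:20) {
    s <- random_sequence(sample(20:120, 1), seed = 700 + k)
    pi_hat <- isoelectric_point(s)
    q <- comphom:::net_charge_at_ph(comphom:::count_residues(s), pi_hat,
                                    comphom:::PKA_TABLES$bjellqvist, TRUE)
    expect_lt(abs(q), 1e-2)
    # bisection agrees with a dense pH-grid root
    grid <- seq(0, 14, by = 1e-4)
    qs <- vapply(grid, function(p) {
      comphom:::net_charge_at_ph(comphom:::count_residues(s), p,
                                 comphom:::PKA_TABLES$bjellqvist, TRUE)
    }, 0)
    root <- grid[which.min(abs(qs))]
    expect_lt(abs(pi_hat - root), 1e-3 + 1e-4)
  }
  expect_gt(isoelectric_point("KKKK"), 7)
  expect_lt(isoelectric_point("DDDD"), 7)
  # the EMBOSS table shifts the estimate but not the ordering
  expect_gt(isoelectric_point("KKKK", pka_set = "emboss"), 7)
})

test_that("CDK consensus scanning separates minimal from optimal sites", {
  s <- cdk_sites("SPSPTP")
  expect_equal(s$minimal, c(1L, 3L, 5L))
  s <- cdk_sites("TPAR")
  expect_equal(s$minimal, 1L)
  expect_equal(s$optimal, 1L)
  s <- cdk_sites("STP")
  expect_equal(s$minimal, 2L)
  expect_length(s$optimal, 0L)
  # optimal sites are a subset of minimal sites; counts are invariant
  # under appending a non-proline residue
  for (k in 1:25) {
    s <- random_sequence(sample(10:200, 1), seed = 810 + k)
    sites <- cdk_sites(s)
    expect_true(all(sites$optimal %in% sites$minimal))
    expect_equal(cdk_sites(paste0(s, "G"))$minimal, sites$minimal)
  }
})

test_that("phospho-dead transform kills every consensus site and nothing else", {
  expect_equal(phospho_dead("MSPATPK")$residues, "MAPAAPK")
  expect_equal(phospho_dead("MKRAAA")$residues, "MKRAAA")
  for (k in 1:25) {
    s <- random_sequence(sample(10:200, 1), seed = 900 + k)
    dead <- phospho_dead(s)
    expect_equal(nchar(dead$residues), nchar(s))
    expect_length(cdk_sites(dead)$minimal, 0L)
    # idempotent
    expect_equal(phospho_dead(dead)$residues, dead$residues)
    # composition changes only by S/T -> A at matched positions
    n_sites <- length(cdk_sites(s)$minimal)
    d <- composition(dead)$counts - composition(s)$counts
    expect_equal(unname(d["A"]), n_sites)
    expect_equal(sum(abs(d)), 2 * n_sites)
  }
})

test_that("AT-hook detection needs the GRP core in basic context", {
  expect_equal(nrow(find_at_hooks("RKRGRPRKEE")), 1L)
  expect_equal(nrow(find_at_hooks("KQGRPKK")), 1L)
  expect_equal(nrow(find_at_hooks("AAAAAA")), 0L)
  # core without basic context is rejected
  expect_equal(nrow(find_at_hooks("AAAGRPAAA")), 0L)
  # degenerate spaced core via the configurable pattern
  expect_equal(nrow(find_at_hooks("KKGARPKK", core = "G.RP")), 1L)
  # two separated hooks both found, never double-reported
  two <- paste0("RKRGRPRKEE", strrep("A", 10), "KQGRPKK")
  hits <- find_at_hooks(two)
  expect_equal(nrow(hits), 2L)
  expect_false(any(duplicated(hits$start)))
})

test_that("site window matrices are column-normalized around the site", {
  m <- site_window_matrix(list(list(seq_record("a", "ACDEFGHIK"), 5)),
                          flank = 4)
  expect_equal(dim(m), c(20L, 9L))
  expect_true(all(colSums(m) == 1))
  expect_true(all(m %in% c(0, 1)))  # one site: one-hot columns
  expect_equal(unname(m["F", "0"]), 1)  # site residue centered

  # two identical windows keep one-hot columns
  m2 <- site_window_matrix(list(list(seq_record("a", "ACDEFGHIK"), 5),
                                list(seq_record("b", "ACDEFGHIK"), 5)),
                           flank = 4)
  expect_identical(m2, m)

  # truncated windows: out-of-range offsets stay empty, observed columns
  # normalize to 1
  m3 <- site_window_matrix(list(list(seq_record("a", "SPKR"), 1)), flank = 4)
  expect_equal(unname(colSums(m3)), c(0, 0, 0, 0, 1, 1, 1, 1, 0))

  expect_error(site_window_matrix(list(list(seq_record("a", "SPKR"),
                                            integer(0)))), "no sites")
})

test_that("site-count regression matches the closed-form OLS oracle", {
  mk <- function(len, count) list(length = len, cdk_minimal = seq_len(count))
  exact <- sites_vs_length_fit(list(mk(100, 5), mk(200, 10), mk(300, 15)))
  expect_equal(exact$slope, 0.05, tolerance = 1e-12)
  expect_equal(exact$intercept, 0, tolerance = 1e-10)
  expect_equal(exact$r, 1)

  flat <- sites_vs_length_fit(list(mk(100, 7), mk(200, 7), mk(300, 7)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r, 0)

  set.seed(15)
  lens <- sample(100:600, 12)
  counts <- round(0.04 * lens + rnorm(12, sd = 2))
  fit <- sites_vs_length_fit(mapply(mk, lens, counts, SIMPLIFY = FALSE))
  orc <- oracle_ols(lens, counts)
  expect_equal(fit$slope, orc$slope, tolerance = 1e-9)
  expect_equal(fit$intercept, orc$intercept, tolerance = 1e-9)

  expect_error(sites_vs_length_fit(list(mk(100, 1), mk(100, 2), mk(100, 3))),
               "variance")
})

test_that("feature profiles bundle the individual metrics consistently", {
  s <- sample_sequence(idr_composition(), 250, seed = 6)
  fp <- feature_profile(s)
  expect_equal(fp$length, 250L)
  expect_equal(fp$fcr, fcr(s))
  expect_equal(fp$pi, isoelectric_point(s))
  expect_equal(fp$cdk_minimal, cdk_sites(s)$minimal)
  expect_equal(length(fp$charge_positions$basic) +
                 length(fp$charge_positions$acidic), round(fp$fcr * 250))
})
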