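test_that("score filter keeps the boundary score and preserves order", {
  pt <- protein_table(matrix(1, 3, 2), accession = c("A", "B", "C"),
                      score = c(4.9, 5.0, 10.0), sample_id = c("s1", "s2"))
  r <- filter_by_score(pt)
  expect_equal(r$table$accession, c("B", "C"))
  expect_equal(r$removed, "A")

  all_pass <- filter_by_score(pt, min_score = 4)
  expect_equal(all_pass$table$accession, pt$accession)
  expect_length(all_pass$removed, 0L)

  none <- filter_by_score(pt, min_score = 100)
  expect_equal(n_proteins(none$table), 0L)
  expect_equal(none$removed, c("A", "B", "C"))
})

test_that("intra-run normalization equalizes totals to the run maximum", {
  des <- make_design(2L)  # S01,S02 in different runs; 3 samples per run
  m <- matrix(0, 2, 6, dimnames = list(c("A", "B"), des$sample_id))
  # run R1: totals 40, 80, 100 -> factors 2.5, 1.25, 1.0
  m[, "S01-A"] <- c(15, 25); m[, "S01-F"] <- c(30, 50); m[, "C-R1"] <- c(40, 60)
  m[, "S02-A"] <- c(5, 45);  m[, "S02-F"] <- c(50, 50); m[, "C-R2"] <- c(20, 30)
  pt <- protein_table(m, accession = c("A", "B"), score = c(9, 9),
                      sample_id = des$sample_id)
  r <- intra_run_normalize(pt, des)
  expect_equal(unname(r$report$intra_run_factors[c("S01-A", "S01-F", "C-R1")]),
               c(2.5, 1.25, 1.0))
  tot <- colSums(r$table$signal)
  expect_equal(unname(tot[c("S01-A", "S01-F", "C-R1")]), rep(100, 3))
  expect_equal(r$table$signal["A", "S01-A"], 15 * 2.5)

  # equal totals -> identity; idempotence
  r2 <- intra_run_normalize(r$table, des)
  expect_equal(r2$table$signal, r$table$signal)
  expect_equal(unname(r2$report$intra_run_factors), rep(1, 6))

  # zero-total sample errors by name
  m[, "S02-A"] <- 0
  pt0 <- protein_table(m, accession = c("A", "B"), score = c(9, 9),
                       sample_id = des$sample_id)
  expect_error(intra_run_normalize(pt0, des), "S02-A")
})

test_that("IRS equalizes control channels across runs via the geometric mean", {
  des <- make_design(2L)
  m <- matrix(6, 2, 6, dimnames = list(c("A", "B"), des$sample_id))
  m["A", "C-R1"] <- 10; m["A", "C-R2"] <- 40   # reference = 20
  m["B", "C-R1"] <- 8;  m["B", "C-R2"] <- 8    # identical: untouched
  m["A", "S01-A"] <- 6
  pt <- protein_table(m, accession = c("A", "B"), score = c(9, 9),
                      sample_id = des$sample_id)
  r <- inter_run_normalize(pt, des)
  expect_equal(r$table$signal["A", "C-R1"], 20)
  expect_equal(r$table$signal["A", "C-R2"], 20)
  expect_equal(r$table$signal["A", "S01-A"], 12)   # run-R1 factor 2.0
  expect_equal(r$table$signal["B", ], pt$signal["B", ])  # identity case
  expect_length(r$report$inter_run_flagged, 0L)

  # protein absent from one run's control: that run untouched, flagged
  m["A", "C-R2"] <- NA
  pt2 <- protein_table(m, accession = c("A", "B"), score = c(9, 9),
                       sample_id = des$sample_id)
  r2 <- inter_run_normalize(pt2, des)
  expect_equal(r2$report$inter_run_flagged, "A")
  expect_equal(r2$table$signal["A", "S02-A"], pt2$signal["A", "S02-A"])

  # zero control value treated as missing with a warning
  m["A", "C-R2"] <- 0
  pt3 <- protein_table(m, accession = c("A", "B"), score = c(9, 9),
                       sample_id = des$sample_id)
  expect_warning(inter_run_normalize(pt3, des), "control value 0")
})

test_that("after IRS, control values agree across runs on real-shaped data", {
  s <- simulate_experiment(sim_config(seed = 13))
  n1 <- intra_run_normalize(filter_by_score(s$proteins)$table, s$design)
  n2 <- inter_run_normalize(n1$table, s$design)
  ctrl <- n2$table$signal[, c("CTRL-R1", "CTRL-R2")]
  both <- stats::complete.cases(ctrl)
  expect_gt(sum(both), 600L)
  cv <- apply(ctrl[both, ], 1L, function(v) stats::sd(v) / mean(v))
  expect_lt(max(cv), 1e-12)
})

test_that("normalizations recover planted loading/batch factors exactly without noise", {
  cfg <- null_sim_config(blood_fraction_range = c(0.25, 0.25),
                         noise_cv = 0, missing_rate = 0,
                         detection_limit_quantile = 0, seed = 5)
  s <- simulate_experiment(cfg)
  for (mode in c("irs", "global")) {
    r <- run_univariate_stages(s, inter = mode)
    expect_lt(max(abs(log2(r$differential$fold_change_abd_vs_fem))), 1e-9)
  }
})
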