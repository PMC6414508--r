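test_that("identical seed and config give identical outputs", {
  a <- simulate_experiment(sim_config(seed = 42))
  b <- simulate_experiment(sim_config(seed = 42))
  expect_identical(a$proteins$signal, b$proteins$signal)
  expect_identical(as.data.frame(a$design), as.data.frame(b$design))
  expect_identical(a$morphology$abdominal_fcs, b$morphology$abdominal_fcs)
  expect_identical(a$truth$blood_fraction, b$truth$blood_fraction)
  c <- simulate_experiment(sim_config(seed = 43))
  expect_false(identical(a$proteins$signal, c$proteins$signal))
})

test_that("generated layout matches the two-run paired TMT design", {
  s <- simulate_experiment(sim_config(seed = 1))
  expect_equal(n_proteins(s$proteins), 651L)        # 610 tissue + 41 blood
  expect_equal(n_samples(s$proteins), 18L)          # 16 study + 2 controls
  expect_equal(length(s$blood), 41L)
  d <- s$design
  for (r in c("R1", "R2")) {
    expect_equal(sum(d$run_id == r), 9L)            # 8 samples + control
    expect_equal(sum(d$run_id == r & d$is_control), 1L)
  }
  expect_equal(nrow(s$morphology), 8L)
  expect_true(all(names(depot_effect_defaults()) %in% s$proteins$accession))
})

test_that("noise-free limit with fixed blood fraction is exactly balanced", {
  cfg <- null_sim_config(blood_fraction_range = c(0.2, 0.2), subject_sd = 0,
                         run_effect_sd = 0, loading_sd = 0, noise_cv = 0,
                         missing_rate = 0, detection_limit_quantile = 0,
                         size_link_sd = 0, seed = 3)
  s <- simulate_experiment(cfg)
  sig <- s$proteins$signal
  frac <- colSums(sig[s$truth$is_blood, ]) / colSums(sig)
  expect_equal(unname(frac), rep(0.2, 18), tolerance = 1e-12)
  abd <- sig[, grep("-ABD$", colnames(sig))]
  fem <- sig[, grep("-FEM$", colnames(sig))]
  expect_equal(abd, fem, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("realized blood share equals the drawn fraction exactly, pre-censoring", {
  cfg <- sim_config(missing_rate = 0, detection_limit_quantile = 0, seed = 11)
  s <- simulate_experiment(cfg)
  frac <- colSums(s$proteins$signal[s$truth$is_blood, ]) /
    colSums(s$proteins$signal)
  expect_equal(frac, s$truth$blood_fraction, tolerance = 1e-9)
  study <- !grepl("^CTRL", names(frac))
  expect_true(all(frac[study] >= 0.18 & frac[study] <= 0.38))
})

test_that("null generator yields uniform paired-t p-values (KS sanity)", {
  cfg <- null_sim_config(n_tissue_proteins = 2000L, missing_rate = 0,
                         detection_limit_quantile = 0, seed = 7)
  s <- simulate_experiment(cfg)
  fit <- depot_fit(s$proteins, s$design, blood = s$blood)
  p <- fit$differential$p_value
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("morphology generator converges to its configured depot means", {
  m <- simulate_morphology(sim_config(seed = 5), n_subjects = 10000L)
  expect_equal(mean(m$abdominal_fcs), 58.0, tolerance = 0.3 / 58)
  expect_equal(mean(m$femoral_fcs), 65.9, tolerance = 0.3 / 65.9)
  # default sds reproduce the reference SEMs at n = 8 in expectation
  expect_equal(sd(m$abdominal_fcs) / sqrt(8), 3.3, tolerance = 0.05)
  expect_equal(sd(m$femoral_fcs) / sqrt(8), 2.3, tolerance = 0.05)
})

test_that("truth report round trips and covers every protein", {
  s <- simulate_experiment(sim_config(seed = 2))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  truth_report(s$truth, tmp)
  back <- read_truth(tmp)
  expect_equal(nrow(back), n_proteins(s$proteins))
  expect_equal(back$true_log2_fc,
               unname(s$truth$depot_effect[back$accession]))
  expect_equal(back$batch_R1, unname(s$truth$batch[back$accession, "R1"]))

  s0 <- simulate_experiment(null_sim_config(seed = 2))
  truth_report(s0$truth, tmp)
  expect_true(all(read_truth(tmp)$true_log2_fc == 0))
})

test_that("invalid configs fail before any sampling", {
  expect_error(sim_config(n_subjects = 7), "even")
  expect_error(sim_config(blood_fraction_range = c(0.5, 1.2)), "interval")
  expect_error(sim_config(noise_cv = -0.1), "nonnegative")
  expect_error(sim_config(missing_rate = 1.2), "missing_rate")
  expect_error(sim_config(depot_effects = c(0.5)), "named")
})
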