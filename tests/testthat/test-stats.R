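test_that("half-minimum imputation uses one global value", {
  m <- matrix(c(4, 8, NA, 0.5, NA, 7), 3, 2,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  pt <- protein_table(m, accession = rownames(m), score = rep(9, 3),
                      sample_id = colnames(m))
  imp <- impute_missing(pt)
  expect_equal(unname(imp$signal[is.na(m)]), c(0.25, 0.25))  # min positive 0.5
  expect_equal(imp$signal[!is.na(m)], m[!is.na(m)])

  # no missing -> identity
  fx <- make_table(seed = 3L)
  expect_equal(impute_missing(fx$table)$signal, fx$table$signal)

  # all-zero/missing matrix cannot be imputed
  z <- protein_table(matrix(c(0, NA), 1, 2), accession = "A", score = 9,
                     sample_id = c("s1", "s2"))
  expect_error(impute_missing(z), "positive")
})

test_that("log2 transform requires positive complete data and is monotone", {
  pt <- protein_table(matrix(c(8, 1, 2, 4), 2, 2), accession = c("A", "B"),
                      score = c(9, 9), sample_id = c("s1", "s2"))
  lt <- log2_transform(pt)
  expect_equal(lt$signal, matrix(c(3, 0, 1, 2), 2, 2), ignore_attr = TRUE)
  expect_equal(lt$scale, "log2")
  pt$signal[1, 1] <- 0
  expect_error(log2_transform(pt), "> 0")
})

test_that("paired t-test matches the closed-form oracle and handles degeneracy", {
  r <- paired_t_test(c(2, 4, 6), c(1, 2, 3))   # d = (1,2,3)
  expect_equal(r$t, sqrt(3) * 2 / 1, tolerance = 1e-12)  # 3.4641
  expect_equal(r$df, 2)
  expect_equal(r$p, 0.0741799, tolerance = 1e-6)
  o <- paired_t_oracle(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$t, o$t); expect_equal(r$p, o$p)

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)

  flip <- paired_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(flip$t, -r$t); expect_equal(flip$p, r$p)

  expect_warning(z <- paired_t_test(c(2, 3, 4), c(1, 2, 3)), "undefined")
  expect_true(is.na(z$p))
})

test_that("BH q-values agree with brute-force enumeration", {
  expect_equal(fdr_qvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdr_qvalues(c(0.04, 0.5)), c(0.08, 0.5))
  expect_equal(fdr_qvalues(0.2), 0.2)
  expect_error(fdr_qvalues(c(0.5, 1.5)), "\\[0, 1\\]")
  expect_equal(fdr_qvalues(c(0.1, NA, 0.05)), c(0.1, NA, 0.1))
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    q <- fdr_qvalues(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone along sorted p
  }
})

test_that("fold change is the geometric-mean paired ratio with inverse symmetry", {
  expect_equal(fold_change(c(4, 4), c(8, 8)), 0.5)
  expect_equal(fold_change(c(3, 5, 9), c(3, 5, 9)), 1.0)
  set.seed(12)
  a <- rlnorm(6); b <- rlnorm(6)
  expect_equal(fold_change(a, b) * fold_change(b, a), 1.0, tolerance = 1e-12)
  expect_error(fold_change(c(-1, 2), c(1, 2)), "positive")
})

test_that("differential table ranks a huge planted effect first and is sorted", {
  cfg <- sim_config(n_tissue_proteins = 50L, depot_effects = c(T9999 = 3),
                    size_linked = data.frame(accession = character(0),
                                             sign = numeric(0),
                                             depot = character(0)),
                    missing_rate = 0, detection_limit_quantile = 0, seed = 8)
  s <- simulate_experiment(cfg)
  r <- run_univariate_stages(s)
  d <- r$differential
  expect_equal(d$accession[1L], "T9999")
  expect_true(all(diff(d$p_value) >= 0))
  expect_true(all(d$q_value >= d$p_value))
  expect_equal(d$fold_change_abd_vs_fem[1L], 8, tolerance = 0.25)
  expect_identical(d$flagged, d$p_value < 0.05)
})

test_that("Spearman matches the exact permutation oracle for small n", {
  r <- spearman_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)
  expect_equal(r$p, 1 / 3, tolerance = 1e-9)
  expect_equal(r$method, "exact")

  expect_equal(spearman_correlation(1:5, (1:5)^3)$rho, 1)
  expect_equal(spearman_correlation(1:5, -(1:5)^3)$rho, -1)

  set.seed(19)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    got <- spearman_correlation(x, y)
    want <- spearman_perm_oracle(x, y)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
  # invariance under strictly monotone transforms
  x <- rexp(8); y <- rexp(8)
  expect_equal(spearman_correlation(exp(x), y)$rho,
               spearman_correlation(x, y^3)$rho)
  expect_warning(z <- spearman_correlation(rep(1, 5), 1:5), "undefined")
  expect_true(is.na(z$rho))
})

test_that("planted size-linked proteins show the planted monotone association", {
  s <- simulate_experiment(sim_config(n_subjects = 200L, seed = 21))
  fit <- depot_fit(s$proteins, s$design, blood = s$blood,
                   morphology = s$morphology)
  co <- fatcell_correlations(fit$tables$log2, s$design, s$morphology,
                             proteins = c("P00325", "Q15063", "P13796"))
  fem <- function(a) co[co$accession == a & co$depot == "femoral", ]
  abd <- function(a) co[co$accession == a & co$depot == "abdominal", ]
  expect_lt(fem("P00325")$rho, -0.4)   # ADH1B negative in both depots
  expect_lt(abd("P00325")$rho, -0.4)
  expect_gt(fem("Q15063")$rho, 0.4)    # POSTN positive, femoral only
  expect_gt(fem("P13796")$rho, 0.4)    # LCP1 positive, femoral only
  expect_lt(abs(abd("Q15063")$rho), 0.3)
  expect_true(all(abs(co$rho) <= 1))
})

test_that("fatcell correlation errors on subject mismatch", {
  s <- simulate_experiment(sim_config(seed = 2))
  mo <- s$morphology[s$morphology$subject_id != "S0001", ]
  expect_error(fatcell_correlations(impute_missing(s$proteins), s$design, mo),
               "S0001")
})

test_that("morphology test reports depot means, SEMs and the paired p", {
  mo <- morphology_table(data.frame(subject_id = sprintf("S%02d", 1:4),
                                    abdominal_fcs = c(55, 58, 60, 57),
                                    femoral_fcs = c(63, 66, 68, 64)))
  r <- morphology_test(mo)
  expect_equal(r$mean_abd, 57.5)
  expect_equal(r$sem_abd, sd(c(55, 58, 60, 57)) / 2)
  o <- paired_t_oracle(mo$abdominal_fcs, mo$femoral_fcs)
  expect_equal(r$p, o$p)

  same <- morphology_table(data.frame(subject_id = c("a", "b"),
                                      abdominal_fcs = c(50, 60),
                                      femoral_fcs = c(50, 60)))
  expect_equal(morphology_test(same)$p, 1)
})
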