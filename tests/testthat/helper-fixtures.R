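# Small in-code fixtures shared across test files.

# Minimal valid two-run paired design: n subjects (even), one control per run.
make_design <- function(n_subjects = 4L) {
  subs <- sprintf("S%02d", seq_len(n_subjects))
  runs <- rep(c("R1", "R2"), each = n_subjects / 2L)
  study <- data.frame(
    sample_id = paste0(rep(subs, each = 2L), c("-A", "-F")),
    subject_id = rep(subs, each = 2L),
    depot = rep(c("abdominal", "femoral"), n_subjects),
    run_id = rep(runs, each = 2L),
    channel_label = "x", is_control = FALSE, stringsAsFactors = FALSE)
  ctrl <- data.frame(sample_id = c("C-R1", "C-R2"), subject_id = "pool",
                     depot = "control", run_id = c("R1", "R2"),
                     channel_label = "c", is_control = TRUE,
                     stringsAsFactors = FALSE)
  sample_design(rbind(study, ctrl))
}

# Random positive protein table matching make_design(n_subjects).
make_table <- function(n_proteins = 10L, n_subjects = 4L, seed = 1L,
                       missing = 0) {
  set.seed(seed)
  des <- make_design(n_subjects)
  m <- matrix(stats::rlnorm(n_proteins * nrow(des), meanlog = 5, sdlog = 1),
              n_proteins, nrow(des))
  if (missing > 0) m[stats::runif(length(m)) < missing] <- NA
  list(table = protein_table(m, accession = sprintf("P%03d", seq_len(n_proteins)),
                             score = rep(10, n_proteins),
                             sample_id = des$sample_id),
       design = des)
}

# Null generator config (no planted effects, no size links).
null_sim_config <- function(...) {
  sim_config(depot_effects = stats::setNames(numeric(0), character(0)),
             size_linked = data.frame(accession = character(0),
                                      sign = numeric(0), depot = character(0),
                                      stringsAsFactors = FALSE),
             ...)
}

# Stage composition used where the strict multivariate stage of depot_fit
# would be degenerate (noise-free data).
run_univariate_stages <- function(sim, inter = "irs") {
  sf <- filter_by_score(sim$proteins)
  n1 <- intra_run_normalize(sf$table, sim$design)
  n2 <- inter_run_normalize(n1$table, sim$design, method = inter)
  bc <- blood_correct(n2$table, sim$blood)
  lt <- log2_transform(impute_missing(bc$corrected))
  list(normalized = n2$table, blood = bc, log2 = lt,
       differential = differential_table(lt, sim$design))
}
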