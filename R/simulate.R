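# Reference set of depot-differential adipose-tissue proteins used as the
# generator's default planted effect map: accession, gene symbol, and the
# abdominal-vs-femoral fold change each protein is planted at.
.depot_reference <- data.frame(
  accession = c("Q15063", "P13796", "O14950", "P37802", "P00338", "P06396",
                "P00441", "P67936", "P40939", "P13489", "P13639", "P60709",
                "P07900", "O95865", "P54727", "P62805", "P08133", "P07355",
                "P04899", "Q16851", "P00325", "P00167"),
  gene_symbol = c("POSTN", "LCP1", "MYL12B", "TAGLN2", "LDHA", "GSN",
                  "SOD1", "TPM4", "HADHA", "RNH1", "EEF2", "ACTB",
                  "HSP90AA1", "DDAH2", "RAD23B", "HIST1H4A", "ANXA6", "ANXA2",
                  "GNAI2", "UGP2", "ADH1B", "CYB5A"),
  fold_change = c(0.80, 0.88, 0.89, 0.92, 0.92, 0.92, 0.93, 0.93, 0.93, 0.93,
                  0.94, 0.95, 1.05, 1.08, 1.09, 1.11, 1.12, 1.13, 1.14, 1.19,
                  1.22, 1.25),
  stringsAsFactors = FALSE)

#' Default planted depot effects
#'
#' The default abdominal-vs-femoral effect map used by [sim_config()]: 22
#' adipose-tissue proteins with fold changes between 0.80 (POSTN, higher in
#' femoral) and 1.25 (CYB5A, higher in abdominal), on the log2 scale.
#'
#' @return named numeric vector of log2 fold changes (ABD vs FEM), names are
#'   UniProt accessions; gene symbols attached as the `"gene_symbol"`
#'   attribute.
#' @export
depot_effect_defaults <- function() {
  structure(log2(.depot_reference$fold_change),
            names = .depot_reference$accession,
            gene_symbol = .depot_reference$gene_symbol)
}

#' Configuration for the synthetic TMT experiment generator
#'
#' Defines the study conditions emulated by [simulate_experiment()]: a paired
#' two-depot design on `n_subjects` subjects split over two TMT runs, each run
#' multiplexing its subjects' samples plus one pooled control channel (the
#' inter-run bridge). Defaults reproduce the structure of an 8-subject,
#' 651-protein (610 tissue + 41 blood) experiment with per-sample
#' blood-contamination fractions in 18-38% of total signal and fat cell sizes
#' of 58.0 um (abdominal) vs 65.9 um (femoral).
#'
#' @param n_subjects even number of subjects (each contributes both depots).
#' @param n_tissue_proteins number of tissue proteins, including the planted
#'   ones named in `depot_effects`.
#' @param n_blood_proteins number of blood-specific (contaminant) proteins.
#' @param depot_effects named numeric vector: log2 fold change (ABD vs FEM)
#'   planted per accession; all other tissue proteins are null.
#' @param blood_fraction_range length-2 interval in (0,1); each sample's blood
#'   share of total signal is drawn uniformly from it.
#' @param baseline_log_mean,baseline_log_sd log2-scale mean and sd of protein
#'   baseline abundances (log-normal across proteins).
#' @param subject_sd sd (log2) of the per-subject, per-protein biological
#'   effect, shared by a subject's two depots.
#' @param run_effect_sd sd (log2) of the per-protein, per-run batch factor.
#' @param loading_sd sd (log2) of the per-sample channel-loading factor.
#' @param noise_cv coefficient of variation of multiplicative measurement
#'   error per cell.
#' @param missing_rate probability a cell is missing at random.
#' @param detection_limit_quantile signals below this quantile of the observed
#'   matrix are censored to missing (left-censoring dropout).
#' @param score_below_threshold_fraction fraction of background tissue
#'   proteins given an identification score below 5 (default 0: all proteins
#'   pass the score filter, matching an already-filtered export).
#' @param fcs_abd_mean,fcs_fem_mean mean fat cell diameters (um) per depot.
#' @param fcs_abd_sd,fcs_fem_sd between-subject sds (um); defaults convert the
#'   reference standard errors (3.3, 2.3 at n = 8) to sds.
#' @param fcs_within_subject_rho correlation between a subject's two depot
#'   fat cell sizes.
#' @param size_linked data.frame with columns `accession`, `sign`, `depot`
#'   (`"both"`, `"abdominal"` or `"femoral"`): proteins given a monotone
#'   subject-level association with fat cell size.
#' @param size_link_strength Gaussian-copula correlation between the fat cell
#'   size latent and the linked protein's subject effect.
#' @param size_link_sd sd (log2) of the linked subject-level component.
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 8L,
                       n_tissue_proteins = 610L,
                       n_blood_proteins = 41L,
                       depot_effects = depot_effect_defaults(),
                       blood_fraction_range = c(0.18, 0.38),
                       baseline_log_mean = 10,
                       baseline_log_sd = 2,
                       subject_sd = 0.25,
                       run_effect_sd = 0.20,
                       loading_sd = 0.25,
                       noise_cv = 0.10,
                       missing_rate = 0,
                       detection_limit_quantile = 0.005,
                       score_below_threshold_fraction = 0,
                       fcs_abd_mean = 58.0,
                       fcs_fem_mean = 65.9,
                       fcs_abd_sd = 3.3 * sqrt(8),
                       fcs_fem_sd = 2.3 * sqrt(8),
                       fcs_within_subject_rho = 0.6,
                       size_linked = data.frame(
                         accession = c("P00325", "Q15063", "P13796"),
                         sign = c(-1, 1, 1),
                         depot = c("both", "femoral", "femoral"),
                         stringsAsFactors = FALSE),
                       size_link_strength = 0.8,
                       size_link_sd = 0.5,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_tissue_proteins = as.integer(n_tissue_proteins),
              n_blood_proteins = as.integer(n_blood_proteins),
              depot_effects = depot_effects,
              blood_fraction_range = as.numeric(blood_fraction_range),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              subject_sd = subject_sd, run_effect_sd = run_effect_sd,
              loading_sd = loading_sd, noise_cv = noise_cv,
              missing_rate = missing_rate,
              detection_limit_quantile = detection_limit_quantile,
              score_below_threshold_fraction = score_below_threshold_fraction,
              fcs_abd_mean = fcs_abd_mean, fcs_fem_mean = fcs_fem_mean,
              fcs_abd_sd = fcs_abd_sd, fcs_fem_sd = fcs_fem_sd,
              fcs_within_subject_rho = fcs_within_subject_rho,
              size_linked = size_linked,
              size_link_strength = size_link_strength,
              size_link_sd = size_link_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_subjects < 2L || cfg$n_subjects %% 2L != 0L)
    stop("n_subjects must be an even integer >= 2 (split over 2 runs)")
  if (length(cfg$depot_effects) &&
      (is.null(names(cfg$depot_effects)) || any(!nzchar(names(cfg$depot_effects)))))
    stop("depot_effects must be a named vector (accession -> log2 FC)")
  if (length(cfg$depot_effects) > cfg$n_tissue_proteins)
    stop("more planted depot_effects than tissue proteins")
  bfr <- cfg$blood_fraction_range
  if (length(bfr) != 2L || bfr[1L] > bfr[2L] || bfr[1L] < 0 || bfr[2L] >= 1)
    stop("blood_fraction_range must be an interval within [0, 1)")
  sds <- c(cfg$baseline_log_sd, cfg$subject_sd, cfg$run_effect_sd,
           cfg$loading_sd, cfg$noise_cv, cfg$fcs_abd_sd, cfg$fcs_fem_sd,
           cfg$size_link_sd)
  if (any(sds < 0)) stop("sd/cv parameters must be nonnegative")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (cfg$detection_limit_quantile < 0 || cfg$detection_limit_quantile >= 1)
    stop("detection_limit_quantile must be in [0, 1)")
  if (abs(cfg$fcs_within_subject_rho) > 1 || abs(cfg$size_link_strength) > 1)
    stop("correlations must lie in [-1, 1]")
  if (cfg$score_below_threshold_fraction < 0 ||
      cfg$score_below_threshold_fraction > 1)
    stop("score_below_threshold_fraction must be in [0, 1]")
  invisible(cfg)
}

# Correlated subject-level morphology: returns fat cell sizes plus the
# standardized latents that drive them (reused by the size-linked copula).
.draw_morphology <- function(n, mean_abd, mean_fem, sd_abd, sd_fem, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  list(abd = mean_abd + sd_abd * z1, fem = mean_fem + sd_fem * z2,
       z = cbind(abdominal = z1, femoral = z2))
}

#' Simulate the morphology component alone
#'
#' Draws paired abdominal/femoral fat cell sizes for `n_subjects` subjects
#' from the correlated bivariate model in `config`.
#'
#' @param config a [sim_config].
#' @param n_subjects optional override of `config$n_subjects`.
#' @return a [morphology_table].
#' @export
simulate_morphology <- function(config = sim_config(), n_subjects = NULL) {
  validate_sim_config(config)
  n <- if (is.null(n_subjects)) config$n_subjects else as.integer(n_subjects)
  set.seed(config$seed)
  m <- .draw_morphology(n, config$fcs_abd_mean, config$fcs_fem_mean,
                        config$fcs_abd_sd, config$fcs_fem_sd,
                        config$fcs_within_subject_rho)
  morphology_table(data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                              abdominal_fcs = pmax(m$abd, 1e-6),
                              femoral_fcs = pmax(m$fem, 1e-6),
                              stringsAsFactors = FALSE))
}

#' Simulate a two-run paired TMT proteome experiment
#'
#' Generates a full synthetic dataset with known ground truth. The signal
#' model, per tissue protein x and study sample i (subject s, depot d, run k):
#'
#' \deqn{signal_{x,i} = baseline_x \cdot 2^{u_{x,s} \pm \Delta_x/2 + link_{x,s,d}}
#'   \cdot batch_{x,k} \cdot loading_i \cdot \epsilon_{x,i}}
#'
#' where the planted depot effect \eqn{\Delta_x} (log2 ABD vs FEM) is split
#' symmetrically (+\eqn{\Delta/2} abdominal, \eqn{-\Delta/2} femoral). Blood
#' proteins share one composition profile across samples and are scaled per
#' sample so the blood share of total signal equals a fraction drawn from
#' `blood_fraction_range`. Each run's control channel is the pooled mean of
#' all study samples' pre-batch, pre-loading true signals — identical across
#' runs by construction, which is the invariant inter-run normalization
#' restores. Low signals are left-censored at `detection_limit_quantile` and a
#' further `missing_rate` fraction is missing at random.
#'
#' All draws use one seeded generator in fixed, documented order, so identical
#' configs give identical outputs.
#'
#' @param config a [sim_config].
#' @return list with elements `proteins` ([protein_table]), `design`
#'   ([sample_design]), `morphology` ([morphology_table]), `blood`
#'   ([blood_list]), `truth` (class `simulation_truth`: per-protein true log2
#'   depot effect and per-run batch factors, per-sample true blood fraction
#'   and loading factor, the morphology latents, and the size-linked map).
#' @export
simulate_experiment <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_sub <- config$n_subjects
  n_per_run <- n_sub / 2L
  subjects <- sprintf("S%04d", seq_len(n_sub))
  run_of_subject <- rep(c("R1", "R2"), each = n_per_run)

  ## --- accessions -----------------------------------------------------------
  planted <- names(config$depot_effects)
  extra <- setdiff(config$size_linked$accession, planted)
  named_tissue <- c(planted, extra)
  if (length(named_tissue) > config$n_tissue_proteins)
    stop("named proteins exceed n_tissue_proteins")
  n_bg <- config$n_tissue_proteins - length(named_tissue)
  tissue_acc <- c(named_tissue, sprintf("T%04d", seq_len(n_bg)))
  blood_acc <- if (config$n_blood_proteins > 0L)
    sprintf("B%04d", seq_len(config$n_blood_proteins)) else character(0)
  acc <- c(tissue_acc, blood_acc)
  n_t <- length(tissue_acc); n_b <- length(blood_acc); n_p <- n_t + n_b
  gene <- acc
  ref_idx <- match(.depot_reference$accession, acc)
  gene[ref_idx[!is.na(ref_idx)]] <- .depot_reference$gene_symbol[!is.na(ref_idx)]

  ## --- design ---------------------------------------------------------------
  tmt10 <- c("126", "127N", "127C", "128N", "128C", "129N", "129C", "130N",
             "130C", "131")
  study <- data.frame(
    sample_id = paste0(rep(subjects, each = 2L), c("-ABD", "-FEM")),
    subject_id = rep(subjects, each = 2L),
    depot = rep(c("abdominal", "femoral"), n_sub),
    run_id = rep(run_of_subject, each = 2L),
    is_control = FALSE, stringsAsFactors = FALSE)
  ctrl <- data.frame(sample_id = c("CTRL-R1", "CTRL-R2"),
                     subject_id = c("pool", "pool"), depot = "control",
                     run_id = c("R1", "R2"), is_control = TRUE,
                     stringsAsFactors = FALSE)
  design <- rbind(study, ctrl)
  chan <- function(k) if (k <= length(tmt10)) tmt10[k] else sprintf("ch%03d", k)
  design$channel_label <- unlist(lapply(c("R1", "R2"), function(r) {
    idx <- which(design$run_id == r)
    ord <- order(design$is_control[idx])  # controls last within run
    lab <- character(length(idx)); lab[ord] <- vapply(seq_along(idx), chan, "")
    lab
  }))
  design <- sample_design(design)
  study_ids <- study$sample_id
  n_study <- length(study_ids)

  ## --- draws in fixed order -------------------------------------------------
  morph <- .draw_morphology(n_sub, config$fcs_abd_mean, config$fcs_fem_mean,
                            config$fcs_abd_sd, config$fcs_fem_sd,
                            config$fcs_within_subject_rho)
  baseline_t <- 2^stats::rnorm(n_t, config$baseline_log_mean, config$baseline_log_sd)
  baseline_b <- 2^stats::rnorm(max(n_b, 1L), config$baseline_log_mean,
                               config$baseline_log_sd)[seq_len(n_b)]
  u <- matrix(stats::rnorm(n_t * n_sub, 0, config$subject_sd), n_t, n_sub,
              dimnames = list(tissue_acc, subjects))
  link_eps <- matrix(stats::rnorm(nrow(config$size_linked) * n_sub),
                     max(nrow(config$size_linked), 1L), n_sub)
  f <- stats::runif(n_study, config$blood_fraction_range[1L],
                    config$blood_fraction_range[2L])
  names(f) <- study_ids
  batch <- matrix(2^stats::rnorm(n_p * 2L, 0, config$run_effect_sd), n_p, 2L,
                  dimnames = list(acc, c("R1", "R2")))
  loading <- 2^stats::rnorm(n_study + 2L, 0, config$loading_sd)
  names(loading) <- c(study_ids, ctrl$sample_id)

  ## --- true tissue signals (pre batch/loading/noise) ------------------------
  delta <- numeric(n_t); names(delta) <- tissue_acc
  delta[names(config$depot_effects)] <- config$depot_effects
  sub_of <- match(study$subject_id, subjects)
  depot_sign <- ifelse(study$depot == "abdominal", 0.5, -0.5)
  log2T <- log2(baseline_t) + u[, sub_of, drop = FALSE] +
    outer(delta, depot_sign)
  # size-linked subject-level component (Gaussian copula on the FCS latent);
  # a "both"-depot link reflects overall adipocyte size, so it uses one
  # shared subject latent (identical in the two depots, cancelling in the
  # paired contrast); a depot-specific link uses that depot's FCS latent.
  if (nrow(config$size_linked)) {
    rho_l <- config$size_link_strength
    rho_z <- config$fcs_within_subject_rho
    z_shared <- (morph$z[, 1L] + morph$z[, 2L]) / sqrt(2 + 2 * rho_z)
    for (j in seq_len(nrow(config$size_linked))) {
      a <- config$size_linked$accession[j]
      sgn <- config$size_linked$sign[j]
      dpt <- config$size_linked$depot[j]
      for (col in seq_len(n_study)) {
        d <- study$depot[col]
        if (dpt == "both" || dpt == d) {
          zz <- if (dpt == "both") z_shared[sub_of[col]] else
            morph$z[sub_of[col], d]
          lat <- rho_l * zz + sqrt(1 - rho_l^2) * link_eps[j, sub_of[col]]
          log2T[a, col] <- log2T[a, col] + sgn * config$size_link_sd * lat
        }
      }
    }
  }
  tissue_true <- 2^log2T
  colnames(tissue_true) <- study_ids

  ## --- blood signals scaled to the drawn per-sample fraction ----------------
  if (n_b > 0L) {
    w <- baseline_b / sum(baseline_b)
    ttot <- colSums(tissue_true)
    blood_true <- outer(w, f / (1 - f) * ttot)
    dimnames(blood_true) <- list(blood_acc, study_ids)
    true <- rbind(tissue_true, blood_true)
  } else {
    true <- tissue_true
  }

  ## --- pooled control (identical in both runs, pre batch/loading) -----------
  pool <- rowMeans(true)
  true_all <- cbind(true, `CTRL-R1` = pool, `CTRL-R2` = pool)
  f_all <- c(f, `CTRL-R1` = if (n_b) sum(pool[blood_acc]) / sum(pool) else 0,
             `CTRL-R2` = if (n_b) sum(pool[blood_acc]) / sum(pool) else 0)

  ## --- batch, loading, measurement noise ------------------------------------
  run_of_sample <- design$run_id[match(colnames(true_all), design$sample_id)]
  obs <- true_all * batch[, run_of_sample] *
    rep(loading[colnames(true_all)], each = n_p)
  if (config$noise_cv > 0) {
    sdl <- sqrt(log(1 + config$noise_cv^2))
    eps <- matrix(exp(stats::rnorm(length(obs), 0, sdl) - sdl^2 / 2),
                  nrow(obs), ncol(obs))
    obs <- obs * eps
  }
  # contamination is a property of the sample, not of the measurement: pin
  # each column's realized blood share of total signal to its drawn fraction
  if (n_b > 0L) {
    bi <- (n_t + 1L):n_p
    btot <- colSums(obs[bi, , drop = FALSE])
    ttot_obs <- colSums(obs[seq_len(n_t), , drop = FALSE])
    adj <- f_all / (1 - f_all) * ttot_obs / btot
    obs[bi, ] <- sweep(obs[bi, , drop = FALSE], 2L, adj, `*`)
  }

  ## --- identification scores -------------------------------------------------
  score <- 5 + stats::rexp(n_p, rate = 1 / 20)
  if (config$score_below_threshold_fraction > 0) {
    bg <- setdiff(tissue_acc, named_tissue)
    k <- min(length(bg), round(config$score_below_threshold_fraction * n_p))
    low <- sample(bg, k)
    score[match(low, acc)] <- stats::runif(k, 0, 5 - 1e-9)
  }

  ## --- missingness -----------------------------------------------------------
  if (config$detection_limit_quantile > 0) {
    lim <- stats::quantile(obs, config$detection_limit_quantile, names = FALSE)
    obs[obs < lim] <- NA_real_
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(obs)) < config$missing_rate,
                   nrow(obs), ncol(obs))
    obs[drop] <- NA_real_
  }

  proteins <- protein_table(obs, accession = acc, score = score,
                            gene_symbol = gene, sample_id = colnames(obs))
  morphology <- morphology_table(data.frame(
    subject_id = subjects, abdominal_fcs = pmax(morph$abd, 1e-6),
    femoral_fcs = pmax(morph$fem, 1e-6), stringsAsFactors = FALSE))
  truth <- structure(
    list(depot_effect = c(delta, stats::setNames(rep(0, n_b), blood_acc)),
         blood_fraction = f_all, loading = loading, batch = batch,
         is_blood = stats::setNames(acc %in% blood_acc, acc),
         morphology_latent = morph$z, size_linked = config$size_linked,
         config = config),
    class = "simulation_truth")
  list(proteins = proteins, design = design, morphology = morphology,
       blood = blood_list(blood_acc), truth = truth)
}

#' Write the generator's per-protein ground truth as TSV
#'
#' One row per protein: accession, blood flag, true log2 depot effect, and the
#' per-run batch factors. Sample-level truth (blood fractions, loading) is
#' written alongside with suffix `_samples` when `samples = TRUE`.
#'
#' @param truth a `simulation_truth` from [simulate_experiment()].
#' @param path output TSV path.
#' @param samples also write `<path>_samples.tsv` with per-sample truth.
#' @export
truth_report <- function(truth, path, samples = FALSE) {
  stopifnot(inherits(truth, "simulation_truth"))
  df <- data.frame(accession = names(truth$depot_effect),
                   is_blood = unname(truth$is_blood),
                   true_log2_fc = unname(truth$depot_effect),
                   batch_R1 = unname(truth$batch[, "R1"]),
                   batch_R2 = unname(truth$batch[, "R2"]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (samples) {
    sf <- data.frame(sample_id = names(truth$blood_fraction),
                     blood_fraction = unname(truth$blood_fraction),
                     loading = unname(truth$loading[names(truth$blood_fraction)]),
                     stringsAsFactors = FALSE)
    utils::write.table(sf, paste0(sub("\\.tsv$", "", path), "_samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @rdname truth_report
#' @return `read_truth` returns the per-protein truth data.frame.
#' @export
read_truth <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}
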