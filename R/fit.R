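#' Fit the paired depot-comparison analysis
#'
#' Runs the full analysis on a protein quantification table and its sample
#' design, in the fixed order: identification-score filter, intra-run loading
#' normalization, inter-run normalization on the pooled control channel,
#' blood-contamination correction, half-minimum imputation, log2 transform,
#' per-protein paired differential testing with BH q-values, classical MDS of
#' sample profiles followed by the paired Hotelling T-squared global test,
#' and — when morphology is supplied — the paired fat-cell-size comparison
#' plus Spearman correlations between flagged proteins and fat cell size.
#' Flagged proteins are additionally Ward-clustered (Euclidean / ward.D) on
#' their standardized log2 values for heatmap reporting.
#'
#' @param proteins a [protein_table] of raw reporter signals.
#' @param design a [sample_design].
#' @param blood optional [blood_list]; `NULL` skips blood correction.
#' @param morphology optional [morphology_table].
#' @param min_score identification-score threshold (strict `<` removal).
#' @param inter_run `"irs"` (per-protein internal reference scaling) or
#'   `"global"` (one scalar per run).
#' @param alpha significance threshold for flagging (strict `p < alpha`).
#' @param n_components MDS components entering the Hotelling test; default
#'   `n_pairs - 1`, the maximal degrees of freedom of the paired design.
#' @return an object of class `depot_fit`; see [summary.depot_fit()].
#' @examples
#' sim <- simulate_experiment(sim_config(seed = 7))
#' fit <- depot_fit(sim$proteins, sim$design, blood = sim$blood,
#'                  morphology = sim$morphology)
#' fit
#' @export
depot_fit <- function(proteins, design, blood = NULL, morphology = NULL,
                      min_score = 5, inter_run = c("irs", "global"),
                      alpha = 0.05, n_components = NULL) {
  inter_run <- match.arg(inter_run)
  validate_protein_table(proteins)
  check_table_design(proteins, design)
  n_input <- n_proteins(proteins)

  sf <- filter_by_score(proteins, min_score = min_score)
  intra <- intra_run_normalize(sf$table, design)
  inter <- inter_run_normalize(intra$table, design, method = inter_run)
  normalized <- inter$table

  if (!is.null(blood) && length(blood)) {
    bc <- blood_correct(normalized, blood)
    corrected <- bc$corrected
  } else {
    bc <- NULL
    corrected <- normalized
  }

  log2_table <- log2_transform(impute_missing(corrected))
  differential <- differential_table(log2_table, design, alpha = alpha)

  prs <- .paired_columns(log2_table, design)
  n_pairs <- length(prs$subjects)
  if (is.null(n_components)) n_components <- n_pairs - 1L
  mds <- mds_reduce(log2_table, design, n_components)
  hotelling <- hotelling_paired(mds$scores, design,
                                n_components = n_components,
                                variance_explained = mds$variance_explained)

  morph_test <- NULL
  correlations <- NULL
  if (!is.null(morphology)) {
    morph_test <- morphology_test(morphology)
    flagged_acc <- differential$accession[differential$flagged]
    if (length(flagged_acc))
      correlations <- fatcell_correlations(log2_table, design, morphology,
                                           proteins = flagged_acc)
  }

  cluster <- NULL
  flagged_acc <- differential$accession[differential$flagged]
  if (length(flagged_acc) >= 2L) {
    study_cols <- log2_table$sample_id[
      !design$is_control[match(log2_table$sample_id, design$sample_id)]]
    z <- standardize_rows(log2_table[flagged_acc, study_cols]$signal)
    cluster <- list(matrix = z,
                    row_tree = hierarchical_cluster(z, axis = "rows"))
  }

  structure(list(
    differential = differential, hotelling = hotelling, mds = mds,
    morphology_test = morph_test, correlations = correlations,
    blood = bc, cluster = cluster,
    tables = list(normalized = normalized, corrected = corrected,
                  log2 = log2_table),
    reports = list(intra = intra$report, inter = inter$report,
                   score_removed = sf$removed),
    counts = list(n_input = n_input,
                  n_after_score = n_proteins(sf$table),
                  n_after_blood = n_proteins(corrected),
                  n_flagged = sum(differential$flagged)),
    params = list(min_score = min_score, inter_run = inter_run,
                  alpha = alpha, n_components = n_components,
                  n_pairs = n_pairs),
    call = match.call()),
    class = "depot_fit")
}

#' @export
print.depot_fit <- function(x, ...) {
  cat("Paired depot proteome comparison\n")
  cat(sprintf("  proteins: %d quantified, %d after score filter, %d analyzed after blood removal\n",
              x$counts$n_input, x$counts$n_after_score, x$counts$n_after_blood))
  if (!is.null(x$blood))
    cat(sprintf("  blood contamination: %.0f-%.0f%% of total signal (%d proteins removed)\n",
                100 * min(x$blood$blood_fraction),
                100 * max(x$blood$blood_fraction), x$blood$n_blood_removed))
  cat(sprintf("  differential (paired t, alpha = %g): %d flagged of %d\n",
              x$params$alpha, x$counts$n_flagged, x$counts$n_after_blood))
  print(x$hotelling)
  invisible(x)
}

#' Summarize a depot-comparison fit
#'
#' @param object a `depot_fit`.
#' @param n_top number of top differential proteins to display.
#' @param ... ignored.
#' @return `object`, invisibly; prints counts, the global multivariate test,
#'   the morphology comparison, and the strongest differential proteins.
#' @export
summary.depot_fit <- function(object, n_top = 10L, ...) {
  print(object)
  if (!is.null(object$morphology_test)) {
    m <- object$morphology_test
    cat(sprintf("  fat cell size: abdominal %.1f +/- %.1f vs femoral %.1f +/- %.1f um (paired p = %.3g)\n",
                m$mean_abd, m$sem_abd, m$mean_fem, m$sem_fem, m$p))
  }
  top <- utils::head(object$differential, n_top)
  cat("  top differential proteins:\n")
  print(data.frame(accession = top$accession, gene = top$gene_symbol,
                   FC = round(top$fold_change_abd_vs_fem, 3),
                   p = signif(top$p_value, 3), q = signif(top$q_value, 3)),
        row.names = FALSE)
  invisible(object)
}

#' Extract per-protein effect estimates
#'
#' @param object a `depot_fit`.
#' @param log2 return log2 fold changes (default) or linear fold changes.
#' @param ... ignored.
#' @return named numeric vector of abdominal-vs-femoral (log2) fold changes.
#' @export
coef.depot_fit <- function(object, log2 = TRUE, ...) {
  fc <- object$differential$fold_change_abd_vs_fem
  stats::setNames(if (log2) base::log2(fc) else fc,
                  object$differential$accession)
}

#' Plot a depot-comparison fit
#'
#' `which = "heatmap"` draws the standardized flagged-protein heatmap ordered
#' by the Ward dendrogram; `which = "mds"` plots the first two MDS components
#' of the sample profiles.
#'
#' @param x a `depot_fit`.
#' @param which `"heatmap"` or `"mds"`.
#' @param ... ignored.
#' @export
plot.depot_fit <- function(x, which = c("heatmap", "mds"), ...) {
  which <- match.arg(which)
  if (which == "heatmap") {
    if (is.null(x$cluster)) stop("no flagged proteins to plot")
    om <- x$cluster$matrix[x$cluster$row_tree$order, , drop = FALSE]
    lim <- max(abs(om))
    pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(255)
    graphics::image(t(om[rev(seq_len(nrow(om))), , drop = FALSE]), col = pal,
                    zlim = c(-lim, lim), axes = FALSE,
                    main = "flagged proteins (standardized log2 signal)")
  } else {
    s <- x$mds$scores
    graphics::plot(s[, 1L], s[, 2L], type = "n", xlab = "PC1", ylab = "PC2",
                   main = "classical MDS of sample profiles")
    graphics::text(s[, 1L], s[, 2L], labels = rownames(s), cex = 0.7)
  }
  invisible(x)
}

#' Run the full pipeline and write all artifacts
#'
#' Orchestrates simulate (optional) -> normalize -> blood-correct -> stats ->
#' report as one reproducible run. Inputs are either file paths or a
#' [sim_config] for a self-generated run; every intermediate table is written
#' to `out_dir` together with a machine-readable `summary.json`.
#'
#' @param out_dir output directory (created if absent).
#' @param proteins,design,blood,morphology file paths to TSV inputs, or the
#'   corresponding objects; all ignored when `sim` is given.
#' @param sim optional [sim_config]: simulate the experiment and use it as
#'   input (the simulated inputs and ground truth are also written).
#' @param min_score,inter_run,alpha,n_components passed to [depot_fit()].
#' @param write_png also render PNG figures (blood fractions, heatmap).
#' @param quiet suppress progress messages.
#' @return the `depot_fit`, invisibly; side effect: artifacts in `out_dir`.
#' @export
run_pipeline <- function(out_dir, proteins = NULL, design = NULL,
                         blood = NULL, morphology = NULL, sim = NULL,
                         min_score = 5, inter_run = "irs", alpha = 0.05,
                         n_components = NULL, write_png = FALSE,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim)) {
    say("simulating experiment (seed ", sim$seed, ")")
    s <- simulate_experiment(sim)
    proteins <- s$proteins; design <- s$design
    blood <- s$blood; morphology <- s$morphology
    write_protein_table(proteins, file.path(out_dir, "proteins.tsv"))
    write_design(design, file.path(out_dir, "design.tsv"))
    write_blood_list(blood, file.path(out_dir, "bloodlist.txt"))
    write_morphology(morphology, file.path(out_dir, "morphology.tsv"))
    truth_report(s$truth, file.path(out_dir, "truth.tsv"), samples = TRUE)
  } else {
    if (is.character(proteins)) proteins <- read_protein_table(proteins)
    if (is.character(design)) design <- read_design(design)
    if (is.character(blood)) blood <- read_blood_list(blood)
    if (is.character(morphology)) morphology <- read_morphology(morphology)
    if (is.null(proteins) || is.null(design))
      stop("need proteins and design (or a sim config)")
  }
  say("fitting: score filter / normalization (", inter_run,
      ") / blood correction / paired statistics")
  fit <- depot_fit(proteins, design, blood = blood, morphology = morphology,
                   min_score = min_score, inter_run = inter_run,
                   alpha = alpha, n_components = n_components)

  write_protein_table(fit$tables$normalized, file.path(out_dir, "normalized.tsv"))
  write_protein_table(fit$tables$corrected, file.path(out_dir, "corrected.tsv"))
  utils::write.table(as.data.frame(fit$differential),
                     file.path(out_dir, "differential.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(fit$blood))
    blood_fraction_report(
      fit$blood, file.path(out_dir, "blood_fractions.tsv"),
      plot_path = if (write_png) file.path(out_dir, "blood_fractions.png"))
  if (!is.null(fit$correlations))
    utils::write.table(fit$correlations,
                       file.path(out_dir, "correlations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(fit$cluster))
    heatmap_export(fit$cluster$matrix, fit$cluster$row_tree,
                   path_tsv = file.path(out_dir, "heatmap_matrix.tsv"),
                   path_newick = file.path(out_dir, "protein_dendrogram.nwk"),
                   path_png = if (write_png) file.path(out_dir, "heatmap.png"))
  ht <- fit$hotelling
  jsonlite::write_json(
    list(T2 = ht$T2, F = ht$F, df1 = ht$df1, df2 = ht$df2,
         p_value = ht$p_value, variance_explained = ht$variance_explained),
    file.path(out_dir, "hotelling.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(fit$morphology_test))
    jsonlite::write_json(fit$morphology_test,
                         file.path(out_dir, "morphology.json"),
                         auto_unbox = TRUE, digits = NA)
  summary_list <- list(
    n_proteins_identified = fit$counts$n_input,
    n_after_score_filter = fit$counts$n_after_score,
    n_after_blood_removal = fit$counts$n_after_blood,
    n_flagged = fit$counts$n_flagged,
    blood_fraction = if (!is.null(fit$blood)) as.list(fit$blood$blood_fraction),
    hotelling = list(T2 = ht$T2, p_value = ht$p_value,
                     variance_explained = ht$variance_explained),
    morphology = fit$morphology_test,
    params = fit$params)
  jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  say("wrote artifacts to ", out_dir)
  invisible(fit)
}
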