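#' Filter proteins by identification score
#'
#' Removes low-quality identifications: proteins with score strictly below
#' `min_score` are dropped (a score exactly at the threshold is kept), with
#' row order otherwise preserved.
#'
#' @param table a [protein_table].
#' @param min_score score threshold (default 5, the Sequest HT convention).
#' @return list with `table` (filtered [protein_table]) and `removed`
#'   (accessions dropped).
#' @export
filter_by_score <- function(table, min_score = 5) {
  validate_protein_table(table)
  keep <- table$score >= min_score
  list(table = table[keep, ], removed = table$accession[!keep])
}

#' Intra-run loading normalization
#'
#' Equalizes total protein signal within each LC-MS run: every sample's
#' signals are multiplied by (highest per-sample total in its run) / (its own
#' total), so all samples in a run end with the same total as the highest one.
#' Totals are computed over present (non-missing) values; missing stays
#' missing.
#'
#' @param table a [protein_table].
#' @param design a [sample_design] assigning each sample to a run.
#' @return list with `table` (normalized) and `report` (a
#'   `normalization_report` holding the per-sample scale factors).
#' @export
intra_run_normalize <- function(table, design) {
  validate_protein_table(table)
  check_table_design(table, design)
  totals <- colSums(table$signal, na.rm = TRUE)
  zero <- names(totals)[totals == 0]
  if (length(zero))
    stop("sample with zero total signal: ", zero[1L])
  run <- design$run_id[match(table$sample_id, design$sample_id)]
  factors <- numeric(length(totals)); names(factors) <- table$sample_id
  for (r in unique(run)) {
    in_run <- run == r
    factors[in_run] <- max(totals[in_run]) / totals[in_run]
  }
  out <- table
  out$signal <- sweep(table$signal, 2L, factors, `*`)
  report <- structure(list(intra_run_factors = factors,
                           inter_run_flagged = character(0),
                           score_removed = character(0)),
                      class = "normalization_report")
  list(table = validate_protein_table(out), report = report)
}

#' Inter-run normalization on the pooled control channel
#'
#' Removes per-protein run-to-run (batch) variation using the identical
#' pooled control sample carried in every run. Two modes:
#'
#' * `"irs"` (default, internal reference scaling): per protein, the reference
#'   is the geometric mean of the control values across runs in which the
#'   control is present; every sample in run k has that protein multiplied by
#'   reference / control value in run k. Afterwards the control values of
#'   each such protein are equal across runs. Proteins missing (or zero, with
#'   a warning) in a run's control are left unchanged in that run and flagged.
#' * `"global"`: a single scalar per run — the geometric mean of control
#'   totals divided by that run's control total — rescales all proteins alike.
#'
#' Apply after [intra_run_normalize()].
#'
#' @param table a [protein_table].
#' @param design a [sample_design]; each run must have exactly one control.
#' @param method `"irs"` or `"global"`.
#' @return list with `table` and `report` (`normalization_report` with the
#'   per-run/per-protein factors and flagged proteins).
#' @export
inter_run_normalize <- function(table, design, method = c("irs", "global")) {
  method <- match.arg(method)
  validate_protein_table(table)
  check_table_design(table, design)
  d <- design[match(table$sample_id, design$sample_id), , drop = FALSE]
  runs <- unique(d$run_id)
  ctrl_ids <- vapply(runs, function(r) {
    id <- d$sample_id[d$run_id == r & d$is_control]
    if (length(id) != 1L) stop("run '", r, "' must have exactly one control sample")
    id
  }, "")
  ctrl <- table$signal[, ctrl_ids, drop = FALSE]  # proteins x runs
  colnames(ctrl) <- runs
  if (any(!is.na(ctrl) & ctrl == 0)) {
    warning("control value 0 treated as missing for inter-run normalization")
    ctrl[!is.na(ctrl) & ctrl == 0] <- NA_real_
  }
  out <- table
  if (method == "global") {
    tot <- colSums(ctrl, na.rm = TRUE)
    ref <- exp(mean(log(tot)))
    fac <- ref / tot
    for (r in runs)
      out$signal[, d$run_id == r] <- out$signal[, d$run_id == r, drop = FALSE] * fac[r]
    report <- structure(list(inter_run_factors = fac,
                             inter_run_flagged = character(0)),
                        class = "normalization_report")
    return(list(table = validate_protein_table(out), report = report))
  }
  ref <- exp(rowMeans(log(ctrl), na.rm = TRUE))  # geometric mean over present runs
  fac <- ref / ctrl                              # proteins x runs; NA where absent
  flagged <- table$accession[apply(is.na(ctrl), 1L, any)]
  for (r in runs) {
    fr <- fac[, r]
    fr[is.na(fr)] <- 1   # protein absent from this run's control: untouched
    cols <- d$run_id == r
    out$signal[, cols] <- out$signal[, cols, drop = FALSE] * fr
  }
  report <- structure(list(inter_run_factors = fac,
                           inter_run_flagged = flagged),
                      class = "normalization_report")
  list(table = validate_protein_table(out), report = report)
}

#' @export
print.normalization_report <- function(x, ...) {
  if (!is.null(x$intra_run_factors))
    cat("intra-run scale factors:",
        paste(sprintf("%.3g", x$intra_run_factors), collapse = " "), "\n")
  if (!is.null(x$inter_run_flagged))
    cat(length(x$inter_run_flagged),
        "protein(s) flagged (absent from a run's control)\n")
  invisible(x)
}
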