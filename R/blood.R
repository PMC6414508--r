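#' Correct tissue signals for blood-protein contamination
#'
#' Adipose-tissue biopsies carry residual blood; its proteins inflate the
#' denominator of every relative quantification. Given an exclusion list of
#' blood-specific proteins, each retained (non-blood) protein value is
#' rescaled to the abundance it would have in a blood-free sample:
#'
#' \deqn{final_{x,i} = normalized_{x,i} \cdot
#'   \frac{\sum_x normalized_{x,i}}{\sum_x normalized_{x,i} - \sum_{blood}
#'   normalized_{x,i}}}
#'
#' Blood-listed proteins are removed from the output; their contribution
#' survives only in the per-sample blood fraction. Sums run over present
#' (non-missing) values. The correction conserves each sample's total signal
#' and preserves all within-sample ratios among retained proteins.
#'
#' @param table a normalized [protein_table].
#' @param blood a [blood_list] of accessions treated as blood-specific.
#' @return object of class `blood_correction`: list with `corrected`
#'   ([protein_table] without blood proteins), `blood_fraction` (named
#'   per-sample share of total signal attributed to blood, in `[0,1)`),
#'   `n_blood_removed`, and `factors` (the per-sample rescaling factors).
#' @export
blood_correct <- function(table, blood) {
  validate_protein_table(table)
  is_blood <- table$accession %in% as.character(blood)
  total <- colSums(table$signal, na.rm = TRUE)
  blood_total <- if (any(is_blood))
    colSums(table$signal[is_blood, , drop = FALSE], na.rm = TRUE)
  else stats::setNames(rep(0, n_samples(table)), table$sample_id)
  bad <- which(blood_total >= total & total > 0)
  if (length(bad))
    stop("blood signal >= total signal for sample '",
         table$sample_id[bad[1L]], "': correction undefined")
  factors <- total / (total - blood_total)
  corrected <- table[!is_blood, ]
  corrected$signal <- sweep(corrected$signal, 2L, factors, `*`)
  structure(list(corrected = validate_protein_table(corrected),
                 blood_fraction = blood_total / total,
                 n_blood_removed = sum(is_blood),
                 factors = factors),
            class = "blood_correction")
}

#' @export
print.blood_correction <- function(x, ...) {
  cat(sprintf("blood correction: %d blood protein(s) removed; blood fraction %0.1f%%-%0.1f%% of total signal\n",
              x$n_blood_removed, 100 * min(x$blood_fraction),
              100 * max(x$blood_fraction)))
  invisible(x)
}

#' Per-sample signal composition report
#'
#' Writes a TSV decomposing each sample's total signal into tissue and blood
#' percentages (summing to 100), in the style of a stacked-bar contamination
#' figure; optionally draws the figure.
#'
#' @param result a `blood_correction` from [blood_correct()].
#' @param path output TSV path.
#' @param plot_path optional PNG path for a stacked-bar figure.
#' @return invisibly, the report data.frame.
#' @export
blood_fraction_report <- function(result, path, plot_path = NULL) {
  stopifnot(inherits(result, "blood_correction"))
  df <- data.frame(sample_id = names(result$blood_fraction),
                   tissue_pct = 100 * (1 - result$blood_fraction),
                   blood_pct = 100 * result$blood_fraction,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 900, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    m <- t(as.matrix(df[, c("blood_pct", "tissue_pct")]))
    colnames(m) <- df$sample_id
    graphics::barplot(m, col = c("firebrick", "grey75"), las = 2,
                      ylab = "% of total signal",
                      legend.text = c("blood", "tissue"))
  }
  invisible(df)
}
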