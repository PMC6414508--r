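#' Half-minimum imputation of missing values
#'
#' Every missing cell is replaced by half of the smallest positive signal in
#' the whole dataset (one global value, not per sample or per protein);
#' present values are untouched.
#'
#' @param table a [protein_table].
#' @return the imputed [protein_table].
#' @export
impute_missing <- function(table) {
  validate_protein_table(table)
  pos <- table$signal[!is.na(table$signal) & table$signal > 0]
  if (!length(pos)) stop("no positive signal anywhere: cannot impute")
  table$signal[is.na(table$signal)] <- min(pos) / 2
  table
}

#' Log2-transform all signals
#'
#' @param table a [protein_table] with strictly positive values (impute
#'   first).
#' @return the transformed [protein_table].
#' @export
log2_transform <- function(table) {
  validate_protein_table(table)
  if (any(is.na(table$signal)) || any(table$signal <= 0))
    stop("log2 transform requires all values present and > 0 (impute first)")
  table$signal <- log2(table$signal)
  table$scale <- "log2"
  table
}

#' Two-sided paired Student's t-test
#'
#' Tests the mean of the paired differences `abd - fem` against zero.
#' Degenerate pairs are handled explicitly: if all differences are identical
#' and zero, t = 0 and p = 1; if identical but nonzero the statistic is
#' undefined and a missing p is returned with a warning (an undefined
#' statistic must not masquerade as significance).
#'
#' @param abd,fem equal-length paired numeric vectors (log2 scale).
#' @return list with `t`, `df`, `p`, `n`.
#' @export
paired_t_test <- function(abd, fem) {
  stopifnot(length(abd) == length(fem), length(abd) >= 2L)
  d <- abd - fem
  if (anyNA(d)) stop("missing values in paired differences")
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = length(d) - 1L, p = 1, n = length(d)))
    warning("zero variance with nonzero mean difference: p undefined")
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_, n = length(d)))
  }
  ht <- stats::t.test(d)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, n = length(d))
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up adjusted p-values `q_(i) = min_(j>=i) p_(j) * m / j`, capped at 1,
#' mapped back to input order; missing p-values propagate as missing and do
#' not count toward m.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return numeric vector of q-values, same length and order.
#' @export
fdr_qvalues <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Geometric-mean paired fold change (ABD vs FEM)
#'
#' `2^mean(log2(abd) - log2(fem))`: the geometric mean of the per-subject
#' abdominal/femoral ratios. Values below 1 mean higher femoral abundance.
#'
#' @param abd,fem positive linear-scale paired vectors.
#' @return positive scalar fold change.
#' @export
fold_change <- function(abd, fem) {
  stopifnot(length(abd) == length(fem))
  if (any(abd <= 0) || any(fem <= 0)) stop("fold change requires positive values")
  2^mean(log2(abd) - log2(fem))
}

#' Per-protein paired differential expression
#'
#' For every protein: the paired t-test on log2 values across subjects
#' (abdominal vs femoral, paired within subject), the geometric-mean fold
#' change, and BH q-values across all proteins. Proteins with p below `alpha`
#' are flagged as (tending to be) differentially expressed.
#'
#' @param table an imputed, log2-transformed [protein_table].
#' @param design a [sample_design]; control samples are excluded.
#' @param alpha flagging threshold on the unadjusted p-value (default 0.05,
#'   strict `<`).
#' @return a `depot_differential` data.frame with columns `accession`,
#'   `gene_symbol`, `fold_change_abd_vs_fem`, `p_value`, `q_value`, `n_pairs`,
#'   `flagged`, sorted by p then accession.
#' @export
differential_table <- function(table, design, alpha = 0.05) {
  validate_protein_table(table)
  check_table_design(table, design)
  prs <- .paired_columns(table, design)
  la <- table$signal[, prs$abd, drop = FALSE]
  lf <- table$signal[, prs$fem, drop = FALSE]
  n <- length(prs$abd)
  res <- lapply(seq_len(n_proteins(table)), function(i) {
    tt <- paired_t_test(la[i, ], lf[i, ])
    c(fc = 2^mean(la[i, ] - lf[i, ]), p = tt$p, n = tt$n)
  })
  res <- do.call(rbind, res)
  out <- data.frame(accession = table$accession,
                    gene_symbol = table$gene_symbol,
                    fold_change_abd_vs_fem = res[, "fc"],
                    p_value = res[, "p"],
                    q_value = fdr_qvalues(res[, "p"]),
                    n_pairs = as.integer(res[, "n"]),
                    stringsAsFactors = FALSE)
  out$flagged <- !is.na(out$p_value) & out$p_value < alpha
  out <- out[order(out$p_value, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("depot_differential", "data.frame")
  out
}

# Match each subject's abdominal and femoral sample columns, in a stable
# subject order; errors if any subject lacks a depot in the table.
.paired_columns <- function(table, design) {
  d <- design[match(table$sample_id, design$sample_id), , drop = FALSE]
  study <- d[!d$is_control, , drop = FALSE]
  subjects <- unique(study$subject_id)
  abd <- fem <- character(length(subjects))
  for (i in seq_along(subjects)) {
    rows <- study[study$subject_id == subjects[i], , drop = FALSE]
    a <- rows$sample_id[rows$depot == "abdominal"]
    f <- rows$sample_id[rows$depot == "femoral"]
    if (length(a) != 1L || length(f) != 1L)
      stop("subject '", subjects[i], "' lacks a complete abdominal/femoral pair")
    abd[i] <- a; fem[i] <- f
  }
  list(subjects = subjects, abd = abd, fem = fem)
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of midranks. The two-sided p-value uses the
#' exact permutation null for n <= `exact_max` when the data are tie-free
#' (the small-cohort case), and the t-approximation otherwise.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @param exact_max largest n for which the exact null is used.
#' @return list with `rho`, `p`, `n`, `method` (`"exact"` or `"approx"`).
#' @export
spearman_correlation <- function(x, y, exact_max = 9L) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation input")
  n <- length(x)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    warning("zero rank variance: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  ties <- anyDuplicated(x) || anyDuplicated(y)
  use_exact <- !ties && n <= exact_max
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = use_exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       method = if (use_exact) "exact" else "approx")
}

#' Correlate protein expression with fat cell size, per depot
#'
#' For each requested protein and each depot, Spearman correlation between
#' the protein's per-subject signal in that depot and the subject's fat cell
#' size in the same depot.
#'
#' @param table a [protein_table] (any monotone scale; rank-based).
#' @param design a [sample_design].
#' @param morphology a [morphology_table] covering the design's subjects.
#' @param proteins accessions to test (default: all in `table`).
#' @return data.frame with `accession`, `depot`, `rho`, `p_value`, `n`.
#' @export
fatcell_correlations <- function(table, design, morphology,
                                 proteins = table$accession) {
  validate_protein_table(table)
  prs <- .paired_columns(table, design)
  midx <- match(prs$subjects, morphology$subject_id)
  if (anyNA(midx))
    stop("subjects missing from morphology: ",
         paste(prs$subjects[is.na(midx)], collapse = ", "))
  fcs <- list(abdominal = morphology$abdominal_fcs[midx],
              femoral = morphology$femoral_fcs[midx])
  cols <- list(abdominal = prs$abd, femoral = prs$fem)
  rows <- list()
  for (acc in proteins) {
    i <- match(acc, table$accession)
    if (is.na(i)) stop("unknown accession: ", acc)
    for (depot in c("abdominal", "femoral")) {
      v <- table$signal[i, cols[[depot]]]
      if (anyNA(v)) next
      sc <- spearman_correlation(v, fcs[[depot]])
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, depot = depot, rho = sc$rho, p_value = sc$p,
        n = sc$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(accession = character(0), depot = character(0),
                      rho = numeric(0), p_value = numeric(0), n = integer(0))
  out
}

#' Paired comparison of depot fat cell sizes
#'
#' Per-depot mean and SEM of fat cell size plus the two-sided paired t-test
#' abdominal vs femoral.
#'
#' @param morphology a [morphology_table].
#' @return list with `mean_abd`, `sem_abd`, `mean_fem`, `sem_fem`, `t`, `df`,
#'   `p`, `n`.
#' @export
morphology_test <- function(morphology) {
  stopifnot(nrow(morphology) >= 2L)
  a <- morphology$abdominal_fcs
  f <- morphology$femoral_fcs
  tt <- paired_t_test(a, f)
  n <- length(a)
  list(mean_abd = mean(a), sem_abd = stats::sd(a) / sqrt(n),
       mean_fem = mean(f), sem_fem = stats::sd(f) / sqrt(n),
       t = tt$t, df = tt$df, p = tt$p, n = n)
}
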