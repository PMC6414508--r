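#' Construct a protein quantification table
#'
#' A `protein_table` holds protein-level reporter signals (summed reporter-ion
#' S/N per protein) for a set of samples, together with per-protein metadata:
#' the accession (primary key), an optional display gene symbol, and the
#' database-search identification score used for quality filtering.
#'
#' Missing quantifications are a distinct state, stored as `NA`; a zero is a
#' present measurement and is rejected only where an operation requires
#' positivity (e.g. the log2 transform).
#'
#' @param signal numeric matrix, proteins x samples. Non-missing entries must
#'   be finite and >= 0; `NA` marks missing values.
#' @param accession character vector of unique protein accessions, one per row.
#' @param score numeric vector of nonnegative identification scores
#'   (Sequest HT-style), one per protein.
#' @param gene_symbol optional character vector of display labels; defaults to
#'   the accession.
#' @param sample_id character vector of unique sample identifiers, one per
#'   column.
#' @param scale `"linear"` (reporter signals, nonnegative) or `"log2"`
#'   (transformed values, any sign).
#' @return An object of class `protein_table`: a list with elements
#'   `signal` (matrix with accession rownames and sample colnames),
#'   `accession`, `gene_symbol`, `score`, `sample_id`, `scale`.
#' @examples
#' pt <- protein_table(matrix(c(1, 2, NA, 4), 2, 2),
#'                     accession = c("P1", "P2"), score = c(10, 7),
#'                     sample_id = c("s1", "s2"))
#' n_proteins(pt)
#' @export
protein_table <- function(signal, accession, score,
                          gene_symbol = accession, sample_id = colnames(signal),
                          scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  accession <- as.character(accession)
  sample_id <- as.character(sample_id)
  if (is.null(sample_id)) stop("sample_id is required (no column names found)")
  rownames(signal) <- accession
  colnames(signal) <- sample_id
  x <- structure(
    list(signal = signal, accession = accession,
         gene_symbol = as.character(gene_symbol),
         score = as.numeric(score), sample_id = sample_id, scale = scale),
    class = "protein_table")
  validate_protein_table(x)
}

#' @rdname protein_table
#' @param x object to validate or query.
#' @export
validate_protein_table <- function(x) {
  stopifnot(inherits(x, "protein_table"))
  n <- length(x$accession)
  if (anyDuplicated(x$accession)) {
    dup <- x$accession[duplicated(x$accession)][1L]
    stop("duplicate accession: ", dup)
  }
  if (anyDuplicated(x$sample_id)) {
    stop("duplicate sample_id: ", x$sample_id[duplicated(x$sample_id)][1L])
  }
  if (nrow(x$signal) != n || ncol(x$signal) != length(x$sample_id))
    stop("signal matrix dimensions do not match accession/sample lists")
  if (length(x$gene_symbol) != n) stop("gene_symbol length mismatch")
  if (length(x$score) != n) stop("score length mismatch")
  present <- !is.na(x$signal)
  if (any(!is.finite(x$signal[present])))
    stop("non-finite signal value present")
  if (is.null(x$scale)) x$scale <- "linear"
  if (x$scale == "linear" && any(x$signal[present] < 0)) {
    idx <- which(x$signal < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative signal for protein '%s', sample '%s'",
                 x$accession[idx[1L]], x$sample_id[idx[2L]]))
  }
  if (length(x$score) && any(!is.na(x$score) & x$score < 0))
    stop("negative identification score")
  x
}

#' @rdname protein_table
#' @export
n_proteins <- function(x) length(x$accession)

#' @rdname protein_table
#' @export
n_samples <- function(x) length(x$sample_id)

#' Subset a protein table by protein and/or sample
#'
#' @param x a `protein_table`.
#' @param i protein index (logical, integer, or accession character vector).
#' @param j sample index (logical, integer, or sample_id character vector).
#' @param ... ignored.
#' @return a `protein_table` with the selected rows/columns.
#' @export
`[.protein_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$accession)
  if (missing(j)) j <- seq_along(x$sample_id)
  if (is.character(i)) i <- match(i, x$accession)
  if (is.character(j)) j <- match(j, x$sample_id)
  if (anyNA(i)) stop("unknown accession in subset")
  if (anyNA(j)) stop("unknown sample_id in subset")
  protein_table(x$signal[i, j, drop = FALSE],
                accession = x$accession[i], score = x$score[i],
                gene_symbol = x$gene_symbol[i], sample_id = x$sample_id[j],
                scale = if (is.null(x$scale)) "linear" else x$scale)
}

#' @export
print.protein_table <- function(x, ...) {
  cat(sprintf("protein_table: %d proteins x %d samples (%d missing values)\n",
              n_proteins(x), n_samples(x), sum(is.na(x$signal))))
  invisible(x)
}

#' @export
dim.protein_table <- function(x) dim(x$signal)

#' Validate a sample design table
#'
#' The design describes the two-run TMT layout: every non-control subject
#' contributes one abdominal and one femoral sample, both multiplexed in the
#' same LC-MS run, and every run carries exactly one pooled control channel
#' (an identical mixture of all study samples, the inter-run bridge).
#'
#' @param design data.frame with columns `sample_id`, `subject_id`, `depot`
#'   (one of `"abdominal"`, `"femoral"`, `"control"`), `run_id`,
#'   `channel_label`, `is_control` (logical).
#' @return the validated design (class `sample_design`, a data.frame).
#' @export
sample_design <- function(design) {
  req <- c("sample_id", "subject_id", "depot", "run_id", "channel_label",
           "is_control")
  miss <- setdiff(req, names(design))
  if (length(miss)) stop("design missing columns: ", paste(miss, collapse = ", "))
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  design$sample_id <- as.character(design$sample_id)
  design$subject_id <- as.character(design$subject_id)
  design$depot <- as.character(design$depot)
  design$run_id <- as.character(design$run_id)
  design$is_control <- as.logical(design$is_control)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design: ",
         design$sample_id[duplicated(design$sample_id)][1L])
  bad <- setdiff(unique(design$depot), c("abdominal", "femoral", "control"))
  if (length(bad)) stop("unknown depot label: ", bad[1L])
  if (any(design$is_control != (design$depot == "control")))
    stop("is_control flag inconsistent with depot == 'control'")
  # one control per run
  for (r in unique(design$run_id)) {
    nctrl <- sum(design$is_control & design$run_id == r)
    if (nctrl != 1L)
      stop(sprintf("run '%s' has %d control samples (expected exactly 1)", r, nctrl))
  }
  # paired-within-run structure for study subjects
  study <- design[!design$is_control, , drop = FALSE]
  for (s in unique(study$subject_id)) {
    rows <- study[study$subject_id == s, , drop = FALSE]
    if (nrow(rows) != 2L || !setequal(rows$depot, c("abdominal", "femoral")))
      stop(sprintf("subject '%s' must appear exactly twice, once per depot", s))
    if (length(unique(rows$run_id)) != 1L)
      stop(sprintf("subject '%s' is split across runs", s))
  }
  class(design) <- c("sample_design", "data.frame")
  design
}

#' Check that a protein table and a design refer to the same samples
#'
#' @param table a `protein_table`.
#' @param design a `sample_design`.
#' @return invisibly `TRUE`; errors if any table sample is absent from the
#'   design.
#' @export
check_table_design <- function(table, design) {
  missing_ids <- setdiff(table$sample_id, design$sample_id)
  if (length(missing_ids))
    stop("samples absent from design: ", paste(missing_ids, collapse = ", "))
  invisible(TRUE)
}

#' Validate a per-subject adipocyte morphology table
#'
#' @param morph data.frame with columns `subject_id`, `abdominal_fcs`,
#'   `femoral_fcs` (mean fat cell diameters in micrometers).
#' @return the validated table (class `morphology_table`).
#' @export
morphology_table <- function(morph) {
  req <- c("subject_id", "abdominal_fcs", "femoral_fcs")
  miss <- setdiff(req, names(morph))
  if (length(miss)) stop("morphology missing columns: ", paste(miss, collapse = ", "))
  morph <- as.data.frame(morph, stringsAsFactors = FALSE)
  morph$subject_id <- as.character(morph$subject_id)
  if (anyDuplicated(morph$subject_id))
    stop("duplicate subject in morphology: ",
         morph$subject_id[duplicated(morph$subject_id)][1L])
  if (any(!is.finite(morph$abdominal_fcs)) || any(!is.finite(morph$femoral_fcs)) ||
      any(morph$abdominal_fcs <= 0) || any(morph$femoral_fcs <= 0))
    stop("fat cell sizes must be finite and strictly positive")
  class(morph) <- c("morphology_table", "data.frame")
  morph
}

#' Validate a blood-protein exclusion list
#'
#' @param accessions character vector of accessions treated as blood-specific.
#' @return character vector of class `blood_list` (unique, no empties).
#' @export
blood_list <- function(accessions) {
  accessions <- unique(as.character(accessions))
  accessions <- accessions[nzchar(accessions)]
  structure(accessions, class = "blood_list")
}
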