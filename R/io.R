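#' Read a protein quantification table from TSV
#'
#' Ingests a Proteome Discoverer-style protein-level export: a UTF-8
#' tab-separated file whose header names `accession`, `gene_symbol` (optional),
#' `score`, and then one column per sample. Empty cells and any string in
#' `missing_tokens` map to the missing state.
#'
#' @param path file path.
#' @param missing_tokens strings (besides the empty cell) to treat as missing.
#' @return a [protein_table].
#' @export
read_protein_table <- function(path, missing_tokens = c("NA", "NaN")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "", fileEncoding = "UTF-8")
  if (!"accession" %in% names(raw)) stop("missing 'accession' column in ", path)
  if (!"score" %in% names(raw)) stop("missing 'score' column in ", path)
  meta_cols <- intersect(c("accession", "gene_symbol", "score"), names(raw))
  sample_cols <- setdiff(names(raw), meta_cols)
  if (!length(sample_cols)) stop("no sample columns in ", path)
  acc <- raw$accession
  if (anyDuplicated(acc))
    stop("duplicate accession: ", acc[duplicated(acc)][1L])
  parse_num <- function(v, col, allow_missing) {
    miss <- v == "" | v %in% missing_tokens
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!miss & is.na(out))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   v[bad[1L]], col, bad[1L]))
    if (!allow_missing && any(miss))
      stop(sprintf("missing value not allowed in column '%s'", col))
    out[miss] <- NA_real_
    out
  }
  sig <- vapply(sample_cols, function(cn) parse_num(raw[[cn]], cn, TRUE),
                numeric(nrow(raw)))
  sig <- matrix(sig, nrow = nrow(raw), ncol = length(sample_cols),
                dimnames = list(acc, sample_cols))
  protein_table(sig, accession = acc,
                score = parse_num(raw$score, "score", FALSE),
                gene_symbol = if ("gene_symbol" %in% names(raw)) raw$gene_symbol else acc,
                sample_id = sample_cols)
}

#' Write a protein table as TSV
#'
#' Columns are `accession`, `gene_symbol`, `score`, then the samples in table
#' order; missing values are written as empty cells; signals are written with
#' full precision so a round trip reproduces values exactly.
#'
#' @param table a [protein_table].
#' @param path output file path.
#' @export
write_protein_table <- function(table, path) {
  validate_protein_table(table)
  fmt <- function(v) ifelse(is.na(v), "", format(v, digits = 17, trim = TRUE,
                                                 scientific = FALSE))
  sig <- apply(table$signal, 2L, fmt)
  if (n_proteins(table) == 0L)
    sig <- matrix(character(0), 0L, n_samples(table))
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = n_proteins(table))
  df <- data.frame(accession = table$accession, gene_symbol = table$gene_symbol,
                   score = fmt(table$score), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(sig, stringsAsFactors = FALSE))
  names(df) <- c("accession", "gene_symbol", "score", table$sample_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample design table from TSV
#'
#' Expected header: `sample_id`, `subject_id`, `depot`, `run_id`,
#' `channel_label`, `is_control`. Validation enforces the paired-within-run
#' two-run layout (see [sample_design]).
#'
#' @param path file path.
#' @return a [sample_design].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  if (is.character(df$is_control))
    df$is_control <- toupper(df$is_control) %in% c("TRUE", "T", "1", "YES")
  sample_design(df)
}

#' @rdname read_design
#' @param design a `sample_design` to write.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a blood-protein exclusion list
#'
#' One accession per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @return a [blood_list].
#' @export
read_blood_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  blood_list(lines[nzchar(lines)])
}

#' @rdname read_blood_list
#' @param blood a `blood_list` to write.
#' @export
write_blood_list <- function(blood, path) {
  writeLines(as.character(blood), path)
  invisible(path)
}

#' Read a per-subject morphology (fat cell size) table from TSV
#'
#' Expected header: `subject_id`, `abdominal_fcs`, `femoral_fcs` (micrometers).
#'
#' @param path file path.
#' @return a [morphology_table].
#' @export
read_morphology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  morphology_table(df)
}

#' @rdname read_morphology
#' @param morph a `morphology_table` to write.
#' @export
write_morphology <- function(morph, path) {
  utils::write.table(as.data.frame(morph), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
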