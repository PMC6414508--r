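#' Standardize protein rows to z-scores
#'
#' Each protein row is mean-centered and divided by its standard deviation.
#' Constant rows (sd 0) cannot be standardized; they are dropped with a
#' warning naming them.
#'
#' @param table a [protein_table] or a numeric matrix (proteins in rows).
#' @return numeric matrix of standardized scores, same dimnames, constant
#'   rows removed.
#' @export
standardize_rows <- function(table) {
  m <- if (inherits(table, "protein_table")) table$signal else as.matrix(table)
  if (anyNA(m)) stop("standardize_rows requires a complete matrix")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant row(s): ",
            paste(rownames(m)[sds == 0], collapse = ", "))
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (m - rowMeans(m)) / sds
}

#' Agglomerative hierarchical clustering (Euclidean / ward.D)
#'
#' Euclidean distances with the ward.D linkage update — Ward's criterion
#' applied through the Lance-Williams recurrence to the *unsquared* input
#' distances (the `hclust(method = "ward.D")` convention; merge heights can
#' differ from implementations that square distances first). Ties break on
#' the smallest cluster index.
#'
#' @param x numeric matrix; rows are the items to cluster.
#' @param axis cluster `"rows"` (proteins, default) or `"cols"` (samples).
#' @return an object of class `hclust`.
#' @export
hierarchical_cluster <- function(x, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  x <- as.matrix(x)
  if (axis == "cols") x <- t(x)
  if (anyNA(x) || any(!is.finite(x))) stop("matrix contains NA/NaN/Inf")
  if (nrow(x) < 2L) stop("need at least 2 items to cluster")
  stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D")
}

#' Export a clustered heatmap
#'
#' Writes the standardized matrix reordered by the dendrogram leaf orders as
#' TSV (for headless inspection and testing), the row dendrogram in Newick
#' format, and optionally a PNG heatmap with a symmetric diverging palette.
#'
#' @param m standardized numeric matrix (proteins x samples).
#' @param row_tree `hclust` over the rows (or NULL to keep input order).
#' @param col_tree optional `hclust` over the columns (default NULL: keep
#'   input column order).
#' @param path_tsv output path for the ordered matrix TSV.
#' @param path_newick optional output path for the row dendrogram in Newick.
#' @param path_png optional output path for the rendered heatmap.
#' @return invisibly, the reordered matrix.
#' @export
heatmap_export <- function(m, row_tree = NULL, col_tree = NULL,
                           path_tsv, path_newick = NULL, path_png = NULL) {
  m <- as.matrix(m)
  ri <- if (is.null(row_tree)) seq_len(nrow(m)) else row_tree$order
  ci <- if (is.null(col_tree)) seq_len(ncol(m)) else col_tree$order
  if (!is.null(row_tree) && length(ri) != nrow(m))
    stop("row tree inconsistent with matrix")
  if (!is.null(col_tree) && length(ci) != ncol(m))
    stop("column tree inconsistent with matrix")
  om <- m[ri, ci, drop = FALSE]
  df <- data.frame(accession = rownames(om), om, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(path_newick) && !is.null(row_tree))
    ape::write.tree(ape::as.phylo(row_tree), file = path_newick)
  if (!is.null(path_png)) {
    lim <- max(abs(om))
    pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(255)
    grDevices::png(path_png, width = 800, height = max(400, 12 * nrow(om) + 100))
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::image(t(om[rev(seq_len(nrow(om))), , drop = FALSE]),
                    col = pal, zlim = c(-lim, lim), axes = FALSE,
                    main = "standardized protein expression")
    graphics::axis(1, at = seq(0, 1, length.out = ncol(om)),
                   labels = colnames(om), las = 2, cex.axis = 0.7)
  }
  invisible(om)
}
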