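#' Classical multidimensional scaling of sample profiles
#'
#' Principal-coordinate embedding of the non-control samples from their
#' pairwise Euclidean distances in protein space (eigendecomposition of the
#' double-centered squared-distance matrix). With Euclidean input this equals
#' PCA scores up to sign; component signs are fixed deterministically by
#' making each component's largest-magnitude score positive. Components are
#' ordered by decreasing eigenvalue and `variance_explained` is the leading
#' eigenvalue sum over the sum of all positive eigenvalues.
#'
#' @param table an imputed, log2-transformed [protein_table].
#' @param design a [sample_design]; controls are dropped.
#' @param n_components number of components to retain (at most the number of
#'   positive eigenvalues, itself at most n_samples - 1).
#' @return list with `scores` (samples x components matrix, rownames =
#'   sample_id), `eig` (all eigenvalues), `variance_explained` (scalar for
#'   the retained components).
#' @export
mds_reduce <- function(table, design, n_components) {
  validate_protein_table(table)
  check_table_design(table, design)
  d <- design[match(table$sample_id, design$sample_id), , drop = FALSE]
  keep <- !d$is_control
  x <- t(table$signal[, keep, drop = FALSE])
  if (anyNA(x)) stop("mds_reduce requires a complete (imputed) table")
  n <- nrow(x)
  if (n_components > n - 1L)
    stop("n_components must be at most n_samples - 1")
  # rank deficiency is handled explicitly below; cmdscale's own warning
  # about dropped eigenvalues is redundant here
  mds <- suppressWarnings(stats::cmdscale(stats::dist(x), k = n - 1L, eig = TRUE))
  pos <- sum(mds$eig > sqrt(.Machine$double.eps) * max(abs(mds$eig)))
  if (n_components > pos)
    stop("n_components (", n_components, ") exceeds the ", pos,
         " positive eigenvalues available")
  scores <- mds$points[, seq_len(n_components), drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- table$sample_id[keep]
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores, eig = mds$eig,
       variance_explained = sum(mds$eig[seq_len(n_components)]) /
         sum(mds$eig[mds$eig > 0]))
}

#' Hotelling's T-squared test for two dependent (paired) samples
#'
#' The multivariate extension of the paired t-test: on the per-subject
#' difference vectors \eqn{d_i = scores_{abd,i} - scores_{fem,i}} in p
#' dimensions,
#' \deqn{T^2 = n \, \bar d^\top S^{-1} \bar d, \qquad
#'       F = \frac{n - p}{p (n - 1)} T^2 \sim F_{p,\,n-p}}
#' with S the sample covariance of the differences. With p = 1 this is
#' exactly the squared paired t statistic. The maximal usable p is n - 1.
#'
#' @param scores samples x components score matrix (rownames = sample_id),
#'   e.g. from [mds_reduce()].
#' @param design a [sample_design] pairing the score rows by subject.
#' @param n_components number of leading score columns to use (default: all,
#'   typically n_pairs - 1).
#' @param variance_explained optional scalar carried into the result.
#' @return object of class `hotelling_result`: list with `T2`, `F`,
#'   `df1`, `df2`, `p_value`, `n_pairs`, `n_components`,
#'   `variance_explained`.
#' @export
hotelling_paired <- function(scores, design, n_components = NULL,
                             variance_explained = NA_real_) {
  ids <- rownames(scores)
  if (is.null(ids)) stop("scores must have sample_id rownames")
  d <- design[match(ids, design$sample_id), , drop = FALSE]
  if (anyNA(d$sample_id)) stop("score rows missing from design")
  study <- d[!d$is_control, , drop = FALSE]
  subjects <- unique(study$subject_id)
  n <- length(subjects)
  if (is.null(n_components)) n_components <- ncol(scores)
  p <- n_components
  if (p > ncol(scores)) stop("n_components exceeds available score columns")
  if (p > n - 1L)
    stop("n_components must be at most n_pairs - 1 (", n - 1L, ")")
  diffs <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) {
    rows <- study[study$subject_id == subjects[i], , drop = FALSE]
    a <- rows$sample_id[rows$depot == "abdominal"]
    f <- rows$sample_id[rows$depot == "femoral"]
    if (length(a) != 1L || length(f) != 1L)
      stop("subject '", subjects[i], "' lacks a complete pair")
    diffs[i, ] <- scores[a, seq_len(p)] - scores[f, seq_len(p)]
  }
  hotelling_from_differences(diffs, variance_explained = variance_explained)
}

#' @rdname hotelling_paired
#' @param diffs n x p matrix of paired difference vectors (one row per
#'   subject).
#' @export
hotelling_from_differences <- function(diffs, variance_explained = NA_real_) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs); p <- ncol(diffs)
  if (n < 2L) stop("need at least 2 pairs")
  if (p > n - 1L) stop("dimension p must be at most n - 1")
  dbar <- colMeans(diffs)
  S <- stats::cov(diffs)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular difference covariance; use fewer components", call. = FALSE))
  T2 <- drop(n * t(dbar) %*% Sinv %*% dbar)
  Fstat <- (n - p) / (p * (n - 1)) * T2
  pval <- stats::pf(Fstat, p, n - p, lower.tail = FALSE)
  structure(list(T2 = T2, F = Fstat, df1 = p, df2 = n - p, p_value = pval,
                 n_pairs = n, n_components = p,
                 variance_explained = variance_explained),
            class = "hotelling_result")
}

#' @export
print.hotelling_result <- function(x, ...) {
  cat(sprintf("Paired Hotelling T2: T2 = %.4g, F(%d, %d) = %.4g, p = %.4g\n",
              x$T2, x$df1, x$df2, x$F, x$p_value))
  if (!is.na(x$variance_explained))
    cat(sprintf("  %d components explaining %.1f%% of total variation, n = %d pairs\n",
                x$n_components, 100 * x$variance_explained, x$n_pairs))
  invisible(x)
}
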