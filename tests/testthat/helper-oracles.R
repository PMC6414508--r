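# Independent brute-force oracles used to cross-check the implementation.

# BH step-up by direct enumeration: q_i = min over admissible thresholds
# t >= p_i of t * m / #{p <= t}, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(vapply(ts, function(t) t * m / sum(p <= t), 0)))
  }, 0)
}

# Agglomerative ward.D by direct Lance-Williams recurrence on the raw
# (unsquared) Euclidean distance matrix; ties break on smallest index pair.
ward_oracle <- function(x) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  active <- seq_len(n)
  size <- rep(1L, n)
  members <- as.list(seq_len(n))
  merges <- list(); heights <- numeric(0)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); bh <- Inf
    for (a in seq_along(active)) for (b in seq_len(a - 1L)) {
      i <- active[a]; j <- active[b]
      if (d[i, j] < bh - 1e-12) { bh <- d[i, j]; best <- sort(c(i, j)) }
    }
    i <- best[1L]; j <- best[2L]
    merges[[step]] <- sort(c(members[[i]], members[[j]]))
    heights[step] <- bh
    # Lance-Williams ward.D update against every other active cluster
    for (l in setdiff(active, c(i, j))) {
      dn <- ((size[i] + size[l]) * d[i, l] + (size[j] + size[l]) * d[j, l] -
               size[l] * d[i, j]) / (size[i] + size[j] + size[l])
      d[i, l] <- d[l, i] <- dn
    }
    members[[i]] <- c(members[[i]], members[[j]])
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  list(members = merges, heights = heights)
}

# Leaf sets at each merge of an hclust object, sorted for comparison.
hclust_members <- function(h) {
  n <- length(h$order)
  out <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    get <- function(v) if (v < 0) -v else out[[v]]
    out[[k]] <- sort(c(get(h$merge[k, 1L]), get(h$merge[k, 2L])))
  }
  out
}

# Exact two-sided Spearman p by full enumeration of rank permutations.
spearman_perm_oracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  rhos <- vapply(perms(ry), function(pp) cor(rx, pp), 0)
  list(rho = obs, p = mean(abs(rhos) >= abs(obs) - 1e-12))
}

# Classical MDS oracle: eigendecomposition of the double-centered squared
# Euclidean distance matrix.
mds_oracle <- function(x, k) {
  D2 <- as.matrix(dist(x))^2
  n <- nrow(D2)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  e <- eigen(B, symmetric = TRUE)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  list(scores = scores, values = e$values)
}

# Closed-form paired t p-value (independent of stats::t.test).
paired_t_oracle <- function(a, b) {
  d <- a - b; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1))
}
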