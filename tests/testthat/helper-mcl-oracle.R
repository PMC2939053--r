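# Independent dense-matrix MCL oracle used to cross-check the package's
# sparse implementation.  Deliberately written with plain base-R dense
# operations and a hand-rolled union-find for component extraction, so it
# shares no code path with lrrcensus::mcl().

mcl_dense_oracle <- function(W, inflation, expansion = 2, max_iter = 200,
                             prune_below = 1e-5, converge_tol = 1e-6) {
  n <- nrow(W)
  diag(W) <- 0
  for (j in seq_len(n)) {
    m <- max(W[, j])
    W[j, j] <- if (m > 0) m else 1
  }
  M <- sweep(W, 2, colSums(W), "/")
  for (it in seq_len(max_iter)) {
    E <- M
    for (k in seq_len(expansion - 1)) E <- E %*% M
    E <- E^inflation
    E[E < prune_below] <- 0
    dead <- colSums(E) == 0
    if (any(dead)) E[cbind(which(dead), which(dead))] <- 1
    E <- sweep(E, 2, colSums(E), "/")
    done <- max(abs(E - M)) < converge_tol
    M <- E
    if (done) break
  }
  # components of the non-zero pattern via union-find
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (M[i, j] != 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Canonical form of a clustering for comparison: sorted list of sorted
# member-id clusters (including singletons as size-1 clusters).
canonical_partition <- function(groups) {
  out <- unname(lapply(groups, function(g) sort(as.character(g))))
  out[order(vapply(out, `[[`, character(1), 1L))]
}

cluster_set_partition <- function(cs) {
  canonical_partition(c(cs$clusters, as.list(cs$singletons)))
}

oracle_partition <- function(ids, membership) {
  canonical_partition(split(ids, membership))
}

# Random sparse-ish weighted graph on n nodes for property tests.
random_graph_edges <- function(n, p = 0.15, ids = sprintf("n%02d", 1:n)) {
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
             e_value = 10^runif(sum(keep), -40, -16),
             stringsAsFactors = FALSE)
}
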