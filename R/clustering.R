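#' Extract LRR-domain subsequences
#'
#' Slices the residues of every LRR domain hit out of its parent protein
#' (1-based inclusive coordinates).  Subsequence ids follow the
#' `proteinid/start-end` convention.
#'
#' @param proteins Protein table with sequences ([read_proteins()] with
#'   `keep_sequences = TRUE`).
#' @param hits Domain-hit table.
#' @param lrr_accessions Accessions treated as LRR (default [lrr_pfam()]).
#' @return data.frame with columns `id`, `parent_protein`, `start`, `end`,
#'   `residues`.
#' @export
extract_subsequences <- function(proteins, hits,
                                 lrr_accessions = lrr_pfam()) {
  sel <- hits[hits$accession %in% lrr_accessions, , drop = FALSE]
  empty <- data.frame(id = character(), parent_protein = character(),
                      start = integer(), end = integer(),
                      residues = character(), stringsAsFactors = FALSE)
  if (nrow(sel) == 0L) return(empty)
  idx <- match(sel$protein_id, proteins$protein_id)
  if (anyNA(idx))
    abort("LRR hits reference unknown protein(s): %s",
          paste(unique(sel$protein_id[is.na(idx)]), collapse = ", "))
  seqs <- proteins$sequence[idx]
  if (anyNA(seqs)) abort("protein sequences required for extraction")
  if (any(sel$end > nchar(seqs)))
    abort("hit coordinates outside sequence for protein '%s'",
          sel$protein_id[which(sel$end > nchar(seqs))[1L]])
  data.frame(id = sprintf("%s/%d-%d", sel$protein_id, sel$start, sel$end),
             parent_protein = sel$protein_id,
             start = sel$start, end = sel$end,
             residues = substr(seqs, sel$start, sel$end),
             stringsAsFactors = FALSE)
}

#' Write subsequences as FASTA (e.g. for external tree building)
#'
#' @param subs Subsequence table from [extract_subsequences()].
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_subsequences_fasta <- function(subs, path) {
  set <- Biostrings::AAStringSet(setNames(subs$residues, subs$id))
  write_atomic(function(tmp) Biostrings::writeXStringSet(set, tmp), path)
  invisible(path)
}

#' Read a similarity edge list
#'
#' 3-column TSV (`id_a`, `id_b`, `e_value`) -- the "ABC" graph dialect
#' used by the MCL tool family.
#'
#' @param path Edge-list path.
#' @return data.frame with columns `a`, `b`, `e_value`.
#' @export
read_edge_list <- function(path) {
  read_tsv(path, c("a", "b", "e_value"),
           c("character", "character", "numeric"), header = FALSE)
}

#' Build a similarity graph from e-value edges
#'
#' Keeps edges with `e_value <= e_cutoff`, weights them
#' `min(-log10(e_value), zero_cap)` (an e-value of exactly 0 maps to the
#' cap), symmetrizes, and discards self-edges.  Duplicate pairs keep their
#' strongest weight.  Nodes listed in `ids` but left without any
#' cutoff-passing edge stay in the graph as isolated nodes and end up as
#' singletons after clustering.
#'
#' @param edges Edge data.frame (`a`, `b`, `e_value`).
#' @param e_cutoff Inclusion threshold on the e-value (default `1e-15`).
#' @param zero_cap Weight cap for vanishing e-values (default 200).
#' @param ids Optional character vector of node ids to include even when
#'   isolated (defaults to the ids seen in `edges`).
#' @return A `similarity_graph`: list with `ids` and the symmetric sparse
#'   `adjacency` matrix (zero diagonal).
#' @export
build_graph <- function(edges, e_cutoff = 1e-15, zero_cap = 200,
                        ids = NULL) {
  stopifnot(e_cutoff > 0, zero_cap > 0)
  if (any(edges$e_value < 0)) abort("negative e-value in edge list")
  ids <- sort(unique(c(ids, edges$a, edges$b)))
  keep <- edges$e_value <= e_cutoff & edges$a != edges$b
  e <- edges[keep, , drop = FALSE]
  w <- ifelse(e$e_value == 0, zero_cap, pmin(-log10(e$e_value), zero_cap))
  n <- length(ids)
  i <- match(e$a, ids); j <- match(e$b, ids)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n), dimnames = list(ids, ids),
                            use.last.ij = FALSE)
  # duplicate pairs: sparseMatrix sums repeats; rebuild with max instead
  if (anyDuplicated(cbind(pmin(i, j), pmax(i, j)))) {
    key <- paste(pmin(i, j), pmax(i, j))
    wmax <- tapply(w, key, max)
    ij <- do.call(rbind, strsplit(names(wmax), " "))
    i2 <- as.integer(ij[, 1L]); j2 <- as.integer(ij[, 2L])
    A <- Matrix::sparseMatrix(i = c(i2, j2), j = c(j2, i2),
                              x = c(wmax, wmax), dims = c(n, n),
                              dimnames = list(ids, ids))
  }
  structure(list(ids = ids, adjacency = A), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  n_edge <- Matrix::nnzero(x$adjacency) / 2
  cat(sprintf("<similarity_graph> %d nodes, %d edges\n",
              length(x$ids), n_edge))
  invisible(x)
}

#' Markov clustering of a similarity graph
#'
#' Sparse implementation of the MCL algorithm: self-loops are added with
#' weight equal to the node's maximum incident edge weight (1 for isolated
#' nodes), columns are normalized to a stochastic matrix, and the process
#' iterates expansion (matrix power), inflation (elementwise power),
#' pruning of entries below `prune_below` and re-normalization until the
#' largest entry change falls below `converge_tol` or `max_iter` is
#' reached.  Clusters are the connected components of the non-zero pattern
#' of the limit matrix; components of size 1, and nodes that entered with
#' no edges, are reported as singletons.
#'
#' @param graph A `similarity_graph` from [build_graph()].
#' @param inflation Inflation exponent (> 1); larger values give finer
#'   clusters.  Default 1.5.
#' @param expansion Matrix-power exponent (default 2).
#' @param max_iter Iteration cap (default 100).
#' @param prune_below Entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param converge_tol Convergence threshold on the max absolute entry
#'   change (default 1e-6).
#' @return A `cluster_set`: list with `clusters` (list of id vectors,
#'   size >= 2, sorted by size then lexically), `singletons` (id vector),
#'   `ids` (the full universe), `converged`, `iterations` and
#'   `max_col_dev` (worst deviation of any column sum from 1 across all
#'   iterations).
#' @export
mcl <- function(graph, inflation = 1.5, expansion = 2L, max_iter = 100L,
                prune_below = 1e-5, converge_tol = 1e-6) {
  stopifnot(inherits(graph, "similarity_graph"))
  if (inflation <= 1) abort("inflation must be > 1")
  if (expansion < 2L) abort("expansion must be >= 2")
  A <- graph$adjacency
  ids <- graph$ids
  n <- length(ids)
  if (n == 0L)
    return(new_cluster_set(list(), character(), character(), TRUE, 0L, 0))
  # self-loops: max incident weight, or 1 for isolated nodes
  loopw <- apply_col_max(A)
  loopw[loopw == 0] <- 1
  M <- A + Matrix::Diagonal(n, loopw)
  M <- col_normalize(M)
  converged <- FALSE
  max_col_dev <- 0
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    E <- M
    for (k in seq_len(expansion - 1L)) E <- E %*% M
    E <- methods::as(E, "CsparseMatrix")
    E@x <- E@x^inflation
    E@x[E@x < prune_below] <- 0
    E <- Matrix::drop0(E)
    E <- revive_dead_columns(E)
    E <- col_normalize(E)
    max_col_dev <- max(max_col_dev, max(abs(Matrix::colSums(E) - 1)))
    delta <- E - M
    change <- if (length(delta@x) == 0L) 0 else max(abs(delta@x))
    M <- E
    if (change < converge_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("MCL did not converge within %d iterations", max_iter),
            call. = FALSE)
  # clusters: connected components of the non-zero pattern
  P <- M != 0
  g <- igraph::graph_from_adjacency_matrix((P | Matrix::t(P)) * 1,
                                           mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(ids, comp)
  sizes <- lengths(groups)
  clusters <- lapply(groups[sizes >= 2L], sort)
  singletons <- unlist(groups[sizes == 1L], use.names = FALSE)
  singletons <- if (is.null(singletons)) character() else sort(singletons)
  new_cluster_set(clusters, singletons, ids, converged, iter, max_col_dev)
}

# Internal: per-column maximum of a sparse non-negative matrix.
apply_col_max <- function(A) {
  A <- methods::as(A, "CsparseMatrix")
  out <- numeric(ncol(A))
  counts <- diff(A@p)
  if (length(A@x) > 0L) {
    colidx <- rep.int(seq_len(ncol(A)), counts)
    mx <- tapply(A@x, colidx, max)
    out[as.integer(names(mx))] <- mx
  }
  out
}

# Internal: column-normalize a sparse matrix with strictly positive
# column sums.
col_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  M %*% Matrix::Diagonal(length(cs), 1 / cs)
}

# Internal: if pruning emptied a column, restore a unit self-loop so the
# matrix stays stochastic.
revive_dead_columns <- function(E) {
  cs <- Matrix::colSums(E)
  dead <- which(cs == 0)
  if (length(dead) > 0L) {
    E <- E + Matrix::sparseMatrix(i = dead, j = dead,
                                  x = rep(1, length(dead)),
                                  dims = dim(E), dimnames = dimnames(E))
  }
  E
}

# Internal: cluster_set constructor, ordering clusters by size descending
# then lexically by first member.
new_cluster_set <- function(clusters, singletons, ids, converged,
                            iterations, max_col_dev) {
  if (length(clusters) > 0L) {
    first <- vapply(clusters, `[[`, character(1), 1L)
    ord <- order(-lengths(clusters), first)
    clusters <- clusters[ord]
  }
  cs <- structure(list(clusters = unname(clusters),
                       singletons = singletons,
                       ids = ids,
                       converged = converged,
                       iterations = iterations,
                       max_col_dev = max_col_dev),
                  class = "cluster_set")
  validate_cluster_set(cs)
  cs
}

# Internal: clusters + singletons must partition the id universe.
validate_cluster_set <- function(cs) {
  all_ids <- c(unlist(cs$clusters, use.names = FALSE), cs$singletons)
  if (anyDuplicated(all_ids) || !setequal(all_ids, cs$ids) ||
      length(all_ids) != length(cs$ids))
    abort("cluster set does not partition its ids")
  if (any(lengths(cs$clusters) < 2L))
    abort("clusters must have size >= 2")
  invisible(cs)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters, %d singletons (%d sequences)%s\n",
              length(x$clusters), length(x$singletons), length(x$ids),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Cluster-set summary statistics
#'
#' @param cs A `cluster_set`.
#' @return List with `n_clusters`, `n_singletons`, `n_sequences`.
#' @export
cluster_stats <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  validate_cluster_set(cs)
  list(n_clusters = length(cs$clusters),
       n_singletons = length(cs$singletons),
       n_sequences = sum(lengths(cs$clusters)) + length(cs$singletons))
}

#' Write clusters in the MCL tool convention
#'
#' One cluster per line, members tab-separated; singletons follow, one per
#' line.
#'
#' @param cs A `cluster_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_clusters <- function(cs, path) {
  lines <- c(vapply(cs$clusters, paste, character(1), collapse = "\t"),
             cs$singletons)
  write_atomic(function(tmp) writeLines(lines, tmp), path)
  invisible(path)
}
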