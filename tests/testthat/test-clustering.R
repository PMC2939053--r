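test_that("LRR subsequences are sliced 1-based inclusive with composite ids", {
  prot <- rbind(protein_row("p1", "s1", 9L, "MKLRRAAAA"),
                protein_row("p2", "s1", 6L, "AAAAAA"))
  hits <- rbind(hit_rows("p1", "PF00560", 3, 5),
                hit_rows("p2", "PF00069", 1, 6))
  subs <- extract_subsequences(prot, hits)
  expect_equal(subs$id, "p1/3-5")
  expect_equal(subs$residues, "LRR")
  # two hits on one protein give two distinct ids
  h2 <- hit_rows("p1", "PF00560", c(1, 4), c(3, 6))
  s2 <- extract_subsequences(prot, h2)
  expect_equal(s2$id, c("p1/1-3", "p1/4-6"))
  expect_equal(s2$residues, c("MKL", "RRA"))
  # coordinates beyond the sequence are an error
  expect_error(extract_subsequences(prot, hit_rows("p1", "PF00560", 3, 50)),
               "outside")
})

test_that("graph construction applies the e-value cutoff, log-weights and zero cap", {
  edges <- data.frame(a = c("x", "x", "y", "z"),
                      b = c("y", "z", "z", "z"),
                      e_value = c(1e-20, 1e-10, 0, 5e-16))
  g <- build_graph(edges)
  expect_equal(g$adjacency["x", "y"], 20)          # -log10(1e-20)
  expect_equal(g$adjacency["x", "z"], 0)           # 1e-10 above cutoff
  expect_equal(g$adjacency["y", "z"], 200)         # e = 0 capped
  expect_equal(g$adjacency, Matrix::t(g$adjacency))# symmetric
  expect_equal(Matrix::diag(g$adjacency), setNames(rep(0, 3), g$ids))
  expect_error(build_graph(transform(edges, e_value = -1)), "negative")
  # isolated ids are retained for singleton accounting
  g2 <- build_graph(edges, ids = c("lonely"))
  expect_true("lonely" %in% g2$ids)
})

test_that("disjoint cliques cluster separately at any inflation", {
  set.seed(21)
  mk_clique <- function(ids) {
    pr <- t(combn(ids, 2))
    data.frame(a = pr[, 1], b = pr[, 2], e_value = 1e-30,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(mk_clique(paste0("a", 1:4)), mk_clique(paste0("b", 1:4)))
  for (infl in c(1.2, 1.5, 2, 4)) {
    cs <- mcl(build_graph(edges), inflation = infl)
    expect_equal(length(cs$clusters), 2L)
    expect_equal(lengths(cs$clusters), c(4L, 4L))
    expect_equal(length(cs$singletons), 0L)
  }
  # one node, no edges
  g1 <- build_graph(edges[0, ], ids = "solo")
  cs1 <- mcl(g1)
  expect_equal(cs1$singletons, "solo")
  expect_equal(cluster_stats(cs1),
               list(n_clusters = 0L, n_singletons = 1L, n_sequences = 1L))
})

test_that("a weakly bridged barbell matches the dense oracle at inflation 1.5", {
  mk_clique <- function(ids, e) {
    pr <- t(combn(ids, 2))
    data.frame(a = pr[, 1], b = pr[, 2], e_value = e,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(mk_clique(paste0("L", 1:6), 1e-40),
                 mk_clique(paste0("R", 1:6), 1e-40),
                 data.frame(a = "L1", b = "R1", e_value = 1e-16))
  g <- build_graph(edges)
  cs <- mcl(g, inflation = 1.5)
  W <- as.matrix(g$adjacency)
  member <- mcl_dense_oracle(W, inflation = 1.5)
  expect_equal(cluster_set_partition(cs), oracle_partition(g$ids, member))
})

test_that("sparse MCL agrees with the dense oracle on random graphs", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    edges <- random_graph_edges(n, p = runif(1, 0.05, 0.4))
    ids <- sprintf("n%02d", 1:n)
    g <- build_graph(edges, ids = ids)
    infl <- sample(c(1.5, 2, 4), 1)
    cs <- mcl(g, inflation = infl)
    member <- mcl_dense_oracle(as.matrix(g$adjacency), inflation = infl)
    expect_equal(cluster_set_partition(cs), oracle_partition(g$ids, member))
  }
})

test_that("iteration keeps columns stochastic and clusters stay within components", {
  set.seed(41)
  edges <- random_graph_edges(30, p = 0.2)
  g <- build_graph(edges, ids = sprintf("n%02d", 1:30))
  cs <- mcl(g, inflation = 1.5)
  expect_lt(cs$max_col_dev, 1e-9)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    (g$adjacency != 0) * 1, mode = "undirected"))$membership
  for (cl in cs$clusters)
    expect_equal(length(unique(comp[cl])), 1L)
})

test_that("node relabeling permutes clusters identically", {
  set.seed(51)
  edges <- random_graph_edges(20, p = 0.25)
  g <- build_graph(edges, ids = sprintf("n%02d", 1:20))
  cs <- mcl(g, inflation = 2)
  relab <- setNames(sprintf("z%02d", sample(20)), sprintf("n%02d", 1:20))
  edges2 <- transform(edges, a = unname(relab[a]), b = unname(relab[b]))
  cs2 <- mcl(build_graph(edges2, ids = unname(relab)), inflation = 2)
  mapped <- canonical_partition(lapply(
    c(cs$clusters, as.list(cs$singletons)), function(g) unname(relab[g])))
  expect_equal(cluster_set_partition(cs2), mapped)
})

test_that("cluster sizes shrink toward dense cores as inflation grows", {
  set.seed(61)
  for (rep in 1:5) {
    edges <- random_graph_edges(25, p = 0.3)
    g <- build_graph(edges, ids = sprintf("n%02d", 1:25))
    largest <- vapply(c(1.2, 1.5, 2, 4, 6), function(infl) {
      cs <- mcl(g, inflation = infl)
      max(c(lengths(cs$clusters), 1L))
    }, numeric(1))
    expect_true(all(diff(largest) <= 0))
  }
})

test_that("cluster statistics are partition-consistent and written in MCL convention", {
  cs <- mcl(build_graph(data.frame(
    a = c("a1", "a1", "a2"), b = c("a2", "a3", "a3"), e_value = 1e-30),
    ids = c("a1", "a2", "a3", "s1")))
  st <- cluster_stats(cs)
  expect_equal(st, list(n_clusters = 1L, n_singletons = 1L, n_sequences = 4L))
  f <- tempfile()
  write_clusters(cs, f)
  lines <- readLines(f)
  expect_equal(lines[1], "a1\ta2\ta3")
  expect_equal(lines[2], "s1")
  # tampering with the partition triggers the invariant check
  broken <- cs
  broken$singletons <- character()
  expect_error(cluster_stats(broken), "partition")
})
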