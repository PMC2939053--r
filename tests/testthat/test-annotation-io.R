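test_that("FASTA reading computes lengths, tolerates empty files and rejects duplicate ids", {
  p <- write_fasta_text(c(">p1 some description", "MKLVAAGHWT"))
  prot <- read_proteins(p, "s1")
  expect_equal(prot$protein_id, "p1")
  expect_equal(prot$length, 10L)
  expect_equal(prot$sequence, "MKLVAAGHWT")

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_equal(nrow(read_proteins(empty, "s1")), 0L)

  dup <- write_fasta_text(c(">p1", "MKL", ">p1", "AAA"))
  expect_error(read_proteins(dup, "s1"), "duplicate.*p1")
})

test_that("TSV domain-hit dialect parses exactly and enforces invariants", {
  f <- tempfile()
  writeLines("p1\tPF00560\tLRR_1\t5\t28\t30.1\t1e-8", f)
  h <- read_domain_hits(f)
  expect_equal(h$protein_id, "p1")
  expect_equal(h$accession, "PF00560")
  expect_equal(h$start, 5L)
  expect_equal(h$end, 28L)
  expect_equal(h$bit_score, 30.1)
  expect_equal(h$e_value, 1e-8)

  writeLines(character(), f)
  expect_equal(nrow(read_domain_hits(f)), 0L)

  writeLines("p1\tPF560\tLRR_1\t5\t28\t30.1\t1e-8", f)
  expect_error(read_domain_hits(f), "accession")

  writeLines("p1\tPF00560\tLRR_1\t28\t5\t30.1\t1e-8", f)
  expect_error(read_domain_hits(f), "coordinates")

  # strict cross-referencing: hit end beyond protein length
  writeLines("p1\tPF00560\tLRR_1\t5\t600\t30.1\t1e-8", f)
  expect_error(read_domain_hits(f, proteins = protein_row(length = 500L)),
               "length")
  # unknown protein: error strict, dropped lenient
  writeLines("ghost\tPF00560\tLRR_1\t5\t28\t30.1\t1e-8", f)
  expect_error(read_domain_hits(f, proteins = protein_row()), "unknown")
  expect_warning(
    h <- read_domain_hits(f, proteins = protein_row(), strict = FALSE),
    "dropped")
  expect_equal(nrow(h), 0L)
})

test_that("HMMER per-domain tables yield envelope coordinates and versionless accessions", {
  f <- tempfile()
  writeLines(c(
    "# comment line",
    paste("LRR_1 PF00560.28 24 p1 - 500 1e-10 40.0 0.1 1 2 1e-9 2e-9",
          "30.1 0.1 1 24 4 27 5 28 0.9 desc here")), f)
  h <- read_domain_hits(f, dialect = "hmmer_domtbl")
  expect_equal(h$protein_id, "p1")
  expect_equal(h$accession, "PF00560")
  expect_equal(h$name, "LRR_1")
  expect_equal(h$start, 5L)   # envelope from
  expect_equal(h$end, 28L)    # envelope to
  expect_equal(h$bit_score, 30.1)
  expect_equal(h$e_value, 2e-9)
})

test_that("TMHMM topology strings expand to one row per helix", {
  f <- tempfile()
  writeLines(c("p1\tlen=500\tExpAA=22\tFirst60=0\tPredHel=1\tTopology=o10-32i",
               "p2\tlen=300\tExpAA=0\tFirst60=0\tPredHel=0\tTopology=o",
               "p3\tlen=200\tExpAA=44\tFirst60=10\tPredHel=2\tTopology=i5-20o45-60i"),
             f)
  tm <- read_tm_helices(f, dialect = "tmhmm_short")
  expect_equal(tm$protein_id, c("p1", "p3", "p3"))
  expect_equal(tm$start, c(10L, 5L, 45L))
  expect_equal(tm$end, c(32L, 20L, 60L))

  writeLines("p4\tTopology=x10-20z", f)
  expect_error(read_tm_helices(f, dialect = "tmhmm_short"), "p4")
})

test_that("SignalP summaries only yield records for positive proteins", {
  f <- tempfile()
  writeLines(c("p1 YES 22", "p2 NO"), f)
  sp <- read_signal_peptides(f, dialect = "signalp_summary")
  expect_equal(sp$protein_id, "p1")
  expect_equal(sp$end, 22L)

  writeLines("p1 YES 0", f)
  expect_error(read_signal_peptides(f, dialect = "signalp_summary"), "end")

  writeLines("p1\t499", f)
  expect_error(
    read_signal_peptides(f, proteins = protein_row(length = 499L)),
    "entire protein")
})

test_that("census tables round-trip losslessly, including the empty census", {
  rules <- builtin_rules()
  proteins <- rbind(protein_row("a1", "spB"), protein_row("a2", "spA"))
  hits <- hit_rows(c("a1", "a2"), "PF00560", c(5, 5), c(28, 28))
  labels <- classify_proteins(proteins, hits, tm_rows(character(), integer(), integer()),
                              sp_row(character(), integer()), rules)
  cen <- census(labels, proteins, rules)
  expect_equal(rownames(cen), c("spA", "spB"))  # sorted lexically
  f <- tempfile()
  write_census(cen, f)
  expect_equal(read_census(f), cen)

  empty <- census(labels[0, , drop = FALSE], proteins[0, ], rules)
  write_census(empty, f)
  expect_equal(length(readLines(f)), 1L)  # header only
  expect_equal(read_census(f), empty)
})

test_that("randomized write/read round trips preserve census counts", {
  set.seed(42)
  rules <- builtin_rules()
  for (rep in 1:5) {
    n_sp <- sample(1:6, 1)
    m <- matrix(sample(0:50, n_sp * length(rules), replace = TRUE),
                n_sp, length(rules),
                dimnames = list(sort(replicate(n_sp, paste(sample(letters, 6), collapse = ""))),
                                names(rules)))
    cen <- structure(m, class = "lrr_census")
    f <- tempfile()
    write_census(cen, f)
    expect_equal(read_census(f), cen)
  }
})

test_that("taxonomy tables reject duplicate species", {
  f <- tempfile()
  writeLines(c("s1\tfungi/ascomycota", "s2\tplants/land_plants"), f)
  tax <- read_taxonomy(f)
  expect_equal(tax$species_id, c("s1", "s2"))
  writeLines(c("s1\tfungi", "s1\tplants"), f)
  expect_error(read_taxonomy(f), "duplicate")
})
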