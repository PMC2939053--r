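test_that("planted N-terminal extensions are recovered at their exact length", {
  sim <- simulate_homolog_family(1200, overhang = 560, seed = 3)
  arch <- build_architecture(sim$query, NULL, sim$tm, NULL)
  rep <- detect_nterm_extension(sim$family, arch)
  expect_equal(rep$overhang_length, 560L)
  expect_true(rep$contains_tm)
  expect_equal(rep$suggested_action, "drop_tm")
  expect_equal(rep$kind, "NTERM_EXTENSION")
})

test_that("flush alignments and sub-threshold overhangs yield no report", {
  sim0 <- simulate_homolog_family(800, overhang = 0, seed = 4)
  arch0 <- build_architecture(sim0$query, NULL, sim0$tm, NULL)
  expect_null(detect_nterm_extension(sim0$family, arch0))
  # threshold edge: overhang 99 at min_overhang 100
  sim99 <- simulate_homolog_family(800, overhang = 99, seed = 5)
  arch99 <- build_architecture(sim99$query, NULL, sim99$tm, NULL)
  expect_null(detect_nterm_extension(sim99$family, arch99))
  expect_equal(
    detect_nterm_extension(sim99$family, arch99, min_overhang = 99)$overhang_length,
    99L)
})

test_that("an overhang without a TM helix is reported with no action", {
  sim <- simulate_homolog_family(1000, overhang = 150, seed = 6)
  tm_far <- tm_rows("query", 400, 422)  # helix outside the overhang
  arch <- build_architecture(sim$query, NULL, tm_far, NULL)
  rep <- detect_nterm_extension(sim$family, arch)
  expect_equal(rep$overhang_length, 150L)
  expect_false(rep$contains_tm)
  expect_equal(rep$suggested_action, "none")
})

test_that("extension detection ignores homolog row order and all-gap columns", {
  sim <- simulate_homolog_family(900, overhang = 200, seed = 7)
  arch <- build_architecture(sim$query, NULL, sim$tm, NULL)
  base <- detect_nterm_extension(sim$family, arch)
  # permute rows (query stays identified by name)
  seqs <- sim$family$sequences
  perm <- homolog_family("query", seqs[sample(length(seqs))])
  expect_equal(detect_nterm_extension(perm, arch), base)
  # insert all-gap columns: column counts shift, query-residue overhang does not
  padded <- homolog_family("query", vapply(seqs, function(s)
    paste0(substr(s, 1, 50), "----------", substring(s, 51)), character(1),
    USE.NAMES = TRUE))
  expect_equal(detect_nterm_extension(padded, arch)$overhang_length,
               base$overhang_length)
  # query absent is an error
  expect_error(homolog_family("ghost", seqs), "ghost")
})

test_that("misplaced N-terminal domains flag the region before them", {
  nterm <- "PF01462"
  a <- arch_of(hit_rows("p1", "PF01462", 500, 540),
               tm_rows("p1", 30, 52), length = 1000L)
  rep <- detect_misplaced_nterm_domain(a, nterm)
  expect_equal(rep$kind, "MISPLACED_NTERM_DOMAIN")
  expect_equal(rep$overhang_length, 499L)
  expect_true(rep$contains_tm)
  expect_equal(rep$suggested_action, "drop_tm")
  # domain near the N-terminus, or absent, is unremarkable
  expect_null(detect_misplaced_nterm_domain(
    arch_of(hit_rows("p1", "PF01462", 5, 45), length = 1000L), nterm))
  expect_null(detect_misplaced_nterm_domain(
    arch_of(hit_rows("p1", "PF00560", 500, 523), length = 1000L), nterm))
})

test_that("corrections drop flagged helices and receptor counts only fall", {
  rules <- builtin_rules()
  # 7 receptor-like proteins; 2 carry a spurious TM inside a flagged overhang
  proteins <- do.call(rbind, lapply(1:7, function(i)
    protein_row(paste0("r", i), "fungus1", 1000L)))
  hits <- hit_rows(paste0("r", 1:7), "PF00560", 600, 623)
  tm <- tm_rows(paste0("r", 1:7), c(rep(300, 5), 80, 90), c(rep(322, 5), 102, 112))
  archs <- build_architectures(proteins, hits, tm, sp_row(character(), integer()))
  before <- vapply(archs, function(a)
    "LRR_RECEPTOR" %in% classify(a, rules)$labels, logical(1))
  expect_equal(sum(before), 7L)
  reports <- data.frame(protein_id = c("r6", "r7"), kind = "NTERM_EXTENSION",
                        overhang_length = 560L, contains_tm = TRUE,
                        suggested_action = "drop_tm", stringsAsFactors = FALSE)
  fixed <- apply_corrections(archs, reports)
  after <- vapply(fixed, function(a)
    "LRR_RECEPTOR" %in% classify(a, rules)$labels, logical(1))
  expect_equal(sum(after), 5L)
  expect_true(all(after <= before))  # labels only lost, never gained
  # empty report list is the identity
  expect_identical(apply_corrections(archs, reports[0, ]), archs)
  # a report whose overhang holds no helix changes nothing
  noop <- data.frame(protein_id = "r1", kind = "NTERM_EXTENSION",
                     overhang_length = 200L, contains_tm = FALSE,
                     suggested_action = "none", stringsAsFactors = FALSE)
  expect_equal(apply_corrections(archs, noop), archs)
  expect_error(apply_corrections(archs, transform(noop, protein_id = "zz")),
               "unknown")
})

test_that("manual add_tm records restore a helix lost to a gene-model error", {
  proteins <- protein_row("q1", "oomycete1", 800L)
  archs <- build_architectures(proteins, hit_rows("q1", "PF00560", 50, 73),
                               tm_rows(character(), integer(), integer()),
                               sp_row(character(), integer()))
  rep <- data.frame(protein_id = "q1", kind = "NTERM_EXTENSION",
                    overhang_length = 0L, contains_tm = FALSE,
                    suggested_action = "add_tm", start = 700L, end = 722L,
                    stringsAsFactors = FALSE)
  fixed <- apply_corrections(archs, rep)
  expect_equal(nrow(fixed$q1$tm_corrected), 1L)
  expect_true("LRR_RECEPTOR" %in% classify(fixed$q1, builtin_rules())$labels)
})

test_that("anomaly reports serialize to TSV including the empty case", {
  f <- tempfile()
  write_anomaly_reports(NULL, f)
  expect_equal(length(readLines(f)), 1L)
  rep <- data.frame(protein_id = "p1", kind = "NTERM_EXTENSION",
                    overhang_length = 560L, contains_tm = TRUE,
                    suggested_action = "drop_tm", stringsAsFactors = FALSE)
  write_anomaly_reports(rep, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$overhang_length, 560L)
  expect_equal(back$suggested_action, "drop_tm")
})
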