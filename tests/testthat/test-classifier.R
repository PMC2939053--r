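test_that("built-in rules encode the receptor-class definitions", {
  rules <- builtin_rules()
  expect_true(all(c("LRR_PROTEIN", "LRR_RECEPTOR", "TLR", "LRR_RK",
                    "SECRETED_LRR", "LRR_AC", "NBS_LRR", "NACHT_PROTEIN",
                    "LRR_NACHT", "STAND", "LYSM_RK") %in% names(rules)))
  expect_equal(rules$LRR_RECEPTOR$tm, tm_exactly(1))
  expect_equal(rules$LRR_RECEPTOR$required, list(lrr_pfam()))
  # TLR = LRR-receptor constraints plus a required TIR group
  expect_equal(rules$TLR$tm, tm_exactly(1))
  expect_true(list("PF01582") %in% rules$TLR$required)
  expect_true(list(lrr_pfam()) %in% rules$TLR$required)
  expect_equal(rules$SECRETED_LRR$tm, tm_exactly(0))
  expect_equal(rules$SECRETED_LRR$sp, "required")
  expect_equal(rules$LRR_RK$required[[2]], c("PF07714", "PF00069"))
  # PRR accessory-domain screens, one per domain
  for (cl in c("PRR_IG", "PRR_LECTIN_C", "PRR_TIR", "PRR_NOD", "PRR_NODP",
               "PRR_ITAM", "PRR_PYRIN", "PRR_CARD"))
    expect_true(cl %in% names(rules))
  expect_equal(rules$PRR_ITAM$required, list(c("PF02189", "PF10538")))
})

test_that("classification follows the rule semantics on canonical architectures", {
  rules <- builtin_rules()
  lab <- function(a) classify(a, rules)$labels
  a1 <- arch_of(hit_rows("p1", "PF00560", c(5, 40), c(28, 63)),
                tm_rows("p1", 300, 322))
  expect_setequal(lab(a1), c("LRR_PROTEIN", "LRR_RECEPTOR"))
  a2 <- arch_of(rbind(hit_rows("p1", "PF00560", 5, 28),
                      hit_rows("p1", "PF00069", 400, 700)),
                tm_rows("p1", 300, 322))
  expect_setequal(lab(a2), c("LRR_PROTEIN", "LRR_RECEPTOR", "LRR_RK"))
  a3 <- arch_of(hit_rows("p1", "PF00560", 5, 28),
                tm_rows("p1", c(300, 400), c(322, 422)))
  expect_equal(lab(a3), "LRR_PROTEIN")
  # TM constraints evaluate corrected helices: SP swallows the only helix
  a4 <- arch_of(hit_rows("p1", "PF00560", 40, 63),
                tm_rows("p1", 5, 27), sp_row("p1", 20))
  expect_setequal(lab(a4), c("LRR_PROTEIN", "SECRETED_LRR"))
})

test_that("classify agrees with an independent brute-force evaluator on random architectures", {
  set.seed(77)
  rules <- builtin_rules()
  for (rep in 1:200) {
    a <- random_arch()
    expect_identical(classify(a, rules)$labels, brute_force_labels(a, rules))
  }
})

test_that("vectorized table classification matches the per-architecture path", {
  set.seed(5)
  n <- 60
  proteins <- do.call(rbind, lapply(seq_len(n), function(i)
    protein_row(sprintf("p%03d", i), sample(c("s1", "s2"), 1), 1200L)))
  archs <- lapply(proteins$protein_id, function(id) random_arch(id))
  hits <- do.call(rbind, lapply(archs, `[[`, "domains"))
  tm <- do.call(rbind, lapply(archs, `[[`, "tm_corrected"))
  sp <- do.call(rbind, lapply(archs, `[[`, "signal_peptide"))
  if (is.null(sp)) sp <- sp_row(character(), integer())
  rules <- builtin_rules()
  m <- classify_proteins(proteins, hits, tm, sp, rules)
  for (i in seq_len(n)) {
    expect_setequal(colnames(m)[m[i, ]], classify(archs[[i]], rules)$labels)
  }
})

test_that("census counts per species with explicit zeros and label multiplicity", {
  rules <- builtin_rules()
  proteins <- do.call(rbind, c(
    lapply(1:6, function(i) protein_row(paste0("a", i), "spA")),
    list(protein_row("b1", "spB"))))
  hits <- rbind(hit_rows(paste0("a", 1:6), "PF00560", 5, 28),
                hit_rows("b1", "PF00560", 5, 28),
                hit_rows("b1", "PF00211", 100, 300))
  labels <- classify_proteins(proteins, hits,
                              tm_rows(character(), integer(), integer()),
                              sp_row(character(), integer()), rules)
  cen <- census(labels, proteins, rules)
  expect_equal(cen["spA", "LRR_PROTEIN"], c(spA = 6L), ignore_attr = TRUE)
  expect_equal(cen["spA", "TLR"], c(spA = 0L), ignore_attr = TRUE)
  # one protein with several labels increments each class once
  expect_equal(cen["spB", "LRR_PROTEIN"], 1L, ignore_attr = TRUE)
  expect_equal(cen["spB", "LRR_AC"], 1L, ignore_attr = TRUE)
  expect_equal(cen["spB", "AC_PROTEIN"], 1L, ignore_attr = TRUE)
  # permuting protein order never changes counts
  perm <- sample(nrow(proteins))
  cen2 <- census(labels[perm, , drop = FALSE], proteins[perm, ], rules)
  expect_equal(cen2, cen)
  # empty input gives an all-zero table
  cen0 <- census(labels[0, , drop = FALSE], proteins[0, ], rules)
  expect_equal(sum(cen0), 0)
})

test_that("taxon summaries apply the high/low/receptor-free thresholds", {
  rules <- builtin_rules()
  m <- matrix(0L, 3, length(rules),
              dimnames = list(c("s1", "s2", "s3"), names(rules)))
  m[, "LRR_PROTEIN"] <- c(6L, 12L, 25L)
  m[, "LRR_RECEPTOR"] <- c(0L, 0L, 3L)
  cen <- structure(m, class = "lrr_census")
  tax <- data.frame(species_id = c("s1", "s2", "s3"),
                    taxon_path = rep("fungi/ascomycota", 3))
  s <- summarize_census(cen, tax)
  expect_equal(s$by_taxon$n_species, 3L)
  expect_equal(s$by_taxon$n_lrr_high, 1L)   # one species >= 20
  expect_equal(s$by_taxon$n_lrr_low, 1L)    # one species < 10
  expect_equal(s$by_taxon$n_receptor_free, 2L)
  rng <- s$class_range[s$class_range$class == "LRR_PROTEIN", ]
  expect_equal(rng$min_species, "s1")
  expect_equal(rng$max_count, 25L)
  expect_error(summarize_census(cen, tax[1:2, ]), "missing")
})

test_that("domain-order checks accept ordered subsequences with gaps and repeats", {
  ord <- c("PF08509", "PF00560", "PF00211")
  good <- arch_of(rbind(hit_rows("p1", "PF08509", 10, 100),
                        hit_rows("p1", "PF00560", c(300, 330), c(323, 353)),
                        hit_rows("p1", "PF00211", 900, 950)))
  expect_true(architecture_order_check(good, ord))
  inverted <- arch_of(rbind(hit_rows("p1", "PF00211", 10, 100),
                            hit_rows("p1", "PF08509", 900, 950)))
  expect_false(architecture_order_check(inverted, ord))
  # missing the N-terminal domain entirely is still consistent
  partial <- arch_of(rbind(hit_rows("p1", "PF00560", 300, 323),
                           hit_rows("p1", "PF00211", 900, 950)))
  expect_true(architecture_order_check(partial, ord))
})

test_that("rule sets round-trip through their YAML serialization", {
  rules <- builtin_rules()
  f <- tempfile(fileext = ".yaml")
  write_rules(rules, f)
  back <- read_rules(f)
  expect_equal(names(back), names(rules))
  for (nm in names(rules)) {
    expect_equal(back[[nm]]$required, rules[[nm]]$required)
    expect_equal(back[[nm]]$tm, rules[[nm]]$tm)
    expect_equal(back[[nm]]$sp, rules[[nm]]$sp)
  }
  custom <- rule_set(list(class_rule("MY_CLASS", required = list("PF99999"),
                                     forbidden = "PF00001",
                                     tm = tm_at_least(2), sp = "forbidden")))
  write_rules(custom, f)
  expect_equal(read_rules(f)$MY_CLASS[1:5], custom$MY_CLASS[1:5])
})
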