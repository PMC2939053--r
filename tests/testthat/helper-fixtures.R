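# Small in-code fixture builders shared across test files.

protein_row <- function(id = "p1", species = "s1", length = 500L,
                        sequence = NA_character_) {
  data.frame(protein_id = id, species_id = species, length = length,
             sequence = sequence, stringsAsFactors = FALSE)
}

hit_rows <- function(id, accession, start, end, name = accession,
                     bit_score = 30, e_value = 1e-8) {
  data.frame(protein_id = id, accession = accession, name = name,
             start = as.integer(start), end = as.integer(end),
             bit_score = bit_score, e_value = e_value,
             stringsAsFactors = FALSE)
}

tm_rows <- function(id, start, end) {
  data.frame(protein_id = id, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

sp_row <- function(id, end) {
  data.frame(protein_id = id, end = as.integer(end),
             stringsAsFactors = FALSE)
}

arch_of <- function(hits = NULL, tm = NULL, sp = NULL, id = "p1",
                    length = 1000L) {
  build_architecture(protein_row(id, length = length), hits, tm, sp)
}

write_fasta_text <- function(lines, path = tempfile(fileext = ".fasta")) {
  writeLines(lines, path)
  path
}

# Draw a random small architecture for property tests: <= 6 domains from a
# mixed accession pool, <= 3 helices, optional signal peptide.
random_arch <- function(id = "p") {
  pool <- c(lrr_pfam(), "PF00069", "PF07714", "PF01582", "PF00211",
            "PF05729", "PF00400", "PF06985", "PF00931", "PF01476")
  n_dom <- sample(0:6, 1)
  n_tm <- sample(0:3, 1)
  len <- 1200L
  hits <- if (n_dom > 0) {
    starts <- sort(sample(30:900, n_dom))
    hit_rows(id, sample(pool, n_dom, replace = TRUE), starts, starts + 40L)
  }
  tm <- if (n_tm > 0) {
    starts <- sort(sample(seq(30L, 1100L, by = 40L), n_tm))
    tm_rows(id, starts, starts + 22L)
  }
  sp <- if (runif(1) < 0.3) sp_row(id, sample(15:25, 1))
  build_architecture(protein_row(id, length = len), hits, tm, sp)
}

# Brute-force rule evaluator, independent of the classifier: tests each
# clause of each rule directly against the architecture tables.
brute_force_labels <- function(arch, rules) {
  out <- character()
  for (rule in rules) {
    ok <- TRUE
    for (grp in rule$required) {
      found <- FALSE
      for (acc in arch$domains$accession) if (acc %in% grp) found <- TRUE
      if (!found) ok <- FALSE
    }
    for (acc in arch$domains$accession)
      if (acc %in% rule$forbidden) ok <- FALSE
    k <- nrow(arch$tm_corrected)
    if (rule$tm$op == "eq" && k != rule$tm$k) ok <- FALSE
    if (rule$tm$op == "ge" && k < rule$tm$k) ok <- FALSE
    if (rule$sp == "required" && is.null(arch$signal_peptide)) ok <- FALSE
    if (rule$sp == "forbidden" && !is.null(arch$signal_peptide)) ok <- FALSE
    if (ok) out <- c(out, rule$name)
  }
  out
}
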