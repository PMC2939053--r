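#' Specify one simulated species
#'
#' @param species_id Species identifier.
#' @param taxon_path Slash-separated taxon path (e.g. `"fungi/ascomycota"`).
#' @param n_proteins Number of proteins to generate.
#' @param frequencies Named numeric vector of architecture-template
#'   probabilities (see [sim_templates()]); must sum to <= 1, the
#'   remainder becomes untracked background proteins.
#' @param artifact_rates List with elements `sp_tm_overlap` (probability
#'   that a signal-peptide-bearing protein gains a false TM helix inside
#'   its signal peptide), `nterm_extension` (probability that an
#'   LRR-bearing membrane-free protein gains a spurious N-terminal
#'   gene-model extension carrying a TM helix) and `extension_length`
#'   (residues, default 560).
#' @return A `sim_species` spec (plain list).
#' @export
sim_species <- function(species_id, taxon_path, n_proteins,
                        frequencies,
                        artifact_rates = list(sp_tm_overlap = 0,
                                              nterm_extension = 0,
                                              extension_length = 560L)) {
  unknown <- setdiff(names(frequencies), sim_templates())
  if (length(unknown) > 0L)
    abort("unknown architecture template(s): %s",
          paste(unknown, collapse = ", "))
  if (any(frequencies < 0) || sum(frequencies) > 1 + 1e-9)
    abort("template frequencies for '%s' must be in [0,1] and sum to <= 1",
          species_id)
  ar <- utils::modifyList(list(sp_tm_overlap = 0, nterm_extension = 0,
                               extension_length = 560L), artifact_rates)
  if (ar$sp_tm_overlap < 0 || ar$sp_tm_overlap > 1 ||
      ar$nterm_extension < 0 || ar$nterm_extension > 1 ||
      ar$extension_length < 1)
    abort("invalid artifact rates for '%s'", species_id)
  list(species_id = species_id, taxon_path = taxon_path,
       n_proteins = as.integer(n_proteins), frequencies = frequencies,
       artifact_rates = ar)
}

#' Simulation configuration
#'
#' @param seed Master seed; each species derives its own reproducible RNG
#'   stream from `(seed, species_id)`.
#' @param species List of [sim_species()] specs.
#' @param length_mean,length_sd Protein-length model (normal, truncated at
#'   each template's minimum viable length); defaults 600 +/- 150
#'   residues.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, species, length_mean = 600, length_sd = 150) {
  ids <- vapply(species, `[[`, character(1), "species_id")
  if (anyDuplicated(ids)) abort("duplicate species ids in sim config")
  list(seed = as.integer(seed), species = species,
       length_mean = length_mean, length_sd = length_sd)
}

#' Names of the built-in architecture templates
#'
#' `LRR_only` (repeats, no membrane anchor), `LRR_1TM` (a canonical
#' single-pass LRR receptor), `LRR_1TM_TIR` (Toll-like receptor),
#' `LRR_1TM_KINASE` (LRR receptor kinase), `SP_LRR_secreted` (signal
#' peptide, no TM), `fungal_AC` (the conserved multi-domain adenylate
#' cyclase: G-alpha binding PF08509, Ras-association PF00788, LRR
#' repeats, protein phosphatase 2C PF00481, catalytic PF00211, N-to-C),
#' `NACHT_WD`, `HET_NACHT_WD` (STAND architecture) and `background`.
#'
#' @return Character vector of template names.
#' @export
sim_templates <- function() {
  c("LRR_only", "LRR_1TM", "LRR_1TM_TIR", "LRR_1TM_KINASE",
    "SP_LRR_secreted", "fungal_AC", "NACHT_WD", "HET_NACHT_WD",
    "background")
}

# Internal: derive a species-specific 31-bit seed from the master seed.
species_seed <- function(seed, species_id) {
  h <- 0
  for (c in utf8ToInt(species_id)) h <- (h * 31 + c) %% 2147483647
  as.integer((h + (seed %% 1000003) * 10007) %% 2147483647)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_residues <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

# Internal: minimum protein length each template needs for its layout.
template_min_len <- c(LRR_only = 220, LRR_1TM = 420, LRR_1TM_TIR = 560,
                      LRR_1TM_KINASE = 600, SP_LRR_secreted = 240,
                      fungal_AC = 1700, NACHT_WD = 900,
                      HET_NACHT_WD = 1000, background = 120)

# Internal: one domain-hit row with simulated score/e-value.
hit_row <- function(pid, acc, name, start, end) {
  data.frame(protein_id = pid, accession = acc, name = name,
             start = as.integer(start), end = as.integer(end),
             bit_score = round(runif(1, 25, 120), 1),
             e_value = signif(10^runif(1, -40, -6), 3),
             stringsAsFactors = FALSE)
}

# Internal: a run of 24-residue LRR repeat hits starting at `from`,
# confined to [from, max_end].
lrr_hits <- function(pid, from, n, max_end) {
  starts <- from + (seq_len(n) - 1L) * 24L
  keep <- starts + 23L <= max_end
  if (!any(keep)) keep[1L] <- TRUE
  starts <- starts[keep]
  accs <- sample(lrr_pfam(), length(starts), replace = TRUE,
                 prob = c(0.7, 0.2, 0.1))
  do.call(rbind, mapply(function(s, a)
    hit_row(pid, a, "LRR", s, min(s + 23L, max_end)),
    starts, accs, SIMPLIFY = FALSE))
}

# Internal: instantiate one template at length L. Returns hits / tm /
# sp_end describing the TRUE (artifact-free) architecture.
instantiate_template <- function(template, pid, L) {
  hits <- NULL; tm <- NULL; sp_end <- NA_integer_
  tm_row <- function(s, e) data.frame(protein_id = pid, start = as.integer(s),
                                      end = as.integer(e),
                                      stringsAsFactors = FALSE)
  n_rep <- function() 2L + stats::rpois(1L, 2L)
  switch(template,
    background = {
      if (runif(1) < 0.5 && L > 260L)
        hits <- hit_row(pid, "PF00069", "Pkinase", L - 200L, L - 60L)
      if (runif(1) < 0.3) tm <- tm_row(50L, 72L)
    },
    LRR_only = {
      hits <- lrr_hits(pid, 30L, n_rep(), L - 10L)
    },
    LRR_1TM = {
      hits <- lrr_hits(pid, 30L, n_rep(), L - 320L)
      tm <- tm_row(L - 300L, L - 278L)
    },
    LRR_1TM_TIR = {
      hits <- rbind(lrr_hits(pid, 30L, n_rep(), L - 320L),
                    hit_row(pid, "PF01582", "TIR", L - 180L, L - 40L))
      tm <- tm_row(L - 300L, L - 278L)
    },
    LRR_1TM_KINASE = {
      kin <- if (runif(1) < 0.2) "PF07714" else "PF00069"
      hits <- rbind(lrr_hits(pid, 30L, n_rep(), L - 320L),
                    hit_row(pid, kin, "Pkinase", L - 260L, L - 40L))
      tm <- tm_row(L - 300L, L - 278L)
    },
    SP_LRR_secreted = {
      sp_end <- sample(18:25, 1L)
      hits <- lrr_hits(pid, 40L, n_rep(), L - 10L)
    },
    fungal_AC = {
      parts <- list()
      drop_galpha <- runif(1) < 0.3
      if (!drop_galpha)
        parts$galpha <- hit_row(pid, "PF08509", "AC_G-alpha_bind", 60L, 160L)
      if (!(drop_galpha && runif(1) < 0.5))
        parts$ra <- hit_row(pid, "PF00788", "RA", 220L, 310L)
      parts$lrr <- lrr_hits(pid, 500L, 5L, 850L)
      parts$pp2c <- hit_row(pid, "PF00481", "PP2C", 900L, 1150L)
      parts$cyc <- hit_row(pid, "PF00211", "Guanylate_cyc", 1300L, 1480L)
      hits <- do.call(rbind, unname(parts))
    },
    NACHT_WD = {
      wd <- do.call(rbind, lapply(0:3, function(i)
        hit_row(pid, "PF00400", "WD40", 600L + i * 45L, 640L + i * 45L)))
      hits <- rbind(hit_row(pid, "PF05729", "NACHT", 150L, 450L), wd)
    },
    HET_NACHT_WD = {
      wd <- do.call(rbind, lapply(0:3, function(i)
        hit_row(pid, "PF00400", "WD40", 700L + i * 45L, 740L + i * 45L)))
      hits <- rbind(hit_row(pid, "PF06985", "HET", 10L, 180L),
                    hit_row(pid, "PF05729", "NACHT", 250L, 550L), wd)
    },
    abort("unknown template '%s'", template))
  list(hits = hits, tm = tm, sp_end = sp_end)
}

#' Generate a synthetic annotated proteome with planted ground truth
#'
#' Emulates the statistical structure the census analysis assumes:
#' species-specific frequencies of receptor architectures, topology
#' false positives (TM helices planted inside signal peptides) and
#' gene-model errors (spurious N-terminal extensions that carry the
#' protein's only predicted helix, each accompanied by a homolog-family
#' alignment whose homologs lack the extension).  Ground-truth labels are
#' the built-in classifier's labels for the artifact-free architecture,
#' so an ideal pipeline run (parse, correct, classify) reproduces them
#' exactly.
#'
#' Byte-identical output for a fixed seed; each species uses its own RNG
#' stream derived from `(seed, species_id)`.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `proteins.fasta`,
#'   `domains.tsv`, `tm.tsv`, `sp.tsv`, `taxonomy.tsv`, `truth.tsv` and
#'   per-protein `alignments/<id>.fasta` for extension artifacts.
#' @param rules Rule set used to derive truth labels (default
#'   [builtin_rules()]).
#' @return List with the generated tables (`proteins`, `hits`, `tm`, `sp`,
#'   `taxonomy`, `truth`), `families` (homolog families for planted
#'   extensions) and `files` (paths, when `out_dir` given).
#' @export
generate <- function(config, out_dir = NULL, rules = builtin_rules()) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  per_species <- lapply(config$species, function(spec)
    generate_species(spec, config, rules))
  bind <- function(field) {
    parts <- lapply(per_species, `[[`, field)
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0L) return(NULL)
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  }
  taxonomy <- data.frame(
    species_id = vapply(config$species, `[[`, character(1), "species_id"),
    taxon_path = vapply(config$species, `[[`, character(1), "taxon_path"),
    stringsAsFactors = FALSE)
  families <- do.call(c, lapply(per_species, `[[`, "families"))
  ds <- list(proteins = bind("proteins"), hits = bind("hits") %||% empty_hits(),
             tm = bind("tm") %||% empty_tm(),
             sp = bind("sp") %||% data.frame(protein_id = character(),
                                             end = integer(),
                                             stringsAsFactors = FALSE),
             taxonomy = taxonomy, truth = bind("truth"),
             families = families %||% list())
  if (!is.null(out_dir)) ds$files <- write_dataset(ds, out_dir)
  ds
}

# Internal: generate one species under its own RNG stream.
generate_species <- function(spec, config, rules) {
  set.seed(species_seed(config$seed, spec$species_id))
  n <- spec$n_proteins
  freq <- spec$frequencies
  templates <- sample(c(names(freq), "background"), n, replace = TRUE,
                      prob = c(freq, max(0, 1 - sum(freq))))
  pids <- sprintf("%s_p%04d", spec$species_id, seq_len(n))
  hits_l <- vector("list", n); tm_true_l <- vector("list", n)
  sp_end <- rep(NA_integer_, n)
  lens <- pmax(template_min_len[templates],
               as.integer(round(rnorm(n, config$length_mean,
                                      config$length_sd))))
  for (i in seq_len(n)) {
    inst <- instantiate_template(templates[i], pids[i], lens[i])
    hits_l[i] <- list(inst$hits)    # [[<-]] with NULL would drop the slot
    tm_true_l[i] <- list(inst$tm)
    sp_end[i] <- inst$sp_end
  }
  rbind_all <- function(l) {
    l <- l[!vapply(l, is.null, logical(1))]
    if (length(l) == 0L) NULL else do.call(rbind, l)
  }
  hits <- rbind_all(hits_l) %||% empty_hits()
  tm_true <- rbind_all(tm_true_l) %||% empty_tm()
  sp <- data.frame(protein_id = pids[!is.na(sp_end)],
                   end = sp_end[!is.na(sp_end)], stringsAsFactors = FALSE)
  proteins_true <- data.frame(protein_id = pids,
                              species_id = spec$species_id,
                              length = lens, sequence = NA_character_,
                              stringsAsFactors = FALSE)
  # truth labels from the artifact-free architecture
  labels <- classify_proteins(proteins_true, hits,
                              correct_tm_helices(tm_true, sp), sp, rules)
  # apply planted artifacts to the EMITTED annotations
  ar <- spec$artifact_rates
  artifacts <- rep("", n)
  tm_emit_l <- tm_true_l
  families <- list()
  ext <- as.integer(ar$extension_length)
  has_sp <- !is.na(sp_end)
  lrr_count <- tabulate(match(
    hits$protein_id[hits$accession %in% lrr_pfam()], pids), nbins = n)
  no_tm <- !pids %in% tm_true$protein_id
  sp_overlap_sel <- has_sp & runif(n) < ar$sp_tm_overlap
  ext_sel <- !has_sp & no_tm & lrr_count > 0L & runif(n) < ar$nterm_extension
  for (i in which(sp_overlap_sel)) {
    helix <- data.frame(protein_id = pids[i],
                        start = max(1L, sp_end[i] - 18L),
                        end = sp_end[i], stringsAsFactors = FALSE)
    tm_emit_l[[i]] <- rbind(tm_emit_l[[i]], helix)
    artifacts[i] <- "SP_TM_OVERLAP"
  }
  lens_emit <- lens
  for (i in which(ext_sel)) {
    lens_emit[i] <- lens[i] + ext
    hits_l[[i]]$start <- hits_l[[i]]$start + ext
    hits_l[[i]]$end <- hits_l[[i]]$end + ext
    helix_end <- if (ext > 33L) ext - 10L else ext
    helix <- data.frame(protein_id = pids[i],
                        start = max(1L, helix_end - 22L),
                        end = helix_end, stringsAsFactors = FALSE)
    tm_emit_l[[i]] <- rbind(tm_emit_l[[i]], helix)
    artifacts[i] <- paste0(artifacts[i], "NTERM_EXTENSION")
  }
  # sequences (after extension, so FASTA lengths match emitted lengths)
  seqs <- vapply(lens_emit, rand_residues, character(1))
  # homolog families for extension artifacts: homologs lack the extension
  for (i in which(ext_sel)) {
    core <- substring(seqs[i], ext + 1L)
    homs <- vapply(seq_len(5L), function(k) {
      chars <- strsplit(core, "", fixed = TRUE)[[1L]]
      mut <- runif(length(chars)) < 0.1
      chars[mut] <- sample(AA20, sum(mut), replace = TRUE)
      paste0(strrep("-", ext), paste(chars, collapse = ""))
    }, character(1))
    fam <- homolog_family(pids[i], c(setNames(seqs[i], pids[i]),
                                     setNames(homs, paste0("homolog_", 1:5))))
    families[[pids[i]]] <- fam
  }
  truth <- data.frame(
    protein_id = pids, template = templates,
    labels = vapply(seq_len(n), function(i)
      paste(colnames(labels)[labels[i, ]], collapse = ";"), character(1)),
    artifacts = artifacts, stringsAsFactors = FALSE)
  list(proteins = transform(proteins_true, length = lens_emit,
                            sequence = seqs),
       hits = rbind_all(hits_l) %||% empty_hits(),
       tm = rbind_all(tm_emit_l) %||% empty_tm(),
       sp = sp, truth = truth, families = families)
}

# Internal: serialize a generated dataset into the dialects the readers
# consume.
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  fa <- Biostrings::AAStringSet(setNames(ds$proteins$sequence,
                                         ds$proteins$protein_id))
  write_atomic(function(tmp) Biostrings::writeXStringSet(fa, tmp),
               p("proteins.fasta"))
  write_tsv(ds$hits, p("domains.tsv"))
  write_tsv(ds$tm, p("tm.tsv"))
  write_tsv(ds$sp, p("sp.tsv"))
  write_tsv(ds$taxonomy, p("taxonomy.tsv"))
  write_tsv(ds$truth, p("truth.tsv"))
  files <- list(proteins = p("proteins.fasta"), domains = p("domains.tsv"),
                tm = p("tm.tsv"), sp = p("sp.tsv"),
                taxonomy = p("taxonomy.tsv"), truth = p("truth.tsv"))
  if (length(ds$families) > 0L) {
    aln_dir <- p("alignments")
    dir.create(aln_dir, showWarnings = FALSE)
    for (pid in names(ds$families)) {
      fam <- ds$families[[pid]]
      set <- Biostrings::AAStringSet(fam$sequences)
      write_atomic(function(tmp) Biostrings::writeXStringSet(set, tmp),
                   file.path(aln_dir, paste0(pid, ".fasta")))
    }
    files$alignments <- aln_dir
  }
  files
}

#' Simulate a similarity graph with a planted partition
#'
#' Complete within-cluster edges with e-values drawn log-uniformly from
#' `10^within_e`, sparse between-cluster edges from `10^between_e`.  In
#' separable mode the within range must lie entirely at or below the
#' e-value cutoff and the between range entirely above it, so
#' thresholding alone recovers the planted partition.
#'
#' @param n_clusters Number of planted clusters.
#' @param cluster_sizes Sizes (recycled to `n_clusters`).
#' @param within_e,between_e Log10 e-value ranges (defaults `c(-50, -20)`
#'   and `c(-10, -1)`).
#' @param seed RNG seed.
#' @param e_cutoff Cutoff the graph will be built with (default `1e-15`),
#'   used only to validate separability.
#' @param between_density Probability of each between-cluster edge
#'   (default 0.2).
#' @param separable Enforce range separation around the cutoff
#'   (default `TRUE`).
#' @return List with `edges` (data.frame `a`, `b`, `e_value`) and
#'   `membership` (data.frame `id`, `cluster`).
#' @export
simulate_similarity_graph <- function(n_clusters, cluster_sizes,
                                      within_e = c(-50, -20),
                                      between_e = c(-10, -1),
                                      seed = 1L, e_cutoff = 1e-15,
                                      between_density = 0.2,
                                      separable = TRUE) {
  if (separable &&
      (max(within_e) > log10(e_cutoff) || min(between_e) <= log10(e_cutoff)))
    abort(paste("separable mode requires within_e entirely at/below the",
                "cutoff and between_e entirely above it"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  sizes <- rep_len(cluster_sizes, n_clusters)
  ids <- unlist(lapply(seq_len(n_clusters), function(k)
    sprintf("c%02d_n%03d", k, seq_len(sizes[k]))))
  member <- rep(seq_len(n_clusters), sizes)
  edges <- list()
  for (k in seq_len(n_clusters)) {
    nodes <- ids[member == k]
    if (length(nodes) < 2L) next
    pr <- t(utils::combn(nodes, 2L))
    edges[[length(edges) + 1L]] <- data.frame(
      a = pr[, 1L], b = pr[, 2L],
      e_value = 10^runif(nrow(pr), within_e[1L], within_e[2L]),
      stringsAsFactors = FALSE)
  }
  if (n_clusters > 1L) {
    cross <- which(outer(member, member, "<"), arr.ind = TRUE)
    cross <- cross[member[cross[, 1L]] != member[cross[, 2L]], , drop = FALSE]
    pick <- runif(nrow(cross)) < between_density
    if (any(pick)) {
      cr <- cross[pick, , drop = FALSE]
      edges[[length(edges) + 1L]] <- data.frame(
        a = ids[cr[, 1L]], b = ids[cr[, 2L]],
        e_value = 10^runif(nrow(cr), between_e[1L], between_e[2L]),
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else
    data.frame(a = character(), b = character(), e_value = numeric(),
               stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  list(edges = edges,
       membership = data.frame(id = ids, cluster = member,
                               stringsAsFactors = FALSE))
}

#' Simulate a homolog family with a planted N-terminal overhang
#'
#' The query carries `overhang` extra N-terminal residues absent (gapped)
#' in every homolog; a TM helix is planted inside the overhang when one
#' exists, otherwise mid-protein.  Used to exercise
#' [detect_nterm_extension()] with a known answer.
#'
#' @param query_length Total query length including the overhang.
#' @param overhang Planted overhang length in residues (>= 0); default 560.
#' @param n_homologs Number of homolog rows (>= 1); default 5.
#' @param seed RNG seed.
#' @param query_id,species_id Identifiers for the query.
#' @return List with `family` (a `homolog_family`), `query` (protein row),
#'   `tm` (helix table), and `truth_overhang`.
#' @export
simulate_homolog_family <- function(query_length, overhang = 560L,
                                    n_homologs = 5L, seed = 1L,
                                    query_id = "query",
                                    species_id = "sim") {
  if (n_homologs < 1L) abort("n_homologs must be >= 1")
  if (overhang >= query_length) abort("overhang must be < query_length")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  qseq <- rand_residues(query_length)
  core <- substring(qseq, overhang + 1L)
  homs <- vapply(seq_len(n_homologs), function(k) {
    chars <- strsplit(core, "", fixed = TRUE)[[1L]]
    mut <- runif(length(chars)) < 0.1
    chars[mut] <- sample(AA20, sum(mut), replace = TRUE)
    paste0(strrep("-", overhang), paste(chars, collapse = ""))
  }, character(1))
  fam <- homolog_family(query_id, c(
    setNames(qseq, query_id),
    setNames(homs, sprintf("homolog_%d", seq_len(n_homologs)))))
  if (overhang >= 41L) {
    tm_end <- overhang - 10L
    tm <- data.frame(protein_id = query_id, start = tm_end - 22L,
                     end = tm_end, stringsAsFactors = FALSE)
  } else {
    mid <- as.integer(round(query_length * 0.6))
    tm <- data.frame(protein_id = query_id, start = mid,
                     end = mid + 22L, stringsAsFactors = FALSE)
  }
  list(family = fam,
       query = data.frame(protein_id = query_id, species_id = species_id,
                          length = as.integer(query_length),
                          sequence = qseq, stringsAsFactors = FALSE),
       tm = tm, truth_overhang = as.integer(overhang))
}
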