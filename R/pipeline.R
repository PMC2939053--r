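# Internal: stage logger -- timestamped record counts on stderr.
log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                  stage, sprintf(fmt, ...)))
}

#' Default simulation configuration for a whole-census run
#'
#' Twenty species across four taxa (ten fungi, four land plants, four
#' metazoa, two oomycetes -- the fungus-heavy sampling the census is
#' designed around), 500 proteins each, with taxon-specific architecture
#' frequencies: plants rich in LRR receptor kinases, metazoa carrying
#' Toll-like receptors, fungi nearly receptor-free but with one
#' LRR-adenylate-cyclase and occasional NACHT/STAND architectures,
#' oomycetes carrying receptor kinases.
#'
#' @param seed Master seed.
#' @param n_species Total species count (allocated 50% fungi, 20% plants,
#'   20% metazoa, 10% oomycetes); default 20.
#' @param n_proteins Proteins per species; default 500.
#' @param sp_tm_overlap,nterm_extension Artifact rates applied uniformly
#'   (default 0 = artifact-free).
#' @param extension_length Spurious-extension length in residues
#'   (default 560).
#' @return A [sim_config()].
#' @export
default_sim_config <- function(seed, n_species = 20L, n_proteins = 500L,
                               sp_tm_overlap = 0, nterm_extension = 0,
                               extension_length = 560L) {
  n_fungi <- max(1L, round(n_species * 0.5))
  n_plant <- max(1L, round(n_species * 0.2))
  n_metaz <- max(1L, round(n_species * 0.2))
  n_oomyc <- max(1L, n_species - n_fungi - n_plant - n_metaz)
  freqs <- list(
    fungi = c(LRR_only = 0.010, SP_LRR_secreted = 0.004,
              fungal_AC = 0.002, NACHT_WD = 0.010, HET_NACHT_WD = 0.004),
    plants = c(LRR_only = 0.100, LRR_1TM = 0.040, LRR_1TM_KINASE = 0.060,
               SP_LRR_secreted = 0.010),
    metazoa = c(LRR_only = 0.080, LRR_1TM = 0.040, LRR_1TM_TIR = 0.020,
                LRR_1TM_KINASE = 0.010, SP_LRR_secreted = 0.010),
    oomycetes = c(LRR_only = 0.040, LRR_1TM = 0.020,
                  LRR_1TM_KINASE = 0.030))
  rates <- list(sp_tm_overlap = sp_tm_overlap,
                nterm_extension = nterm_extension,
                extension_length = extension_length)
  mk <- function(taxon, sub, k, i) {
    sim_species(sprintf("%s_sp%02d", sub, i), paste0(taxon, "/", sub),
                n_proteins, freqs[[taxon]], rates)
  }
  species <- c(
    lapply(seq_len(n_fungi), function(i)
      mk("fungi", c("ascomycota", "basidiomycota")[1L + i %% 2L], n_fungi, i)),
    lapply(seq_len(n_plant), function(i) mk("plants", "land_plants", n_plant, i)),
    lapply(seq_len(n_metaz), function(i) mk("metazoa", "deuterostomia", n_metaz, i)),
    lapply(seq_len(n_oomyc), function(i) mk("oomycetes", "peronosporales", n_oomyc, i)))
  sim_config(seed, species)
}

#' Assemble a pipeline configuration
#'
#' One structured source of truth for a run; [read_pipeline_config()]
#' loads the same structure from a YAML file.  All unset fields take the
#' documented defaults.
#'
#' @param inputs Named list of paths: `proteins`, `domains`, `tm`, `sp`,
#'   `taxonomy`, optional `alignments` (directory of aligned FASTA, one
#'   file `<protein_id>.fasta` per suspect protein) and `edges` (edge-list
#'   TSV for clustering).
#' @param rules `"builtin"` or a path to a YAML rule set
#'   ([write_rules()]).
#' @param lrr_accessions LRR accessions (default [lrr_pfam()]).
#' @param dialects Named list of input dialects (defaults: all `"tsv"`).
#' @param anomaly List: `occupancy`, `min_overhang`, `nterm_accessions`
#'   (`NULL` disables the misplaced-domain screen), `position_fraction`.
#' @param clustering List: `e_cutoff`, `inflation`, `zero_cap`.
#' @param thresholds List: `high`, `low` census summary thresholds.
#' @param correct_tm Apply the signal-peptide/TM overlap correction
#'   (default `TRUE`; disabling is only useful for demonstrating the
#'   correction's effect).
#' @param strict Strict cross-referencing of annotations to proteins.
#' @param out Output directory.
#' @param seed Seed for `simulate` runs.
#' @param simulate Optional [sim_config()] (or arguments for
#'   [default_sim_config()]) driving [run_simulate()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(inputs = list(), rules = "builtin",
                            lrr_accessions = lrr_pfam(),
                            dialects = list(),
                            anomaly = list(), clustering = list(),
                            thresholds = list(), correct_tm = TRUE,
                            strict = TRUE, out = NULL, seed = 1L,
                            simulate = NULL, simulate_graph = NULL) {
  cfg <- list(
    inputs = inputs, rules = rules, lrr_accessions = lrr_accessions,
    dialects = utils::modifyList(
      list(domains = "tsv", tm = "tsv", sp = "tsv"), dialects),
    anomaly = utils::modifyList(
      list(occupancy = 0.5, min_overhang = 100L,
           nterm_accessions = NULL, position_fraction = 0.25), anomaly),
    clustering = utils::modifyList(
      list(e_cutoff = 1e-15, inflation = 1.5, zero_cap = 200), clustering),
    thresholds = utils::modifyList(list(high = 20L, low = 10L), thresholds),
    correct_tm = isTRUE(correct_tm), strict = isTRUE(strict),
    out = out, seed = as.integer(seed), simulate = simulate,
    simulate_graph = simulate_graph)
  if (cfg$clustering$inflation <= 1)
    abort("clustering inflation must be > 1")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML config path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

# Internal: resolve the rule set named by a config.
config_rules <- function(config) {
  if (identical(config$rules, "builtin"))
    builtin_rules(lrr_accessions = config$lrr_accessions)
  else if (inherits(config$rules, "rule_set")) config$rules
  else read_rules(config$rules)
}

# Internal: check required input paths up front, so failures name the file.
require_inputs <- function(config, fields) {
  for (f in fields) {
    p <- config$inputs[[f]]
    if (is.null(p)) abort("config lacks required input '%s'", f)
    if (!file.exists(p)) abort("input '%s' not found: '%s'", f, p)
  }
}

#' Run the census pipeline
#'
#' Fixed stage order: parse, TM/signal-peptide correction, architectures,
#' anomaly detection (alignment-based when an alignments directory is
#' configured, plus the misplaced-N-terminal-domain screen when
#' `nterm_accessions` is set), anomaly corrections, classification,
#' census, taxon summary.  Identical inputs give identical outputs;
#' per-stage record counts are logged to stderr.
#'
#' Writes `census.tsv`, `summary.tsv`, `anomalies.tsv`, `labels.tsv` and
#' `run_summary.json` under `config$out` when set.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `census`, `summary`, `anomalies`,
#'   `labels` (logical matrix) and `files`.
#' @export
run_census <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  require_inputs(config, c("proteins", "domains", "tm", "sp", "taxonomy"))
  rules <- config_rules(config)
  proteins <- do.call(rbind, parse_proteins_input(config))
  log_stage("parse", "%d proteins", nrow(proteins))
  hits <- read_domain_hits(config$inputs$domains,
                           dialect = config$dialects$domains,
                           proteins = proteins, strict = config$strict)
  tm <- read_tm_helices(config$inputs$tm, dialect = config$dialects$tm,
                        proteins = proteins, strict = config$strict)
  sp <- read_signal_peptides(config$inputs$sp, dialect = config$dialects$sp,
                             proteins = proteins, strict = config$strict)
  taxonomy <- read_taxonomy(config$inputs$taxonomy)
  log_stage("parse", "%d domain hits, %d TM helices, %d signal peptides",
            nrow(hits), nrow(tm), nrow(sp))
  tm_corr <- if (config$correct_tm) correct_tm_helices(tm, sp) else tm
  log_stage("correct", "%d of %d TM helices survive SP overlap correction",
            nrow(tm_corr), nrow(tm))
  reports <- detect_anomalies(config, proteins, hits, tm_corr, sp)
  log_stage("anomaly", "%d reports", nrow(reports))
  tm_final <- apply_corrections_tm(tm_corr, reports)
  labels <- classify_proteins(proteins, hits, tm_final, sp, rules)
  log_stage("classify", "%d proteins against %d classes",
            nrow(labels), ncol(labels))
  cen <- census(labels, proteins, rules)
  check_census_laws(cen)
  summ <- summarize_census(cen, taxonomy, high = config$thresholds$high,
                           low = config$thresholds$low)
  files <- NULL
  if (!is.null(config$out)) {
    out <- config$out
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    files <- list(census = file.path(out, "census.tsv"),
                  summary = file.path(out, "summary.tsv"),
                  anomalies = file.path(out, "anomalies.tsv"),
                  labels = file.path(out, "labels.tsv"),
                  run_summary = file.path(out, "run_summary.json"))
    write_census(cen, files$census)
    write_tsv(summ$by_taxon, files$summary)
    write_anomaly_reports(reports, files$anomalies)
    lab_df <- data.frame(protein_id = rownames(labels),
                         labels = apply(labels, 1L, function(r)
                           paste(colnames(labels)[r], collapse = ";")),
                         stringsAsFactors = FALSE)
    write_tsv(lab_df, files$labels)
    run_info <- list(stage_counts = list(
      proteins = nrow(proteins), domain_hits = nrow(hits),
      tm_raw = nrow(tm), tm_corrected = nrow(tm_corr),
      tm_final = nrow(tm_final), signal_peptides = nrow(sp),
      anomalies = nrow(reports), species = nrow(cen),
      classes = ncol(cen)))
    write_atomic(function(tmp) jsonlite::write_json(
      run_info, tmp, auto_unbox = TRUE, pretty = TRUE), files$run_summary)
  }
  invisible(list(census = cen, summary = summ, anomalies = reports,
                 labels = labels, files = files))
}

# Internal: proteins input may be one FASTA (species inferred from the
# taxonomy when it has one species, else "unknown") or a named list
# species_id -> FASTA.
parse_proteins_input <- function(config) {
  pin <- config$inputs$proteins
  if (is.character(pin) && length(pin) == 1L && is.null(names(pin))) {
    tax <- read_taxonomy(config$inputs$taxonomy)
    # protein ids in generated data are prefixed "<species>_"; recover the
    # species from the taxonomy by longest matching prefix, falling back
    # to a single-species dataset.
    prot <- read_proteins(pin, species_id = NA_character_)
    if (nrow(tax) == 1L) {
      prot$species_id <- tax$species_id
    } else {
      sp_sorted <- tax$species_id[order(-nchar(tax$species_id))]
      for (s in sp_sorted) {
        hit <- startsWith(prot$protein_id, paste0(s, "_"))
        prot$species_id[is.na(prot$species_id) & hit] <- s
      }
      if (anyNA(prot$species_id))
        abort("cannot infer species for protein(s): %s",
              paste(head(prot$protein_id[is.na(prot$species_id)], 3L),
                    collapse = ", "))
    }
    return(list(prot))
  }
  lapply(names(pin), function(s) read_proteins(pin[[s]], s))
}

# Internal: run the configured anomaly detectors.
detect_anomalies <- function(config, proteins, hits, tm_corr, sp) {
  reports <- list()
  aln_dir <- config$inputs$alignments
  need_arch <- character()
  if (!is.null(aln_dir) && dir.exists(aln_dir)) {
    aln_files <- list.files(aln_dir, pattern = "\\.fasta$",
                            full.names = TRUE)
    need_arch <- sub("\\.fasta$", "", basename(aln_files))
    for (f in aln_files) {
      pid <- sub("\\.fasta$", "", basename(f))
      idx <- match(pid, proteins$protein_id)
      if (is.na(idx)) abort("alignment for unknown protein '%s'", pid)
      arch <- build_architecture(
        proteins[idx, ],
        hits[hits$protein_id == pid, , drop = FALSE],
        tm_corr[tm_corr$protein_id == pid, , drop = FALSE],
        sp[sp$protein_id == pid, , drop = FALSE])
      arch$tm_corrected <- arch$tm_raw  # already corrected upstream
      rep <- detect_nterm_extension(read_homolog_family(f, pid), arch,
                                    occupancy = config$anomaly$occupancy,
                                    min_overhang = config$anomaly$min_overhang)
      if (!is.null(rep)) reports[[length(reports) + 1L]] <- rep
    }
  }
  nterm <- config$anomaly$nterm_accessions
  if (!is.null(nterm)) {
    cand <- unique(hits$protein_id[hits$accession %in% nterm])
    for (pid in cand) {
      idx <- match(pid, proteins$protein_id)
      arch <- build_architecture(
        proteins[idx, ],
        hits[hits$protein_id == pid, , drop = FALSE],
        tm_corr[tm_corr$protein_id == pid, , drop = FALSE],
        sp[sp$protein_id == pid, , drop = FALSE])
      arch$tm_corrected <- arch$tm_raw
      rep <- detect_misplaced_nterm_domain(
        arch, nterm, position_fraction = config$anomaly$position_fraction)
      if (!is.null(rep)) reports[[length(reports) + 1L]] <- rep
    }
  }
  if (length(reports) == 0L)
    return(data.frame(protein_id = character(), kind = character(),
                      overhang_length = integer(), contains_tm = logical(),
                      suggested_action = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, reports)
}

# Internal: post-census subset-law assertions; violation means a
# classification defect, so fail loudly.
check_census_laws <- function(cen) {
  m <- unclass(cen)
  need <- c("TLR", "LRR_RECEPTOR", "LRR_PROTEIN", "LRR_RK")
  if (!all(need %in% colnames(m))) return(invisible(TRUE))
  stopifnot(all(m[, "TLR"] <= m[, "LRR_RECEPTOR"]),
            all(m[, "LRR_RK"] <= m[, "LRR_RECEPTOR"]),
            all(m[, "LRR_RECEPTOR"] <= m[, "LRR_PROTEIN"]))
  invisible(TRUE)
}

#' Run the LRR-domain clustering stage
#'
#' Consumes a similarity edge list (and, when protein sequences are
#' configured, extracts LRR subsequences so that unmatched subsequences
#' count as singletons and a FASTA export is written for external tree
#' building), thresholds and weights the graph, and runs [mcl()].
#'
#' Writes `clusters.txt`, `cluster_stats.json` and (with sequences)
#' `lrr_subsequences.fasta` under `config$out`.
#'
#' @param config A [pipeline_config()]; uses `inputs$edges` and
#'   optionally `inputs$proteins`/`inputs$domains`.
#' @return Invisibly, list with `clusters` (a `cluster_set`), `stats` and
#'   `files`.
#' @export
run_cluster <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ids <- NULL
  subs <- NULL
  if (!is.null(config$inputs$proteins) && !is.null(config$inputs$domains)) {
    proteins <- do.call(rbind, parse_proteins_input(config))
    hits <- read_domain_hits(config$inputs$domains,
                             dialect = config$dialects$domains,
                             proteins = proteins, strict = config$strict)
    subs <- extract_subsequences(proteins, hits, config$lrr_accessions)
    ids <- subs$id
    log_stage("extract", "%d LRR subsequences", length(ids))
  }
  edges <- if (!is.null(config$inputs$edges)) {
    read_edge_list(config$inputs$edges)
  } else {
    data.frame(a = character(), b = character(), e_value = numeric(),
               stringsAsFactors = FALSE)
  }
  log_stage("graph", "%d candidate edges", nrow(edges))
  graph <- build_graph(edges, e_cutoff = config$clustering$e_cutoff,
                       zero_cap = config$clustering$zero_cap, ids = ids)
  cs <- mcl(graph, inflation = config$clustering$inflation)
  stats <- cluster_stats(cs)
  log_stage("mcl", "%d clusters, %d singletons (%d iterations)",
            stats$n_clusters, stats$n_singletons, cs$iterations)
  files <- NULL
  if (!is.null(config$out)) {
    out <- config$out
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    files <- list(clusters = file.path(out, "clusters.txt"),
                  stats = file.path(out, "cluster_stats.json"))
    write_clusters(cs, files$clusters)
    write_atomic(function(tmp) jsonlite::write_json(
      stats, tmp, auto_unbox = TRUE, pretty = TRUE), files$stats)
    if (!is.null(subs) && nrow(subs) > 0L) {
      files$subsequences <- file.path(out, "lrr_subsequences.fasta")
      write_subsequences_fasta(subs, files$subsequences)
    }
  }
  invisible(list(clusters = cs, stats = stats, files = files))
}

#' Generate a synthetic dataset from a config
#'
#' Delegates to [generate()] and writes a YAML snapshot of the simulation
#' parameters next to the outputs for provenance.
#'
#' @param config A [pipeline_config()] whose `simulate` field is a
#'   [sim_config()] (or a list of [default_sim_config()] arguments);
#'   `out` must be set.
#' @return Invisibly, the generated dataset (see [generate()]).
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$out)) abort("simulate requires config$out")
  sim <- config$simulate
  if (is.null(sim)) sim <- default_sim_config(config$seed)
  if (is.null(sim$species))  # argument list, not a full sim_config
    sim <- do.call(default_sim_config, c(list(seed = config$seed), sim))
  ds <- generate(sim, out_dir = config$out)
  snapshot <- list(seed = sim$seed,
                   length_mean = sim$length_mean,
                   length_sd = sim$length_sd,
                   species = lapply(sim$species, function(s)
                     list(species_id = s$species_id,
                          taxon_path = s$taxon_path,
                          n_proteins = s$n_proteins,
                          frequencies = as.list(s$frequencies),
                          artifact_rates = s$artifact_rates)))
  write_atomic(function(tmp) yaml::write_yaml(snapshot, tmp),
               file.path(config$out, "sim_config.yaml"))
  log_stage("simulate", "%d species, %d proteins",
            length(sim$species), nrow(ds$proteins))
  invisible(ds)
}

#' Run simulate, census and cluster end to end
#'
#' Simulates a dataset (plus a planted-partition similarity graph for the
#' clustering stage), then runs the census and clustering on the
#' generated files.  Deterministic: the same seed yields byte-identical
#' output trees.
#'
#' @param config A [pipeline_config()] with `out` set; `simulate` as in
#'   [run_simulate()].  The similarity graph uses
#'   `config$clustering$e_cutoff` and three planted clusters of five
#'   unless `config$simulate_graph` overrides `n_clusters`/`cluster_sizes`.
#' @return Invisibly, list with `dataset`, `census` and `cluster` results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$out)) abort("run_all requires config$out")
  sim_dir <- file.path(config$out, "simulated")
  cfg_sim <- config; cfg_sim$out <- sim_dir
  ds <- run_simulate(cfg_sim)
  g <- config$simulate_graph %||% list(n_clusters = 3L, cluster_sizes = 5L)
  sg <- simulate_similarity_graph(g$n_clusters, g$cluster_sizes,
                                  seed = config$seed,
                                  e_cutoff = config$clustering$e_cutoff)
  edges_path <- file.path(sim_dir, "edges.tsv")
  write_atomic(function(tmp)
    utils::write.table(sg$edges, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE), edges_path)
  cfg_cen <- config
  cfg_cen$inputs <- list(proteins = ds$files$proteins,
                         domains = ds$files$domains, tm = ds$files$tm,
                         sp = ds$files$sp, taxonomy = ds$files$taxonomy,
                         alignments = ds$files$alignments)
  cfg_cen$out <- file.path(config$out, "census")
  cen <- run_census(cfg_cen)
  cfg_clu <- config
  cfg_clu$inputs <- list(edges = edges_path)
  cfg_clu$out <- file.path(config$out, "clusters")
  clu <- run_cluster(cfg_clu)
  invisible(list(dataset = ds, census = cen, cluster = clu))
}
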