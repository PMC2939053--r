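# Internal: evaluate one rule on per-protein features.
rule_matches <- function(rule, accessions, n_tm, has_sp) {
  for (grp in rule$required) {
    if (!any(accessions %in% grp)) return(FALSE)
  }
  if (length(rule$forbidden) > 0L && any(accessions %in% rule$forbidden))
    return(FALSE)
  ok_tm <- switch(rule$tm$op,
                  any = TRUE,
                  eq = n_tm == rule$tm$k,
                  ge = n_tm >= rule$tm$k)
  if (!ok_tm) return(FALSE)
  switch(rule$sp, any = TRUE, required = has_sp, forbidden = !has_sp)
}

#' Classify one protein architecture
#'
#' Evaluates every rule of a rule set against a protein architecture.
#' Transmembrane constraints are evaluated on the corrected helices
#' (`tm_corrected`), never the raw predictions.  Classes are
#' non-exclusive: a protein can carry several labels.
#'
#' @param arch A `protein_architecture` from [build_architecture()].
#' @param rules A `rule_set`, e.g. [builtin_rules()].
#' @return List with `protein_id` and `labels` (character vector of
#'   matching class names, in rule order).
#' @export
#' @examples
#' p <- data.frame(protein_id = "p1", species_id = "s", length = 500L)
#' h <- data.frame(protein_id = "p1", accession = "PF00560", name = "LRR_1",
#'                 start = 30L, end = 53L, bit_score = 30, e_value = 1e-8)
#' tm <- data.frame(protein_id = "p1", start = 300L, end = 322L)
#' classify(build_architecture(p, h, tm, NULL), builtin_rules())$labels
classify <- function(arch, rules) {
  accs <- arch$domains$accession
  n_tm <- nrow(arch$tm_corrected)
  has_sp <- !is.null(arch$signal_peptide)
  hit <- vapply(rules, rule_matches, logical(1),
                accessions = accs, n_tm = n_tm, has_sp = has_sp)
  list(protein_id = arch$protein_id, labels = names(rules)[hit])
}

#' Classify a whole protein table at once
#'
#' Vectorized equivalent of applying [classify()] to every protein:
#' operates directly on annotation tables, so whole-proteome censuses do
#' not require building per-protein objects.
#'
#' @param proteins Protein table ([read_proteins()]).
#' @param hits Domain-hit table.
#' @param tm_corrected Corrected TM helices (see [correct_tm_helices()]).
#' @param sp Signal-peptide table.
#' @param rules A `rule_set`.
#' @return Logical matrix, proteins x classes, rownames = protein ids.
#' @export
classify_proteins <- function(proteins, hits, tm_corrected, sp, rules) {
  ids <- proteins$protein_id
  n <- length(ids)
  n_tm <- tabulate(match(tm_corrected$protein_id, ids), nbins = n)
  has_sp <- ids %in% sp$protein_id
  out <- matrix(FALSE, n, length(rules),
                dimnames = list(ids, names(rules)))
  for (j in seq_along(rules)) {
    rule <- rules[[j]]
    ok <- rep(TRUE, n)
    for (grp in rule$required) {
      with_grp <- unique(hits$protein_id[hits$accession %in% grp])
      ok <- ok & ids %in% with_grp
    }
    if (length(rule$forbidden) > 0L) {
      with_forb <- unique(hits$protein_id[hits$accession %in% rule$forbidden])
      ok <- ok & !(ids %in% with_forb)
    }
    ok <- ok & switch(rule$tm$op, any = TRUE, eq = n_tm == rule$tm$k,
                      ge = n_tm >= rule$tm$k)
    ok <- ok & switch(rule$sp, any = TRUE, required = has_sp,
                      forbidden = !has_sp)
    out[, j] <- ok
  }
  out
}

# Internal: census constructor.
new_census <- function(m) {
  stopifnot(is.matrix(m))
  structure(m, class = "lrr_census")
}

#' Per-species class counts
#'
#' Builds the species x class count matrix from classification results.
#' Species rows are sorted lexically; absent combinations are explicit
#' zeros; a protein with several labels increments every matching class.
#'
#' @param labels Either the logical matrix from [classify_proteins()] or a
#'   list of results from [classify()].
#' @param proteins Protein table supplying the species of each protein
#'   (every species present appears as a row even if all zero).
#' @param rules Rule set defining the class columns and their order.
#' @return An `lrr_census`: integer matrix with class attributes.
#' @export
census <- function(labels, proteins, rules) {
  classes <- names(rules)
  if (is.list(labels) && !is.matrix(labels)) {
    m <- matrix(FALSE, nrow(proteins), length(classes),
                dimnames = list(proteins$protein_id, classes))
    for (res in labels) m[res$protein_id, res$labels] <- TRUE
    labels <- m
  }
  stopifnot(identical(colnames(labels), classes))
  species <- sort(unique(proteins$species_id))
  sp_of <- proteins$species_id[match(rownames(labels), proteins$protein_id)]
  if (anyNA(sp_of)) abort("classified protein missing from protein table")
  counts <- matrix(0L, length(species), length(classes),
                   dimnames = list(species, classes))
  if (nrow(labels) > 0L) {
    agg <- rowsum(labels + 0L, group = sp_of)
    counts[rownames(agg), ] <- agg
  }
  storage.mode(counts) <- "integer"
  new_census(counts)
}

#' @export
print.lrr_census <- function(x, ...) {
  cat(sprintf("<lrr_census> %d species x %d classes\n", nrow(x), ncol(x)))
  print(unclass(x))
  invisible(x)
}

#' Taxon-level census summary
#'
#' Aggregates a census by taxon group: number of species, species with a
#' high LRR-protein complement (>= `high`), with a low one (< `low`),
#' receptor-free species (zero LRR-receptors), plus the per-class
#' minimum/maximum species and counts within each group.
#'
#' @param x An `lrr_census`.
#' @param taxonomy Taxonomy table from [read_taxonomy()]; must cover every
#'   census species.
#' @param high,low Count thresholds (defaults 20 and 10).
#' @param level Depth of the slash-separated taxon path to group by
#'   (default 1, the top-level group).
#' @return List with `by_taxon` (one row per group) and `class_range`
#'   (per group and class: min/max values with the species attaining them).
#' @export
summarize_census <- function(x, taxonomy, high = 20L, low = 10L, level = 1L) {
  stopifnot(inherits(x, "lrr_census"))
  m <- unclass(x)
  missing <- setdiff(rownames(m), taxonomy$species_id)
  if (length(missing) > 0L)
    abort("species missing from taxonomy: %s", paste(missing, collapse = ", "))
  path <- taxonomy$taxon_path[match(rownames(m), taxonomy$species_id)]
  grp <- vapply(strsplit(path, "/", fixed = TRUE), function(p)
    paste(p[seq_len(min(level, length(p)))], collapse = "/"), character(1))
  groups <- sort(unique(grp))
  lrr <- if ("LRR_PROTEIN" %in% colnames(m)) m[, "LRR_PROTEIN"] else
    rep(NA_integer_, nrow(m))
  rec <- if ("LRR_RECEPTOR" %in% colnames(m)) m[, "LRR_RECEPTOR"] else
    rep(NA_integer_, nrow(m))
  by_taxon <- do.call(rbind, lapply(groups, function(g) {
    sel <- grp == g
    data.frame(taxon = g,
               n_species = sum(sel),
               n_lrr_high = sum(lrr[sel] >= high, na.rm = TRUE),
               n_lrr_low = sum(lrr[sel] < low, na.rm = TRUE),
               n_receptor_free = sum(rec[sel] == 0L, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  class_range <- do.call(rbind, lapply(groups, function(g) {
    sel <- which(grp == g)
    do.call(rbind, lapply(colnames(m), function(cl) {
      v <- m[sel, cl]
      i_min <- sel[which.min(v)]; i_max <- sel[which.max(v)]
      data.frame(taxon = g, class = cl,
                 min_species = rownames(m)[i_min], min_count = min(v),
                 max_species = rownames(m)[i_max], max_count = max(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(by_taxon = by_taxon, class_range = class_range)
}

#' Check conservation of domain order
#'
#' Tests whether, restricted to the accessions of `expected_order`, a
#' protein's hits appear N-to-C as a subsequence consistent with that
#' order.  Missing accessions are allowed; repeated hits of one accession
#' are allowed.
#'
#' @param arch A `protein_architecture`.
#' @param expected_order Non-empty character vector of accessions in the
#'   expected N-to-C order.
#' @return `TRUE` or `FALSE`.
#' @export
architecture_order_check <- function(arch, expected_order) {
  stopifnot(length(expected_order) > 0L)
  accs <- arch$domains$accession           # already sorted by start
  idx <- match(accs[accs %in% expected_order], expected_order)
  all(diff(idx) >= 0L)
}
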