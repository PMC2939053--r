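#' Remove transmembrane helices that overlap a predicted signal peptide
#'
#' Topology predictors can mistake an N-terminal signal peptide for a
#' transmembrane helix.  This correction drops every predicted helix that
#' shares at least one residue with the signal-peptide region (residues
#' `1..end`); proteins without a signal-peptide record keep their helices
#' unchanged.  The operation is idempotent and preserves row order.
#'
#' @param tm data.frame of helices (`protein_id`, `start`, `end`); may
#'   cover many proteins.
#' @param sp data.frame of signal peptides (`protein_id`, `end`) or `NULL`.
#' @param min_overlap Minimum number of shared residues that counts as an
#'   overlap (default 1).
#' @return The surviving subset of `tm`, original order preserved.
#' @export
#' @examples
#' tm <- data.frame(protein_id = "p1", start = 10L, end = 32L)
#' sp <- data.frame(protein_id = "p1", end = 22L)
#' correct_tm_helices(tm, sp)        # helix removed
#' correct_tm_helices(tm, NULL)      # unchanged
correct_tm_helices <- function(tm, sp, min_overlap = 1L) {
  if (is.null(sp) || nrow(sp) == 0L || nrow(tm) == 0L) {
    rownames(tm) <- NULL
    return(tm)
  }
  sp_end <- sp$end[match(tm$protein_id, sp$protein_id)]
  # overlap with [1, sp_end] is min(end, sp_end) - start + 1 residues
  overlap <- pmin(tm$end, sp_end) - tm$start + 1L
  keep <- is.na(sp_end) | overlap < min_overlap
  out <- tm[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a per-protein domain architecture
#'
#' Joins a protein with its domain hits, raw TM helices and signal peptide
#' into one architecture object: domains sorted by start (ties by end,
#' then accession), TM helices corrected against the signal peptide via
#' [correct_tm_helices()].  Overlapping or duplicate domain hits are all
#' retained.
#'
#' @param protein One-row data.frame (or list) with `protein_id`,
#'   `species_id`, `length`.
#' @param hits Domain hits for this protein (may be empty).
#' @param tm Raw TM helices for this protein (may be empty).
#' @param sp Signal-peptide record for this protein (0- or 1-row
#'   data.frame, or `NULL`).
#' @return A `protein_architecture` object: list with `protein_id`,
#'   `species_id`, `length`, `domains`, `tm_raw`, `tm_corrected`,
#'   `signal_peptide` (`NULL` or 1-row data.frame).
#' @export
build_architecture <- function(protein, hits = NULL, tm = NULL, sp = NULL) {
  pid <- protein$protein_id
  stopifnot(length(pid) == 1L)
  hits <- if (is.null(hits)) empty_hits() else hits
  tm <- if (is.null(tm)) empty_tm() else tm
  check_ids <- function(df, what) {
    alien <- setdiff(unique(df$protein_id), pid)
    if (length(alien) > 0L)
      abort("%s for protein '%s' passed to architecture of '%s'",
            what, alien[[1L]], pid)
  }
  check_ids(hits, "domain hits")
  check_ids(tm, "TM helices")
  if (!is.null(sp) && nrow(sp) > 0L) {
    check_ids(sp, "signal peptide")
    if (nrow(sp) > 1L) abort("multiple signal peptides for protein '%s'", pid)
  } else sp <- NULL
  ord <- order(hits$start, hits$end, hits$accession)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(protein_id = pid,
                 species_id = protein$species_id,
                 length = as.integer(protein$length),
                 domains = hits,
                 tm_raw = tm,
                 tm_corrected = correct_tm_helices(tm, sp),
                 signal_peptide = sp),
            class = "protein_architecture")
}

empty_hits <- function() {
  data.frame(protein_id = character(), accession = character(),
             name = character(), start = integer(), end = integer(),
             bit_score = numeric(), e_value = numeric(),
             stringsAsFactors = FALSE)
}

empty_tm <- function() {
  data.frame(protein_id = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Build architectures for a whole protein table
#'
#' @param proteins Protein table from [read_proteins()].
#' @param hits,tm,sp Annotation tables covering those proteins.
#' @return Named list of `protein_architecture`, keyed by protein id.
#' @export
build_architectures <- function(proteins, hits, tm, sp) {
  by_id <- function(df) split(df, factor(df$protein_id, levels = proteins$protein_id))
  hs <- by_id(hits); ts <- by_id(tm); ss <- by_id(sp)
  out <- vector("list", nrow(proteins))
  names(out) <- proteins$protein_id
  for (i in seq_len(nrow(proteins))) {
    out[[i]] <- build_architecture(proteins[i, ], hs[[i]], ts[[i]], ss[[i]])
  }
  out
}

#' @export
print.protein_architecture <- function(x, ...) {
  cat(sprintf("<protein_architecture> %s (%s, %d aa)\n",
              x$protein_id, x$species_id, x$length))
  cat("  ", architecture_string(x), "\n", sep = "")
  invisible(x)
}

#' Token string of an architecture
#'
#' Hyphen-joined domain accessions in N-to-C order with `TM` tokens
#' interleaved at corrected-helix positions and an `SP` prefix when a
#' signal peptide is present.  Ties (a domain and a helix starting at the
#' same residue) order the domain first.
#'
#' @param arch A `protein_architecture`.
#' @return A single string; `""` for an empty architecture.
#' @export
architecture_string <- function(arch) {
  tok <- c(arch$domains$accession, rep("TM", nrow(arch$tm_corrected)))
  pos <- c(arch$domains$start, arch$tm_corrected$start)
  # stable tie-break: domains come first in `tok`, order() is stable
  tok <- tok[order(pos)]
  if (!is.null(arch$signal_peptide)) tok <- c("SP", tok)
  paste(tok, collapse = "-")
}

#' Count LRR domain hits on a protein
#'
#' Counts individual hits whose accession is one of the LRR families;
#' hits are not merged into repeat regions.
#'
#' @param arch A `protein_architecture`.
#' @param lrr_accessions Accessions counted as LRR (default [lrr_pfam()]).
#' @return Non-negative integer.
#' @export
count_lrr_domains <- function(arch, lrr_accessions = lrr_pfam()) {
  stopifnot(length(lrr_accessions) > 0L)
  sum(arch$domains$accession %in% lrr_accessions)
}
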