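#' Construct a homolog family (multiple alignment)
#'
#' A query protein aligned with close homologs, used to detect gene-model
#' anomalies such as spurious N-terminal extensions.
#'
#' @param query_id Row label of the query sequence.
#' @param sequences Named character vector of aligned rows (equal lengths;
#'   `-` for gaps), including the query; at least 2 rows.
#' @return A `homolog_family` object.
#' @export
homolog_family <- function(query_id, sequences) {
  if (length(sequences) < 2L) abort("homolog family needs >= 2 rows")
  if (!query_id %in% names(sequences))
    abort("query '%s' absent from alignment", query_id)
  w <- nchar(sequences)
  if (length(unique(w)) != 1L)
    abort("aligned rows have unequal lengths")
  structure(list(query_id = query_id, sequences = sequences,
                 width = w[[1L]]),
            class = "homolog_family")
}

#' Read a homolog family from aligned FASTA
#'
#' @param path Aligned-FASTA file.
#' @param query_id Query row label; defaults to the first record.
#' @return A `homolog_family`.
#' @export
read_homolog_family <- function(path, query_id = NULL) {
  aln <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aln), "[ \t]+"), `[[`, character(1), 1L)
  seqs <- setNames(as.character(aln), ids)
  homolog_family(query_id %||% ids[[1L]], seqs)
}

#' Detect a spurious N-terminal gene-model extension
#'
#' A gene model wrongly extended at its 5' end shows up in a multiple
#' alignment as a long stretch of query residues before the column where
#' its homologs start.  The detector finds the first alignment column
#' where at least `occupancy` of the non-query rows are non-gap, counts
#' the query residues falling before that column (the overhang), and
#' reports the protein when the overhang reaches `min_overhang` residues.
#' When the overhang contains a (corrected) transmembrane helix entirely,
#' the report suggests dropping it: such helices are artifacts of the
#' gene-model error, not real membrane anchors.
#'
#' @param family A `homolog_family` whose query is `arch$protein_id`.
#' @param arch The query's `protein_architecture`.
#' @param occupancy Fraction of non-query rows that must be aligned for a
#'   column to count as the homolog start (default 0.5).
#' @param min_overhang Minimum overhang, in residues, to report
#'   (default 100).
#' @return A one-row anomaly report data.frame (`protein_id`, `kind`,
#'   `overhang_length`, `contains_tm`, `suggested_action`), or `NULL` when
#'   no anomaly is found.
#' @export
detect_nterm_extension <- function(family, arch, occupancy = 0.5,
                                   min_overhang = 100L) {
  stopifnot(inherits(family, "homolog_family"))
  if (family$query_id != arch$protein_id)
    abort("family query '%s' does not match architecture '%s'",
          family$query_id, arch$protein_id)
  rows <- do.call(rbind, strsplit(family$sequences, "", fixed = TRUE))
  rownames(rows) <- names(family$sequences)
  qi <- which(rownames(rows) == family$query_id)[[1L]]
  others <- rows[-qi, , drop = FALSE]
  frac <- colMeans(others != "-")
  cstar <- which(frac >= occupancy)[1L]
  before <- if (is.na(cstar)) ncol(rows) else cstar - 1L
  overhang <- if (before == 0L) 0L else
    sum(rows[qi, seq_len(before)] != "-")
  if (overhang < min_overhang) return(NULL)
  anomaly_report(arch$protein_id, "NTERM_EXTENSION", overhang,
                 arch$tm_corrected)
}

# Internal: assemble a report row; contains_tm is TRUE when some helix
# lies entirely within query residues 1..overhang.
anomaly_report <- function(protein_id, kind, overhang, tm_corrected) {
  tm_in <- tm_corrected[tm_corrected$protein_id == protein_id, , drop = FALSE]
  contains_tm <- nrow(tm_in) > 0L && any(tm_in$end <= overhang)
  data.frame(protein_id = protein_id, kind = kind,
             overhang_length = as.integer(overhang),
             contains_tm = contains_tm,
             suggested_action = if (contains_tm) "drop_tm" else "none",
             stringsAsFactors = FALSE)
}

#' Detect an N-terminal domain stranded mid-protein
#'
#' An "LRR N-terminal" capping domain found deep inside a protein suggests
#' the annotated start lies upstream of the true one: everything before
#' the domain is then a suspect 5' extension.  Reported when such a domain
#' starts after `position_fraction` of the protein length; the overhang is
#' everything before the domain.
#'
#' @param arch A `protein_architecture`.
#' @param nterm_accessions Accessions of N-terminal capping domains (no
#'   package-wide default is asserted; `PF01462` is the Pfam LRR
#'   N-terminal family).
#' @param position_fraction Fraction of the protein length beyond which an
#'   N-terminal domain is anomalous (default 0.25).
#' @return One-row report data.frame as in [detect_nterm_extension()], or
#'   `NULL`.
#' @export
detect_misplaced_nterm_domain <- function(arch, nterm_accessions,
                                          position_fraction = 0.25) {
  stopifnot(length(nterm_accessions) > 0L)
  cand <- arch$domains[arch$domains$accession %in% nterm_accessions, ,
                       drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  first <- cand$start[[1L]]          # domains already sorted by start
  if (first <= position_fraction * arch$length) return(NULL)
  anomaly_report(arch$protein_id, "MISPLACED_NTERM_DOMAIN", first - 1L,
                 arch$tm_corrected)
}

#' Apply anomaly corrections to architectures
#'
#' For every report whose `suggested_action` is `drop_tm`, removes the
#' corrected TM helices lying entirely within the flagged overhang
#' (residues `1..overhang_length`).  All other architectures pass through
#' unchanged.  A manual `add_tm` record (for the symmetric case of a
#' gene-model error that removed a real helix) re-inserts a helix given as
#' `start`/`end` columns in the report.
#'
#' @param archs Named list of `protein_architecture` (see
#'   [build_architectures()]).
#' @param reports Anomaly-report data.frame (rows from the detectors, or
#'   manual records with `suggested_action = "add_tm"` plus `start`, `end`).
#' @return The corrected list of architectures.
#' @export
apply_corrections <- function(archs, reports) {
  if (is.null(reports) || nrow(reports) == 0L) return(archs)
  unknown <- setdiff(reports$protein_id, names(archs))
  if (length(unknown) > 0L)
    abort("anomaly report for unknown protein(s): %s",
          paste(unknown, collapse = ", "))
  for (i in seq_len(nrow(reports))) {
    r <- reports[i, ]
    a <- archs[[r$protein_id]]
    if (identical(r$suggested_action, "drop_tm")) {
      keep <- a$tm_corrected$end > r$overhang_length
      a$tm_corrected <- a$tm_corrected[keep, , drop = FALSE]
      rownames(a$tm_corrected) <- NULL
    } else if (identical(r$suggested_action, "add_tm")) {
      a$tm_corrected <- rbind(a$tm_corrected, data.frame(
        protein_id = r$protein_id, start = as.integer(r$start),
        end = as.integer(r$end), stringsAsFactors = FALSE))
    }
    archs[[r$protein_id]] <- a
  }
  archs
}

# Internal, table-level form used by the pipeline: drop flagged helices
# straight from a corrected TM table.
apply_corrections_tm <- function(tm_corrected, reports) {
  if (is.null(reports) || nrow(reports) == 0L) return(tm_corrected)
  drop <- rep(FALSE, nrow(tm_corrected))
  dr <- reports[reports$suggested_action == "drop_tm", , drop = FALSE]
  for (i in seq_len(nrow(dr))) {
    drop <- drop | (tm_corrected$protein_id == dr$protein_id[i] &
                      tm_corrected$end <= dr$overhang_length[i])
  }
  out <- tm_corrected[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write anomaly reports as TSV
#'
#' Columns: protein_id, kind, overhang_length, contains_tm,
#' suggested_action.
#'
#' @param reports Report data.frame (possibly zero rows).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_anomaly_reports <- function(reports, path) {
  cols <- c("protein_id", "kind", "overhang_length", "contains_tm",
            "suggested_action")
  if (is.null(reports) || nrow(reports) == 0L) {
    reports <- data.frame(protein_id = character(), kind = character(),
                          overhang_length = integer(),
                          contains_tm = logical(),
                          suggested_action = character(),
                          stringsAsFactors = FALSE)
  }
  write_tsv(reports[, cols], path)
  invisible(path)
}
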