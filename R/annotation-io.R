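#' Pfam accessions of the three leucine-rich-repeat families
#'
#' The three LRR families in Pfam (LRR_1, LRR_2, LRR_4) that define an
#' LRR-containing protein throughout this package.
#'
#' @return Character vector of Pfam accessions.
#' @export
#' @examples
#' lrr_pfam()
lrr_pfam <- function() c("PF00560", "PF07723", "PF07725")

#' Read a proteome FASTA file
#'
#' Reads protein sequences for one species.  The first whitespace-delimited
#' token of each header is taken as the protein id; ids must be unique.
#'
#' @param path Path to a (possibly empty) protein FASTA file.
#' @param species_id Species identifier attached to every record.
#' @param keep_sequences Keep residue strings in the result (needed for
#'   LRR-subsequence extraction); set `FALSE` to save memory.
#' @return A data.frame with columns `protein_id`, `species_id`, `length`
#'   and `sequence` (`NA` when `keep_sequences = FALSE`).
#' @export
read_proteins <- function(path, species_id, keep_sequences = TRUE) {
  if (!file.exists(path)) abort("file not found: '%s'", path)
  empty <- data.frame(protein_id = character(), species_id = character(),
                      length = integer(), sequence = character(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) return(empty)
  ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    abort("duplicate protein id(s) in '%s': %s", path,
          paste(unique(dup), collapse = ", "))
  data.frame(protein_id = ids,
             species_id = species_id,
             length = Biostrings::width(seqs),
             sequence = if (keep_sequences) as.character(seqs) else NA_character_,
             stringsAsFactors = FALSE)
}

# Internal: cross-reference annotation rows against a protein table.
# strict = TRUE errors on unknown ids; FALSE warns and drops them.
xref_proteins <- function(df, proteins, strict, what) {
  if (is.null(proteins)) return(df)
  unknown <- setdiff(df$protein_id, proteins$protein_id)
  if (length(unknown) > 0L) {
    msg <- sprintf("%s reference unknown protein(s): %s", what,
                   paste(head(unknown, 5L), collapse = ", "))
    if (strict) abort("%s", msg)
    warning(msg, ", dropped", call. = FALSE)
    df <- df[df$protein_id %in% proteins$protein_id, , drop = FALSE]
  }
  if ("end" %in% names(df)) {
    len <- proteins$length[match(df$protein_id, proteins$protein_id)]
    bad <- which(df$end > len)
    if (length(bad) > 0L)
      abort("%s exceed protein length for: %s", what,
            paste(unique(df$protein_id[bad]), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Read Pfam domain hits
#'
#' Parses per-domain hit tables in either the HMMER3 per-domain tabular
#' format (`--domtblout` of `hmmscan`, the format behind `pfam_scan`) or a
#' plain 7-column TSV.  Coordinates are 1-based inclusive; for the HMMER
#' dialect the envelope (`env`) coordinates are used, matching the
#' boundaries `pfam_scan` reports.  No score filtering is applied: Pfam
#' gathering thresholds are assumed already applied upstream (an optional
#' `max_evalue` filter is available but off by default).
#'
#' @param path Path to the hit table.
#' @param dialect `"tsv"` (columns: protein_id, accession, name, start,
#'   end, bit_score, e_value) or `"hmmer_domtbl"`.
#' @param proteins Optional protein table from [read_proteins()] used to
#'   validate ids and coordinates.
#' @param strict With `proteins` given: error on hits for unknown proteins
#'   (`TRUE`, default) or warn and drop them (`FALSE`).
#' @param max_evalue Optional e-value cutoff; `NULL` (default) keeps all.
#' @return data.frame with columns `protein_id`, `accession`, `name`,
#'   `start`, `end`, `bit_score`, `e_value`.
#' @export
read_domain_hits <- function(path, dialect = c("tsv", "hmmer_domtbl"),
                             proteins = NULL, strict = TRUE,
                             max_evalue = NULL) {
  dialect <- match.arg(dialect)
  df <- if (dialect == "tsv") {
    read_tsv(path,
             c("protein_id", "accession", "name", "start", "end",
               "bit_score", "e_value"),
             c("character", "character", "character", "integer", "integer",
               "numeric", "numeric"))
  } else {
    parse_domtbl(path)
  }
  bad_acc <- which(!grepl("^PF\\d{5}$", df$accession))
  if (length(bad_acc) > 0L)
    abort("'%s': malformed Pfam accession '%s' (record %d)",
          path, df$accession[bad_acc[1L]], bad_acc[1L])
  bad <- which(df$start < 1L | df$start > df$end)
  if (length(bad) > 0L)
    abort("'%s': invalid coordinates start=%d end=%d (record %d)",
          path, df$start[bad[1L]], df$end[bad[1L]], bad[1L])
  if (any(df$e_value < 0))
    abort("'%s': negative e-value", path)
  if (!is.null(max_evalue)) df <- df[df$e_value <= max_evalue, , drop = FALSE]
  xref_proteins(df, proteins, strict, "domain hits")
}

# Internal: HMMER3 hmmscan --domtblout parser.  Whitespace-delimited;
# query (protein) in column 4, model accession in column 2 (version suffix
# stripped), independent e-value col 13, domain score col 14, envelope
# coordinates cols 20-21.
parse_domtbl <- function(path) {
  if (!file.exists(path)) abort("file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  empty <- data.frame(protein_id = character(), accession = character(),
                      name = character(), start = integer(), end = integer(),
                      bit_score = numeric(), e_value = numeric(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(trimws(lines), "[ \t]+")
  short <- which(vapply(fields, length, integer(1)) < 22L)
  if (length(short) > 0L)
    abort("'%s': line %d has fewer than 22 fields", path, short[1L])
  col <- function(i) vapply(fields, `[[`, character(1), i)
  data.frame(protein_id = col(4L),
             accession = sub("\\.\\d+$", "", col(2L)),
             name = col(1L),
             start = as.integer(col(20L)),
             end = as.integer(col(21L)),
             bit_score = as.numeric(col(14L)),
             e_value = as.numeric(col(13L)),
             stringsAsFactors = FALSE)
}

#' Read transmembrane-helix predictions
#'
#' Parses TMHMM output in short format (one line per protein carrying a
#' `Topology=` string such as `o10-32i`) or a 3-column TSV
#' (protein_id, start, end).  One row per predicted helix.
#'
#' @inheritParams read_domain_hits
#' @param dialect `"tsv"` or `"tmhmm_short"`.
#' @return data.frame with columns `protein_id`, `start`, `end`.
#' @export
read_tm_helices <- function(path, dialect = c("tsv", "tmhmm_short"),
                            proteins = NULL, strict = TRUE) {
  dialect <- match.arg(dialect)
  df <- if (dialect == "tsv") {
    read_tsv(path, c("protein_id", "start", "end"),
             c("character", "integer", "integer"))
  } else {
    parse_tmhmm_short(path)
  }
  bad <- which(df$start < 1L | df$start > df$end)
  if (length(bad) > 0L)
    abort("'%s': invalid helix coordinates for protein '%s'",
          path, df$protein_id[bad[1L]])
  xref_proteins(df, proteins, strict, "TM helices")
}

# Internal: TMHMM short-format parser.  Topology strings look like
# "i", "o", "o10-32i" or "i5-20o45-60i": alternating side letters with
# 1-based inclusive helix spans between them.
parse_tmhmm_short <- function(path) {
  if (!file.exists(path)) abort("file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    fields <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    id <- fields[[1L]]
    topo_field <- grep("^Topology=", fields, value = TRUE)
    if (length(topo_field) != 1L)
      abort("TMHMM line for '%s' lacks a Topology= field", id)
    topo <- sub("^Topology=", "", topo_field)
    if (!grepl("^[io](\\d+-\\d+[io])*$", topo))
      abort("unparsable topology string '%s' for protein '%s'", topo, id)
    spans <- regmatches(topo, gregexpr("\\d+-\\d+", topo))[[1L]]
    if (length(spans) == 0L) next
    coords <- do.call(rbind, strsplit(spans, "-"))
    out[[length(out) + 1L]] <- data.frame(
      protein_id = id,
      start = as.integer(coords[, 1L]),
      end = as.integer(coords[, 2L]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Read signal-peptide predictions
#'
#' Parses SignalP-style summaries (whitespace-delimited rows
#' `id YES end` / `id NO`) or a 2-column TSV (protein_id, end).  Only
#' signal-peptide-positive proteins yield records; `end` is the 1-based
#' index of the last signal-peptide residue (the region is residues
#' 1..end).
#'
#' @inheritParams read_domain_hits
#' @param dialect `"tsv"` or `"signalp_summary"`.
#' @return data.frame with columns `protein_id`, `end`.
#' @export
read_signal_peptides <- function(path, dialect = c("tsv", "signalp_summary"),
                                 proteins = NULL, strict = TRUE) {
  dialect <- match.arg(dialect)
  df <- if (dialect == "tsv") {
    read_tsv(path, c("protein_id", "end"), c("character", "integer"))
  } else {
    parse_signalp_summary(path)
  }
  bad <- which(df$end < 1L)
  if (length(bad) > 0L)
    abort("'%s': signal peptide end %d < 1 for protein '%s'",
          path, df$end[bad[1L]], df$protein_id[bad[1L]])
  if (!is.null(proteins)) {
    len <- proteins$length[match(df$protein_id, proteins$protein_id)]
    over <- which(!is.na(len) & df$end >= len)
    if (length(over) > 0L)
      abort("signal peptide spans entire protein '%s' (end=%d, length=%d)",
            df$protein_id[over[1L]], df$end[over[1L]], len[over[1L]])
  }
  xref_proteins(df, proteins, strict, "signal peptides")
}

# Internal: SignalP summary parser ("p1 YES 22" / "p2 NO").
parse_signalp_summary <- function(path) {
  if (!file.exists(path)) abort("file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  out_id <- character()
  out_end <- integer()
  for (ln in lines) {
    fields <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    call <- toupper(fields[[2L]])
    if (call == "NO") next
    if (call != "YES" || length(fields) < 3L)
      abort("unparsable SignalP summary line: '%s'", ln)
    out_id <- c(out_id, fields[[1L]])
    out_end <- c(out_end, as.integer(fields[[3L]]))
  }
  data.frame(protein_id = out_id, end = out_end, stringsAsFactors = FALSE)
}

#' Read a species-to-taxon mapping table
#'
#' 2-column TSV: species_id and a slash-separated taxon path (e.g.
#' `fungi/ascomycota`).  Every species in a dataset must appear exactly
#' once.
#'
#' @param path Path to the taxonomy TSV.
#' @return data.frame with columns `species_id`, `taxon_path`.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv(path, c("species_id", "taxon_path"),
                 c("character", "character"))
  dup <- df$species_id[duplicated(df$species_id)]
  if (length(dup) > 0L)
    abort("'%s': duplicate species id(s): %s", path,
          paste(unique(dup), collapse = ", "))
  df
}

#' Write / read a census table
#'
#' Serializes a census (see [census()]) as a TSV with one species row
#' (sorted lexically) and one column per class; `read_census()` inverts it
#' losslessly.
#'
#' @param x A `lrr_census` object.
#' @param path Output path.
#' @return `write_census()` the path, invisibly; `read_census()` a
#'   `lrr_census` object.
#' @export
write_census <- function(x, path) {
  stopifnot(inherits(x, "lrr_census"))
  m <- unclass(x)
  df <- data.frame(species_id = rownames(m) %||% character(),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_census
#' @export
read_census <- function(path) {
  if (!file.exists(path)) abort("file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) abort("'%s': missing census header", path)
  classes <- strsplit(lines[[1L]], "\t")[[1L]][-1L]
  if (length(lines) == 1L) {
    m <- matrix(0L, 0L, length(classes), dimnames = list(NULL, classes))
    return(new_census(m))
  }
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  new_census(m)
}
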