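#' Construct a species-annotated ASV database
#'
#' The core container: one row per amplicon sequence variant (ASV), each
#' carrying a variant identifier, a source accession, a species identifier
#' and a seven-rank taxonomy, with the sequence stored in the reference
#' frame (optional leading-gap padding, no internal gaps).
#'
#' @param records Data frame with columns `variant_id`, `accession`,
#'   `species_id`, `taxonomy` (semicolon-joined, exactly 7 ranks) and
#'   `sequence`.
#' @param domain "bacteria" or "archaea".
#' @return An object of class `primer_db` with elements `domain`, `records`,
#'   `species_index` (species_id -> variant_ids), `n_species`, `n_variants`.
#' @export
primer_db <- function(records, domain = c("bacteria", "archaea")) {
  domain <- match.arg(domain)
  need <- c("variant_id", "accession", "species_id", "taxonomy", "sequence")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)[need]
  if (nrow(records)) {
    if (anyDuplicated(records$variant_id)) {
      stop("duplicate variant_id: ",
           records$variant_id[duplicated(records$variant_id)][1L], call. = FALSE)
    }
    if (any(!nzchar(records$species_id) | is.na(records$species_id))) {
      stop("missing species_id", call. = FALSE)
    }
    n_ranks <- lengths(strsplit(records$taxonomy, ";", fixed = TRUE))
    if (any(n_ranks != 7L)) {
      bad <- records$variant_id[n_ranks != 7L][1L]
      stop("record ", bad, ": taxonomy must have exactly 7 ranks", call. = FALSE)
    }
    if (any(grepl("-", sub("^-*", "", records$sequence), fixed = TRUE))) {
      bad <- records$variant_id[grepl("-", sub("^-*", "", records$sequence))][1L]
      stop("record ", bad, ": internal gaps are not allowed", call. = FALSE)
    }
  }
  structure(
    list(
      domain = domain,
      records = records,
      species_index = split(records$variant_id, records$species_id),
      n_species = length(unique(records$species_id)),
      n_variants = nrow(records)
    ),
    class = "primer_db"
  )
}

#' @export
print.primer_db <- function(x, ...) {
  cat(sprintf("primer_db: %s, %d variants, %d species\n",
              x$domain, x$n_variants, x$n_species))
  invisible(x)
}

# Species-level name (7th taxonomy rank) for each species_id in the database.
species_names <- function(db) {
  first <- !duplicated(db$records$species_id)
  ranks <- strsplit(db$records$taxonomy[first], ";", fixed = TRUE)
  stats::setNames(vapply(ranks, `[`, character(1L), 7L),
                  db$records$species_id[first])
}

parse_db_header <- function(header, lineno) {
  # tolerant parse: fields may be separated by whitespace and the taxonomy
  # may be one semicolon-joined token or 7 further whitespace tokens
  fields <- strsplit(trimws(header), "[ \t]+")[[1L]]
  if (length(fields) < 4L) {
    stop(sprintf("malformed header at line %d: '%s'", lineno, header),
         call. = FALSE)
  }
  taxonomy_fields <- fields[-(1:3)]
  taxonomy <- paste(unlist(strsplit(taxonomy_fields, ";", fixed = TRUE)),
                    collapse = ";")
  n_ranks <- length(strsplit(taxonomy, ";", fixed = TRUE)[[1L]])
  if (n_ranks != 7L) {
    stop(sprintf("header at line %d ('%s'): expected 7 taxonomy ranks, found %d",
                 lineno, fields[1L], n_ranks), call. = FALSE)
  }
  list(variant_id = fields[1L], accession = fields[2L],
       species_id = fields[3L], taxonomy = taxonomy)
}

#' Read a species-annotated ASV database from FASTA
#'
#' Header dialect: `>variant_id accession species_id rank1;...;rank7`, with
#' the taxonomy accepted either semicolon-joined or as seven further
#' whitespace-separated fields. Sequences are uppercased; U and I are mapped
#' to T and N; gap characters other than a leading run are rejected.
#'
#' @param path FASTA file path.
#' @param domain "bacteria" or "archaea".
#' @return A [primer_db()] object.
#' @export
read_database <- function(path, domain = c("bacteria", "archaea")) {
  domain <- match.arg(domain)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    return(primer_db(data.frame(variant_id = character(0),
                                accession = character(0),
                                species_id = character(0),
                                taxonomy = character(0),
                                sequence = character(0),
                                stringsAsFactors = FALSE), domain))
  }
  parsed <- lapply(seq_along(seqs), function(i) {
    parse_db_header(names(seqs)[i], i)
  })
  records <- data.frame(
    variant_id = vapply(parsed, `[[`, character(1L), "variant_id"),
    accession = vapply(parsed, `[[`, character(1L), "accession"),
    species_id = vapply(parsed, `[[`, character(1L), "species_id"),
    taxonomy = vapply(parsed, `[[`, character(1L), "taxonomy"),
    sequence = vapply(as.character(seqs), canonicalize_sequence,
                      character(1L), allow_gaps = TRUE, USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  primer_db(records, domain)
}

#' Write a database in the canonical FASTA dialect
#'
#' Emits `>variant_id accession species_id rank1;...;rank7` headers and
#' 80-column wrapped sequences. Reading the file back reproduces the
#' database exactly, and a second write is byte-stable.
#'
#' @param db A [primer_db()] object.
#' @param path Output FASTA path.
#' @export
write_database <- function(db, path) {
  stopifnot(inherits(db, "primer_db"))
  seqs <- Biostrings::BStringSet(db$records$sequence)
  names(seqs) <- with(db$records,
                      paste(variant_id, accession, species_id, taxonomy))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}
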