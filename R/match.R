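# Zero-mismatch matching of degenerate primers against reference-frame
# sequences. A primer letter p matches a sequence letter s iff s is a
# concrete base contained in iupac_set(p); ambiguous database letters (N,
# R, ...) and gap characters never satisfy a primer position.

# Translate a canonical IUPAC primer into a PCRE character-class pattern over
# concrete bases only. Wrapped in a lookahead so overlapping occurrences are
# all reported by gregexpr().
primer_pattern <- function(search_sequence) {
  classes <- vapply(strsplit(search_sequence, "", fixed = TRUE)[[1L]],
                    function(l) {
                      set <- iupac_set(l)
                      if (length(set) == 1L) set else
                        paste0("[", paste(set, collapse = ""), "]")
                    }, character(1L), USE.NAMES = FALSE)
  paste0("(?=", paste(classes, collapse = ""), ")")
}

#' Locate all exact matches of a primer in one sequence
#'
#' Scans a sense-strand, reference-frame sequence for every window where all
#' primer positions match with zero mismatches. Forward primers are searched
#' as written; reverse primers are searched as their reverse complement
#' (their `search_sequence`), so coordinates always refer to the sense
#' strand. Leading gap padding occupies positions, so reported coordinates
#' are reference-frame positions; gaps themselves never match.
#'
#' @param primer One-row primer data frame from [canonicalize_primer()].
#' @param sequence Sequence string (canonical IUPAC plus optional leading
#'   gaps).
#' @return Data frame with columns `start` and `end` (1-based, inclusive,
#'   both strands reported on the sense strand), sorted by `start`; zero rows
#'   when there is no match.
#' @examples
#' p <- canonicalize_primer("OP_F001", "F", "AR")
#' find_matches(p, "AAGTAG")  # hits at (1,2) and (4,5)
#' @export
find_matches <- function(primer, sequence) {
  stopifnot(is.data.frame(primer), nrow(primer) == 1L,
            is.character(sequence), length(sequence) == 1L)
  len <- nchar(primer$search_sequence)
  hits <- gregexpr(primer_pattern(primer$search_sequence), sequence, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  start <- as.integer(hits)
  data.frame(start = start, end = start + len - 1L)
}

# All matches of one primer across a database: data frame
# (variant_id, species_id, start, end), one row per occurrence.
db_matches <- function(primer, db) {
  stopifnot(inherits(db, "primer_db"))
  pat <- primer_pattern(primer$search_sequence)
  len <- nchar(primer$search_sequence)
  hits <- gregexpr(pat, db$records$sequence, perl = TRUE)
  n_per <- vapply(hits, function(h) if (h[1L] == -1L) 0L else length(h), integer(1L))
  idx <- rep.int(seq_len(nrow(db$records)), n_per)
  start <- as.integer(unlist(hits[n_per > 0L], use.names = FALSE))
  data.frame(
    variant_id = db$records$variant_id[idx],
    species_id = db$records$species_id[idx],
    start = start,
    end = start + len - 1L,
    stringsAsFactors = FALSE
  )
}
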