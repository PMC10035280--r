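#' Build a canonical primer record
#'
#' Validates and normalizes one primer: the sequence is uppercased, U is
#' mapped to T and inosine (I) to N, and any other non-IUPAC character is
#' rejected with the offending position. Reverse primers additionally carry
#' `search_sequence`, the reverse complement used to locate the primer on the
#' sense-strand database sequences.
#'
#' @param primer_id Unique identifier, conventionally `OP_`/`KP_` followed by
#'   direction letter and a three-digit number (e.g. "OP_F001"), but any
#'   unique string is accepted.
#' @param direction One of "F"/"forward", "R"/"reverse", "UI"/"unidentified".
#' @param sequence 5' to 3' IUPAC sequence as written for synthesis.
#' @param source Provenance tag (free text, e.g. "oral" or "klindworth").
#' @return A one-row data frame with columns `primer_id`, `direction`,
#'   `sequence`, `source`, `search_sequence`.
#' @examples
#' canonicalize_primer("OP_F001", "F", "acgru")
#' @export
canonicalize_primer <- function(primer_id, direction, sequence, source = NA_character_) {
  stopifnot(is.character(primer_id), length(primer_id) == 1L, nzchar(primer_id))
  dir <- canonical_direction(direction)
  seq <- tryCatch(
    canonicalize_sequence(sequence),
    error = function(e) {
      stop(sprintf("primer %s: %s", primer_id, conditionMessage(e)), call. = FALSE)
    }
  )
  search <- if (dir == "reverse") reverse_complement(seq) else seq
  data.frame(
    primer_id = primer_id,
    direction = dir,
    sequence = seq,
    source = source,
    search_sequence = search,
    stringsAsFactors = FALSE
  )
}

canonical_direction <- function(direction) {
  stopifnot(is.character(direction), length(direction) == 1L)
  d <- toupper(direction)
  out <- switch(d,
    "F" = , "FORWARD" = "forward",
    "R" = , "REVERSE" = "reverse",
    "UI" = , "U" = , "UNIDENTIFIED" = "unidentified",
    NULL
  )
  if (is.null(out)) stop("unknown primer direction: '", direction, "'", call. = FALSE)
  out
}

#' Read a primer list from a tab-separated file
#'
#' Expected columns: `primer_id`, `direction`, `sequence` and optionally
#' `source`; lines starting with `#` are ignored. Each row is canonicalized
#' via [canonicalize_primer()].
#'
#' @param path Path to the TSV file.
#' @return A primer-set data frame (one row per primer).
#' @export
read_primers <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("primer_id", "direction", "sequence")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("primer file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("no primers in ", path, call. = FALSE)
  if (is.null(tab$source)) tab$source <- NA_character_
  if (anyDuplicated(tab$primer_id)) {
    stop("duplicate primer_id in ", path, ": ",
         tab$primer_id[duplicated(tab$primer_id)][1L], call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    canonicalize_primer(tab$primer_id[i], tab$direction[i],
                        tab$sequence[i], tab$source[i])
  }))
  rownames(out) <- NULL
  out
}

#' Write a primer set to a tab-separated file
#'
#' @param primers Primer-set data frame.
#' @param path Output path.
#' @export
write_primers <- function(primers, path) {
  utils::write.table(
    primers[, c("primer_id", "direction", "sequence", "source")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Deduplicate primers by canonical sequence
#'
#' Primers with byte-identical canonical 5' to 3' sequences are merged; the
#' first-seen identifier (file order) is kept as the representative, so the
#' reduction is reproducible. Primers differing by at least one nucleotide
#' (including a different ambiguity code) are kept apart.
#'
#' @param primers Primer-set data frame from [read_primers()] or
#'   [canonicalize_primer()].
#' @return A list with `primers` (the distinct set, original order) and
#'   `duplicate_map` (named list: representative id -> ids of merged members,
#'   representative excluded; empty when all sequences are distinct).
#' @export
dedup_primers <- function(primers) {
  stopifnot(is.data.frame(primers), nrow(primers) >= 1L)
  first <- !duplicated(primers$sequence)
  reps <- primers$primer_id[first][match(primers$sequence, primers$sequence[first])]
  dup_map <- list()
  for (r in unique(reps[duplicated(reps) | duplicated(reps, fromLast = TRUE)])) {
    members <- primers$primer_id[reps == r]
    dup_map[[r]] <- setdiff(members, r)
  }
  list(primers = primers[first, , drop = FALSE], duplicate_map = dup_map)
}
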