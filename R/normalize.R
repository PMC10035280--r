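# Reference-frame normalization. The original multi-sequence alignment step
# only served to impose E. coli coordinates, so each record is aligned
# pairwise to the reference (ends-free global alignment: match +1, mismatch
# -1, gap open 5, gap extend 1), alignment-internal gaps are discarded, and
# the record is stored as leading-gap padding followed by its own bases.

normalize_scoring <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE, type = "DNA")
}

#' Align one raw sequence to the reference frame
#'
#' Ends-free global alignment of a gap-free sequence to the reference.
#' `leading_offset` is the frame position of the sequence's first retained
#' base minus one; the returned `aligned_sequence` is that many gap
#' characters followed by the sequence itself with alignment-internal gaps
#' removed. Bases mapping below frame position 1 (a 5' extension beyond the
#' reference start) are trimmed off and counted in `trimmed_5p`. Records
#' whose aligned span has < `min_identity` identity are flagged
#' "unalignable" and should be excluded by the caller.
#'
#' @param raw_sequence Gap-free IUPAC sequence, ideally >= 100 nt.
#' @param frame A [reference_frame()].
#' @param min_identity Identity floor over the aligned span (default 0.6).
#' @return List with `leading_offset`, `aligned_sequence`, `trimmed_5p`,
#'   `identity`, `flags` (character vector, possibly empty).
#' @export
align_to_reference <- function(raw_sequence, frame, min_identity = 0.6) {
  stopifnot(inherits(frame, "reference_frame"))
  raw <- canonicalize_sequence(raw_sequence)
  aln <- Biostrings::pairwiseAlignment(
    pattern = raw, subject = frame$sequence, type = "overlap",
    substitutionMatrix = normalize_scoring(),
    gapOpening = 5, gapExtension = 1
  )
  identity <- Biostrings::pid(aln, type = "PID1") / 100
  flags <- character(0)
  # ends-free alignment can degenerate to a tiny high-identity window for an
  # unrelated sequence, so a record must also align over a reasonable share
  # of its length to count as placed in the frame
  aligned_fraction <-
    BiocGenerics::width(Biostrings::pattern(aln)) / nchar(raw)
  if (identity < min_identity || aligned_fraction < 0.3) {
    return(list(leading_offset = NA_integer_, aligned_sequence = NA_character_,
                trimmed_5p = 0L, identity = identity, flags = "unalignable"))
  }
  subject_start <- BiocGenerics::start(Biostrings::subject(aln))
  pattern_start <- BiocGenerics::start(Biostrings::pattern(aln))
  # frame position of raw base 1; negative when the record extends 5' of the
  # reference start, in which case those bases sit below position 1
  leading_offset <- subject_start - pattern_start
  trimmed_5p <- 0L
  if (leading_offset < 0L) {
    trimmed_5p <- -leading_offset
    raw <- substring(raw, trimmed_5p + 1L)
    leading_offset <- 0L
    flags <- c(flags, "trimmed_5p")
  }
  list(
    leading_offset = as.integer(leading_offset),
    aligned_sequence = paste0(strrep("-", leading_offset), raw),
    trimmed_5p = trimmed_5p,
    identity = identity,
    flags = flags
  )
}

#' Trim a frame-aligned sequence to the frame limit
#'
#' Removes bases whose frame position exceeds the limit (default 2000).
#' Bases below position 1 are already removed by [align_to_reference()].
#'
#' @param aligned_sequence Leading-gap padded sequence in frame coordinates.
#' @param frame A [reference_frame()].
#' @return The trimmed sequence (length <= `frame$frame_limit`).
#' @export
trim_to_frame <- function(aligned_sequence, frame) {
  stopifnot(inherits(frame, "reference_frame"))
  if (nchar(aligned_sequence) <= frame$frame_limit) return(aligned_sequence)
  substring(aligned_sequence, 1L, frame$frame_limit)
}

#' Flag records whose length is inconsistent with their reference span
#'
#' Heuristic for internally duplicated segments (e.g. a record carrying two
#' copies of the same gene region): a record is flagged when its total
#' length exceeds 120% of the reference span its alignment covers. Flagged
#' records are reported for review, never auto-deleted.
#'
#' @param raw_sequence Gap-free sequence.
#' @param frame A [reference_frame()].
#' @param threshold Length / reference-span ratio above which to flag
#'   (default 1.2).
#' @return `TRUE` when the record looks redundant.
#' @export
flag_redundant <- function(raw_sequence, frame, threshold = 1.2) {
  raw <- canonicalize_sequence(raw_sequence)
  # local alignment isolates the best single matching segment, so a record
  # carrying a second copy of a region is much longer than its span
  aln <- Biostrings::pairwiseAlignment(
    pattern = raw, subject = frame$sequence, type = "local",
    substitutionMatrix = normalize_scoring(),
    gapOpening = 5, gapExtension = 1
  )
  span <- BiocGenerics::width(Biostrings::subject(aln))
  nchar(raw) / span > threshold
}

#' Normalize a raw database into the reference frame
#'
#' Strips any pre-existing leading-gap padding (making the operation
#' idempotent), aligns every record to the reference, trims to the frame
#' limit, and drops records flagged "unalignable", shorter than
#' `min_length`, or empty after trimming. Returns the normalized database
#' and a per-record QC report.
#'
#' @param db A [primer_db()] with raw (or already normalized) sequences.
#' @param frame A [reference_frame()].
#' @param min_identity Identity floor passed to [align_to_reference()].
#' @param min_length Minimum raw length to attempt alignment (default 100).
#' @return List with `db` (normalized [primer_db()]) and `qc` (data frame:
#'   `variant_id`, `leading_offset`, `trimmed_5p`, `trimmed_3p`, `flags`,
#'   `kept`).
#' @export
normalize_database <- function(db, frame, min_identity = 0.6, min_length = 100L) {
  stopifnot(inherits(db, "primer_db"), inherits(frame, "reference_frame"))
  n <- nrow(db$records)
  qc <- data.frame(
    variant_id = db$records$variant_id,
    leading_offset = NA_integer_, trimmed_5p = 0L, trimmed_3p = 0L,
    flags = "", kept = FALSE, stringsAsFactors = FALSE
  )
  out_seq <- character(n)
  for (i in seq_len(n)) {
    raw <- sub("^-+", "", db$records$sequence[i])
    if (nchar(raw) < min_length) {
      qc$flags[i] <- "too_short"
      next
    }
    res <- align_to_reference(raw, frame, min_identity = min_identity)
    if ("unalignable" %in% res$flags) {
      qc$flags[i] <- "unalignable"
      next
    }
    if (flag_redundant(raw, frame)) {
      res$flags <- c(res$flags, "redundant")
    }
    trimmed <- trim_to_frame(res$aligned_sequence, frame)
    trimmed_3p <- nchar(res$aligned_sequence) - nchar(trimmed)
    if (trimmed_3p > 0L) res$flags <- c(res$flags, "trimmed_3p")
    if (nchar(sub("^-+", "", trimmed)) == 0L) {
      qc$flags[i] <- paste(c(res$flags, "fully_trimmed"), collapse = ",")
      next
    }
    qc$leading_offset[i] <- res$leading_offset
    qc$trimmed_5p[i] <- res$trimmed_5p
    qc$trimmed_3p[i] <- trimmed_3p
    qc$flags[i] <- paste(res$flags, collapse = ",")
    qc$kept[i] <- TRUE
    out_seq[i] <- trimmed
  }
  keep <- qc$kept
  records <- db$records[keep, , drop = FALSE]
  records$sequence <- out_seq[keep]
  list(db = primer_db(records, db$domain), qc = qc)
}
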