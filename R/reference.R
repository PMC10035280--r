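#' Reference coordinate frame
#'
#' All databases live in a 1-based coordinate frame in which position 1 is
#' the first nucleotide of the Escherichia coli J01859.1 16S rRNA gene and
#' sequences are trimmed at position 2000 (insertions relative to the
#' reference let frame positions run past the 1542-nt gene end). The package
#' ships a clearly labelled synthetic 1542-nt stand-in so that every fixture
#' and test is self-contained; supply the real J01859.1 sequence via
#' `fasta_path` for production use — any 1542-nt replacement is accepted.
#'
#' @param fasta_path Path to a single-record FASTA holding the reference;
#'   default is the bundled synthetic stand-in.
#' @param frame_limit Largest retained frame position (default 2000).
#' @return An object of class `reference_frame` with elements
#'   `reference_id`, `sequence`, `length`, `frame_limit`.
#' @export
reference_frame <- function(fasta_path = NULL, frame_limit = 2000L) {
  if (is.null(fasta_path)) {
    fasta_path <- system.file("extdata", "synthetic_reference_16S.fasta",
                              package = "primercover", mustWork = TRUE)
  }
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) != 1L) {
    stop("reference FASTA must contain exactly one record", call. = FALSE)
  }
  sequence <- canonicalize_sequence(as.character(seqs[[1L]]))
  structure(
    list(
      reference_id = strsplit(names(seqs)[1L], "[ \t]")[[1L]][1L],
      sequence = sequence,
      length = nchar(sequence),
      frame_limit = as.integer(frame_limit)
    ),
    class = "reference_frame"
  )
}

#' @export
print.reference_frame <- function(x, ...) {
  cat(sprintf("reference_frame: %s (%d nt, frame limit %d)\n",
              x$reference_id, x$length, x$frame_limit))
  invisible(x)
}

#' Read a conserved/hypervariable region table
#'
#' The table tiles the reference frame (positions 1..1542 by default) into
#' 10 conserved (C1-C10) and 9 hypervariable (V1-V9) intervals in the style
#' of the Baker et al. E. coli region definitions. Boundaries are
#' configuration, not ground truth; the bundled defaults can be replaced by
#' any disjoint, contiguous, sorted tiling.
#'
#' @param path TSV with columns `label`, `start`, `end`; default is the
#'   bundled table.
#' @return Data frame of class `region_table`, ordered by `start`.
#' @export
read_region_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "region_table.tsv",
                        package = "primercover", mustWork = TRUE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("label", "start", "end") %in% names(tab)))
  tab <- tab[order(tab$start), , drop = FALSE]
  if (tab$start[1L] != 1L ||
      any(tab$start[-1L] != tab$end[-nrow(tab)] + 1L) ||
      any(tab$end < tab$start)) {
    stop("region table must tile the frame contiguously from position 1",
         call. = FALSE)
  }
  rownames(tab) <- NULL
  class(tab) <- c("region_table", "data.frame")
  tab
}
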