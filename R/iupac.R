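#' IUPAC nucleotide ambiguity codes
#'
#' The 15 IUPAC degenerate-base letters mapped to the concrete bases each one
#' stands for. A degenerate primer letter anneals to any concrete base in its
#' set; database letters that are themselves ambiguous (e.g. N) never satisfy
#' a primer position.
#'
#' @format A named list of character vectors.
#' @keywords internal
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_SETS)

#' Concrete base set of an IUPAC letter
#'
#' @param letter A single canonical IUPAC letter.
#' @return Character vector of the concrete bases (subset of A, C, G, T) the
#'   letter represents.
#' @examples
#' iupac_set("R")  # A, G
#' iupac_set("N")  # A, C, G, T
#' @export
iupac_set <- function(letter) {
  stopifnot(is.character(letter), length(letter) == 1L)
  set <- IUPAC_SETS[[letter]]
  if (is.null(set)) {
    stop("not a canonical IUPAC letter: '", letter, "'", call. = FALSE)
  }
  set
}

#' Canonicalize a nucleotide sequence string
#'
#' Uppercases, maps U to T and inosine (I) to N, and rejects any character
#' outside the 15-letter IUPAC alphabet. Gap characters are rejected unless
#' `allow_gaps = TRUE` (used for reference-frame sequences with leading-gap
#' padding).
#'
#' @param sequence Raw sequence string.
#' @param allow_gaps Accept '-' characters (default `FALSE`).
#' @return The canonical sequence string.
#' @export
canonicalize_sequence <- function(sequence, allow_gaps = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  seq <- chartr("UI", "TN", toupper(sequence))
  alphabet <- IUPAC_LETTERS
  if (allow_gaps) alphabet <- c(alphabet, "-")
  letters_seen <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!letters_seen %in% alphabet)
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d",
                 letters_seen[bad[1L]], bad[1L]), call. = FALSE)
  }
  seq
}

# IUPAC-aware complement lookup, written out so the pairing logic is explicit:
# A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H; S, W and N are self-complementary.
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N", `-` = "-"
)

#' Reverse complement of an IUPAC sequence
#'
#' IUPAC-aware: ambiguity codes complement to the code of the complemented
#' base set (R to Y, K to M, B to V, D to H; S, W, N map to themselves).
#'
#' @param sequence Canonical IUPAC sequence string (gaps allowed).
#' @return The reverse complement, 5' to 3'.
#' @examples
#' reverse_complement("ACGT")  # "ACGT"
#' reverse_complement("AYG")   # "CRT"
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  letters_seen <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  comp <- IUPAC_COMPLEMENT[letters_seen]
  if (anyNA(comp)) {
    stop("non-IUPAC character in sequence: '",
         letters_seen[which(is.na(comp))[1L]], "'", call. = FALSE)
  }
  paste(rev(comp), collapse = "")
}

#' All concrete expansions of a degenerate sequence
#'
#' Enumerates every A/C/G/T string compatible with the degenerate sequence.
#' Used by the brute-force oracle; intentionally simple.
#'
#' @param sequence Canonical IUPAC sequence string.
#' @return Character vector of concrete expansions.
#' @export
expand_degenerate <- function(sequence) {
  letters_seen <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sets <- lapply(letters_seen, iupac_set)
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}
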