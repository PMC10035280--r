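#' Select candidate primers by species-level coverage
#'
#' Primers whose SC on the relevant database reaches the threshold
#' (inclusive, default 75.00%) are retained and split by direction.
#' Thresholding uses the rounded 2-decimal percentage, so an SC printed as
#' exactly 75.00 is kept.
#'
#' @param coverage A [coverage_table()] data frame.
#' @param threshold Minimum SC percent (default 75).
#' @return List with `forward` and `reverse` character vectors of
#'   `primer_id`s (unidentified-direction primers are dropped).
#' @export
select_candidates <- function(coverage, threshold = 75) {
  keep <- coverage$sc_percent >= threshold
  list(
    forward = coverage$primer_id[keep & coverage$direction == "forward"],
    reverse = coverage$primer_id[keep & coverage$direction == "reverse"]
  )
}

#' Amplicon length category
#'
#' The three mean-amplicon-length bins used to match sequencing regimes:
#' 100-300 bp (short reads), 301-600 bp (long reads), > 600 bp
#' (near-full-length). Applied to the mean length rounded to an integer.
#'
#' @param mean_length Numeric mean amplicon length(s).
#' @return Character vector: "100-300", "301-600", ">600", or `NA` below
#'   100.
#' @export
length_category <- function(mean_length) {
  len <- round_half_away(mean_length, 0L)
  out <- rep(NA_character_, length(len))
  out[len >= 100 & len <= 300] <- "100-300"
  out[len >= 301 & len <= 600] <- "301-600"
  out[len > 600] <- ">600"
  out
}

#' Enumerate admissible forward x reverse primer pairs
#'
#' Forms all F x R combinations and keeps those satisfying the two
#' admission conditions: (1) the mean position of the forward primer's
#' first nucleotide is lower than that of the reverse primer's last; and
#' (2) the distance between the two means is at least `min_distance`
#' (default 100 nt). The mean amplicon length is the inclusive span
#' `mean_r_last - mean_f_first + 1`. Primers without defined mean positions
#' (no matches) are excluded.
#'
#' @param f_stats,r_stats [position_stats()] rows for candidate forward and
#'   reverse primers.
#' @param min_distance Minimum distance between the two means (default 100).
#' @return Data frame sorted by (`forward_id`, `reverse_id`): mean
#'   positions, `mean_amplicon_length`, `length_category`.
#' @export
enumerate_pairs <- function(f_stats, r_stats, min_distance = 100) {
  f_stats <- f_stats[!is.na(f_stats$mean_first), , drop = FALSE]
  r_stats <- r_stats[!is.na(r_stats$mean_last), , drop = FALSE]
  if (!nrow(f_stats) || !nrow(r_stats)) {
    return(data.frame(forward_id = character(0), reverse_id = character(0),
                      mean_f_first = numeric(0), mean_r_last = numeric(0),
                      mean_amplicon_length = numeric(0),
                      length_category = character(0), stringsAsFactors = FALSE))
  }
  grid <- expand.grid(f = seq_len(nrow(f_stats)), r = seq_len(nrow(r_stats)))
  mean_f_first <- f_stats$mean_first[grid$f]
  mean_r_last <- r_stats$mean_last[grid$r]
  admitted <- mean_f_first < mean_r_last &
    (mean_r_last - mean_f_first) >= min_distance
  out <- data.frame(
    forward_id = f_stats$primer_id[grid$f][admitted],
    reverse_id = r_stats$primer_id[grid$r][admitted],
    mean_f_first = mean_f_first[admitted],
    mean_r_last = mean_r_last[admitted],
    stringsAsFactors = FALSE
  )
  out$mean_amplicon_length <- out$mean_r_last - out$mean_f_first + 1
  out$length_category <- length_category(out$mean_amplicon_length)
  out <- out[order(out$forward_id, out$reverse_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage of a primer pair against a database
#'
#' A variant is covered by a pair when both primers match that same variant
#' and at least one combination of sites has amplification geometry: a
#' forward first-position strictly below a reverse last-position. VC and SC
#' then follow the single-primer definitions.
#'
#' @param f_primer,r_primer One-row primer data frames (forward, reverse).
#' @param db A non-empty [primer_db()].
#' @return A `coverage_result`; `primer_id` is "forward_id-reverse_id".
#' @export
pair_coverage <- function(f_primer, r_primer, db) {
  stopifnot(inherits(db, "primer_db"))
  if (db$n_variants == 0L) stop("empty database", call. = FALSE)
  mf <- db_matches(f_primer, db)
  mr <- db_matches(r_primer, db)
  pair_id <- paste0(f_primer$primer_id, "-", r_primer$primer_id)
  if (!nrow(mf) || !nrow(mr)) {
    return(new_coverage_result(pair_id, db$domain, character(0), character(0), db))
  }
  # geometry check per variant: exists F.start < R.end, i.e.
  # min(F.start) < max(R.end)
  f_min <- tapply(mf$start, mf$variant_id, min)
  r_max <- tapply(mr$end, mr$variant_id, max)
  shared <- intersect(names(f_min), names(r_max))
  covered_variants <- shared[f_min[shared] < r_max[shared]]
  rec_idx <- match(covered_variants, db$records$variant_id)
  new_coverage_result(pair_id, db$domain, covered_variants,
                      unique(db$records$species_id[rec_idx]), db)
}

#' Domain specificity of a primer pair
#'
#' Classification uses the unrounded species fractions: "specific" for one
#' domain means literally zero covered species in the other.
#'
#' @param bacterial_result,archaeal_result `coverage_result`s of the same
#'   pair on the two databases.
#' @return One of "bacteria_specific", "archaea_specific", "non_specific",
#'   "dead".
#' @export
classify_specificity <- function(bacterial_result, archaeal_result) {
  b <- bacterial_result$n_species_covered > 0L
  a <- archaeal_result$n_species_covered > 0L
  if (b && a) "non_specific"
  else if (b) "bacteria_specific"
  else if (a) "archaea_specific"
  else "dead"
}

#' Species not covered by a primer pair
#'
#' @param f_primer,r_primer One-row primer data frames.
#' @param db A [primer_db()].
#' @return Data frame sorted by `species_id` with the species-level
#'   taxonomy name attached.
#' @export
not_covered_report <- function(f_primer, r_primer, db) {
  cv <- pair_coverage(f_primer, r_primer, db)
  nm <- species_names(db)
  data.frame(
    species_id = cv$not_covered_species,
    species_name = unname(nm[cv$not_covered_species]),
    stringsAsFactors = FALSE
  )
}
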