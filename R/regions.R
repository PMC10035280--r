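# Position statistics over primer match populations and assignment to
# conserved/hypervariable regions of the reference frame.

# Most frequent value of an integer multiset; ties broken by minimal
# absolute distance to the mean, residual ties toward the smaller value.
mode_nearest_mean <- function(values) {
  if (!length(values)) return(NA_integer_)
  tab <- table(values)
  cand <- as.integer(names(tab)[tab == max(tab)])
  m <- mean(values)
  cand <- cand[order(abs(cand - m), cand)]
  cand[1L]
}

#' Position statistics of a primer's matches in a database
#'
#' Collects the first and last annealing positions of every match across
#' all matched variants, and reports their means and modes. With more than
#' one mode, the one closest to the mean is chosen; a residual tie
#' (equidistant modes) resolves to the smaller position. With no matches
#' all statistics are undefined (`NA`), not an error.
#'
#' @param primer One-row primer data frame.
#' @param db A [primer_db()].
#' @return A one-row data frame: `primer_id`, `direction`, `mean_first`,
#'   `mean_last`, `mode_first`, `mode_last`, `n_observations`.
#' @export
position_stats <- function(primer, db) {
  m <- db_matches(primer, db)
  data.frame(
    primer_id = primer$primer_id,
    direction = primer$direction,
    mean_first = if (nrow(m)) mean(m$start) else NA_real_,
    mean_last = if (nrow(m)) mean(m$end) else NA_real_,
    mode_first = mode_nearest_mean(m$start),
    mode_last = mode_nearest_mean(m$end),
    n_observations = nrow(m),
    stringsAsFactors = FALSE
  )
}

#' Region containing a frame position
#'
#' @param position Integer position, >= 1. Positions beyond the last region
#'   boundary (past the reference end but within the frame limit) return
#'   "beyond-reference".
#' @param region_table A [read_region_table()] table.
#' @return The region label (e.g. "V4" or "C3").
#' @export
assign_region <- function(position, region_table) {
  stopifnot(length(position) == 1L, !is.na(position))
  if (position < 1) stop("position must be >= 1", call. = FALSE)
  hit <- which(region_table$start <= position & position <= region_table$end)
  if (!length(hit)) return("beyond-reference")
  region_table$label[hit[1L]]
}

# Hypervariable-region number for one primer: a mode inside V<k> gives k; a
# mode inside a conserved region takes the hypervariable region it flanks on
# the amplicon-interior side (forward -> next V downstream, reverse -> next V
# upstream), since universal primers anneal in the conserved flanks but are
# named by the V region they amplify. C<k> sits between V<k-1> and V<k>.
primer_region_number <- function(mode_position, direction, region_table) {
  if (is.na(mode_position)) return("undefined")
  label <- assign_region(mode_position, region_table)
  if (label == "beyond-reference") return("undefined")
  k <- as.integer(sub("^[CV]", "", label))
  n_v <- sum(grepl("^V", region_table$label))
  if (grepl("^V", label)) return(as.character(k))
  if (direction == "reverse") {
    as.character(max(k - 1L, 1L))
  } else {
    as.character(min(k, n_v))
  }
}

#' Gene-region label of a primer pair
#'
#' Combines the forward and reverse primers' hypervariable-region numbers
#' into the conventional pair label ("3-4"); equal numbers collapse to a
#' single figure ("3"). A primer with no matches, or whose mode position
#' lies beyond the reference, contributes "undefined".
#'
#' @param f_stats,r_stats One-row [position_stats()] frames for the forward
#'   and reverse primer.
#' @param region_table A [read_region_table()] table.
#' @return The label string.
#' @export
pair_region <- function(f_stats, r_stats, region_table) {
  f <- primer_region_number(f_stats$mode_first, "forward", region_table)
  r <- primer_region_number(r_stats$mode_last, "reverse", region_table)
  if (identical(f, r)) f else paste0(f, "-", r)
}

#' Tabulate position statistics for a primer set
#'
#' @param primers Primer-set data frame.
#' @param db A [primer_db()].
#' @param region_table Optional region table; when supplied a `region`
#'   column with each primer's hypervariable-region number is appended.
#' @return Data frame, one row per primer.
#' @export
position_table <- function(primers, db, region_table = NULL) {
  out <- do.call(rbind, lapply(seq_len(nrow(primers)), function(i) {
    position_stats(primers[i, , drop = FALSE], db)
  }))
  rownames(out) <- NULL
  if (!is.null(region_table)) {
    out$region <- vapply(seq_len(nrow(out)), function(i) {
      anchor <- if (out$direction[i] == "reverse") out$mode_last[i] else out$mode_first[i]
      primer_region_number(anchor, out$direction[i], region_table)
    }, character(1L))
  }
  out
}
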