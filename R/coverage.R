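#' Round half away from zero
#'
#' Percentages are reported to a fixed number of decimals with halves
#' rounded away from zero, so table values are byte-stable across platforms
#' (base R `round()` rounds half to even). Raw fractions are kept alongside
#' every rounded figure.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

new_coverage_result <- function(primer_id, domain, matched_variants,
                                covered_species, db) {
  all_species <- sort(names(db$species_index))
  covered <- sort(intersect(all_species, covered_species))
  not_covered <- setdiff(all_species, covered)
  vc_raw <- if (db$n_variants) length(matched_variants) / db$n_variants else NA_real_
  sc_raw <- if (db$n_species) length(covered) / db$n_species else NA_real_
  structure(
    list(
      primer_id = primer_id,
      domain = db$domain,
      vc_fraction = vc_raw,
      sc_fraction = sc_raw,
      vc_percent = round_half_away(100 * vc_raw),
      sc_percent = round_half_away(100 * sc_raw),
      n_variants_matched = length(matched_variants),
      n_species_covered = length(covered),
      n_species_not_covered = length(not_covered),
      covered_species = covered,
      not_covered_species = not_covered
    ),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("%s vs %s: VC = %.2f%% (%d variants), SC = %.2f%% (%d/%d species)\n",
              x$primer_id, x$domain, x$vc_percent, x$n_variants_matched,
              x$sc_percent, x$n_species_covered,
              x$n_species_covered + x$n_species_not_covered))
  invisible(x)
}

#' Coverage of a single primer against a database
#'
#' A variant counts as matched when the primer has at least one
#' zero-mismatch occurrence in it ([find_matches()]). Variant-level
#' coverage (VC) is the percentage of matched variants over all variants;
#' species-level coverage (SC) is the percentage of species with at least
#' one matched variant. SC deliberately discounts variants truncated at the
#' sequence ends: a species whose full-length variant is matched stays
#' covered even when its truncated variants are not.
#'
#' @param primer One-row primer data frame.
#' @param db A non-empty [primer_db()].
#' @return A `coverage_result` with VC and SC fields, raw fractions,
#'   and sorted covered / not-covered species lists.
#' @export
primer_coverage <- function(primer, db) {
  stopifnot(inherits(db, "primer_db"))
  if (db$n_variants == 0L) stop("empty database", call. = FALSE)
  m <- db_matches(primer, db)
  new_coverage_result(primer$primer_id, db$domain,
                      unique(m$variant_id), unique(m$species_id), db)
}

#' @rdname primer_coverage
#' @export
variant_coverage <- primer_coverage

#' @rdname primer_coverage
#' @export
species_coverage <- primer_coverage

#' Tabulate coverage of a primer set against a database
#'
#' @param primers Primer-set data frame.
#' @param db A [primer_db()].
#' @return Data frame, one row per primer, with VC/SC percentages and
#'   species counts.
#' @export
coverage_table <- function(primers, db) {
  rows <- lapply(seq_len(nrow(primers)), function(i) {
    cv <- primer_coverage(primers[i, , drop = FALSE], db)
    data.frame(
      primer_id = cv$primer_id,
      direction = primers$direction[i],
      domain = cv$domain,
      vc_percent = cv$vc_percent,
      sc_percent = cv$sc_percent,
      sc_fraction = cv$sc_fraction,
      n_variants_matched = cv$n_variants_matched,
      n_species_covered = cv$n_species_covered,
      n_species_not_covered = cv$n_species_not_covered,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
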