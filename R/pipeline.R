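# End-to-end runs: per-primer evaluation and the full pair pipeline.
# TSV is the canonical output; every run writes a manifest echoing the
# effective configuration and input checksums so results are reproducible.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_manifest <- function(out_dir, config, counts) {
  paths <- config[vapply(config, function(x)
    is.character(x) && length(x) == 1L && file.exists(x), logical(1L))]
  lines <- c(
    "# primercover run manifest",
    vapply(names(config), function(k) {
      paste0(k, "\t", paste(format(config[[k]]), collapse = ","))
    }, character(1L)),
    vapply(names(paths), function(k) {
      paste0("md5_", k, "\t", unname(tools::md5sum(paths[[k]])))
    }, character(1L)),
    vapply(names(counts), function(k) {
      paste0("count_", k, "\t", counts[[k]])
    }, character(1L))
  )
  writeLines(lines, file.path(out_dir, "manifest.tsv"))
}

#' Evaluate individual primers against both databases
#'
#' Reads (or receives) a primer list and the two domain databases,
#' deduplicates primers by sequence, computes per-primer VC/SC, position
#' statistics and region assignment on each database, and cross-tabulates
#' primers by whether they cover only bacteria, only archaea, both domains
#' or neither.
#'
#' @param primers Primer-set data frame or path to a primer TSV.
#' @param bacteria,archaea [primer_db()] objects or FASTA paths.
#' @param region_table A [read_region_table()] table (default bundled).
#' @param out_dir Optional directory for TSV reports
#'   (`primers_bacteria.tsv`, `primers_archaea.tsv`, `primer_crosstab.tsv`,
#'   `manifest.tsv`).
#' @return List with `bacteria` and `archaea` coverage/position tables,
#'   `crosstab`, `dedup` (the duplicate map) and `counts`.
#' @export
run_eval_primers <- function(primers, bacteria, archaea,
                             region_table = read_region_table(),
                             out_dir = NULL) {
  config <- list(
    primers = if (is.character(primers)) primers else "<in-memory>",
    bacteria = if (is.character(bacteria)) bacteria else "<in-memory>",
    archaea = if (is.character(archaea)) archaea else "<in-memory>"
  )
  if (is.character(primers)) primers <- read_primers(primers)
  if (is.character(bacteria)) bacteria <- read_database(bacteria, "bacteria")
  if (is.character(archaea)) archaea <- read_database(archaea, "archaea")
  if (nrow(primers) == 0L) stop("no primers", call. = FALSE)
  dd <- dedup_primers(primers)
  primers <- dd$primers

  eval_one <- function(db) {
    cv <- coverage_table(primers, db)
    ps <- position_table(primers, db, region_table)
    merge(cv, ps[, setdiff(names(ps), "direction")], by = "primer_id",
          sort = FALSE)
  }
  bac <- eval_one(bacteria)
  arc <- eval_one(archaea)
  in_b <- bac$n_species_covered > 0L
  in_a <- arc$n_species_covered > 0L
  group <- ifelse(in_b & in_a, "both",
                  ifelse(in_b, "bacteria_only",
                         ifelse(in_a, "archaea_only", "neither")))
  crosstab <- as.data.frame(table(group = group,
                                  direction = bac$direction),
                            stringsAsFactors = FALSE)
  counts <- list(primers_read = nrow(primers) +
                   length(unlist(dd$duplicate_map)),
                 primers_distinct = nrow(primers))
  out <- list(bacteria = bac, archaea = arc, crosstab = crosstab,
              dedup = dd$duplicate_map, counts = counts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(bac, file.path(out_dir, "primers_bacteria.tsv"))
    write_tsv(arc, file.path(out_dir, "primers_archaea.tsv"))
    write_tsv(crosstab, file.path(out_dir, "primer_crosstab.tsv"))
    run_manifest(out_dir, config, counts)
  }
  out
}

#' Run the full primer-pair pipeline
#'
#' Candidate selection (SC at or above `sc_threshold` on either database),
#' pair enumeration under the two admission conditions on that domain's
#' position statistics, merging of pairs admitted in both domains,
#' dual-domain pair coverage, specificity classification, amplicon length
#' category and gene-region label.
#'
#' @inheritParams run_eval_primers
#' @param sc_threshold Candidate SC threshold in percent (default 75).
#' @param min_distance Minimum distance between mean positions (default
#'   100).
#' @param not_covered For at most this many pairs (by descending bacterial
#'   then archaeal SC) write per-pair not-covered species TSVs; `0`
#'   disables (default 0).
#' @return List with `pairs` (one row per admitted pair), `candidates`,
#'   `primer_eval` (the [run_eval_primers()] result) and `counts`.
#' @export
run_eval_pairs <- function(primers, bacteria, archaea,
                           region_table = read_region_table(),
                           sc_threshold = 75, min_distance = 100,
                           out_dir = NULL, not_covered = 0L) {
  config <- list(
    primers = if (is.character(primers)) primers else "<in-memory>",
    bacteria = if (is.character(bacteria)) bacteria else "<in-memory>",
    archaea = if (is.character(archaea)) archaea else "<in-memory>",
    sc_threshold = sc_threshold, min_distance = min_distance
  )
  if (is.character(primers)) primers <- read_primers(primers)
  if (is.character(bacteria)) bacteria <- read_database(bacteria, "bacteria")
  if (is.character(archaea)) archaea <- read_database(archaea, "archaea")
  ev <- run_eval_primers(primers, bacteria, archaea, region_table)
  primers <- dedup_primers(primers)$primers

  enumerate_domain <- function(tab) {
    cand <- select_candidates(tab, sc_threshold)
    pairs <- enumerate_pairs(
      tab[tab$primer_id %in% cand$forward, , drop = FALSE],
      tab[tab$primer_id %in% cand$reverse, , drop = FALSE],
      min_distance
    )
    list(candidates = cand, pairs = pairs)
  }
  bac_enum <- enumerate_domain(ev$bacteria)
  arc_enum <- enumerate_domain(ev$archaea)

  key_b <- paste(bac_enum$pairs$forward_id, bac_enum$pairs$reverse_id)
  key_a <- paste(arc_enum$pairs$forward_id, arc_enum$pairs$reverse_id)
  merged <- rbind(bac_enum$pairs, arc_enum$pairs[!key_a %in% key_b, , drop = FALSE])
  merged$candidate_domains <- c(
    ifelse(key_b %in% key_a, "both", "bacteria"),
    rep("archaea", sum(!key_a %in% key_b))
  )
  merged <- merged[order(merged$forward_id, merged$reverse_id), , drop = FALSE]
  rownames(merged) <- NULL

  pair_rows <- lapply(seq_len(nrow(merged)), function(i) {
    f <- primers[primers$primer_id == merged$forward_id[i], , drop = FALSE]
    r <- primers[primers$primer_id == merged$reverse_id[i], , drop = FALSE]
    b <- pair_coverage(f, r, bacteria)
    a <- pair_coverage(f, r, archaea)
    stats_tab <- if (merged$candidate_domains[i] == "archaea")
      ev$archaea else ev$bacteria
    fs <- stats_tab[stats_tab$primer_id == f$primer_id, , drop = FALSE]
    rs <- stats_tab[stats_tab$primer_id == r$primer_id, , drop = FALSE]
    data.frame(
      forward_id = f$primer_id, reverse_id = r$primer_id,
      candidate_domains = merged$candidate_domains[i],
      mean_f_first = merged$mean_f_first[i],
      mean_r_last = merged$mean_r_last[i],
      mean_amplicon_length = merged$mean_amplicon_length[i],
      length_category = merged$length_category[i],
      region = pair_region(
        data.frame(mode_first = fs$mode_first),
        data.frame(mode_last = rs$mode_last), region_table),
      bacterial_vc = b$vc_percent, bacterial_sc = b$sc_percent,
      bacterial_covered = b$n_species_covered,
      bacterial_not_covered = b$n_species_not_covered,
      archaeal_vc = a$vc_percent, archaeal_sc = a$sc_percent,
      archaeal_covered = a$n_species_covered,
      archaeal_not_covered = a$n_species_not_covered,
      specificity = classify_specificity(b, a),
      stringsAsFactors = FALSE
    )
  })
  pairs <- do.call(rbind, pair_rows)
  if (is.null(pairs)) pairs <- data.frame()
  counts <- c(ev$counts, list(
    bacterial_candidates = length(unlist(bac_enum$candidates)),
    archaeal_candidates = length(unlist(arc_enum$candidates)),
    bacterial_pairs = nrow(bac_enum$pairs),
    archaeal_pairs = nrow(arc_enum$pairs),
    shared_pairs = sum(key_b %in% key_a),
    pairs_evaluated = nrow(pairs)
  ))
  out <- list(pairs = pairs,
              candidates = list(bacteria = bac_enum$candidates,
                                archaea = arc_enum$candidates),
              primer_eval = ev, counts = counts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(pairs, file.path(out_dir, "pairs.tsv"))
    write_tsv(ev$bacteria, file.path(out_dir, "primers_bacteria.tsv"))
    write_tsv(ev$archaea, file.path(out_dir, "primers_archaea.tsv"))
    if (not_covered > 0L && nrow(pairs)) {
      nc_dir <- file.path(out_dir, "not_covered")
      dir.create(nc_dir, showWarnings = FALSE)
      ord <- order(-pairs$bacterial_sc, -pairs$archaeal_sc)
      for (i in utils::head(ord, not_covered)) {
        f <- primers[primers$primer_id == pairs$forward_id[i], , drop = FALSE]
        r <- primers[primers$primer_id == pairs$reverse_id[i], , drop = FALSE]
        nc <- rbind(
          cbind(domain = "bacteria", not_covered_report(f, r, bacteria)),
          cbind(domain = "archaea", not_covered_report(f, r, archaea))
        )
        write_tsv(nc, file.path(
          nc_dir, paste0(pairs$forward_id[i], "-", pairs$reverse_id[i], ".tsv")))
      }
    }
    run_manifest(out_dir, config, counts)
  }
  out
}
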