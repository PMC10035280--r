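# Deterministic synthetic fixtures with oracle-computed ground truth.
# Sequences are derived from the bundled reference with per-species and
# per-variant mutations; primer sites are implanted exactly where declared;
# a fraction of variants is truncated at the sequence ends (emulating the
# missing-end annotations that depress VC but not SC) and padded with
# leading gaps; a small rate of N letters emulates ambiguous base calls.

#' Describe a synthetic fixture
#'
#' @param seed Integer seed; identical seed and spec give byte-identical
#'   output.
#' @param n_species Number of species per domain.
#' @param variants_per_species Length-2 integer range; each species draws
#'   its variant count uniformly from it.
#' @param sequence_length Full-length variant size (frame positions
#'   1..sequence_length), at most 2000.
#' @param implants List of implant descriptions, each a list with
#'   `primer_id`, `direction` ("F"/"R"), `position` (frame position of the
#'   site's first base), `length` (site length, default 18), `degeneracy`
#'   (number of degenerate positions in the primer, default 2),
#'   `fraction_of_species`, `fraction_of_variants` (fractions receiving an
#'   exact site; remaining variants get the site actively broken), and
#'   `domains` (subset of c("bacteria", "archaea"), default both).
#' @param truncation Fraction of variants clipped at the 5' or 3' end.
#' @param ambiguity_rate Per-base probability of an N call.
#' @param species_divergence,variant_divergence Per-base substitution rates
#'   from the reference (species level) and from the species consensus
#'   (variant level).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_species = 10L,
                         variants_per_species = c(1L, 6L),
                         sequence_length = 500L,
                         implants = default_implants(),
                         truncation = 0.3,
                         ambiguity_rate = 0.01,
                         species_divergence = 0.05,
                         variant_divergence = 0.01) {
  stopifnot(sequence_length >= 100L, sequence_length <= 2000L,
            length(variants_per_species) == 2L,
            variants_per_species[1L] >= 1L,
            truncation >= 0, truncation <= 1,
            ambiguity_rate >= 0, ambiguity_rate < 1)
  for (im in implants) {
    len <- if (is.null(im$length)) 18L else im$length
    if (im$position < 1L || im$position + len - 1L > sequence_length) {
      stop("implant ", im$primer_id, ": site [", im$position, ", ",
           im$position + len - 1L, "] falls outside the ",
           sequence_length, "-nt sequence", call. = FALSE)
    }
  }
  structure(
    list(seed = as.integer(seed), n_species = as.integer(n_species),
         variants_per_species = as.integer(variants_per_species),
         sequence_length = as.integer(sequence_length),
         implants = implants, truncation = truncation,
         ambiguity_rate = ambiguity_rate,
         species_divergence = species_divergence,
         variant_divergence = variant_divergence),
    class = "fixture_spec"
  )
}

#' @rdname fixture_spec
#' @export
default_implants <- function() {
  list(
    list(primer_id = "OP_F001", direction = "F", position = 40L,
         fraction_of_species = 0.9, fraction_of_variants = 0.9),
    list(primer_id = "OP_F002", direction = "F", position = 160L,
         fraction_of_species = 0.8, fraction_of_variants = 0.7,
         domains = "bacteria"),
    list(primer_id = "OP_R001", direction = "R", position = 420L,
         fraction_of_species = 0.9, fraction_of_variants = 0.9),
    list(primer_id = "OP_R002", direction = "R", position = 300L,
         fraction_of_species = 0.6, fraction_of_variants = 0.6,
         domains = "archaea")
  )
}

# sample() treats a length-1 numeric as 1:x; this does not
resample <- function(x, size = 1L) x[sample.int(length(x), size)]

MUTATE_ALTS <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))

mutate_bases <- function(bases, rate) {
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(MUTATE_ALTS[[bases[i]]], 1L)
  }
  bases
}

# two-base IUPAC codes containing each base, used to widen primer letters
DEGENERATE_CHOICES <- list(A = c("R", "W", "M"), C = c("Y", "S", "M"),
                           G = c("R", "S", "K"), T = c("Y", "W", "K"))

build_implant_primers <- function(spec, refseq) {
  rows <- lapply(spec$implants, function(im) {
    len <- if (is.null(im$length)) 18L else as.integer(im$length)
    degen <- if (is.null(im$degeneracy)) 2L else as.integer(im$degeneracy)
    site <- strsplit(substring(refseq, im$position, im$position + len - 1L),
                     "")[[1L]]
    primer <- site
    if (degen > 0L) {
      at <- sample(seq_len(len), min(degen, len))
      for (i in at) primer[i] <- sample(DEGENERATE_CHOICES[[primer[i]]], 1L)
    }
    seq5to3 <- paste(primer, collapse = "")
    if (toupper(im$direction) %in% c("R", "REVERSE")) {
      seq5to3 <- reverse_complement(seq5to3)
    }
    canonicalize_primer(im$primer_id, im$direction, seq5to3, "synthetic")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# a concrete sense-strand realization of one primer's annealing site
realize_site <- function(primer_row) {
  letters_seen <- strsplit(primer_row$search_sequence, "", fixed = TRUE)[[1L]]
  paste(vapply(letters_seen, function(l) {
    set <- iupac_set(l)
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1L)), collapse = "")
}

# break a site so zero-mismatch matching is impossible: pick a primer
# position with a proper subset and place a base outside it
break_site <- function(bases, primer_row, offset) {
  letters_seen <- strsplit(primer_row$search_sequence, "", fixed = TRUE)[[1L]]
  fixable <- which(vapply(letters_seen, function(l) length(iupac_set(l)) < 4L,
                          logical(1L)))
  j <- resample(fixable)
  outside <- setdiff(c("A", "C", "G", "T"), iupac_set(letters_seen[j]))
  bases[offset + j - 1L] <- sample(outside, 1L)
  bases
}

generate_domain <- function(spec, refseq, domain, primers) {
  n_sp <- spec$n_species
  sp_ids <- sprintf("SP%05d", seq_len(n_sp) +
                      if (domain == "archaea") 500L else 0L)
  prefix <- if (domain == "archaea") "AS" else "TS"
  implants <- spec$implants
  # implants excluded from this domain never receive a site: their windows
  # are actively broken in every variant so the domain's truth SC is zero
  active <- vapply(implants, function(im) {
    domain %in% (if (is.null(im$domains)) c("bacteria", "archaea") else im$domains)
  }, logical(1L))
  # species chosen for each implant (seeded, without replacement)
  implant_species <- lapply(implants, function(im) {
    sample(seq_len(n_sp), round(im$fraction_of_species * n_sp))
  })
  taxa <- sprintf("k_%s;p_%s;c_x;o_x;f_x;g_x;s_species%03d",
                  substr(domain, 1L, 3L), substr(domain, 1L, 3L),
                  seq_len(n_sp))
  records <- list()
  vid <- 0L
  for (s in seq_len(n_sp)) {
    base <- mutate_bases(strsplit(substring(refseq, 1L, spec$sequence_length),
                                  "")[[1L]], spec$species_divergence)
    n_var <- resample(seq.int(spec$variants_per_species[1L],
                              spec$variants_per_species[2L]))
    for (v in seq_len(n_var)) {
      bases <- mutate_bases(base, spec$variant_divergence)
      for (k in seq_along(implants)) {
        im <- implants[[k]]
        p <- primers[primers$primer_id == im$primer_id, , drop = FALSE]
        len <- nchar(p$search_sequence)
        if (active[k] && s %in% implant_species[[k]] &&
            stats::runif(1L) < im$fraction_of_variants) {
          site <- strsplit(realize_site(p), "", fixed = TRUE)[[1L]]
          bases[im$position:(im$position + len - 1L)] <- site
        } else {
          bases <- break_site(bases, p, im$position)
        }
      }
      # ambiguous base calls
      amb <- which(stats::runif(length(bases)) < spec$ambiguity_rate)
      bases[amb] <- "N"
      seqstr <- paste(bases, collapse = "")
      # end truncation: clip 5' (leading-gap padding keeps the frame) or 3'
      if (stats::runif(1L) < spec$truncation) {
        clip <- resample(10:floor(spec$sequence_length / 4))
        if (stats::runif(1L) < 0.5) {
          seqstr <- paste0(strrep("-", clip),
                           substring(seqstr, clip + 1L))
        } else {
          seqstr <- substring(seqstr, 1L, nchar(seqstr) - clip)
        }
      }
      vid <- vid + 1L
      records[[vid]] <- data.frame(
        variant_id = sprintf("%s%06d", prefix, vid),
        accession = sprintf("NR_%06d", vid),
        species_id = sp_ids[s],
        taxonomy = taxa[s],
        sequence = seqstr,
        stringsAsFactors = FALSE
      )
    }
  }
  primer_db(do.call(rbind, records), domain)
}

#' Generate a synthetic fixture with oracle ground truth
#'
#' Builds a primer set and one database per domain from a [fixture_spec()],
#' then computes the expected VC/SC of every primer and every forward x
#' reverse combination with the brute-force oracle ([oracle_coverage()]),
#' which is independent of the matching engine. Optionally writes the
#' primer TSV, the two FASTA databases and the truth tables to `out_dir`.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional output directory.
#' @return List with `primers`, `bacteria`, `archaea` ([primer_db()]s),
#'   `truth` (list of `primers` and `pairs` data frames with oracle VC/SC
#'   per domain).
#' @export
generate_fixture <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  refseq <- reference_frame()$sequence
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  primers <- build_implant_primers(spec, refseq)
  bacteria <- generate_domain(spec, refseq, "bacteria", primers)
  archaea <- generate_domain(spec, refseq, "archaea", primers)
  truth <- oracle_truth(primers, bacteria, archaea)
  out <- list(primers = primers, bacteria = bacteria, archaea = archaea,
              truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_primers(primers, file.path(out_dir, "primers.tsv"))
    write_database(bacteria, file.path(out_dir, "bacteria.fasta"))
    write_database(archaea, file.path(out_dir, "archaea.fasta"))
    utils::write.table(truth$primers, file.path(out_dir, "truth_primers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$pairs, file.path(out_dir, "truth_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ---- brute-force oracle -----------------------------------------------
# Independent of the regex engine: degenerate primers are expanded into all
# concrete A/C/G/T strings (reverse primers are reverse-complemented per
# expansion with a plain base swap) and every window of every sequence is
# compared for string equality. Windows containing gaps or ambiguity codes
# equal no expansion, so they never match.

oracle_search_strings <- function(primer_row) {
  exps <- expand_degenerate(primer_row$sequence)
  if (primer_row$direction == "reverse") {
    exps <- vapply(exps, function(e) {
      paste(rev(strsplit(chartr("ACGT", "TGCA", e), "", fixed = TRUE)[[1L]]),
            collapse = "")
    }, character(1L), USE.NAMES = FALSE)
  }
  unique(exps)
}

oracle_match_positions <- function(search_strings, sequence) {
  len <- nchar(search_strings[1L])
  n <- nchar(sequence)
  if (n < len) return(integer(0))
  starts <- seq_len(n - len + 1L)
  windows <- substring(sequence, starts, starts + len - 1L)
  starts[windows %in% search_strings]
}

#' Brute-force oracle coverage of one primer
#'
#' @param primer_row One-row primer data frame.
#' @param db A [primer_db()].
#' @return List with `vc_percent`, `sc_percent`, `covered_species`.
#' @export
oracle_coverage <- function(primer_row, db) {
  ss <- oracle_search_strings(primer_row)
  matched <- vapply(db$records$sequence, function(s) {
    length(oracle_match_positions(ss, s)) > 0L
  }, logical(1L), USE.NAMES = FALSE)
  covered <- sort(unique(db$records$species_id[matched]))
  list(
    vc_percent = round_half_away(100 * sum(matched) / db$n_variants),
    sc_percent = round_half_away(100 * length(covered) / db$n_species),
    covered_species = covered
  )
}

#' Brute-force oracle coverage of a primer pair
#'
#' @param f_row,r_row One-row primer data frames.
#' @param db A [primer_db()].
#' @return As [oracle_coverage()].
#' @export
oracle_pair_coverage <- function(f_row, r_row, db) {
  fs <- oracle_search_strings(f_row)
  rs <- oracle_search_strings(r_row)
  rlen <- nchar(r_row$sequence)
  matched <- vapply(db$records$sequence, function(s) {
    fpos <- oracle_match_positions(fs, s)
    if (!length(fpos)) return(FALSE)
    rpos <- oracle_match_positions(rs, s)
    if (!length(rpos)) return(FALSE)
    min(fpos) < max(rpos) + rlen - 1L
  }, logical(1L), USE.NAMES = FALSE)
  covered <- sort(unique(db$records$species_id[matched]))
  list(
    vc_percent = round_half_away(100 * sum(matched) / db$n_variants),
    sc_percent = round_half_away(100 * length(covered) / db$n_species),
    covered_species = covered
  )
}

oracle_truth <- function(primers, bacteria, archaea) {
  per_primer <- do.call(rbind, lapply(seq_len(nrow(primers)), function(i) {
    p <- primers[i, , drop = FALSE]
    b <- oracle_coverage(p, bacteria)
    a <- oracle_coverage(p, archaea)
    data.frame(primer_id = p$primer_id, direction = p$direction,
               bacterial_vc = b$vc_percent, bacterial_sc = b$sc_percent,
               archaeal_vc = a$vc_percent, archaeal_sc = a$sc_percent,
               stringsAsFactors = FALSE)
  }))
  fwd <- primers[primers$direction == "forward", , drop = FALSE]
  rev <- primers[primers$direction == "reverse", , drop = FALSE]
  combos <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  per_pair <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    f <- fwd[combos$f[k], , drop = FALSE]
    r <- rev[combos$r[k], , drop = FALSE]
    b <- oracle_pair_coverage(f, r, bacteria)
    a <- oracle_pair_coverage(f, r, archaea)
    data.frame(forward_id = f$primer_id, reverse_id = r$primer_id,
               bacterial_vc = b$vc_percent, bacterial_sc = b$sc_percent,
               archaeal_vc = a$vc_percent, archaeal_sc = a$sc_percent,
               stringsAsFactors = FALSE)
  }))
  list(primers = per_primer, pairs = per_pair)
}
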