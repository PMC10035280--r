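# Shared fixture builders. Everything is generated in code; no files.

# minimal database from explicit sequences: species_ids and sequences are
# parallel vectors
make_db <- function(sequences, species_ids, domain = "bacteria",
                    prefix = "TS") {
  n <- length(sequences)
  if (n == 0) {
    return(primer_db(data.frame(variant_id = character(0),
                                accession = character(0),
                                species_id = character(0),
                                taxonomy = character(0),
                                sequence = character(0)), domain))
  }
  primer_db(data.frame(
    variant_id = sprintf("%s%06d", prefix, seq_len(n)),
    accession = sprintf("NR_%06d", seq_len(n)),
    species_id = species_ids,
    taxonomy = paste0("k;p;c;o;f;g;s_", species_ids),
    sequence = sequences,
    stringsAsFactors = FALSE
  ), domain)
}

# database with a given number of covered / uncovered single-variant
# species; the primer site "ACGTACGTAC" is implanted only in covered ones
make_count_db <- function(n_covered, n_total, domain = "bacteria") {
  site <- "ACGTACGTAC"
  base <- strrep("GT", 30)
  seqs <- c(
    rep(paste0(substr(base, 1, 20), site, substr(base, 31, 60)), n_covered),
    rep(base, n_total - n_covered)
  )
  make_db(seqs, sprintf("SP%05d", seq_len(n_total)), domain)
}

count_probe_primer <- function() {
  canonicalize_primer("OP_F900", "F", "ACGTACGTAC")
}

# brute-force match positions via the oracle path (concrete expansions +
# window scan), for direct comparison with find_matches()
oracle_match_positions_test <- function(primer_row, sequence) {
  ss <- primercover:::oracle_search_strings(primer_row)
  primercover:::oracle_match_positions(ss, sequence)
}

# randomized fixture specification for engine-vs-oracle property tests
random_fixture_spec <- function(seed) {
  set.seed(seed)
  len <- sample(200:400, 1)
  slots <- sample(c(20L, 60L, 110L, 160L))
  mk <- function(id, dir, pos) {
    list(primer_id = id, direction = dir, position = pos,
         length = sample(14:20, 1), degeneracy = sample(0:3, 1),
         fraction_of_species = runif(1, 0.3, 1),
         fraction_of_variants = runif(1, 0.3, 1),
         domains = sample(list(c("bacteria", "archaea"), "bacteria",
                               "archaea"), 1)[[1]])
  }
  fixture_spec(
    seed = seed,
    n_species = sample(3:20, 1),
    variants_per_species = sort(sample(1:10, 2)),
    sequence_length = len,
    implants = list(mk("FX_F001", "F", slots[1]), mk("FX_F002", "F", slots[2]),
                    mk("FX_R001", "R", slots[3]), mk("FX_R002", "R", slots[4])),
    truncation = runif(1, 0, 0.5),
    ambiguity_rate = runif(1, 0, 0.02)
  )
}

# engine VC/SC for every primer and every F x R combination, shaped like
# the fixture truth tables
engine_truth <- function(fx) {
  per_primer <- do.call(rbind, lapply(seq_len(nrow(fx$primers)), function(i) {
    p <- fx$primers[i, , drop = FALSE]
    b <- primer_coverage(p, fx$bacteria)
    a <- primer_coverage(p, fx$archaea)
    data.frame(primer_id = p$primer_id, direction = p$direction,
               bacterial_vc = b$vc_percent, bacterial_sc = b$sc_percent,
               archaeal_vc = a$vc_percent, archaeal_sc = a$sc_percent,
               stringsAsFactors = FALSE)
  }))
  fwd <- fx$primers[fx$primers$direction == "forward", , drop = FALSE]
  rev <- fx$primers[fx$primers$direction == "reverse", , drop = FALSE]
  combos <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  per_pair <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    f <- fwd[combos$f[k], , drop = FALSE]
    r <- rev[combos$r[k], , drop = FALSE]
    b <- pair_coverage(f, r, fx$bacteria)
    a <- pair_coverage(f, r, fx$archaea)
    data.frame(forward_id = f$primer_id, reverse_id = r$primer_id,
               bacterial_vc = b$vc_percent, bacterial_sc = b$sc_percent,
               archaeal_vc = a$vc_percent, archaeal_sc = a$sc_percent,
               stringsAsFactors = FALSE)
  }))
  list(primers = per_primer, pairs = per_pair)
}
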