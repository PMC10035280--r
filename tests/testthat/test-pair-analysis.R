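stats_row <- function(id, dir, first, last) {
  data.frame(primer_id = id, direction = dir, mean_first = first,
             mean_last = last, mode_first = as.integer(round(first)),
             mode_last = as.integer(round(last)), n_observations = 10L,
             stringsAsFactors = FALSE)
}

test_that("candidate selection uses an inclusive SC threshold", {
  cov <- data.frame(
    primer_id = c("F1", "F2", "R1", "U1"),
    direction = c("forward", "forward", "reverse", "unidentified"),
    sc_percent = c(75.00, 74.99, 80.00, 99.00),
    stringsAsFactors = FALSE
  )
  cand <- select_candidates(cov)
  expect_equal(cand$forward, "F1")
  expect_equal(cand$reverse, "R1")
})

test_that("pair admission enforces order and minimum distance", {
  f <- rbind(stats_row("F1", "forward", 100, 117),
             stats_row("F2", "forward", 200, 217))
  r <- rbind(stats_row("R1", "reverse", 130, 150),   # too close to F1
             stats_row("R2", "reverse", 80, 100),    # 5' of both F
             stats_row("R3", "reverse", 400, 420))
  pairs <- enumerate_pairs(f, r)
  expect_equal(paste(pairs$forward_id, pairs$reverse_id),
               c("F1 R3", "F2 R3"))
  # F1-R3: 420 - 100 + 1
  expect_equal(pairs$mean_amplicon_length[1], 321)

  # 3 x 4 all mutually admissible
  f3 <- do.call(rbind, lapply(1:3, function(i)
    stats_row(paste0("F", i), "forward", 100 + i, 120 + i)))
  r4 <- do.call(rbind, lapply(1:4, function(i)
    stats_row(paste0("R", i), "reverse", 600 + i, 620 + i)))
  expect_equal(nrow(enumerate_pairs(f3, r4)), 12)

  # primers without defined positions are excluded
  f_na <- rbind(f, stats_row("F9", "forward", NA_real_, NA_real_))
  expect_equal(nrow(enumerate_pairs(f_na, r)), 2)

  # output invariant to input ordering
  scrambled <- enumerate_pairs(f3[c(3, 1, 2), ], r4[c(4, 2, 3, 1), ])
  expect_equal(scrambled, enumerate_pairs(f3, r4))
})

test_that("amplicon length categories partition at the stated edges", {
  expect_equal(length_category(c(300, 301, 600, 601)),
               c("100-300", "301-600", "301-600", ">600"))
  expect_equal(length_category(c(100, 99)), c("100-300", NA))
  expect_equal(length_category(300.4), "100-300")
  expect_equal(length_category(300.5), "301-600")  # rounds half away
})

test_that("pair coverage requires both primers on one variant with geometry", {
  f <- canonicalize_primer("FX_F001", "F", "ACGTACGTAC")
  r <- canonicalize_primer("FX_R001", "R", "GGCATGCATG")  # site CATGCATGCC
  f_site <- "ACGTACGTAC"
  r_site <- reverse_complement(r$sequence)
  spacer <- strrep("G", 20)
  both <- paste0(f_site, spacer, r_site)
  f_only <- paste0(f_site, spacer, strrep("A", 10))
  r_before_f <- paste0(r_site, spacer, f_site)
  db <- make_db(c(both, f_only, r_before_f),
                c("SP00001", "SP00002", "SP00003"))
  cv <- pair_coverage(f, r, db)
  expect_equal(cv$covered_species, "SP00001")
  expect_equal(cv$vc_percent, round_half_away(100 / 3))
  expect_equal(cv$n_species_not_covered, 2)

  nc <- not_covered_report(f, r, db)
  expect_equal(nc$species_id, c("SP00002", "SP00003"))
  expect_equal(nc$species_name, c("s_SP00002", "s_SP00003"))
})

test_that("pair coverage is bounded by its single primers on fixtures", {
  for (s in c(41, 42)) {
    fx <- generate_fixture(random_fixture_spec(s))
    tp <- fx$truth$primers
    for (k in seq_len(nrow(fx$truth$pairs))) {
      row <- fx$truth$pairs[k, ]
      f <- fx$primers[fx$primers$primer_id == row$forward_id, , drop = FALSE]
      r <- fx$primers[fx$primers$primer_id == row$reverse_id, , drop = FALSE]
      cv <- pair_coverage(f, r, fx$bacteria)
      expect_lte(cv$sc_percent,
                 min(tp$bacterial_sc[tp$primer_id == row$forward_id],
                     tp$bacterial_sc[tp$primer_id == row$reverse_id]))
      expect_lte(cv$vc_percent,
                 min(tp$bacterial_vc[tp$primer_id == row$forward_id],
                     tp$bacterial_vc[tp$primer_id == row$reverse_id]))
    }
  }
})

test_that("specificity classification follows the zero-SC rule", {
  res <- function(n_cov) {
    structure(list(n_species_covered = n_cov), class = "coverage_result")
  }
  expect_equal(classify_specificity(res(753), res(0)), "bacteria_specific")
  expect_equal(classify_specificity(res(0), res(186)), "archaea_specific")
  expect_equal(classify_specificity(res(10), res(2)), "non_specific")
  expect_equal(classify_specificity(res(0), res(0)), "dead")
})
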