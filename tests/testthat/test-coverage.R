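probe <- count_probe_primer()

test_that("VC and SC arithmetic on forced counts", {
  # 1 of 4 variants matched, all one species
  db <- make_count_db(1, 4)
  db <- primer_db(within(db$records, species_id <- rep("SP00001", 4)),
                  "bacteria")
  cv <- primer_coverage(probe, db)
  expect_equal(cv$vc_percent, 25.00)
  expect_equal(cv$sc_percent, 100.00)

  # nothing matched
  none <- primer_coverage(canonicalize_primer("OP_F901", "F", "TTTTTTTTTT"),
                          make_count_db(2, 4))
  expect_equal(none$vc_percent, 0)
  expect_equal(none$sc_percent, 0)
  expect_equal(none$n_species_not_covered, 4)

  # sp1: 2 variants (1 matched), sp2: 1 (0), sp3: 1 (0)
  site <- "ACGTACGTAC"
  db3 <- make_db(
    c(paste0("GGGG", site, "GGGG"), strrep("G", 18),
      strrep("C", 18), strrep("T", 18)),
    c("SP00001", "SP00001", "SP00002", "SP00003"))
  cv3 <- primer_coverage(probe, db3)
  expect_equal(cv3$vc_percent, 25.00)
  expect_equal(cv3$sc_percent, 33.33)
  expect_equal(cv3$covered_species, "SP00001")
  expect_equal(cv3$not_covered_species, c("SP00002", "SP00003"))

  expect_error(primer_coverage(probe, make_db(character(0), character(0))),
               "empty database")
})

test_that("SC is robust to end-truncated variants while VC is not", {
  site <- "ACGTACGTAC"
  full <- paste0(strrep("G", 30), site, strrep("G", 30))
  truncated <- paste0(strrep("-", 45), substring(full, 46))  # site clipped
  db <- make_db(c(full, truncated), c("SP00001", "SP00001"))
  cv <- primer_coverage(probe, db)
  expect_equal(cv$vc_percent, 50.00)
  expect_equal(cv$sc_percent, 100.00)
})

test_that("coverage invariants hold on random fixtures", {
  for (s in 1:3) {
    fx <- generate_fixture(random_fixture_spec(s + 300))
    for (i in seq_len(nrow(fx$primers))) {
      cv <- primer_coverage(fx$primers[i, , drop = FALSE], fx$bacteria)
      expect_equal(cv$n_species_covered + cv$n_species_not_covered,
                   fx$bacteria$n_species)
      expect_equal(cv$vc_percent == 0, cv$sc_percent == 0)
      if (cv$vc_percent == 100) expect_equal(cv$sc_percent, 100)
      expect_gte(cv$sc_fraction, cv$vc_fraction)  # species pool at least as covered
    }
  }
})

test_that("adding variants to a covered species cannot reduce SC", {
  site <- "ACGTACGTAC"
  base <- make_db(c(paste0("GG", site, "GG"), strrep("G", 14)),
                  c("SP00001", "SP00002"))
  sc0 <- primer_coverage(probe, base)$sc_fraction
  more <- primer_db(rbind(base$records, within(base$records[2, ], {
    variant_id <- "TS000099"
    species_id <- "SP00001"
  })), "bacteria")
  expect_gte(primer_coverage(probe, more)$sc_fraction, sc0)
  # a new unmatched species strictly decreases SC
  new_sp <- primer_db(rbind(base$records, within(base$records[2, ], {
    variant_id <- "TS000098"
    species_id <- "SP00003"
  })), "bacteria")
  expect_lt(primer_coverage(probe, new_sp)$sc_fraction, sc0)
})

test_that("percentages round half away from zero at two decimals", {
  expect_equal(round_half_away(97.9192), 97.92)
  expect_equal(round_half_away(0.005), 0.01)   # base round() would give 0
  expect_equal(round_half_away(-0.005), -0.01)
  expect_equal(round_half_away(33 + 1 / 3), 33.33)
  expect_equal(round_half_away(287.5, 0), 288)
})
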