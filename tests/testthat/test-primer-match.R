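test_that("primer canonicalization uppercases and maps U and inosine", {
  p <- canonicalize_primer("OP_F001", "F", "acgru")
  expect_equal(p$sequence, "ACGRT")
  expect_equal(p$direction, "forward")

  p <- canonicalize_primer("KP_F020", "F", "CAGCIGCCGCGGTAA")
  expect_equal(p$sequence, "CAGCNGCCGCGGTAA")

  expect_error(canonicalize_primer("OP_F002", "F", "ACGX"), "position 4")
})

test_that("reverse primers carry a sense-strand search sequence", {
  p <- canonicalize_primer("OP_R001", "R", "AYG")
  expect_equal(p$sequence, "AYG")
  expect_equal(p$search_sequence, "CRT")
})

test_that("sequence deduplication keeps the first-seen identifier", {
  primers <- rbind(
    canonicalize_primer("OP_F001", "F", "ACGTACGTAA"),
    canonicalize_primer("OP_F002", "F", "ACGTACGTCC"),
    canonicalize_primer("KP_F010", "F", "acgtacgtaa")  # same as OP_F001
  )
  dd <- dedup_primers(primers)
  expect_equal(dd$primers$primer_id, c("OP_F001", "OP_F002"))
  expect_equal(dd$duplicate_map, list(OP_F001 = "KP_F010"))

  all_distinct <- dedup_primers(primers[1:2, ])
  expect_equal(all_distinct$primers, primers[1:2, ])
  expect_length(all_distinct$duplicate_map, 0)
})

test_that("IUPAC base sets follow the standard code", {
  expect_equal(iupac_set("A"), "A")
  expect_equal(iupac_set("Y"), c("C", "T"))
  expect_equal(iupac_set("B"), c("C", "G", "T"))
  expect_error(iupac_set("X"), "IUPAC")
})

test_that("reverse complement is IUPAC-aware and involutive", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AYG"), "CRT")

  set.seed(42)
  for (i in 1:25) {
    x <- paste(sample(names(primercover:::IUPAC_SETS), 20, TRUE), collapse = "")
    expect_equal(reverse_complement(reverse_complement(x)), x)
    # per-letter oracle: the complement letter's base set must equal the
    # set of complemented bases
    letters_x <- strsplit(x, "")[[1]]
    letters_c <- rev(strsplit(reverse_complement(x), "")[[1]])
    for (j in seq_along(letters_x)) {
      expect_setequal(iupac_set(letters_c[j]),
                      chartr("ACGT", "TGCA",
                             iupac_set(letters_x[j])))
    }
  }
})

test_that("find_matches reports all overlapping zero-mismatch sites", {
  # brute-force scan: "AR" matches AA (1), AG (2) and AG (5) in AAGTAG
  p <- canonicalize_primer("OP_F001", "F", "AR")
  m <- find_matches(p, "AAGTAG")
  expect_equal(m$start, c(1L, 2L, 5L))
  expect_equal(m$end, c(2L, 3L, 6L))

  # overlapping occurrences are all reported
  p2 <- canonicalize_primer("OP_F002", "F", "AA")
  expect_equal(find_matches(p2, "AAAA")$start, 1:3)

  # gaps and ambiguous database letters never match
  p3 <- canonicalize_primer("OP_F003", "F", "ACGT")
  expect_equal(nrow(find_matches(p3, "AC-GT")), 0)
  p4 <- canonicalize_primer("OP_F004", "F", "NNNN")
  expect_equal(nrow(find_matches(p4, "ACNT")), 0)
  expect_equal(nrow(find_matches(p4, "ACGTT")), 2)
})

test_that("leading-gap padding offsets match coordinates into the frame", {
  p <- canonicalize_primer("OP_F001", "F", "ACGT")
  plain <- find_matches(p, "ACGTGACGT")
  for (k in c(1L, 7L, 40L)) {
    padded <- find_matches(p, paste0(strrep("-", k), "ACGTGACGT"))
    expect_equal(padded$start, plain$start + k)
    expect_equal(padded$end, plain$end + k)
  }
})

test_that("matching equals brute-force expansion on random inputs", {
  set.seed(7)
  for (i in 1:40) {
    plen <- sample(4:12, 1)
    primer_seq <- paste(sample(c("A", "C", "G", "T", "R", "Y", "N", "W"),
                               plen, TRUE, prob = c(rep(.2, 4), rep(.05, 4))),
                        collapse = "")
    dir <- sample(c("F", "R"), 1)
    p <- canonicalize_primer("FX_F001", dir, primer_seq)
    seq <- paste(sample(c("A", "C", "G", "T", "N", "-"), sample(50:500, 1),
                        TRUE, prob = c(rep(.24, 4), .02, .02)),
                 collapse = "")
    m <- find_matches(p, seq)
    # oracle: enumerate concrete expansions, compare every window
    expected <- oracle_match_positions_test(p, seq)
    expect_equal(m$start, expected)
    expect_equal(m$start, sort(unique(m$start)))  # sorted, no duplicates
    if (nrow(m)) expect_true(all(m$end - m$start + 1 == plen))
  }
})
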