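regions <- read_region_table()

test_that("mode tie-breaks resolve toward the mean, then the smaller value", {
  expect_equal(primercover:::mode_nearest_mean(c(5, 5, 7, 7, 9)), 7)  # mean 6.6
  expect_equal(primercover:::mode_nearest_mean(c(5, 5, 7, 7)), 5)     # mean 6
  expect_equal(primercover:::mode_nearest_mean(342), 342)
  expect_equal(primercover:::mode_nearest_mean(integer(0)), NA_integer_)
  # permutation invariance
  set.seed(9)
  vals <- sample(1:20, 60, TRUE)
  m <- primercover:::mode_nearest_mean(vals)
  for (i in 1:5) {
    expect_equal(primercover:::mode_nearest_mean(sample(vals)), m)
  }
})

test_that("position statistics summarize the full match population", {
  site <- "ACGTACGTAC"
  db <- make_db(
    c(paste0(strrep("G", 4), site, strrep("G", 6)),   # site at 5
      paste0(strrep("G", 4), site, strrep("G", 6)),
      paste0(strrep("G", 8), site, strrep("G", 2))),  # site at 9
    c("SP00001", "SP00002", "SP00003"))
  ps <- position_stats(count_probe_primer(), db)
  expect_equal(ps$n_observations, 3)
  expect_equal(ps$mean_first, mean(c(5, 5, 9)))
  expect_equal(ps$mode_first, 5)
  expect_equal(ps$mode_last, 14)
  expect_true(ps$mode_first <= ps$mode_last)

  empty <- position_stats(canonicalize_primer("OP_F902", "F", "TTTTTTTTTT"), db)
  expect_equal(empty$n_observations, 0)
  expect_true(is.na(empty$mode_first))
  expect_true(is.na(empty$mean_first))
})

test_that("region lookup is a total tiling of the reference", {
  expect_equal(assign_region(600, regions), "V4")
  expect_equal(assign_region(433, regions), "V3")   # interval start
  expect_equal(assign_region(432, regions), "C3")   # last base of previous
  expect_equal(assign_region(1600, regions), "beyond-reference")
  expect_error(assign_region(0, regions), ">= 1")
  # every frame position belongs to exactly one region
  pos <- seq_len(1542)
  hits <- vapply(regions$start, function(s) s, numeric(1))
  counts <- rowSums(outer(pos, seq_len(nrow(regions)), function(p, i) {
    regions$start[i] <= p & p <= regions$end[i]
  }))
  expect_true(all(counts == 1))
})

test_that("primers in conserved flanks take the amplicon-interior region", {
  # forward primer in C4 (498-575) is named by downstream V4
  expect_equal(primercover:::primer_region_number(520, "forward", regions), "4")
  # reverse primer in C4 is named by upstream V3
  expect_equal(primercover:::primer_region_number(520, "reverse", regions), "3")
  expect_equal(primercover:::primer_region_number(600, "forward", regions), "4")
  expect_equal(primercover:::primer_region_number(NA, "forward", regions),
               "undefined")
  expect_equal(primercover:::primer_region_number(1600, "reverse", regions),
               "undefined")
})

test_that("pair labels join, collapse and degrade as in published tables", {
  f3 <- data.frame(mode_first = 440)   # V3
  r4 <- data.frame(mode_last = 600)    # V4
  r3 <- data.frame(mode_last = 470)    # V3
  r_na <- data.frame(mode_last = NA_integer_)
  expect_equal(pair_region(f3, r4, regions), "3-4")
  expect_equal(pair_region(f3, r3, regions), "3")
  expect_equal(pair_region(f3, r_na, regions), "3-undefined")
})
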