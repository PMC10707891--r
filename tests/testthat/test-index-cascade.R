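test_that("index reproduces the candidate's per-bulk values", {
  expect_identical(compute_index(29, 29), 1)
  expect_identical(compute_index(2, 16), 0.125)
  expect_identical(round(compute_index(2, 16), 2), 0.12)
  expect_identical(compute_index(0, 10), 0)
  expect_true(is.na(compute_index(0, 0)))
  expect_error(compute_index(3, 0), "exceeds")
  expect_error(compute_index(-1, 5), "non-negative")
})

test_that("index is scale-free in depth", {
  set.seed(1)
  a <- rbinom(50, 20, 0.4)
  d <- rep(20L, 50)
  for (k in c(2L, 7L))
    expect_equal(compute_index(k * a, k * d), compute_index(a, d))
})

test_that("annotation computes both indices, preserves order, honours min_depth", {
  v <- toy_variants()
  idx <- annotate_index(v)
  expect_equal(idx$pos, v$pos)
  expect_equal(idx$wt_index, v$wt_alt / v$wt_total)
  expect_equal(idx$mut_index, v$mut_alt / v$mut_total)

  z <- variant_table("chr01", 9L, "C", "T", 0L, 0L, 5L, 5L)
  expect_true(is.na(annotate_index(z)$wt_index))
  expect_equal(annotate_index(z)$mut_index, 1)
  crit <- filter_criteria(min_depth = 10L)
  idx10 <- annotate_index(variant_table("chr01", 9L, "C", "T", 2L, 8L, 5L, 5L),
                          crit)
  expect_true(is.na(idx10$wt_index) && is.na(idx10$mut_index))

  expect_equal(nrow(annotate_index(toy_variants()[0, ])), 0L)
})

test_that("each stage implements its predicate", {
  mk <- function(wt_alt, wt_total, mut_alt, mut_total) {
    annotate_index(variant_table("c", 1L, "C", "T",
                                 wt_alt, wt_total, mut_alt, mut_total))
  }
  # stage 1: removed only when below the cutoff in both bulks
  expect_equal(nrow(stage_low_index(mk(1L, 10L, 2L, 15L))), 0L)  # .10/.13
  expect_equal(nrow(stage_low_index(mk(2L, 16L, 29L, 29L))), 1L)
  expect_equal(nrow(stage_low_index(mk(8L, 15L, 10L, 20L))), 1L) # .53/.50
  # undefined index disqualifies at stage 1
  expect_equal(nrow(stage_low_index(mk(0L, 0L, 29L, 29L))), 0L)
  expect_equal(nrow(stage_low_index(mk(2L, 16L, 0L, 0L))), 0L)
  # stage 2: exact fixation, no rounding tolerance
  expect_equal(nrow(stage_mut_fixed(mk(2L, 16L, 29L, 29L))), 1L)
  expect_equal(nrow(stage_mut_fixed(mk(2L, 16L, 19L, 20L))), 0L)
  expect_equal(nrow(stage_mut_fixed(mk(2L, 16L, 10L, 20L))), 0L)
  # stage 3: strict upper bound
  expect_equal(nrow(stage_wt_bounded(mk(2L, 16L, 29L, 29L))), 1L)
  expect_equal(nrow(stage_wt_bounded(mk(8L, 16L, 29L, 29L))), 0L)  # 0.5 exactly
  expect_equal(nrow(stage_wt_bounded(mk(10L, 15L, 29L, 29L))), 0L)
})

test_that("the cascade reproduces the hand-evaluated five-site funnel", {
  rep <- mutmap_filter(toy_variants())
  expect_equal(rep$stages$n_total, c(5L, 4L, 2L, 1L))
  expect_equal(funnel_text(rep), "5 -> 4 -> 2 -> 1")
  expect_equal(rep$survivors$pos, 100L)
  expect_equal(rep$stages$n_snp[1], 4L)
  expect_equal(rep$stages$n_indel[1], 1L)
  # same table through the file reader
  path <- system.file("extdata", "toy_variants.tsv", package = "mutmapr")
  expect_equal(funnel_text(mutmap_filter(read_variants(path))),
               "5 -> 4 -> 2 -> 1")
})

test_that("the candidate alone survives all stages; empty input yields zeros", {
  cand <- variant_table("chr01", 2771134L, "C", "T", 2L, 16L, 29L, 29L)
  rep <- mutmap_filter(cand)
  expect_equal(rep$stages$n_total, c(1L, 1L, 1L, 1L))
  expect_equal(rep$survivors$wt_index, 0.125)
  expect_equal(rep$survivors$mut_index, 1)

  rep0 <- mutmap_filter(toy_variants()[0, ])
  expect_equal(rep0$stages$n_total, c(0L, 0L, 0L, 0L))
  expect_equal(nrow(rep0$survivors), 0L)
})

test_that("cascade is monotone and matches a brute-force per-site oracle", {
  crit <- filter_criteria()
  for (seed in 1:5) {
    set.seed(seed)
    v <- random_variants(400)
    rep <- mutmap_filter(v, criteria = crit)
    expect_true(all(diff(rep$stages$n_total) <= 0))
    # independent single-pass predicate evaluation
    wt <- ifelse(v$wt_total >= 1, v$wt_alt / v$wt_total, NA)
    mut <- ifelse(v$mut_total >= 1, v$mut_alt / v$mut_total, NA)
    keep <- !is.na(wt) & !is.na(mut) &
      !(wt < 0.3 & mut < 0.3) & mut >= 1 & wt < 0.5
    expect_equal(paste(rep$survivors$chrom, rep$survivors$pos),
                 paste(v$chrom, v$pos)[keep])
  }
})

test_that("stages 2 and 3 commute on randomized tables", {
  crit <- filter_criteria()
  for (seed in 1:5) {
    set.seed(seed + 100)
    idx <- annotate_index(random_variants(300), crit)
    s1 <- stage_low_index(idx, crit)
    a <- stage_wt_bounded(stage_mut_fixed(s1, crit), crit)
    b <- stage_mut_fixed(stage_wt_bounded(s1, crit), crit)
    expect_identical(a, b)
  }
})

test_that("mutations fixed in both bulks are always rejected at the wt bound", {
  set.seed(9)
  n <- 30
  tot_wt <- rpois(n, 18) + 1L
  tot_mut <- rpois(n, 21) + 1L
  fixed <- variant_table("chr05", seq_len(n), "G", "A",
                         tot_wt, tot_wt, tot_mut, tot_mut)
  rep <- mutmap_filter(fixed)
  expect_equal(rep$stages$n_total, c(n, n, n, 0L))
})

test_that("filter report serializes to JSON with the funnel and survivors", {
  rep <- mutmap_filter(toy_variants())
  js <- jsonlite::fromJSON(report_json(rep))
  expect_equal(js$funnel, "5 -> 4 -> 2 -> 1")
  expect_equal(js$survivors$pos, 100L)
  expect_equal(js$criteria$wt_index_max, 0.5)
})
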