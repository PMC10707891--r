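test_that("Haldane map function matches its closed form and limits", {
  expect_identical(haldane_r(0), 0)
  expect_equal(haldane_r(50), 0.5 * (1 - exp(-1)), tolerance = 1e-12)
  expect_lt(abs(haldane_r(1e6) - 0.5), 1e-12)
  expect_true(all(diff(haldane_r(seq(0, 300, by = 10))) > 0))
  expect_error(haldane_r(-1), "non-negative")
})

test_that("config validation catches inconsistent setups", {
  expect_error(bsa_sim_config(causal = list(chrom = "chrX", pos = 5)),
               "not declared")
  expect_error(bsa_sim_config(causal = list(chrom = "chr01", pos = 1e9)),
               "outside")
  expect_error(bsa_sim_config(error_rate = 1.5), "rates")
  expect_error(bsa_sim_config(n_background = -1), "counts")
  expect_error(bsa_sim_config(n_progeny = 10), "bulk size")
  tiny <- data.frame(name = "c1", length_bp = 10L, length_cM = 1)
  expect_error(
    simulate_bsa(bsa_sim_config(chromosomes = tiny, n_background = 50L,
                                n_fixed = 0L,
                                causal = list(chrom = "c1", pos = 5L))),
    "genome too small")
})

test_that("site generation honours counts, spectrum and determinism", {
  cfg <- small_sim_config(transition_fraction = 1)
  set.seed(11); s1 <- generate_variants(cfg)
  set.seed(11); s2 <- generate_variants(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 46L)  # 40 het + 5 hom + causal
  expect_equal(sum(s1$is_causal), 1L)
  expect_equal(sum(s1$zygosity == "hom"), 5L)
  # forced transition spectrum: every pair is C>T or G>A
  pair <- paste0(s1$ref, ">", s1$alt)
  expect_true(all(pair %in% c("C>T", "G>A")))
  # genetic position proportional to physical position
  k <- match(s1$chrom, cfg$chromosomes$name)
  expect_equal(s1$cM, s1$pos / cfg$chromosomes$length_bp[k] *
                 cfg$chromosomes$length_cM[k])

  only_causal <- bsa_sim_config(n_background = 0L, n_fixed = 0L)
  set.seed(2)
  expect_equal(nrow(generate_variants(only_causal)), 1L)
})

test_that("unlinked background avoids the causal chromosome", {
  cfg <- small_sim_config(unlinked_background = TRUE)
  set.seed(3)
  s <- generate_variants(cfg)
  expect_false(any(s$chrom == "chr01" & !s$is_causal))
  expect_error(bsa_sim_config(
    chromosomes = rice_genome()[1, ], unlinked_background = TRUE,
    causal = list(chrom = "chr01", pos = 100L)), "two chromosomes")
})

test_that("selfing a heterozygote segregates 3:1 and transmits fixed sites", {
  cfg <- bsa_sim_config(n_background = 0L, n_fixed = 3L)
  set.seed(5)
  sites <- generate_variants(cfg)
  prog <- self_progeny(sites, 6000L)
  frac <- mean(prog$phenotype == "mutant")
  ci <- qnorm(0.995) * sqrt(0.25 * 0.75 / 6000)
  expect_lt(abs(frac - 0.25), ci)
  expect_true(all(prog$genotypes[, !sites$is_causal] == 2L))
  causal_g <- prog$genotypes[, sites$is_causal]
  expect_identical(prog$phenotype == "mutant", causal_g == 2L)
})

test_that("a marker at zero map distance co-segregates perfectly", {
  sites <- data.frame(
    chrom = "chr01", pos = c(1000L, 1001L), ref = "C", alt = "T",
    zygosity = "het", is_causal = c(TRUE, FALSE), cM = c(0.5, 0.5))
  set.seed(8)
  prog <- self_progeny(sites, 500L)
  expect_identical(prog$genotypes[, 1L], prog$genotypes[, 2L])
})

test_that("an unlinked marker is independent of phenotype", {
  sites <- data.frame(
    chrom = c("chr01", "chr02"), pos = 1000L, ref = "C", alt = "T",
    zygosity = "het", is_causal = c(TRUE, FALSE), cM = 4)
  set.seed(13)
  prog <- self_progeny(sites, 8000L)
  for (cls in c("wt", "mutant")) {
    g <- prog$genotypes[prog$phenotype == cls, 2L]
    ci <- qnorm(0.995) * sqrt(0.5 * 0.5 / (2 * length(g)))
    expect_lt(abs(mean(g) / 2 - 0.5), ci)
  }
})

test_that("bulk allele frequencies follow the recessive bulking logic", {
  cfg <- bsa_sim_config(n_background = 0L, n_fixed = 2L)
  set.seed(21)
  sites <- generate_variants(cfg)
  causal_col <- which(sites$is_causal)
  wt_means <- replicate(200, {
    prog <- self_progeny(sites, 200L)
    f <- build_bulks(prog, cfg$design)
    # mutant bulk is fixed at the causal site; fixed sites fixed in both
    stopifnot(f$mut_freq[causal_col] == 1,
              all(f$wt_freq[-causal_col] == 1),
              all(f$mut_freq[-causal_col] == 1))
    f$wt_freq[causal_col]
  })
  # wt-phenotype class is 1/3 AA + 2/3 Aa => mean allele frequency 1/3
  se <- sd(wt_means) / sqrt(length(wt_means))
  expect_lt(abs(mean(wt_means) - 1 / 3), qnorm(0.995) * se + 1e-12)
})

test_that("bulking fails with instructive error when progeny are scarce", {
  sites <- data.frame(chrom = "chr01", pos = 1000L, ref = "C", alt = "T",
                      zygosity = "het", is_causal = TRUE, cM = 4)
  set.seed(2)
  prog <- self_progeny(sites, 70L)
  expect_error(build_bulks(prog, bulk_design()), "increase n_progeny")
})

test_that("read sampling reproduces edge frequencies and the compound law", {
  set.seed(31)
  d <- rpois(500, 20)
  expect_true(all(sample_alt_depths(d, rep(1, 500)) == d))
  expect_true(all(sample_alt_depths(d, rep(0, 500)) == 0L))
  # f = 0.5, mean depth 20: mean index ~ 0.5 and variance matches
  # E[1/D | D >= 1] / 4 for the binomial-within-Poisson compound
  n <- 4000
  sites <- data.frame(chrom = "chr01", pos = seq_len(n), ref = "C",
                      alt = "T", zygosity = "het", is_causal = FALSE, cM = 1)
  v <- sample_depths(data.frame(wt_freq = 0.5, mut_freq = 0.5), sites,
                     bulk_design(mean_depth_wt = 20, mean_depth_mut = 20))
  idx <- compute_index(v$wt_alt, v$wt_total)
  expect_lt(abs(mean(idx, na.rm = TRUE) - 0.5), 0.01)
  dd <- v$wt_total[v$wt_total >= 1]
  expect_lt(abs(var(idx, na.rm = TRUE) - mean(0.25 / dd)), 0.002)
})

test_that("a full simulated experiment is seed-deterministic end to end", {
  cfg <- small_sim_config()
  ex1 <- simulate_bsa(cfg, seed = 99)
  ex2 <- simulate_bsa(cfg, seed = 99)
  expect_identical(ex1$variants, ex2$variants)
  expect_identical(ex1$truth, ex2$truth)
  expect_false(identical(ex1$variants, simulate_bsa(cfg, seed = 100)$variants))
  # byte-identical files from identical seeds
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_variants(ex1$variants, p1)
  write_variants(ex2$variants, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("with no background the cascade recovers exactly the causal site", {
  cfg <- bsa_sim_config(n_background = 0L, n_fixed = 0L)
  ex <- simulate_bsa(cfg, seed = 4)
  expect_equal(ex$variants$mut_alt, ex$variants$mut_total)  # index exactly 1
  rep <- mutmap_filter(ex$variants, cfg$design)
  expect_equal(nrow(rep$survivors), 1L)
  expect_equal(rep$survivors$pos, cfg$causal$pos)
})

test_that("truth JSON names the causal site", {
  ex <- simulate_bsa(small_sim_config(), seed = 17)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(ex, path, sites = TRUE)
  js <- jsonlite::fromJSON(readLines(path))
  expect_equal(js$causal$chrom, "chr01")
  expect_equal(js$causal$pos, 2771134L)
  expect_equal(nrow(js$sites), nrow(ex$variants))
})
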