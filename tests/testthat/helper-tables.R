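# Shared fixtures built in code.

# The five-site worked example: A survives, B fails mutant fixation,
# C fails the wild-type bound, D is removed as low-index noise, E (an
# indel) fails mutant fixation.
toy_variants <- function() {
  variant_table(
    chrom = c("chr01", "chr01", "chr02", "chr02", "chr03"),
    pos = c(100L, 200L, 300L, 400L, 500L),
    ref = c("C", "G", "C", "A", "CA"),
    alt = c("T", "A", "T", "C", "C"),
    wt_alt = c(3L, 3L, 10L, 2L, 8L), wt_total = 15L,
    mut_alt = c(20L, 19L, 20L, 2L, 10L), mut_total = 20L)
}

# Random valid variant table for property-style tests.
random_variants <- function(n) {
  total_wt <- rpois(n, 15)
  total_mut <- rpois(n, 15)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  indel <- runif(n) < 0.2
  ref[indel] <- paste0(ref[indel], sample(bases, sum(indel), replace = TRUE))
  variant_table(
    chrom = sample(sprintf("chr%02d", 1:3), n, replace = TRUE),
    pos = sample.int(1e6, n), ref = ref, alt = alt,
    wt_alt = rbinom(n, total_wt, runif(n)), wt_total = total_wt,
    mut_alt = rbinom(n, total_mut, runif(n)), mut_total = total_mut)
}

small_sim_config <- function(...) {
  bsa_sim_config(n_background = 40L, n_fixed = 5L, ...)
}
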