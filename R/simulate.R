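#' Haldane map function
#'
#' Converts a genetic map distance `d` (centimorgans) into a recombination
#' fraction assuming independent crossovers (no interference):
#' `r = (1 - exp(-2 d / 100)) / 2`. `r` is 0 at complete linkage and
#' approaches 0.5 as `d` grows (free recombination).
#'
#' @param d Map distance in cM (non-negative, vectorized).
#' @return Recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane_r(0)     # 0
#' haldane_r(50)    # (1 - exp(-1))/2 ~ 0.3161
#' @export
haldane_r <- function(d) {
  if (any(d < 0, na.rm = TRUE))
    stop("map distance must be non-negative", call. = FALSE)
  0.5 * (1 - exp(-2 * d / 100))
}

#' A rice-like reference genome layout
#'
#' Twelve chromosomes with physical lengths approximating the rice genome
#' (~373 Mb total) and a uniform genetic map of 4 cM/Mb (~1,500 cM total).
#'
#' @return Data frame with columns `name`, `length_bp`, `length_cM`.
#' @export
rice_genome <- function() {
  mb <- c(43.3, 35.9, 36.4, 35.5, 29.9, 31.2,
          29.7, 28.4, 23.0, 23.2, 29.0, 27.5)
  data.frame(name = sprintf("chr%02d", 1:12),
             length_bp = as.integer(mb * 1e6),
             length_cM = mb * 4,
             stringsAsFactors = FALSE)
}

#' Configuration of a bulked-segregant simulation
#'
#' Describes the forward-genetic experiment the simulator emulates: a plant
#' heterozygous for a single recessive causal mutation (and carrying a load
#' of background EMS-induced variants, some heterozygous, some already
#' fixed) is selfed; progeny are phenotyped, bulked by phenotype, and the
#' two bulks are sequenced. Defaults follow the study design: bulks of
#' 30 + 30 plants at mean depths 18.06x / 20.90x, a causal C>T site, a 90%
#' transition-biased EMS spectrum, 2,000 heterozygous plus 100 fixed
#' background variants, and no sequencing error or misphenotyping.
#'
#' @param chromosomes Data frame with columns `name`, `length_bp`,
#'   `length_cM` (default [rice_genome()]).
#' @param n_background Heterozygous background EMS variants in the parent.
#' @param n_fixed Background variants homozygous (fixed) in the parent.
#' @param transition_fraction Probability a background variant is a C>T or
#'   G>A transition (EMS bias, default 0.9).
#' @param causal List `(chrom, pos)` of the causal site (always C>T,
#'   heterozygous in the parent).
#' @param unlinked_background If `TRUE`, background variants are placed only
#'   on chromosomes other than the causal one, so every background site
#'   assorts independently of the phenotype (default `FALSE`: uniform
#'   genome-wide placement, which also produces causal-linked background).
#' @param design A [bulk_design()].
#' @param n_progeny Selfed progeny to simulate before bulking; must comfortably
#'   exceed `4 * n_mut` so a mutant bulk can always be drawn (default 240).
#' @param error_rate Per-read allele miscall probability (default 0).
#' @param misphenotyping_rate Probability a plant's phenotype label is
#'   flipped (default 0).
#' @param seed Default random seed used by [simulate_bsa()].
#' @return An object of class `bsa_sim_config`.
#' @export
bsa_sim_config <- function(chromosomes = rice_genome(),
                           n_background = 2000L, n_fixed = 100L,
                           transition_fraction = 0.9,
                           causal = list(chrom = "chr01", pos = 2771134L),
                           unlinked_background = FALSE,
                           design = bulk_design(), n_progeny = 240L,
                           error_rate = 0, misphenotyping_rate = 0,
                           seed = 1L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_bp", "length_cM") %in% names(chromosomes)),
            nrow(chromosomes) >= 1L, all(chromosomes$length_bp >= 1),
            all(chromosomes$length_cM > 0))
  n_background <- as.integer(n_background)
  n_fixed <- as.integer(n_fixed)
  n_progeny <- as.integer(n_progeny)
  if (n_background < 0L || n_fixed < 0L)
    stop("variant counts must be >= 0", call. = FALSE)
  if (n_progeny < design$n_wt + design$n_mut)
    stop("n_progeny must be at least the total bulk size", call. = FALSE)
  for (r in c(transition_fraction, error_rate, misphenotyping_rate))
    if (!is.numeric(r) || r < 0 || r > 1)
      stop("rates must lie in [0, 1]", call. = FALSE)
  ci <- match(causal$chrom, chromosomes$name)
  if (is.na(ci))
    stop("causal chromosome '", causal$chrom, "' is not declared",
         call. = FALSE)
  if (causal$pos < 1L || causal$pos > chromosomes$length_bp[ci])
    stop("causal position lies outside its chromosome", call. = FALSE)
  if (isTRUE(unlinked_background) && nrow(chromosomes) < 2L)
    stop("unlinked background needs at least two chromosomes", call. = FALSE)
  structure(list(chromosomes = chromosomes, n_background = n_background,
                 n_fixed = n_fixed, transition_fraction = transition_fraction,
                 causal = list(chrom = causal$chrom,
                               pos = as.integer(causal$pos)),
                 unlinked_background = isTRUE(unlinked_background),
                 design = design, n_progeny = n_progeny,
                 error_rate = error_rate,
                 misphenotyping_rate = misphenotyping_rate,
                 seed = as.integer(seed)),
            class = "bsa_sim_config")
}

#' @export
print.bsa_sim_config <- function(x, ...) {
  cat("Bulked-segregant simulation\n")
  cat(sprintf("  genome: %d chromosome(s), %.1f Mb / %.0f cM\n",
              nrow(x$chromosomes), sum(x$chromosomes$length_bp) / 1e6,
              sum(x$chromosomes$length_cM)))
  cat(sprintf("  causal site: %s:%d (C>T, recessive)\n",
              x$causal$chrom, x$causal$pos))
  cat(sprintf("  background: %d heterozygous + %d fixed (transition fraction %.2f)\n",
              x$n_background, x$n_fixed, x$transition_fraction))
  cat(sprintf("  progeny: %d selfed; error rate %g; misphenotyping %g\n",
              x$n_progeny, x$error_rate, x$misphenotyping_rate))
  print(x$design)
  invisible(x)
}

ems_alleles <- function(n, transition_fraction) {
  # EMS alkylates G, yielding mostly C>T / G>A transitions
  transition <- stats::runif(n) < transition_fraction
  ref <- character(n)
  alt <- character(n)
  tr <- sum(transition)
  if (tr > 0L) {
    pick <- sample(c(TRUE, FALSE), tr, replace = TRUE)
    ref[transition] <- ifelse(pick, "C", "G")
    alt[transition] <- ifelse(pick, "T", "A")
  }
  if (tr < n) {
    tv <- list(A = c("C", "T"), C = c("A", "G"),
               G = c("C", "T"), T = c("A", "G"))
    r <- sample(names(tv), n - tr, replace = TRUE)
    ref[!transition] <- r
    alt[!transition] <- vapply(tv[r], sample, character(1L), size = 1L)
  }
  list(ref = ref, alt = alt)
}

#' Draw the parent's variant sites
#'
#' Places `n_background` heterozygous and `n_fixed` homozygous EMS variants
#' uniformly at random on the genome (no collisions with each other or the
#' causal site), draws their alleles from the transition-biased EMS
#' spectrum, and assigns genetic positions proportional to physical
#' position within each chromosome. The causal site itself is always a
#' heterozygous C>T. Consumes the current RNG state; [simulate_bsa()] seeds
#' it.
#'
#' @param config A [bsa_sim_config()].
#' @return Data frame sorted by (chrom, pos) with columns `chrom`, `pos`,
#'   `ref`, `alt`, `zygosity` (`"het"`/`"hom"`), `cM`, `is_causal`.
#' @export
generate_variants <- function(config) {
  chr <- config$chromosomes
  full_chr <- chr
  if (config$unlinked_background)
    chr <- chr[chr$name != config$causal$chrom, , drop = FALSE]
  n_sites <- config$n_background + config$n_fixed
  total_bp <- sum(as.numeric(chr$length_bp))
  if (n_sites + 1 > total_bp)
    stop("genome too small for the requested variant count", call. = FALSE)
  offset <- c(0, cumsum(as.numeric(chr$length_bp)))
  ci <- match(config$causal$chrom, chr$name)
  causal_gpos <- if (is.na(ci)) -1 else offset[ci] + config$causal$pos
  gpos <- numeric(0)
  while (length(gpos) < n_sites) {
    cand <- ceiling(stats::runif(n_sites - length(gpos)) * total_bp)
    gpos <- unique(c(gpos, setdiff(cand, causal_gpos)))
  }
  chrom_i <- findInterval(gpos - 0.5, offset)
  pos <- as.integer(gpos - offset[chrom_i])
  al <- ems_alleles(n_sites, config$transition_fraction)
  zyg <- rep(c("het", "hom"), c(config$n_background, config$n_fixed))
  sites <- data.frame(chrom = c(chr$name[chrom_i], config$causal$chrom),
                      pos = c(pos, config$causal$pos),
                      ref = c(al$ref, "C"), alt = c(al$alt, "T"),
                      zygosity = c(zyg, "het"),
                      is_causal = c(rep(FALSE, n_sites), TRUE),
                      stringsAsFactors = FALSE)
  k <- match(sites$chrom, full_chr$name)
  sites$cM <- sites$pos / full_chr$length_bp[k] * full_chr$length_cM[k]
  sites[order(k, sites$pos), , drop = FALSE]
}

#' Self a heterozygous parent
#'
#' Produces selfed progeny genotypes at the parent's variant sites. Each
#' progeny receives two independent gametes; within a gamete, alleles at
#' heterozygous sites on a chromosome follow a linear Markov walk along
#' genetic positions with crossover probability `haldane_r(delta cM)`
#' between adjacent sites; chromosomes assort independently. Sites fixed in
#' the parent transmit the mutant allele always. The phenotype is mutant
#' iff the causal genotype is homozygous mutant (recessive), then flipped
#' with probability `misphenotyping_rate`.
#'
#' @param sites Site table from [generate_variants()].
#' @param n_progeny Number of selfed progeny.
#' @param misphenotyping_rate Probability of a phenotype-label flip.
#' @return List with `genotypes` (`n_progeny x n_sites` integer matrix of
#'   mutant-allele copies, 0/1/2), `phenotype` (`"wt"`/`"mutant"`) and
#'   `sites`.
#' @export
self_progeny <- function(sites, n_progeny, misphenotyping_rate = 0) {
  n_sites <- nrow(sites)
  n_gam <- 2L * n_progeny
  G <- matrix(2L, nrow = n_progeny, ncol = n_sites)
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch & sites$zygosity == "het")
    if (length(idx) == 0L) next
    idx <- idx[order(sites$cM[idx])]
    m <- length(idx)
    A <- matrix(0L, nrow = n_gam, ncol = m)
    A[, 1L] <- stats::rbinom(n_gam, 1L, 0.5)
    if (m > 1L) {
      r <- haldane_r(diff(sites$cM[idx]))
      X <- matrix(stats::rbinom(n_gam * (m - 1L), 1L, rep(r, each = n_gam)),
                  nrow = n_gam)
      for (j in 2:m) A[, j] <- (A[, j - 1L] + X[, j - 1L]) %% 2L
    }
    G[, idx] <- A[seq_len(n_progeny), , drop = FALSE] +
      A[n_progeny + seq_len(n_progeny), , drop = FALSE]
  }
  causal_col <- which(sites$is_causal)
  phenotype <- ifelse(G[, causal_col] == 2L, "mutant", "wt")
  if (misphenotyping_rate > 0) {
    flip <- stats::runif(n_progeny) < misphenotyping_rate
    phenotype[flip] <- ifelse(phenotype[flip] == "mutant", "wt", "mutant")
  }
  list(genotypes = G, phenotype = phenotype, sites = sites)
}

#' Pool progeny into phenotype bulks
#'
#' Selects `n_wt` wild-type-phenotype and `n_mut` mutant-phenotype plants
#' uniformly without replacement and pools their DNA in equal proportion,
#' so the bulk mutant-allele frequency at a site is the genotype sum over
#' selected plants divided by twice the bulk size.
#'
#' @param progeny Output of [self_progeny()].
#' @param design A [bulk_design()].
#' @return Data frame with per-site columns `wt_freq`, `mut_freq`.
#' @export
build_bulks <- function(progeny, design = bulk_design()) {
  wt_pool <- which(progeny$phenotype == "wt")
  mut_pool <- which(progeny$phenotype == "mutant")
  if (length(wt_pool) < design$n_wt || length(mut_pool) < design$n_mut)
    stop(sprintf(paste0("not enough progeny of each phenotype class ",
                        "(%d wt, %d mutant available; %d + %d needed): ",
                        "increase n_progeny"),
                 length(wt_pool), length(mut_pool),
                 design$n_wt, design$n_mut), call. = FALSE)
  wt_sel <- sample(wt_pool, design$n_wt)
  mut_sel <- sample(mut_pool, design$n_mut)
  data.frame(
    wt_freq = colSums(progeny$genotypes[wt_sel, , drop = FALSE]) /
      (2 * design$n_wt),
    mut_freq = colSums(progeny$genotypes[mut_sel, , drop = FALSE]) /
      (2 * design$n_mut))
}

#' Sample alternate-read counts for pooled sequencing
#'
#' Given a site's true mutant-allele frequency `freq` in a bulk and a total
#' read depth, draws the alternate-read count binomially with per-read
#' success probability `freq * (1 - error_rate) + (1 - freq) * error_rate`
#' (a symmetric miscall model: a true-alt read can be miscalled reference
#' and vice versa).
#'
#' @param total_depth Total reads per site (vectorized).
#' @param freq True mutant-allele frequency in the bulk, in `[0, 1]`.
#' @param error_rate Per-read miscall probability.
#' @return Integer vector of alternate-read counts.
#' @export
sample_alt_depths <- function(total_depth, freq, error_rate = 0) {
  stopifnot(all(freq >= 0 & freq <= 1),
            error_rate >= 0, error_rate <= 1)
  p <- freq * (1 - error_rate) + (1 - freq) * error_rate
  stats::rbinom(length(total_depth), total_depth, p)
}

#' Sample per-bulk read depths for all sites
#'
#' Total depth per site per bulk follows a Poisson law at the bulk's mean
#' depth; alternate counts come from [sample_alt_depths()]. Zero-depth
#' outcomes are kept — downstream they yield an undefined index.
#'
#' @param bulk_freqs Output of [build_bulks()].
#' @param sites Site table (supplies chrom/pos/alleles).
#' @param design A [bulk_design()].
#' @param error_rate Per-read miscall probability.
#' @return A [variant_table()].
#' @export
sample_depths <- function(bulk_freqs, sites, design = bulk_design(),
                          error_rate = 0) {
  n <- nrow(sites)
  wt_total <- stats::rpois(n, design$mean_depth_wt)
  mut_total <- stats::rpois(n, design$mean_depth_mut)
  variant_table(sites$chrom, sites$pos, sites$ref, sites$alt,
                wt_alt = sample_alt_depths(wt_total, bulk_freqs$wt_freq,
                                           error_rate),
                wt_total = wt_total,
                mut_alt = sample_alt_depths(mut_total, bulk_freqs$mut_freq,
                                            error_rate),
                mut_total = mut_total)
}

#' Simulate a complete bulked-segregant experiment
#'
#' Composes [generate_variants()], [self_progeny()], [build_bulks()] and
#' [sample_depths()] into one seeded, reproducible experiment: identical
#' config and seed give identical output.
#'
#' @param config A [bsa_sim_config()].
#' @param seed Random seed (defaults to `config$seed`).
#' @return An object of class `bsa_experiment`: a list with `variants`
#'   (a [variant_table()], writable via [write_variants()]) and `truth`
#'   (causal site plus the per-site zygosity, map position and realized
#'   bulk allele frequencies).
#' @examples
#' cfg <- bsa_sim_config(n_background = 50, n_fixed = 5)
#' ex <- simulate_bsa(cfg, seed = 7)
#' mutmap_filter(ex$variants, cfg$design)
#' @export
simulate_bsa <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "bsa_sim_config"))
  set.seed(seed)
  sites <- generate_variants(config)
  progeny <- self_progeny(sites, config$n_progeny,
                          config$misphenotyping_rate)
  freqs <- build_bulks(progeny, config$design)
  variants <- sample_depths(freqs, sites, config$design, config$error_rate)
  structure(list(variants = variants,
                 truth = list(causal = config$causal,
                              sites = cbind(sites, freqs)),
                 config = config, seed = as.integer(seed)),
            class = "bsa_experiment")
}

#' @export
print.bsa_experiment <- function(x, ...) {
  cat(sprintf("Simulated bulked-segregant experiment (seed %d)\n", x$seed))
  cat(sprintf("  %d variant sites; causal %s:%d\n", nrow(x$variants),
              x$truth$causal$chrom, x$truth$causal$pos))
  invisible(x)
}

#' Write the ground truth of a simulated experiment as JSON
#'
#' @param experiment A `bsa_experiment`.
#' @param path Output path.
#' @param sites Include the full per-site truth table (default `FALSE`:
#'   causal site only).
#' @return `path`, invisibly.
#' @export
write_truth <- function(experiment, path, sites = FALSE) {
  stopifnot(inherits(experiment, "bsa_experiment"))
  out <- list(causal = experiment$truth$causal, seed = experiment$seed)
  if (sites) out$sites <- experiment$truth$sites
  writeLines(jsonlite::toJSON(out, dataframe = "rows", auto_unbox = TRUE,
                              digits = NA, pretty = TRUE), path)
  invisible(path)
}
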