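---
title: "Isolating a recessive causal mutation by bulked-segregant index filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating a recessive causal mutation by bulked-segregant index filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutmapr)
```

## The genetic model

A recessive mutation `a` induced by EMS mutagenesis segregates in the
selfed progeny of a heterozygous (`Aa`) parent as 1 `AA` : 2 `Aa` : 1 `aa`,
so a quarter of progeny show the mutant phenotype — the 3:1 ratio that
`chisq_segregation()` tests with an uncorrected Pearson goodness-of-fit
statistic. The uncorrected convention matters: on counts of 102:30 the
statistic is 0.3636 without a continuity correction and about 0.25 with
one, and only the former matches how such tests are conventionally
reported for segregation data.

Sorting progeny by phenotype and sequencing the two pooled bulks turns
genotype frequencies into allele frequencies, estimated per site by the
SNP/Indel-index (alternate reads over total reads). Under the model:

* **causal site**: mutant bulk is all `aa`, index exactly 1; the wild-type
  bulk is 1/3 `AA` + 2/3 `Aa`, expected index 1/3, always below 0.5 in
  expectation;
* **heterozygous background variant, unlinked**: expected index 0.5 in
  both bulks;
* **variant fixed in the parent**: index ~1 in both bulks;
* **linked heterozygous variant**: indices drift from background values
  toward the causal pattern as map distance shrinks.

The three cascade stages of `mutmap_filter()` are per-site predicates on
the two indices: remove if below `low_index_cutoff` (0.3) in both bulks;
require the mutant-bulk index to reach `mut_index_required` (1, exact);
require the wild-type-bulk index strictly below `wt_index_max` (0.5).
Because stages two and three are pure per-site predicates their order is
immaterial; the package fixes the order only so survivor counts after
each stage — the filtering funnel — are well defined.

## Semantics chosen where the rules are underdetermined

* **"Index is 1" is exact.** With integer depths the index equals 1 iff
  every covering read carries the mutant allele, so no epsilon is applied.
  `mut_index_required` can be lowered to study relaxed variants of the
  criterion; the default keeps the exact rule.
* **"Below 0.5" is strict.** A wild-type bulk composed purely of
  heterozygotes has expected index exactly 0.5 and must be excludable.
* **Stage 1 is conjunctive**: a site is removed only when *both* bulks sit
  below the cutoff, the established reading in MutMap-style pipelines.
* **Undefined indices disqualify.** If a bulk has total depth below
  `min_depth` (default 1, i.e. zero coverage) the index is undefined
  there; such sites are removed at stage 1 because an uncovered mutant
  bulk cannot certify fixation. How uncovered sites were treated upstream
  of published pipelines is generally unstated; this rule is the
  conservative choice and is exposed via `min_depth`.
* **Multi-allelic records are split per ALT allele**, each split keeping
  the summed allelic depths as its denominator so the index denominator
  remains site coverage. Whether upstream callers split or drop such
  records varies; splitting loses no candidate.
* **Presentation rounding is two decimals** (0.125 prints as 0.12);
  comparisons always use unrounded values.

## What the simulator emulates

`simulate_bsa()` composes four steps, each exposed for testing:

1. `generate_variants()` places `n_background` heterozygous and `n_fixed`
   homozygous parent variants uniformly on the genome, with C>T / G>A
   transitions at probability `transition_fraction` (0.9, the EMS bias;
   the causal site is always C>T) and genetic positions linear in physical
   position.
2. `self_progeny()` forms each progeny from two independent gametes; along
   a chromosome, alleles at heterozygous sites follow a Markov walk with
   crossover probability `haldane_r(d)` — the Haldane map function
   `r = (1 − exp(−2d/100))/2`, i.e. independent crossovers without
   interference — between adjacent sites. Phenotype is recessive in the
   causal genotype, optionally mislabelled at `misphenotyping_rate`.
3. `build_bulks()` draws the two bulks by phenotype without replacement
   and pools plants in equal proportion, so a site's bulk allele frequency
   is the genotype sum over 2x bulk-size chromosomes.
4. `sample_depths()` draws each site's total depth Poisson at the bulk's
   mean and the alternate count binomially at
   `f(1 − e) + (1 − f)e`, where `e` is the per-read miscall rate.
   Zero-depth draws are kept deliberately: they exercise the
   undefined-index path.

Reads are thus sampled from the *bulk* allele frequency (infinite-template
pooling) rather than read-by-read from individual plants; plant-level
stochasticity enters through bulk composition. This matches
equal-proportion DNA pooling and keeps the depth model a clean
Poisson–binomial compound. The simulator starts at allele depths — no
FASTQ reads, mapping biases or caller error model — because that is where
the analysis itself starts; consequently passing tests validate the
genetics and the filter algebra, not robustness to alignment artefacts,
depth overdispersion, or reference bias in real data.

## Defaults and the conditions they encode

| Parameter | Default | Why |
|---|---|---|
| `n_wt`, `n_mut` | 30, 30 | the study's bulk sizes |
| `mean_depth_wt`, `mean_depth_mut` | 18.06x, 20.90x | the study's realized mean depths |
| `causal` | chr01:2,771,134, C>T | the study's candidate site, used as a realistic anchor |
| `n_background` | 2,000 | order-of-magnitude convention for an EMS line's heterozygous load; no genome-wide count is published for this line |
| `n_fixed` | 100 | small fixed load to exercise the both-bulks-fixed rejection path |
| `transition_fraction` | 0.9 | EMS alkylates G, biasing strongly toward C>T/G>A |
| `error_rate`, `misphenotyping_rate` | 0 | the criteria themselves neglect sequencing error; nonzero values let users probe the exact-1 criterion's fragility |
| `n_progeny` | 240 | at 3:1, 60 mutant progeny expected; a shortfall below 30 is a ~4e-6 event |
| genome | 12 chromosomes, ~373 Mb, 4 cM/Mb | rice-like layout with a uniform genetic map; a nonuniform map is out of scope |

`unlinked_background = TRUE` confines background variants to chromosomes
other than the causal one. This encodes the idealized condition in which
every background site assorts independently of the phenotype; with
genome-wide placement (the default) sites within a few cM of the causal
mutation co-segregate with it and legitimately survive the cascade, which
is the realistic behaviour but makes "a unique surviving candidate" a
property of mutation density near the locus rather than of the filter.

## Power evaluation

`power_eval()` runs seeded replicates (replicate `i` derives its seed
deterministically from the base seed, so results are independent of
execution order) and reports sensitivity, the median survivor count and
false positives split into fixed, linked (within `linked_window_cM`,
default 30) and unlinked classes — the three classes fail for different
reasons, so their rates respond to different design knobs. Under the
default design the median survivor count is 1 with sensitivity around
0.85–0.9; the dominant failure mode is a wild-type bulk whose realized
index at the causal site reaches 0.5 through binomial sampling at ~18x.
Two closed forms anchor the Monte-Carlo machinery in the tests: with no
background and deep sequencing, sensitivity approaches
`1 − (2/3)^30` (the chance the wild-type bulk is not all-heterozygous),
and at miscall rate `e` and depth `d` the exact-fixation criterion holds
with probability `(1 − e)^d` — which is why the exact-1 rule, innocuous
at 20x with clean data, collapses as depth grows under any nonzero error
rate. `power_sweep()` exposes exactly this trade-off over grids of depth,
bulk size and error rate, using common random numbers across grid points.

Problem sizes used in the shipped tests — 100 replicates at the full
default design for the unique-candidate property, thousands of progeny for
segregation checks, 4,000 draws for the error-model law — were chosen so
each Monte-Carlo check resolves its 99% interval comfortably.

## Pigment quantification

`pigment_content()` evaluates the ethanol/acetone-extract calibration
literally: `Chl a = (12.21 OD665 − 2.81 OD649) V/W`,
`Chl b = (20.13 OD649 − 5.03 OD665) V/W`,
`Caro = (1000 OD470 V/W − 3.27 Chl a − 104 Chl b)/198`, with the
chlorophyll values feeding the carotenoid term. The formulas' native
output scale is the calibration's concentration unit per gram fresh
weight; published tables in this area often report mg/g without stating
the conversion from the formula scale, so the function applies none and
the documentation says so rather than guessing a factor. Negative outputs
are returned as computed but flagged — they indicate absorbances outside
the calibration range. The chlorophyll pair is a 2x2 linear map of
(OD665, OD649), which the tests invert and round-trip to 1e-9.

## Known limitations

* Per-site filtering only: no sliding-window index curves or delta-index
  confidence envelopes of classical QTL-seq, and no variant-consequence
  annotation.
* The uniform genetic map and no-interference crossover model are
  idealizations; both bias linked-background survival rates somewhat.
* Real sequencing depth is overdispersed relative to Poisson and real
  pools deviate from equal proportion; both effects widen index noise and
  would lower the exact-fixation criterion's sensitivity relative to the
  simulator's estimate.
* Real-scale dataset figures (tens of thousands of genome-wide variants
  at ~18–21x) depend on raw reads and an upstream caller; they enter this
  package only as design defaults and documentation, not as computed
  results.
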