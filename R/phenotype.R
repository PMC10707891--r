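#' Chi-square test of a Mendelian segregation ratio
#'
#' Pearson goodness-of-fit test (no continuity correction) of observed
#' phenotype counts against an expected Mendelian ratio, by default 3:1
#' wild-type : mutant as produced by selfing a plant heterozygous for a
#' recessive mutation. Expected counts are the ratio applied to the
#' observed total; the statistic is the usual sum of (O - E)^2 / E on 1
#' degree of freedom.
#'
#' @param n_wt_phenotype Count of wild-type-phenotype plants.
#' @param n_mut_phenotype Count of mutant-phenotype plants.
#' @param ratio Expected `(wt, mut)` ratio, default `c(3, 1)`.
#' @return An object of class `htest` (statistic, df, p-value).
#' @examples
#' chisq_segregation(102, 30)   # X-squared = 0.36, p > 0.05: fits 3:1
#' chisq_segregation(99, 33)    # X-squared = 0 exactly
#' @export
chisq_segregation <- function(n_wt_phenotype, n_mut_phenotype,
                              ratio = c(3, 1)) {
  if (length(ratio) != 2L || any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratio must be two positive numbers", call. = FALSE)
  obs <- c(n_wt_phenotype, n_mut_phenotype)
  if (any(!is.finite(obs)) || any(obs < 0) || sum(obs) <= 0)
    stop("counts must be non-negative with a positive total", call. = FALSE)
  ht <- stats::chisq.test(obs, p = ratio / sum(ratio))
  ht$data.name <- sprintf("%g wild-type : %g mutant vs %g:%g",
                          obs[1L], obs[2L], ratio[1L], ratio[2L])
  ht$method <- "Chi-squared test of Mendelian segregation (no correction)"
  ht
}

#' Chlorophyll and carotenoid content from absorbance readings
#'
#' Evaluates the standard ethanol/acetone-extract calibration formulas from
#' absorbances at 665, 649 and 470 nm, an extract volume `V` and a fresh
#' weight `W`:
#'
#' * `Chl a = (12.21 * OD665 - 2.81 * OD649) * V / W`
#' * `Chl b = (20.13 * OD649 - 5.03 * OD665) * V / W`
#' * `Caro  = (1000 * OD470 * V / W - 3.27 * Chl a - 104 * Chl b) / 198`
#'
#' The formulas are evaluated literally, in this order (the chlorophylls
#' feed the carotenoid term), and their native output scale is the
#' calibration's concentration unit per gram fresh weight; no unit
#' conversion is applied. Negative outputs are returned as computed but
#' flagged with a warning — physically they indicate readings outside the
#' calibration range.
#'
#' @param od470,od649,od665 Absorbances (dimensionless, >= 0; vectorized).
#' @param volume Extract volume V in mL (> 0).
#' @param mass Fresh weight W in g (> 0).
#' @return Data frame with columns `chl_a`, `chl_b`, `carotenoid`.
#' @examples
#' pigment_content(od470 = 0.8, od649 = 0.25, od665 = 0.5,
#'                 volume = 10, mass = 0.1)
#' @export
pigment_content <- function(od470, od649, od665, volume, mass) {
  if (any(volume <= 0) || any(mass <= 0))
    stop("volume and mass must be positive", call. = FALSE)
  if (any(c(od470, od649, od665) < 0))
    stop("absorbances must be non-negative", call. = FALSE)
  vw <- volume / mass
  chl_a <- (12.21 * od665 - 2.81 * od649) * vw
  chl_b <- (20.13 * od649 - 5.03 * od665) * vw
  caro <- (1000 * od470 * vw - 3.27 * chl_a - 104 * chl_b) / 198
  out <- data.frame(chl_a = chl_a, chl_b = chl_b, carotenoid = caro)
  if (any(out < 0))
    warning("negative pigment content: absorbance readings lie outside ",
            "the calibration range", call. = FALSE)
  out
}
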