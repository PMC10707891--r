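#' Two-bulk experimental design
#'
#' Describes a MutMap+/QTL-seq style bulked-segregant design: two pools of
#' selfed progeny sorted by phenotype (wild-type-like vs mutant), each pooled
#' in equal DNA proportion and sequenced to a target mean depth. Defaults
#' correspond to bulks of 30 plants each sequenced at 18.06x (wild-type bulk)
#' and 20.90x (mutant bulk).
#'
#' @param n_wt Number of plants in the wild-type-phenotype bulk (>= 1).
#' @param n_mut Number of plants in the mutant-phenotype bulk (>= 1).
#' @param mean_depth_wt Expected sequencing depth of the wild-type bulk (> 0).
#' @param mean_depth_mut Expected sequencing depth of the mutant bulk (> 0).
#' @param wt_bulk_id,mut_bulk_id Sample labels used in VCF input/output.
#' @return An object of class `bulk_design`.
#' @examples
#' bulk_design()
#' bulk_design(n_wt = 20, n_mut = 20, mean_depth_wt = 30, mean_depth_mut = 30)
#' @export
bulk_design <- function(n_wt = 30L, n_mut = 30L,
                        mean_depth_wt = 18.06, mean_depth_mut = 20.90,
                        wt_bulk_id = "wt_bulk", mut_bulk_id = "mut_bulk") {
  n_wt <- as.integer(n_wt)
  n_mut <- as.integer(n_mut)
  if (is.na(n_wt) || n_wt < 1L || is.na(n_mut) || n_mut < 1L)
    stop("bulk sizes must be integers >= 1", call. = FALSE)
  if (!is.numeric(mean_depth_wt) || mean_depth_wt <= 0 ||
      !is.numeric(mean_depth_mut) || mean_depth_mut <= 0)
    stop("mean depths must be > 0", call. = FALSE)
  if (identical(wt_bulk_id, mut_bulk_id))
    stop("the two bulk ids must differ", call. = FALSE)
  structure(list(n_wt = n_wt, n_mut = n_mut,
                 mean_depth_wt = mean_depth_wt,
                 mean_depth_mut = mean_depth_mut,
                 wt_bulk_id = wt_bulk_id, mut_bulk_id = mut_bulk_id),
            class = "bulk_design")
}

#' @export
print.bulk_design <- function(x, ...) {
  cat("Bulked-segregant design\n")
  cat(sprintf("  wild-type bulk: %-10s n = %d, mean depth = %.2fx\n",
              x$wt_bulk_id, x$n_wt, x$mean_depth_wt))
  cat(sprintf("  mutant bulk:    %-10s n = %d, mean depth = %.2fx\n",
              x$mut_bulk_id, x$n_mut, x$mean_depth_mut))
  invisible(x)
}

#' Filtering-cascade thresholds
#'
#' The three criteria of the causal-mutation filtering cascade:
#'
#' 1. *Low-index removal*: drop sites whose index is below
#'    `low_index_cutoff` in **both** bulks (noise / homozygous reference);
#' 2. *Mutant-bulk fixation*: for an unambiguous recessive phenotype every
#'    plant in the mutant bulk is homozygous mutant, so the mutant-bulk index
#'    must reach `mut_index_required` (default 1, i.e. every covering read
#'    carries the mutant allele — an exact requirement, no tolerance);
#' 3. *Wild-type-bulk bound*: the wild-type-phenotype bulk mixes homozygous
#'    wild-type (index 0) and heterozygous (expected index 0.5) plants, so
#'    its index must be strictly below `wt_index_max`.
#'
#' `min_depth` sets the minimum total depth for an index to be defined at
#' all; sites with an undefined index in either bulk cannot certify the
#' criteria and are removed at stage 1.
#'
#' @param low_index_cutoff Stage-1 cutoff in `[0, 1]` (default 0.3).
#' @param mut_index_required Required mutant-bulk index in `(0, 1]`
#'   (default 1).
#' @param wt_index_max Strict upper bound for the wild-type-bulk index in
#'   `(0, 1]` (default 0.5).
#' @param min_depth Minimum total depth per bulk for a site to be evaluable
#'   (default 1).
#' @return An object of class `filter_criteria`.
#' @examples
#' filter_criteria()
#' filter_criteria(mut_index_required = 0.95)  # relaxed fixation criterion
#' @export
filter_criteria <- function(low_index_cutoff = 0.3, mut_index_required = 1,
                            wt_index_max = 0.5, min_depth = 1L) {
  if (!is.numeric(low_index_cutoff) || low_index_cutoff < 0 || low_index_cutoff > 1)
    stop("low_index_cutoff must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(mut_index_required) || mut_index_required <= 0 || mut_index_required > 1)
    stop("mut_index_required must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(wt_index_max) || wt_index_max <= 0 || wt_index_max > 1)
    stop("wt_index_max must lie in (0, 1]", call. = FALSE)
  min_depth <- as.integer(min_depth)
  if (is.na(min_depth) || min_depth < 1L)
    stop("min_depth must be an integer >= 1", call. = FALSE)
  structure(list(low_index_cutoff = low_index_cutoff,
                 mut_index_required = mut_index_required,
                 wt_index_max = wt_index_max,
                 min_depth = min_depth),
            class = "filter_criteria")
}

#' @export
print.filter_criteria <- function(x, ...) {
  cat("Filtering criteria\n")
  cat(sprintf("  stage 1: remove sites with index < %g in both bulks (min depth %d)\n",
              x$low_index_cutoff, x$min_depth))
  cat(sprintf("  stage 2: mutant-bulk index >= %g\n", x$mut_index_required))
  cat(sprintf("  stage 3: wild-type-bulk index < %g (strict)\n", x$wt_index_max))
  invisible(x)
}
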