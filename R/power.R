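sub_seed <- function(seed, i) {
  # deterministic per-replicate seed, kept within 32-bit integer range
  as.integer((as.numeric(seed) + 48271 * as.numeric(i)) %% 2147483647)
}

classify_survivors <- function(survivors, truth, linked_window_cM) {
  if (nrow(survivors) == 0L)
    return(list(causal = FALSE, fixed = 0L, linked = 0L, unlinked = 0L))
  key <- paste(survivors$chrom, survivors$pos)
  tt <- truth$sites
  m <- match(key, paste(tt$chrom, tt$pos))
  causal_row <- tt[tt$is_causal, ]
  is_causal <- tt$is_causal[m]
  fixed <- tt$zygosity[m] == "hom"
  linked <- !is_causal & !fixed & tt$chrom[m] == causal_row$chrom &
    abs(tt$cM[m] - causal_row$cM) <= linked_window_cM
  unlinked <- !is_causal & !fixed & !linked
  list(causal = any(is_causal), fixed = sum(fixed),
       linked = sum(linked), unlinked = sum(unlinked))
}

#' Monte-Carlo power evaluation of the filtering cascade
#'
#' Repeatedly simulates the bulked-segregant experiment and runs the
#' cascade, then summarizes its operating characteristics: sensitivity
#' (how often the causal site survives) and the false-positive load,
#' broken down by background class — `fixed` (homozygous in the parent,
#' index ~1 in both bulks), `linked` (heterozygous within
#' `linked_window_cM` of the causal site) and `unlinked`. Replicate `i`
#' uses a seed derived deterministically from `(seed, i)`, so results are
#' reproducible and independent of execution order.
#'
#' @param config A [bsa_sim_config()].
#' @param n_replicates Number of simulated experiments (>= 1).
#' @param criteria A [filter_criteria()].
#' @param seed Base seed for the replicate stream.
#' @param linked_window_cM Map window around the causal site within which a
#'   heterozygous background site counts as linked (default 30 cM).
#' @return An object of class `bsa_power`: `sensitivity`,
#'   `mean_false_positives` (total and per class), `median_survivors`,
#'   `stage_means`, plus the per-replicate table `replicates`.
#' @export
power_eval <- function(config, n_replicates = 100L,
                       criteria = filter_criteria(), seed = 1L,
                       linked_window_cM = 30) {
  stopifnot(inherits(config, "bsa_sim_config"), n_replicates >= 1L)
  rows <- vector("list", n_replicates)
  stage_mat <- matrix(0, nrow = n_replicates, ncol = 4L)
  for (i in seq_len(n_replicates)) {
    ex <- simulate_bsa(config, seed = sub_seed(seed, i))
    rep_i <- mutmap_filter(ex$variants, config$design, criteria)
    cl <- classify_survivors(rep_i$survivors, ex$truth, linked_window_cM)
    stage_mat[i, ] <- rep_i$stages$n_total
    rows[[i]] <- data.frame(replicate = i, causal_survives = cl$causal,
                            n_survivors = nrow(rep_i$survivors),
                            fp_fixed = cl$fixed, fp_linked = cl$linked,
                            fp_unlinked = cl$unlinked)
  }
  reps <- do.call(rbind, rows)
  structure(list(
    n_replicates = n_replicates,
    sensitivity = mean(reps$causal_survives),
    mean_false_positives = c(
      total = mean(reps$fp_fixed + reps$fp_linked + reps$fp_unlinked),
      fixed = mean(reps$fp_fixed), linked = mean(reps$fp_linked),
      unlinked = mean(reps$fp_unlinked)),
    median_survivors = as.integer(stats::median(reps$n_survivors)),
    stage_means = stats::setNames(colMeans(stage_mat),
                                  c("input", "low_index_removed",
                                    "mut_index_fixed", "wt_index_bounded")),
    replicates = reps, seed = as.integer(seed),
    linked_window_cM = linked_window_cM),
    class = "bsa_power")
}

#' @export
print.bsa_power <- function(x, ...) {
  cat(sprintf("Cascade power over %d simulated experiments (seed %d)\n",
              x$n_replicates, x$seed))
  cat(sprintf("  sensitivity (causal site survives): %.3f\n", x$sensitivity))
  cat(sprintf("  median survivor count: %d\n", x$median_survivors))
  fp <- x$mean_false_positives
  cat(sprintf("  mean false positives: %.3f (fixed %.3f, linked %.3f, unlinked %.3f)\n",
              fp["total"], fp["fixed"], fp["linked"], fp["unlinked"]))
  cat("  mean funnel:", paste(sprintf("%.1f", x$stage_means), collapse = " -> "),
      "\n")
  invisible(x)
}

#' Power sweep over design parameters
#'
#' Evaluates the cascade over a grid of mean depths, bulk sizes and error
#' rates. Each grid point reuses the same base seed, so replicate `i`
#' shares its random stream across grid points (common random numbers),
#' which makes paired comparisons along the grid low-noise.
#'
#' @param config Baseline [bsa_sim_config()].
#' @param mean_depths Mean depths applied to both bulks (default: keep the
#'   config's).
#' @param bulk_sizes Plants per bulk, applied to both bulks.
#' @param error_rates Per-read miscall rates.
#' @param n_replicates Replicates per grid point.
#' @param criteria A [filter_criteria()].
#' @param seed Base seed shared by all grid points.
#' @param linked_window_cM Passed to [power_eval()].
#' @return Data frame with one row per grid point: the varied parameters
#'   plus sensitivity, median survivors and mean false-positive counts.
#' @export
power_sweep <- function(config, mean_depths = NULL, bulk_sizes = NULL,
                        error_rates = NULL, n_replicates = 20L,
                        criteria = filter_criteria(), seed = 1L,
                        linked_window_cM = 30) {
  grid <- expand.grid(
    mean_depth = if (is.null(mean_depths))
      mean(c(config$design$mean_depth_wt, config$design$mean_depth_mut))
    else mean_depths,
    bulk_size = if (is.null(bulk_sizes)) config$design$n_wt else bulk_sizes,
    error_rate = if (is.null(error_rates)) config$error_rate else error_rates)
  if (nrow(grid) == 0L) stop("empty parameter grid", call. = FALSE)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$design <- bulk_design(
      n_wt = grid$bulk_size[g], n_mut = grid$bulk_size[g],
      mean_depth_wt = grid$mean_depth[g], mean_depth_mut = grid$mean_depth[g],
      wt_bulk_id = config$design$wt_bulk_id,
      mut_bulk_id = config$design$mut_bulk_id)
    cfg$error_rate <- grid$error_rate[g]
    if (cfg$n_progeny < 5L * grid$bulk_size[g])
      cfg$n_progeny <- 8L * as.integer(grid$bulk_size[g])
    pw <- power_eval(cfg, n_replicates, criteria, seed, linked_window_cM)
    out[[g]] <- cbind(grid[g, , drop = FALSE],
                      sensitivity = pw$sensitivity,
                      median_survivors = pw$median_survivors,
                      fp_total = pw$mean_false_positives[["total"]],
                      fp_fixed = pw$mean_false_positives[["fixed"]],
                      fp_linked = pw$mean_false_positives[["linked"]],
                      fp_unlinked = pw$mean_false_positives[["unlinked"]])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
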