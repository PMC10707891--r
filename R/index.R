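#' SNP/Indel-index from allele depths
#'
#' The SNP/Indel-index of a site in one bulk is the ratio between the number
#' of reads carrying the mutant (alternate) allele and the total number of
#' reads covering the site: `alt_depth / total_depth`. It estimates the
#' mutant-allele frequency in the pooled DNA: 1 when the bulk is fixed for
#' the mutant allele, 0 when fixed wild-type, about 0.5 for a heterozygous
#' pool. The ratio is returned at full floating precision; round only for
#' display (the conventional presentation uses two decimals).
#'
#' @param alt_depth Reads supporting the alternate allele (non-negative,
#'   `<= total_depth`).
#' @param total_depth Total reads covering the site.
#' @param min_depth Sites with `total_depth < min_depth` get an undefined
#'   index (`NA`). Default 1, i.e. only zero-coverage sites are undefined.
#' @return Numeric vector of indices in `[0, 1]`, `NA` where undefined.
#' @examples
#' compute_index(29, 29)          # 1: mutant bulk fixed for the mutation
#' compute_index(2, 16)           # 0.125, displayed as 0.12
#' compute_index(0, 10)           # 0
#' compute_index(0, 0)            # NA: no coverage, index undefined
#' @export
compute_index <- function(alt_depth, total_depth, min_depth = 1L) {
  if (length(alt_depth) != length(total_depth))
    stop("alt_depth and total_depth must have equal length", call. = FALSE)
  if (any(alt_depth < 0 | total_depth < 0, na.rm = TRUE))
    stop("depths must be non-negative", call. = FALSE)
  bad <- which(alt_depth > total_depth)
  if (length(bad))
    stop("alt_depth exceeds total_depth at position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  out <- rep(NA_real_, length(alt_depth))
  ok <- total_depth >= min_depth
  out[ok] <- alt_depth[ok] / total_depth[ok]
  out
}

#' Annotate a variant table with per-bulk indices
#'
#' Adds `wt_index` and `mut_index` columns (the SNP/Indel-index in the
#' wild-type and mutant bulk). Row order is preserved; indices are `NA`
#' where the bulk's total depth is below `criteria$min_depth`.
#'
#' @param variants A [variant_table()].
#' @param criteria A [filter_criteria()] (supplies `min_depth`).
#' @return The table with two extra numeric columns.
#' @export
annotate_index <- function(variants, criteria = filter_criteria()) {
  v <- as_variant_table(variants)
  v$wt_index <- compute_index(v$wt_alt, v$wt_total, criteria$min_depth)
  v$mut_index <- compute_index(v$mut_alt, v$mut_total, criteria$min_depth)
  v
}

needs_index <- function(v) {
  if (!all(c("wt_index", "mut_index") %in% names(v)))
    stop("variants must be annotated with annotate_index() first",
         call. = FALSE)
  v
}

#' Cascade stage 1: low-index removal
#'
#' Removes a site iff its index is below `low_index_cutoff` in **both**
#' bulks (conjunctive reading: such sites are uninformative noise or
#' residual reference calls). Sites with an undefined index in either bulk
#' are also removed here: an uncovered bulk can certify neither downstream
#' criterion.
#'
#' @param indexed Output of [annotate_index()].
#' @param criteria A [filter_criteria()].
#' @return The surviving subset, order preserved.
#' @export
stage_low_index <- function(indexed, criteria = filter_criteria()) {
  v <- needs_index(indexed)
  undef <- is.na(v$wt_index) | is.na(v$mut_index)
  both_low <- !undef &
    v$wt_index < criteria$low_index_cutoff &
    v$mut_index < criteria$low_index_cutoff
  v[!(undef | both_low), , drop = FALSE]
}

#' Cascade stage 2: mutant-bulk fixation
#'
#' Keeps a site iff its mutant-bulk index is defined and at least
#' `mut_index_required`. With the default of 1 this demands
#' `alt_depth == total_depth` exactly — every read covering the site in the
#' mutant bulk carries the mutant allele, as expected for a recessive causal
#' site in a bulk of phenotypically mutant (hence homozygous) plants.
#'
#' @inheritParams stage_low_index
#' @return The surviving subset, order preserved.
#' @export
stage_mut_fixed <- function(indexed, criteria = filter_criteria()) {
  v <- needs_index(indexed)
  v[!is.na(v$mut_index) & v$mut_index >= criteria$mut_index_required, ,
    drop = FALSE]
}

#' Cascade stage 3: wild-type-bulk bound
#'
#' Keeps a site iff its wild-type-bulk index is defined and **strictly**
#' below `wt_index_max`. The wild-type-phenotype bulk is a mix of homozygous
#' wild-type (index 0) and heterozygous (expected index 0.5) plants, so a
#' trait-linked site must sit below 0.5; mutations fixed in the parent show
#' index ~1 in both bulks and are rejected here.
#'
#' @inheritParams stage_low_index
#' @return The surviving subset, order preserved.
#' @export
stage_wt_bounded <- function(indexed, criteria = filter_criteria()) {
  v <- needs_index(indexed)
  v[!is.na(v$wt_index) & v$wt_index < criteria$wt_index_max, , drop = FALSE]
}

#' Run the causal-mutation filtering cascade
#'
#' Annotates every site with its per-bulk SNP/Indel-index and applies the
#' three filtering stages in order — low-index removal, mutant-bulk
#' fixation, wild-type-bulk bound (see [filter_criteria()]). The result
#' records the survivor count after every stage (the filtering "funnel"),
#' separately for SNPs and indels, plus the surviving sites themselves.
#'
#' @param variants A [variant_table()] (or coercible data frame).
#' @param design A [bulk_design()] (kept for reporting and VCF output).
#' @param criteria A [filter_criteria()].
#' @return An object of class `mutmap_filter` with components `stages`
#'   (data frame: stage name, SNP / indel / total survivor counts),
#'   `survivors` (annotated [variant_table()]), `design`, `criteria`.
#' @examples
#' v <- variant_table(
#'   chrom = "chr01", pos = c(100, 200, 300, 400, 500),
#'   ref = "C", alt = "T",
#'   wt_alt = c(3, 3, 10, 2, 8), wt_total = 15,
#'   mut_alt = c(20, 19, 20, 2, 10), mut_total = 20)
#' mutmap_filter(v)   # funnel 5 -> 4 -> 2 -> 1
#' @export
mutmap_filter <- function(variants, design = bulk_design(),
                          criteria = filter_criteria()) {
  v <- annotate_index(as_variant_table(variants), criteria)
  s1 <- stage_low_index(v, criteria)
  s2 <- stage_mut_fixed(s1, criteria)
  s3 <- stage_wt_bounded(s2, criteria)
  count <- function(x) c(sum(x$vclass == "SNP"), sum(x$vclass == "INDEL"))
  m <- vapply(list(v, s1, s2, s3), count, integer(2L))
  stages <- data.frame(
    stage = c("input", "low_index_removed", "mut_index_fixed",
              "wt_index_bounded"),
    n_snp = m[1L, ], n_indel = m[2L, ], n_total = colSums(m),
    stringsAsFactors = FALSE)
  structure(list(stages = stages, survivors = s3,
                 design = design, criteria = criteria),
            class = "mutmap_filter")
}

#' Funnel text for a filtering report
#'
#' @param x A `mutmap_filter` object.
#' @return A single string such as `"5 -> 4 -> 2 -> 1"`.
#' @export
funnel_text <- function(x) {
  stopifnot(inherits(x, "mutmap_filter"))
  paste(x$stages$n_total, collapse = " -> ")
}

#' @export
print.mutmap_filter <- function(x, ...) {
  cat("MutMap+ filtering cascade\n")
  cat("  funnel (all sites):", funnel_text(x), "\n")
  cat(sprintf("  input: %d SNPs, %d indels\n",
              x$stages$n_snp[1L], x$stages$n_indel[1L]))
  st <- x$stages
  for (i in 2:nrow(st))
    cat(sprintf("  after %-18s %6d (%d SNPs, %d indels)\n",
                paste0(st$stage[i], ":"), st$n_total[i],
                st$n_snp[i], st$n_indel[i]))
  n <- nrow(x$survivors)
  if (n > 0L && n <= 10L) {
    cat("  survivors:\n")
    s <- x$survivors
    for (i in seq_len(n))
      cat(sprintf("    %s:%d %s>%s  wt-index %.2f  mut-index %.2f  [%s]\n",
                  s$chrom[i], s$pos[i], s$ref[i], s$alt[i],
                  s$wt_index[i], s$mut_index[i], s$vclass[i]))
  } else {
    cat("  survivors:", n, "sites\n")
  }
  invisible(x)
}

#' @export
summary.mutmap_filter <- function(object, ...) {
  print(object$criteria)
  print(object$design)
  print(object)
  invisible(object)
}

#' Funnel bar plot of a filtering report
#'
#' @param x A `mutmap_filter` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.mutmap_filter <- function(x, ...) {
  graphics::barplot(x$stages$n_total, names.arg = x$stages$stage,
                    ylab = "surviving sites", las = 2,
                    main = "Filtering funnel", ...)
  invisible(x)
}

#' Serialize a filtering report to JSON
#'
#' @param x A `mutmap_filter` object.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "mutmap_filter"))
  out <- list(stages = x$stages,
              funnel = funnel_text(x),
              criteria = unclass(x$criteria),
              survivors = as.data.frame(x$survivors))
  js <- jsonlite::toJSON(out, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
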