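#' Build a validated variant table
#'
#' A variant table is a data frame with one row per bi-allelic variant site
#' and the per-bulk allele depths needed for SNP/Indel-index computation:
#' columns `chrom`, `pos` (1-based), `ref`, `alt`, `vclass` (`"SNP"` or
#' `"INDEL"`), `wt_alt`, `wt_total`, `mut_alt`, `mut_total`. `*_alt` counts
#' reads supporting the mutant (ALT) allele; `*_total` counts all reads
#' covering the site in that bulk. The variant class is derived from the
#' alleles: a SNP iff both alleles have length 1.
#'
#' @param chrom Chromosome identifiers (character).
#' @param pos 1-based positions (positive integers).
#' @param ref,alt Reference and alternate alleles (non-empty uppercase DNA
#'   strings, `alt != ref`).
#' @param wt_alt,wt_total Alternate-allele and total read depth in the
#'   wild-type-phenotype bulk.
#' @param mut_alt,mut_total Alternate-allele and total read depth in the
#'   mutant bulk.
#' @return A `data.frame` of class `variant_table`.
#' @examples
#' variant_table("chr01", 2771134, "C", "T", 2, 16, 29, 29)
#' @export
variant_table <- function(chrom, pos, ref, alt,
                          wt_alt, wt_total, mut_alt, mut_total) {
  v <- data.frame(chrom = as.character(chrom),
                  pos = as.integer(pos),
                  ref = as.character(ref),
                  alt = as.character(alt),
                  wt_alt = as.integer(wt_alt),
                  wt_total = as.integer(wt_total),
                  mut_alt = as.integer(mut_alt),
                  mut_total = as.integer(mut_total),
                  stringsAsFactors = FALSE)
  v$vclass <- classify_variant(v$ref, v$alt)
  validate_variant_table(v)
}

#' Classify alleles as SNP or INDEL
#'
#' A pure function of allele lengths: `"SNP"` iff both the reference and
#' the alternate allele have length 1, `"INDEL"` otherwise.
#'
#' @param ref,alt Allele strings.
#' @return Character vector of `"SNP"` / `"INDEL"`.
#' @examples
#' classify_variant("C", "T")    # SNP
#' classify_variant("AT", "A")   # INDEL
#' @export
classify_variant <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "INDEL")
}

validate_variant_table <- function(v) {
  fail <- function(rows, what) {
    stop(sprintf("invalid variant table: %s at row(s) %s", what,
                 paste(utils::head(rows, 5L), collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(v) > 0L) {
    bad <- which(is.na(v$pos) | v$pos < 1L)
    if (length(bad)) fail(bad, "position must be a positive integer")
    bad <- which(!grepl("^[ACGT]+$", v$ref) | !grepl("^[ACGT]+$", v$alt))
    if (length(bad)) fail(bad, "alleles must be non-empty uppercase DNA strings")
    bad <- which(v$ref == v$alt)
    if (length(bad)) fail(bad, "alt allele equals ref allele")
    dep <- cbind(v$wt_alt, v$wt_total, v$mut_alt, v$mut_total)
    bad <- which(apply(is.na(dep) | dep < 0L, 1L, any))
    if (length(bad)) fail(bad, "depths must be non-negative integers")
    bad <- which(v$wt_alt > v$wt_total | v$mut_alt > v$mut_total)
    if (length(bad)) fail(bad, "alt_depth exceeds total_depth")
  }
  v$vclass <- classify_variant(v$ref, v$alt)
  class(v) <- unique(c("variant_table", class(v)))
  v
}

#' Coerce to a variant table
#'
#' @param x A `variant_table` or a data frame with the eight required columns.
#' @return A validated `variant_table`.
#' @export
as_variant_table <- function(x) {
  need <- c("chrom", "pos", "ref", "alt",
            "wt_alt", "wt_total", "mut_alt", "mut_total")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("expected a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  validate_variant_table(as.data.frame(x)[, union(need, names(x))])
}

empty_variant_table <- function() {
  variant_table(character(0), integer(0), character(0), character(0),
                integer(0), integer(0), integer(0), integer(0))
}
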