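#' Read a variant table from VCF or TSV
#'
#' Reads the minimal variant representation the pipeline works on: site,
#' alleles and per-bulk allele depths. Two dialects are supported:
#'
#' * **VCF** (4.x): the file must contain exactly the two bulk sample columns
#'   named in `design` and a `FORMAT` field `AD` (allelic depths). The
#'   alternate-allele depth is taken from the AD entry of the ALT allele and
#'   the total depth is the sum of all AD entries (site coverage).
#'   Multi-allelic records are split into one row per ALT allele; every split
#'   row inherits the summed AD total.
#' * **TSV**: a tab-separated table with a `#`-prefixed header line and
#'   columns `chrom`, `pos`, `ref`, `alt`, `wt_alt`, `wt_total`, `mut_alt`,
#'   `mut_total`.
#'
#' Both dialects use 1-based point coordinates, so positions agree across
#' formats. Input row order is preserved.
#'
#' @param path Path to an existing file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @param design A [bulk_design()]; its `wt_bulk_id`/`mut_bulk_id` name the
#'   VCF sample columns.
#' @return A [variant_table()].
#' @seealso [write_variants()]
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          design = bulk_design()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  switch(format, vcf = read_variants_vcf(path, design),
         tsv = read_variants_tsv(path))
}

read_variants_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty TSV file: ", path, call. = FALSE)
  if (!startsWith(lines[[1L]], "#"))
    stop("TSV header line must be '#'-prefixed: ", path, call. = FALSE)
  header <- strsplit(sub("^#", "", lines[[1L]]), "\t", fixed = TRUE)[[1L]]
  need <- c("chrom", "pos", "ref", "alt",
            "wt_alt", "wt_total", "mut_alt", "mut_total")
  if (!all(need %in% header))
    stop("TSV is missing column(s): ",
         paste(setdiff(need, header), collapse = ", "), call. = FALSE)
  if (length(lines) == 1L) return(empty_variant_table())
  df <- utils::read.table(text = lines[-1L], sep = "\t",
                          col.names = header, stringsAsFactors = FALSE,
                          colClasses = "character")
  variant_table(df$chrom, as.integer(df$pos), df$ref, df$alt,
                as.integer(df$wt_alt), as.integer(df$wt_total),
                as.integer(df$mut_alt), as.integer(df$mut_total))
}

read_variants_vcf <- function(path, design) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  if (nrow(fix) == 0L) return(empty_variant_table())
  samples <- colnames(gt)[-1L]
  for (id in c(design$wt_bulk_id, design$mut_bulk_id))
    if (!id %in% samples)
      stop(sprintf("sample '%s' not found in VCF (has: %s)", id,
                   paste(samples, collapse = ", ")), call. = FALSE)
  fmt <- strsplit(gt[, "FORMAT"], ":", fixed = TRUE)
  ad_pos <- vapply(fmt, function(f) match("AD", f), integer(1L))
  if (anyNA(ad_pos))
    stop("VCF FORMAT lacks the AD field at row(s) ",
         paste(utils::head(which(is.na(ad_pos)), 5L), collapse = ", "),
         call. = FALSE)
  parse_ad <- function(cell, k) {
    as.integer(strsplit(strsplit(cell, ":", fixed = TRUE)[[1L]][k],
                        ",", fixed = TRUE)[[1L]])
  }
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    ad_wt <- parse_ad(gt[i, design$wt_bulk_id], ad_pos[i])
    ad_mut <- parse_ad(gt[i, design$mut_bulk_id], ad_pos[i])
    if (length(ad_wt) != length(alts) + 1L || length(ad_mut) != length(alts) + 1L)
      stop("AD entry count does not match allele count at VCF row ", i,
           call. = FALSE)
    # each split allele keeps the site's total coverage as its denominator
    rows[[i]] <- data.frame(chrom = unname(fix[i, "CHROM"]),
                            pos = as.integer(fix[i, "POS"]),
                            ref = unname(fix[i, "REF"]), alt = unname(alts),
                            wt_alt = ad_wt[-1L], wt_total = sum(ad_wt),
                            mut_alt = ad_mut[-1L], mut_total = sum(ad_mut),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  v <- do.call(rbind, rows)
  rownames(v) <- NULL
  validate_variant_table(v)
}

#' Write a variant table as VCF or TSV
#'
#' Writing then reading back reproduces every field of the table
#' (round-trip stability). The VCF output is a minimal VCF 4.2 with a
#' `FORMAT` field `AD` carrying `ref_depth,alt_depth` for each of the two
#' bulk samples, where `ref_depth = total - alt`.
#'
#' @param variants A [variant_table()] (or coercible data frame).
#' @param path Output path.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @param design A [bulk_design()] supplying the VCF sample names.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, format = c("auto", "vcf", "tsv"),
                           design = bulk_design()) {
  v <- as_variant_table(variants)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing", call. = FALSE))
  on.exit(close(con))
  if (format == "tsv") {
    cols <- c("chrom", "pos", "ref", "alt",
              "wt_alt", "wt_total", "mut_alt", "mut_total")
    writeLines(paste0("#", paste(cols, collapse = "\t")), con)
    if (nrow(v) > 0L)
      utils::write.table(v[, cols], con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=bsa-mutfind",
                 paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                        "Description=\"Allelic depths for the ref and alt alleles\">"),
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", design$wt_bulk_id,
                         design$mut_bulk_id), collapse = "\t")), con)
    if (nrow(v) > 0L) {
      ad <- function(alt, total) paste0(total - alt, ",", alt)
      writeLines(paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", ".", ".", "AD",
                       ad(v$wt_alt, v$wt_total), ad(v$mut_alt, v$mut_total),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}
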