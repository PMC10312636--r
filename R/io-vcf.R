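#' Read single-nucleotide variants from a VCF file
#'
#' Multi-allelic records are split into one record per ALT allele before
#' the SNV filter; records that are not single-nucleotide substitutions
#' (or have malformed POS/REF/ALT) are skipped with a warning and counted.
#' `POS` is converted to the internal 0-based convention; the `PS` FORMAT
#' tag of the first sample, when present, becomes the phase set.
#'
#' @param path VCF 4.x file.
#' @param caller Provenance label stored on each record.
#' @return List of [variant_record()]; attribute `n_skipped` counts
#'   skipped records.
#' @export
read_vcf <- function(path, caller = "unknown") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    ref <- unname(fix[i, "REF"])
    alts <- unname(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    if (is.na(pos) || is.na(ref) || length(alts) == 0L) {
      warning("skipping malformed VCF record #", i)
      skipped <- skipped + 1L
      next
    }
    ps <- NA_character_; geno <- NA_character_
    if (!is.null(gt) && ncol(gt) >= 2L) {
      fmt <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
      smp <- strsplit(gt[i, 2], ":", fixed = TRUE)[[1]]
      gi <- match("GT", fmt); pi <- match("PS", fmt)
      if (!is.na(gi) && gi <= length(smp)) geno <- smp[gi]
      if (!is.na(pi) && pi <= length(smp)) ps <- smp[pi]
    }
    for (alt in alts) {
      if (nchar(ref) != 1L || nchar(alt) != 1L ||
          !ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T") ||
          ref == alt) {
        warning("skipping non-SNV record at ", fix[i, "CHROM"], ":", pos)
        skipped <- skipped + 1L
        next
      }
      out[[length(out) + 1L]] <- variant_record(
        unname(fix[i, "CHROM"]), pos - 1L, ref, alt, unname(qual),
        phase_set = unname(ps), genotype = unname(geno), caller = caller)
    }
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Write variant records to a VCF 4.2 file
#'
#' Plain-text writer supporting the package's custom `ISO` INFO key (the
#' comma-separated isoform names carrying each variant) and the `PS`
#' phase-set FORMAT tag.
#'
#' @param records List of `variant_record`.
#' @param path Output path.
#' @param iso Optional list (parallel to `records`) of character vectors
#'   of isoform names.
#' @param sample Sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, iso = NULL, sample = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=ISO,Number=.,Type=String,Description=\"Isoforms carrying this variant\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  body <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    info <- "."
    if (!is.null(iso) && length(iso[[i]]) > 0L)
      info <- paste0("ISO=", paste(iso[[i]], collapse = ","))
    geno <- if (is.na(r$genotype)) "./." else r$genotype
    if (!is.na(r$phase_set)) {
      fmt <- "GT:PS"; smp <- paste0(geno, ":", r$phase_set)
    } else {
      fmt <- "GT"; smp <- geno
    }
    paste(r$chrom, r$pos0 + 1L, ".", r$ref_allele, r$alt_allele,
          if (is.na(r$qual)) "." else format(r$qual), ".", info, fmt, smp,
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
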