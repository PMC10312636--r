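#' Read isoform models from a BED12 file
#'
#' BED12 is the package's native isoform interchange format; the `name`
#' column encodes `<transcript_id>_<gene_id>` (gene id after the last
#' underscore). Round-trips losslessly with [write_bed12()].
#'
#' @param path BED12 file.
#' @param source Source label to give the models.
#' @return List of [transcript_model()].
#' @export
read_bed12 <- function(path, source = "annotated") {
  if (length(readLines(path, warn = FALSE)) == 0L) return(list())
  gr <- rtracklayer::import(path, format = "bed")
  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    nm <- gr$name[i]
    us <- gregexpr("_", nm, fixed = TRUE)[[1]]
    if (identical(as.integer(us), -1L)) {
      tid <- nm; gid <- nm
    } else {
      cut <- us[length(us)]
      tid <- substr(nm, 1L, cut - 1L)
      gid <- substr(nm, cut + 1L, nchar(nm))
    }
    if (!is.null(gr$blocks) && length(gr$blocks[[i]]) > 0L) {
      bl <- gr$blocks[[i]]
      # blocks are 1-based within the feature
      st <- BiocGenerics::start(gr)[i] - 1L + BiocGenerics::start(bl) - 1L
      en <- BiocGenerics::start(gr)[i] - 1L + BiocGenerics::end(bl)
    } else {
      st <- BiocGenerics::start(gr)[i] - 1L
      en <- BiocGenerics::end(gr)[i]
    }
    out[[i]] <- transcript_model(tid, gid,
                                 as.character(GenomicRanges::seqnames(gr))[i],
                                 as.character(BiocGenerics::strand(gr))[i],
                                 cbind(st, en), source = source)
  }
  out
}

#' Write isoform models to a BED12 file
#'
#' @param isoforms List of `transcript_model`.
#' @param path Output path.
#' @param scores Optional numeric vector (e.g. read support), recycled.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(isoforms, path, scores = 0L) {
  if (length(isoforms) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  scores <- rep_len(scores, length(isoforms))
  lines <- vapply(seq_along(isoforms), function(i) {
    tx <- isoforms[[i]]
    cs <- tx$exons[1, 1]
    ce <- tx$exons[nrow(tx$exons), 2]
    sizes <- tx$exons[, 2] - tx$exons[, 1]
    starts <- tx$exons[, 1] - cs
    paste(tx$chrom, cs, ce,
          paste0(tx$transcript_id, "_", tx$gene_id),
          scores[i], tx$strand, cs, ce, "0",
          nrow(tx$exons),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write spliced isoform sequences to FASTA
#'
#' One record per model, named `<transcript_id>_<gene_id>`; sequences are
#' exon concatenations, reverse-complemented for minus-strand models.
#'
#' @param isoforms List of `transcript_model`.
#' @param genome Named `DNAStringSet` or character vector.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_isoform_fasta <- function(isoforms, genome, path) {
  seqs <- vapply(isoforms, tx_sequence, character(1), genome = genome)
  names(seqs) <- vapply(isoforms, function(tx)
    paste0(tx$transcript_id, "_", tx$gene_id), character(1))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write isoform models in all output formats
#'
#' Convenience writer producing the BED12 + GTF + spliced-FASTA trio.
#'
#' @param isoforms List of `transcript_model`.
#' @param bed_path,gtf_path,fasta_path Output paths (`NULL` to skip one).
#' @param genome Named `DNAStringSet`/character, required for FASTA.
#' @return Invisibly, a named list of written paths.
#' @export
write_isoforms <- function(isoforms, bed_path = NULL, gtf_path = NULL,
                           fasta_path = NULL, genome = NULL) {
  if (!is.null(bed_path)) write_bed12(isoforms, bed_path)
  if (!is.null(gtf_path)) write_gtf(isoforms, gtf_path)
  if (!is.null(fasta_path)) {
    stopifnot(!is.null(genome))
    write_isoform_fasta(isoforms, genome, fasta_path)
  }
  invisible(list(bed = bed_path, gtf = gtf_path, fasta = fasta_path))
}

#' Read short-read splice junction evidence from a BED-like file
#'
#' Expects at least chrom, donor(0-based), acceptor, and optionally a
#' count column (4th or 5th) and strand (6th).
#'
#' @param path Tab-separated file.
#' @return data.frame with columns chrom, donor, acceptor, strand, weight.
#' @export
read_junction_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), donor = integer(0),
                      acceptor = integer(0), strand = character(0),
                      weight = integer(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    chrom = vapply(f, `[`, character(1), 1),
    donor = as.integer(vapply(f, `[`, character(1), 2)),
    acceptor = as.integer(vapply(f, `[`, character(1), 3)),
    strand = vapply(f, function(x) if (length(x) >= 6) x[6] else "*",
                    character(1)),
    weight = vapply(f, function(x) {
      v <- suppressWarnings(as.integer(x[5]))
      if (is.na(v) && length(x) >= 4) v <- suppressWarnings(as.integer(x[4]))
      if (is.na(v)) 1L else v
    }, integer(1)),
    stringsAsFactors = FALSE)
}
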