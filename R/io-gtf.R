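#' Read transcript models from a GTF file
#'
#' Parses exon features (Ensembl attribute dialect, via rtracklayer) into
#' transcript models grouped by gene. GTF's 1-based closed coordinates are
#' converted to the package's 0-based half-open convention.
#'
#' @param path GTF file.
#' @return Named list: `gene_id` -> list of [transcript_model()].
#' @export
read_gtf <- function(path) {
  n_lines <- length(grep("^[^#]", readLines(path, warn = FALSE), value = TRUE))
  if (n_lines == 0L) {
    warning("GTF file ", path, " contains no features")
    return(structure(list(), names = character(0)))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) {
    warning("GTF file ", path, " contains no exon features")
    return(structure(list(), names = character(0)))
  }
  tid <- gr$transcript_id
  gid <- gr$gene_id
  if (is.null(tid) || is.null(gid))
    stop("GTF exon features lack transcript_id/gene_id attributes entirely")
  if (any(is.na(tid)) || any(is.na(gid))) {
    bad <- which(is.na(tid) | is.na(gid))[1]
    stop("exon feature #", bad, " lacks transcript_id/gene_id attribute")
  }
  sr <- as.character(BiocGenerics::strand(gr))
  chr <- as.character(GenomicRanges::seqnames(gr))
  st <- BiocGenerics::start(gr) - 1L  # to 0-based half-open
  en <- BiocGenerics::end(gr)
  out <- list()
  for (t in unique(tid)) {
    i <- which(tid == t)
    if (length(unique(sr[i])) != 1L)
      stop("transcript ", t, " has exons on mixed strands")
    if (length(unique(chr[i])) != 1L)
      stop("transcript ", t, " has exons on multiple chromosomes")
    tx <- transcript_model(t, gid[i[1]], chr[i[1]], sr[i[1]],
                           cbind(st[i], en[i]), source = "annotated")
    out[[gid[i[1]]]] <- c(out[[gid[i[1]]]], list(tx))
  }
  out
}

#' Flatten a gene -> transcripts mapping into a list of transcripts
#' @param genes Result of [read_gtf()].
#' @return Unnamed list of `transcript_model`.
#' @export
flatten_transcripts <- function(genes) {
  unlist(genes, recursive = FALSE, use.names = FALSE)
}

#' Write transcript models to a GTF file
#'
#' @param isoforms List of `transcript_model`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(isoforms, path) {
  if (length(isoforms) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  rows <- lapply(isoforms, function(tx) {
    data.frame(chrom = tx$chrom, start = tx$exons[, 1] + 1L,
               end = tx$exons[, 2], strand = tx$strand,
               gene_id = tx$gene_id, transcript_id = tx$transcript_id,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$source <- "loriso"
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
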