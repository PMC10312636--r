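#' @title Core domain types
#' @description
#' All genomic coordinates inside the package are 0-based, half-open
#' (BED convention). GTF and VCF use 1-based coordinates and are converted
#' at the I/O boundary, never internally.
#' @name loriso-types
#' @keywords internal
NULL

#' Construct a transcript model
#'
#' A transcript model is an ordered, disjoint exon chain on one chromosome
#' and strand, the unit of isoform detection.
#'
#' @param transcript_id,gene_id Identifiers. Must not contain whitespace;
#'   underscores are reserved as the separator in BED12 names.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column integer matrix (`start`, `end`), 0-based
#'   half-open, will be sorted by start.
#' @param source `"annotated"` or `"novel"`.
#' @return A list of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             source = "annotated") {
  stopifnot(is.character(transcript_id), is.character(gene_id),
            strand %in% c("+", "-"), source %in% c("annotated", "novel"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 1] < 0) || any(exons[, 2] <= exons[, 1]))
    stop("invalid exon interval (need 0 <= start < end)")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in transcript ", transcript_id)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 source = source),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d [%s] %d exon(s), %s\n",
              x$transcript_id, x$gene_id, x$chrom, x$exons[1, 1],
              x$exons[nrow(x$exons), 2], x$strand, nrow(x$exons), x$source))
  invisible(x)
}

#' Total exonic length of a transcript model
#' @param tx A `transcript_model`.
#' @return Integer length in bp.
#' @export
tx_length <- function(tx) sum(tx$exons[, 2] - tx$exons[, 1])

#' Splice junction chain of a transcript model
#'
#' @param tx A `transcript_model`.
#' @return Integer matrix with columns `donor` (end of exon i, 0-based
#'   position of the first intronic base) and `acceptor` (start of exon
#'   i+1); zero rows for mono-exon transcripts.
#' @export
junction_chain <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("donor", "acceptor"))))
  cbind(donor = tx$exons[-n, 2], acceptor = tx$exons[-1, 1])
}

#' Junction chain key string
#'
#' Canonical grouping key: chromosome, strand and the ordered
#' donor/acceptor pairs. Two reads or transcripts with equal keys have the
#' same splice junction chain.
#' @param chrom,strand Location.
#' @param jx Junction matrix as from [junction_chain()].
#' @return Single string.
#' @export
chain_key <- function(chrom, strand, jx) {
  if (nrow(jx) == 0L) return(paste0(chrom, strand, ":."))
  paste0(chrom, strand, ":", paste(jx[, 1], jx[, 2], sep = "-", collapse = ","))
}

#' Exon boundary offsets in transcript coordinates
#'
#' @param tx A `transcript_model`.
#' @return Integer vector of internal exon-exon boundary positions in
#'   transcript (spliced, 5'-to-3') coordinates; empty for mono-exon.
#' @export
tx_junction_offsets <- function(tx) {
  lens <- tx$exons[, 2] - tx$exons[, 1]
  if (tx$strand == "-") lens <- rev(lens)
  if (length(lens) < 2L) return(integer(0))
  cumsum(lens)[-length(lens)]
}

#' Map genomic positions to transcript coordinates
#'
#' @param tx A `transcript_model`.
#' @param pos Integer vector of genomic positions (0-based).
#' @return Integer vector of transcript coordinates (0-based, 5' to 3',
#'   strand-aware); `NA` for positions outside the exons.
#' @export
genome_to_tx <- function(tx, pos) {
  lens <- tx$exons[, 2] - tx$exons[, 1]
  offs <- cumsum(c(0L, lens[-length(lens)]))  # plus-strand spliced offsets
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(tx$exons))) {
    inside <- !is.na(pos) & pos >= tx$exons[i, 1] & pos < tx$exons[i, 2]
    out[inside] <- offs[i] + (pos[inside] - tx$exons[i, 1])
  }
  if (tx$strand == "-") out <- sum(lens) - 1L - out
  out
}

#' Convert between 0-based half-open and 1-based closed intervals
#'
#' `to_1based` / `to_0based` are inverses of each other.
#' @param start,end Interval in the source convention.
#' @return Two-element integer vector `c(start, end)` in the target
#'   convention.
#' @export
to_1based <- function(start, end) c(as.integer(start) + 1L, as.integer(end))

#' @rdname to_1based
#' @export
to_0based <- function(start, end) c(as.integer(start) - 1L, as.integer(end))

#' Reverse-complement a DNA string
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Spliced sequence of a transcript model
#'
#' Concatenates exon sequences from the genome; reverse-complemented for
#' minus-strand models so the result reads 5' to 3' on the transcript.
#'
#' @param tx A `transcript_model`.
#' @param genome Named `DNAStringSet` (or named character vector).
#' @return Character scalar.
#' @export
tx_sequence <- function(tx, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!tx$chrom %in% names(genome))
    stop("chromosome ", tx$chrom, " not in genome")
  chr <- genome[[tx$chrom]]
  if (tx$exons[nrow(tx$exons), 2] > length(chr))
    stop("exon beyond chromosome end in ", tx$transcript_id)
  parts <- vapply(seq_len(nrow(tx$exons)), function(i)
    as.character(Biostrings::subseq(chr, tx$exons[i, 1] + 1L, tx$exons[i, 2])),
    character(1))
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  s
}

#' Construct a single-nucleotide variant record
#'
#' @param chrom Chromosome. @param pos0 0-based position.
#' @param ref_allele,alt_allele Single bases, unequal.
#' @param qual Variant quality. @param phase_set Optional phase set id.
#' @param genotype Optional genotype string (e.g. `"0|1"`).
#' @param caller Free-text provenance.
#' @return A list of class `variant_record`.
#' @export
variant_record <- function(chrom, pos0, ref_allele, alt_allele, qual = NA_real_,
                           phase_set = NA_character_, genotype = NA_character_,
                           caller = "unknown") {
  stopifnot(nchar(ref_allele) == 1L, nchar(alt_allele) == 1L,
            ref_allele != alt_allele, pos0 >= 0)
  structure(list(chrom = chrom, pos0 = as.integer(pos0),
                 ref_allele = toupper(ref_allele),
                 alt_allele = toupper(alt_allele), qual = as.numeric(qual),
                 phase_set = phase_set, genotype = genotype, caller = caller),
            class = "variant_record")
}

#' Variants as a data frame
#' @param variants List of `variant_record`.
#' @return data.frame with one row per record.
#' @export
variants_df <- function(variants) {
  if (length(variants) == 0L)
    return(data.frame(chrom = character(0), pos0 = integer(0),
                      ref_allele = character(0), alt_allele = character(0),
                      qual = numeric(0), phase_set = character(0),
                      genotype = character(0), caller = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(variants, function(v)
    data.frame(chrom = v$chrom, pos0 = v$pos0, ref_allele = v$ref_allele,
               alt_allele = v$alt_allele, qual = v$qual,
               phase_set = v$phase_set, genotype = v$genotype,
               caller = v$caller, stringsAsFactors = FALSE)))
}
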