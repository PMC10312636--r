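#' Phasing configuration
#'
#' @param min_coverage Minimum read coverage for a variant site to be
#'   retained when combining call sets. Default 10.
#' @param min_haplotype_support Minimum reads for a variant combination
#'   to become a haplotype. Default 3.
#' @param min_haplotype_fraction Minimum fraction of the isoform's reads
#'   (inclusive). Default 0.10.
#' @param absorb_errors Absorb low-support allele vectors differing from
#'   a surviving haplotype at exactly one position (sequencing-error
#'   dilution guard). Default TRUE.
#' @return List of class `phasing_config`.
#' @export
phasing_config <- function(min_coverage = 10L, min_haplotype_support = 3L,
                           min_haplotype_fraction = 0.10,
                           absorb_errors = TRUE) {
  structure(list(min_coverage = as.integer(min_coverage),
                 min_haplotype_support = as.integer(min_haplotype_support),
                 min_haplotype_fraction = min_haplotype_fraction,
                 absorb_errors = isTRUE(absorb_errors)),
            class = "phasing_config")
}

#' Combine variant call sets with a coverage filter
#'
#' Union of SNV records from several callers; per-site read coverage is
#' computed from the genome alignments and sites below `min_coverage`
#' are dropped. Duplicate sites (same chrom/pos/alt) are merged keeping
#' the maximum quality and concatenating caller provenance.
#'
#' @param vcfs Non-empty list of variant-record lists (e.g. several
#'   [read_vcf()] results).
#' @param reads Genome `read_alignment` list used for coverage.
#' @param min_coverage Inclusive threshold.
#' @return List of `variant_record`.
#' @export
combine_variant_calls <- function(vcfs, reads, min_coverage = 10L) {
  if (length(vcfs) == 0L) stop("no variant input")
  all <- do.call(c, vcfs)
  if (length(all) == 0L) return(list())
  key <- vapply(all, function(v) paste(v$chrom, v$pos0, v$alt_allele),
                character(1))
  merged <- list()
  for (k in unique(key)) {
    grp <- all[key == k]
    best <- grp[[which.max(vapply(grp, function(v)
      ifelse(is.na(v$qual), -Inf, v$qual), numeric(1)))]]
    best$caller <- paste(sort(unique(vapply(grp, `[[`, character(1),
                                            "caller"))), collapse = ",")
    merged[[length(merged) + 1L]] <- best
  }
  keep <- vapply(merged, function(v) {
    cov <- sum(vapply(reads, function(a) {
      a$target_id == v$chrom &&
        aln_state_at(a, v$pos0)$state %in% c("match", "mismatch")
    }, logical(1)))
    cov >= min_coverage
  }, logical(1))
  merged <- merged[keep]
  ord <- order(vapply(merged, `[[`, character(1), "chrom"),
               vapply(merged, `[[`, integer(1), "pos0"))
  merged[ord]
}

#' Allele carried by one read at one variant site
#'
#' @param read Genome `read_alignment`.
#' @param variant A `variant_record`.
#' @return `"ref"`, `"alt"`, `"other"` or `"uncovered"` (deletions and
#'   spliced-out positions count as uncovered for phasing).
#' @export
read_allele_at <- function(read, variant) {
  if (read$target_id != variant$chrom) return("uncovered")
  st <- aln_state_at(read, variant$pos0)
  switch(st$state,
         match = "ref",
         mismatch = if (identical(st$base, variant$alt_allele)) "alt" else "other",
         "uncovered")
}

.allele_matrix <- function(reads, variants) {
  m <- matrix("uncovered", nrow = length(reads), ncol = length(variants))
  for (j in seq_along(variants))
    for (i in seq_along(reads))
      m[i, j] <- read_allele_at(reads[[i]], variants[[j]])
  rownames(m) <- vapply(reads, `[[`, character(1), "read_id")
  m
}

#' Tabulate variant combinations (haplotypes) on one isoform
#'
#' Ploidy-agnostic mode: each supporting read maps to its allele vector
#' over the isoform's variant positions; complete vectors are counted and
#' those passing the support and fraction thresholds become haplotypes
#' (indexed by descending support; ties broken lexicographically).
#' Complete vectors below the support threshold that differ from a
#' surviving haplotype at exactly one position are absorbed into it;
#' incomplete reads are credited to the unique surviving haplotype
#' consistent with their covered positions, if there is exactly one.
#'
#' @param isoform A `transcript_model`.
#' @param reads The isoform's supporting genome `read_alignment` list.
#' @param variants List of `variant_record` (any; restricted to the
#'   isoform's exons internally).
#' @param cfg A [phasing_config()].
#' @return List of haplotypes: `isoform_id`, `haplotype_index`,
#'   `alleles` (named character, names are genomic pos0), `support`,
#'   `read_ids`.
#' @export
tabulate_haplotypes <- function(isoform, reads, variants,
                                cfg = phasing_config()) {
  variants <- Filter(function(v) {
    v$chrom == isoform$chrom &&
      any(v$pos0 >= isoform$exons[, 1] & v$pos0 < isoform$exons[, 2])
  }, variants)
  if (length(variants) == 0L || length(reads) == 0L) return(list())
  pos <- vapply(variants, `[[`, integer(1), "pos0")
  am <- .allele_matrix(reads, variants)
  known <- am == "ref" | am == "alt"
  complete <- rowSums(known) == ncol(am)
  vec_of <- function(i) paste(am[i, ], collapse = "|")
  n_total <- length(reads)
  counts <- list()   # vector string -> read ids
  for (i in which(complete)) {
    v <- vec_of(i)
    counts[[v]] <- c(counts[[v]], rownames(am)[i])
  }
  if (length(counts) == 0L) return(list())
  supp <- vapply(counts, length, integer(1))
  surviving <- names(counts)[supp >= cfg$min_haplotype_support &
                               supp / n_total >= cfg$min_haplotype_fraction]
  if (length(surviving) == 0L) return(list())
  hap_reads <- counts[surviving]
  if (cfg$absorb_errors) {
    minor <- setdiff(names(counts), surviving)
    for (v in minor) {
      if (length(counts[[v]]) >= cfg$min_haplotype_support) next
      vv <- strsplit(v, "|", fixed = TRUE)[[1]]
      diffs <- vapply(surviving, function(s)
        sum(strsplit(s, "|", fixed = TRUE)[[1]] != vv), integer(1))
      hit <- which(diffs == 1L)
      if (length(hit) == 1L)
        hap_reads[[surviving[hit]]] <- c(hap_reads[[surviving[hit]]],
                                         counts[[v]])
    }
  }
  # incomplete reads: credit the unique consistent surviving haplotype
  surv_mat <- do.call(rbind, strsplit(surviving, "|", fixed = TRUE))
  for (i in which(!complete)) {
    kn <- known[i, ]
    if (!any(kn)) next
    cons <- which(apply(surv_mat, 1, function(s) all(s[kn] == am[i, kn])))
    if (length(cons) == 1L)
      hap_reads[[surviving[cons]]] <- c(hap_reads[[surviving[cons]]],
                                        rownames(am)[i])
  }
  supp2 <- vapply(hap_reads, length, integer(1))
  ord <- order(-supp2, names(hap_reads))
  out <- list()
  for (r in seq_along(ord)) {
    v <- names(hap_reads)[ord[r]]
    alleles <- strsplit(v, "|", fixed = TRUE)[[1]]
    names(alleles) <- as.character(pos)
    out[[r]] <- list(isoform_id = isoform$transcript_id,
                     haplotype_index = r, alleles = alleles,
                     support = length(hap_reads[[ord[r]]]),
                     read_ids = sort(unique(hap_reads[[ord[r]]])))
  }
  out
}

#' Phase an isoform's reads using caller phase sets
#'
#' Diploid mode: reads carrying phase-set (`PS`) and haplotype (`HP`)
#' tags are partitioned by (phase set, haplotype); each partition's
#' allele vector is taken from the VCF's phased genotypes. Reads whose
#' carried allele conflicts with their tag follow the tag (conflicts are
#' counted); untagged reads are excluded and counted.
#'
#' @param isoform A `transcript_model`.
#' @param reads Supporting genome `read_alignment` list (with `hp`/`ps`).
#' @param variants Phased `variant_record` list (genotype like `"0|1"`,
#'   `phase_set` set).
#' @param cfg A [phasing_config()].
#' @return List of haplotypes as in [tabulate_haplotypes()], with
#'   attributes `n_untagged` and `n_conflict`.
#' @export
phase_by_phase_set <- function(isoform, reads, variants,
                               cfg = phasing_config()) {
  variants <- Filter(function(v) {
    v$chrom == isoform$chrom && !is.na(v$phase_set) &&
      any(v$pos0 >= isoform$exons[, 1] & v$pos0 < isoform$exons[, 2])
  }, variants)
  if (length(variants) == 0L || length(reads) == 0L) return(list())
  pos <- vapply(variants, `[[`, integer(1), "pos0")
  tagged <- Filter(function(a) !is.na(a$hp) && !is.na(a$ps), reads)
  n_untagged <- length(reads) - length(tagged)
  if (length(tagged) == 0L) {
    out <- list(); attr(out, "n_untagged") <- n_untagged
    attr(out, "n_conflict") <- 0L
    return(out)
  }
  am <- .allele_matrix(tagged, variants)
  part <- paste(vapply(tagged, `[[`, character(1), "ps"),
                vapply(tagged, function(a) as.character(a$hp), character(1)),
                sep = "/")
  n_conflict <- 0L
  haps <- list()
  for (p in sort(unique(part))) {
    idx <- which(part == p)
    ps <- sub("/.*$", "", p)
    hp <- as.integer(sub("^.*/", "", p))
    alleles <- vapply(variants, function(v) {
      if (!identical(v$phase_set, ps)) return(NA_character_)
      gt <- strsplit(v$genotype, "[|/]")[[1]]
      if (length(gt) < hp || is.na(gt[hp])) return(NA_character_)
      if (gt[hp] == "0") "ref" else "alt"
    }, character(1))
    keep <- !is.na(alleles)
    if (!any(keep)) next
    # conflict count: tagged reads carrying the opposite allele
    for (i in idx) for (j in which(keep)) {
      obs <- am[i, j]
      if (obs %in% c("ref", "alt") && obs != alleles[j])
        n_conflict <- n_conflict + 1L
    }
    a <- alleles[keep]
    names(a) <- as.character(pos[keep])
    haps[[length(haps) + 1L]] <- list(
      isoform_id = isoform$transcript_id, alleles = a,
      support = length(idx),
      read_ids = sort(vapply(tagged[idx], `[[`, character(1), "read_id")))
  }
  supp <- vapply(haps, `[[`, integer(1), "support")
  n_total <- length(reads)
  sel <- supp >= cfg$min_haplotype_support &
    supp / n_total >= cfg$min_haplotype_fraction
  haps <- haps[sel]
  ord <- order(-vapply(haps, `[[`, integer(1), "support"),
               vapply(haps, function(h) paste(h$alleles, collapse = "|"),
                      character(1)))
  haps <- haps[ord]
  for (r in seq_along(haps)) haps[[r]]$haplotype_index <- r
  attr(haps, "n_untagged") <- n_untagged
  attr(haps, "n_conflict") <- n_conflict
  haps
}

#' Fisher test for haplotype-biased isoform usage within a gene
#'
#' For every (isoform, haplotype) of a gene with at least two isoforms
#' and two haplotypes, tests the 2x2 table
#' \[reads of this isoform on this haplotype vs others\] x
#' \[reads of other isoforms on this haplotype vs others\] with the
#' two-sided Fisher's exact test; adjusted p-values are computed over all
#' supplied genes (transcriptome-wide BH).
#'
#' @param hap_table data.frame with columns gene_id, isoform_id,
#'   haplotype_key (an identifier comparable across the gene's isoforms,
#'   e.g. the allele vector or phase-set haplotype), support.
#' @param alpha Significance level on the adjusted p-value. Default 0.05.
#' @param method Adjustment method for [bh_adjust()].
#' @return data.frame: gene_id, isoform_id, haplotype_key, a, b, c, d,
#'   p, p_adj, significant.
#' @export
hst_bias_test <- function(hap_table, alpha = 0.05, method = "bh") {
  empty <- data.frame(gene_id = character(0), isoform_id = character(0),
                      haplotype_key = character(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (nrow(hap_table) == 0L) return(empty)
  rows <- list()
  for (g in unique(hap_table$gene_id)) {
    sub <- hap_table[hap_table$gene_id == g, , drop = FALSE]
    isoforms <- unique(sub$isoform_id)
    haps <- unique(sub$haplotype_key)
    if (length(isoforms) < 2L || length(haps) < 2L) next
    tot <- sum(sub$support)
    for (iso in isoforms) for (h in haps) {
      a <- sum(sub$support[sub$isoform_id == iso & sub$haplotype_key == h])
      b <- sum(sub$support[sub$isoform_id == iso & sub$haplotype_key != h])
      cc <- sum(sub$support[sub$isoform_id != iso & sub$haplotype_key == h])
      d <- tot - a - b - cc
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, isoform_id = iso, haplotype_key = h,
        a = a, b = b, c = cc, d = d,
        p = fisher_exact_two_sided(a, b, cc, d), p_adj = NA_real_,
        significant = NA, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p, method = method)
  out$significant <- out$p_adj < alpha
  out
}

#' Write haplotype-specific transcript outputs
#'
#' Per haplotype, the isoform's spliced sequence with the haplotype's alt
#' alleles substituted (in transcript-strand orientation; a genome-level
#' T>C alt on a minus-strand isoform appears as A>G in the transcript).
#' Models are duplicated per haplotype under the naming convention
#' `<transcript_id>_<haplotype_index>_<gene_id>`; the VCF is annotated
#' with an `ISO` INFO key listing carrying isoforms.
#'
#' @param haplotypes Named list isoform_id -> haplotype list (from either
#'   phasing mode).
#' @param isoforms Named list transcript_id -> `transcript_model`.
#' @param variants The combined `variant_record` list.
#' @param genome Named `DNAStringSet`/character.
#' @param fasta_path,bed_path,vcf_path Output paths (NULL to skip).
#' @return Invisibly, list with `models` (the per-haplotype
#'   `transcript_model`s) and `sequences` (named character).
#' @export
emit_hst_outputs <- function(haplotypes, isoforms, variants, genome,
                             fasta_path = NULL, bed_path = NULL,
                             vcf_path = NULL) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  models <- list(); seqs <- character(0)
  var_iso <- lapply(variants, function(v) character(0))
  vkey <- vapply(variants, function(v) paste(v$chrom, v$pos0, v$alt_allele),
                 character(1))
  for (iso_id in names(haplotypes)) {
    tx <- isoforms[[iso_id]]
    base_seq <- tx_sequence(tx, genome)
    for (h in haplotypes[[iso_id]]) {
      nm <- paste0(tx$transcript_id, "_", h$haplotype_index)
      htx <- tx
      htx$transcript_id <- nm
      models[[length(models) + 1L]] <- htx
      s <- strsplit(base_seq, "")[[1]]
      for (k in seq_along(h$alleles)) {
        if (h$alleles[k] != "alt") next
        gpos <- as.integer(names(h$alleles)[k])
        tp <- genome_to_tx(tx, gpos)
        stopifnot(!is.na(tp))  # alleles lie inside exons by construction
        vi <- which(vapply(variants, function(v)
          v$chrom == tx$chrom && v$pos0 == gpos, logical(1)))[1]
        alt <- variants[[vi]]$alt_allele
        if (tx$strand == "-") alt <- revcomp(alt)
        s[tp + 1L] <- alt
        var_iso[[vi]] <- c(var_iso[[vi]], paste0(nm, "_", tx$gene_id))
      }
      seqs[paste0(nm, "_", tx$gene_id)] <- paste(s, collapse = "")
    }
  }
  if (!is.null(fasta_path))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  if (!is.null(bed_path)) write_bed12(models, bed_path)
  if (!is.null(vcf_path)) write_vcf(variants, vcf_path, iso = var_iso)
  invisible(list(models = models, sequences = seqs))
}
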