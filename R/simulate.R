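#' Simulation configuration
#'
#' Defaults emulate high-accuracy consensus long-read cDNA data: ~1%
#' substitution error (the ~99% consensus-accuracy regime), a 30%
#' incidence of 5'/3' truncation, and 100 reads per transcript.
#'
#' @param seed Integer seed; the same configuration always produces
#'   byte-identical artifacts.
#' @param n_genes,transcripts_per_gene Locus counts.
#' @param exon_range,intron_range Length ranges in bp.
#' @param reads_per_transcript Reads drawn per transcript.
#' @param error_rate Per-base substitution probability.
#' @param truncation_prob Probability a read is truncated.
#' @param truncation_max_frac Maximum truncated fraction of the
#'   transcript length.
#' @param variants_per_kb Heterozygous SNV density over a gene's shared
#'   exonic sequence (0 disables variant simulation).
#' @param conditions Character vector of condition names for editing
#'   simulations.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 10L, transcripts_per_gene = 2L,
                       exon_range = c(120L, 300L),
                       intron_range = c(200L, 500L),
                       reads_per_transcript = 100L, error_rate = 0.01,
                       truncation_prob = 0.3, truncation_max_frac = 0.4,
                       variants_per_kb = 0, conditions = "sample") {
  stopifnot(error_rate >= 0, error_rate <= 1, truncation_prob >= 0,
            truncation_prob <= 1, seed == as.integer(seed))
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 transcripts_per_gene = as.integer(transcripts_per_gene),
                 exon_range = as.integer(exon_range),
                 intron_range = as.integer(intron_range),
                 reads_per_transcript = as.integer(reads_per_transcript),
                 error_rate = error_rate, truncation_prob = truncation_prob,
                 truncation_max_frac = truncation_max_frac,
                 variants_per_kb = variants_per_kb,
                 conditions = conditions),
            class = "sim_config")
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

#' Simulate a reference genome and annotation
#'
#' One chromosome carrying `n_genes` loci on alternating strands. Each
#' gene has 4+ exons; isoform k skips internal exon k+1, so isoforms of
#' a gene share ends but differ in at least one junction. Intron
#' boundaries carry canonical GT..AG dinucleotides on the gene strand.
#'
#' @param cfg A [sim_config()].
#' @return List: `genome` (named `DNAStringSet`), `genes`
#'   (gene_id -> list of `transcript_model`), `transcripts` (named by
#'   transcript_id), `chrom`.
#' @export
simulate_reference <- function(cfg) {
  set.seed(cfg$seed)
  chrom <- "chr1"
  gap <- 1000L
  chars <- character(0)
  cursor <- gap
  genes <- list()
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("gene%02d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    n_ex <- sample(max(4L, cfg$transcripts_per_gene + 1L):6L, 1)
    ex_len <- sample(cfg$exon_range[1]:cfg$exon_range[2], n_ex, replace = TRUE)
    in_len <- sample(cfg$intron_range[1]:cfg$intron_range[2], n_ex - 1L,
                     replace = TRUE)
    st <- integer(n_ex); en <- integer(n_ex)
    p <- cursor
    for (i in seq_len(n_ex)) {
      st[i] <- p; en[i] <- p + ex_len[i]
      p <- en[i] + if (i < n_ex) in_len[i] else 0L
    }
    exons <- cbind(st, en)
    txs <- list()
    for (k in seq_len(cfg$transcripts_per_gene)) {
      keep <- seq_len(n_ex)
      if (k > 1L) keep <- keep[-(k)]  # skip internal exon k (k>=2)
      txs[[k]] <- transcript_model(sprintf("%s.t%d", gid, k), gid, chrom,
                                   strand, exons[keep, , drop = FALSE])
    }
    genes[[gid]] <- txs
    cursor <- p + gap
  }
  glen <- cursor + gap
  seq <- strsplit(.rand_dna(glen), "")[[1]]
  # plant canonical splice dinucleotides for every annotated intron
  for (txs in genes) for (tx in txs) {
    jx <- junction_chain(tx)
    for (i in seq_len(nrow(jx))) {
      d <- jx[i, 1]; a <- jx[i, 2]
      if (tx$strand == "+") {
        seq[(d + 1L):(d + 2L)] <- c("G", "T")
        seq[(a - 1L):a] <- c("A", "G")
      } else {
        seq[(d + 1L):(d + 2L)] <- c("C", "T")
        seq[(a - 1L):a] <- c("A", "C")
      }
    }
  }
  genome <- Biostrings::DNAStringSet(structure(paste(seq, collapse = ""),
                                               names = chrom))
  transcripts <- flatten_transcripts(genes)
  names(transcripts) <- vapply(transcripts, `[[`, character(1),
                               "transcript_id")
  list(genome = genome, genes = genes, transcripts = transcripts,
       chrom = chrom)
}

.shared_exonic_positions <- function(txs) {
  # genomic positions exonic in every isoform of the gene
  pos <- NULL
  for (tx in txs) {
    p <- unlist(lapply(seq_len(nrow(tx$exons)), function(i)
      tx$exons[i, 1]:(tx$exons[i, 2] - 1L)))
    pos <- if (is.null(pos)) p else intersect(pos, p)
  }
  sort(pos)
}

.junction_guard <- function(txs, flank = 6L) {
  # positions too close to any junction to host a planted feature
  bad <- integer(0)
  for (tx in txs) {
    jx <- junction_chain(tx)
    for (i in seq_len(nrow(jx)))
      bad <- c(bad, (jx[i, 1] - flank):(jx[i, 1] + flank),
               (jx[i, 2] - flank):(jx[i, 2] + flank))
  }
  unique(bad)
}

#' Simulate phased heterozygous variants
#'
#' Plants `variants_per_kb` het SNVs per kb of each gene's shared exonic
#' sequence (at least 2 per gene), away from splice junctions, with a
#' random phased genotype (`0|1` or `1|0`) and one phase set per gene.
#'
#' @param cfg A [sim_config()] with `variants_per_kb > 0`.
#' @param ref From [simulate_reference()].
#' @return List: `variants` (list of `variant_record`), `hap_allele`
#'   (function(gene_id, hap, pos0) -> base).
#' @export
simulate_variants <- function(cfg, ref) {
  set.seed(cfg$seed + 101L)
  chr <- strsplit(as.character(ref$genome[[ref$chrom]]), "")[[1]]
  variants <- list()
  allele_map <- list()  # key "pos" -> c(hap1 base, hap2 base)
  for (gid in names(ref$genes)) {
    txs <- ref$genes[[gid]]
    pool <- setdiff(.shared_exonic_positions(txs), .junction_guard(txs))
    n <- max(2L, round(length(.shared_exonic_positions(txs)) / 1000 *
                         cfg$variants_per_kb))
    pos <- sort(sample(pool, min(n, length(pool))))
    ps <- as.character(match(gid, names(ref$genes)))
    for (p in pos) {
      refb <- chr[p + 1L]
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      gt <- sample(c("0|1", "1|0"), 1)
      variants[[length(variants) + 1L]] <- variant_record(
        ref$chrom, p, refb, altb, qual = 50, phase_set = ps,
        genotype = gt, caller = "simulated")
      hap_bases <- c(refb, refb)
      g <- strsplit(gt, "|", fixed = TRUE)[[1]]
      hap_bases[g == "1"] <- altb
      allele_map[[as.character(p)]] <- list(gene = gid, bases = hap_bases)
    }
  }
  hap_allele <- function(pos0) allele_map[[as.character(pos0)]]
  list(variants = variants, allele_map = allele_map)
}

#' Simulate condition-dependent edit sites
#'
#' Picks adenosines (gene-strand sense) in exonic sequence shared by all
#' of a gene's isoforms and assigns each site an edited-read fraction
#' per condition; optionally adds tight clusters emulating hyperediting.
#'
#' @param cfg A [sim_config()].
#' @param ref From [simulate_reference()].
#' @param n_sites Total number of dispersed sites.
#' @param fractions Named list condition -> vector (recycled) of edit
#'   fractions, e.g. `list(control = 0.5, knockdown = 0.1)`.
#' @param clusters Optional list(n = clusters, size = sites each,
#'   span = bp) of additional hyperediting clusters (edited at the
#'   maximum control fraction).
#' @param min_gap Minimum distance between dispersed sites. Default 55.
#' @return data.frame: chrom, pos0, strand, plus `frac_<condition>`
#'   columns and `cluster` (0 = dispersed).
#' @export
simulate_edit_sites <- function(cfg, ref, n_sites = 50L,
                                fractions = list(control = 0.5,
                                                 knockdown = 0.1),
                                clusters = NULL, min_gap = 55L) {
  set.seed(cfg$seed + 202L)
  chr <- strsplit(as.character(ref$genome[[ref$chrom]]), "")[[1]]
  gene_ids <- names(ref$genes)
  rows <- list()
  taken <- integer(0)
  sense_base <- function(strand) if (strand == "+") "A" else "T"
  pick <- function(gid, k, gap) {
    txs <- ref$genes[[gid]]
    strand <- txs[[1]]$strand
    pool <- setdiff(.shared_exonic_positions(txs), .junction_guard(txs))
    pool <- pool[chr[pool + 1L] == sense_base(strand)]
    got <- integer(0)
    pool <- sample(pool)
    for (p in pool) {
      if (length(got) == k) break
      if (all(abs(c(taken, got) - p) >= gap) || (length(taken) == 0L &&
                                                 length(got) == 0L))
        got <- c(got, p)
    }
    got
  }
  per_gene <- diff(round(seq(0, n_sites, length.out = length(gene_ids) + 1)))
  for (gi in seq_along(gene_ids)) {
    gid <- gene_ids[gi]
    pos <- pick(gid, per_gene[gi], min_gap)
    taken <- c(taken, pos)
    strand <- ref$genes[[gid]][[1]]$strand
    for (p in pos)
      rows[[length(rows) + 1L]] <- data.frame(chrom = ref$chrom, pos0 = p,
                                              strand = strand, cluster = 0L,
                                              stringsAsFactors = FALSE)
  }
  if (!is.null(clusters) && clusters$n > 0L) {
    cl_genes <- rep_len(gene_ids, clusters$n)
    for (ci in seq_len(clusters$n)) {
      gid <- cl_genes[ci]
      txs <- ref$genes[[gid]]
      strand <- txs[[1]]$strand
      pool <- setdiff(.shared_exonic_positions(txs), .junction_guard(txs))
      pool <- pool[chr[pool + 1L] == sense_base(strand)]
      pool <- setdiff(pool, unlist(lapply(taken, function(t)
        (t - 10L):(t + 10L))))
      anchors <- pool[vapply(pool, function(a)
        sum(pool >= a & pool < a + clusters$span) >= clusters$size,
        logical(1))]
      if (length(anchors) == 0L) next
      a <- sample(anchors, 1)
      win <- sort(pool[pool >= a & pool < a + clusters$span])
      pos <- sort(sample(win, clusters$size))
      taken <- c(taken, pos)
      for (p in pos)
        rows[[length(rows) + 1L]] <- data.frame(chrom = ref$chrom, pos0 = p,
                                                strand = strand,
                                                cluster = ci,
                                                stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  for (cond in names(fractions)) {
    fr <- rep_len(fractions[[cond]], sum(df$cluster == 0L))
    col <- numeric(nrow(df))
    col[df$cluster == 0L] <- fr
    col[df$cluster != 0L] <- max(unlist(fractions[[cond]]))
    df[[paste0("frac_", cond)]] <- col
  }
  df <- df[order(df$pos0), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Simulate long reads with errors, truncation, haplotypes and edits
#'
#' Reads are drawn uniformly from the reference transcripts. Each read
#' optionally carries one haplotype's alleles, Bernoulli edits at the
#' condition's per-site fraction, substitution errors, and 5' (75% of
#' truncations) or 3' truncation of uniform extent.
#'
#' @param cfg A [sim_config()].
#' @param ref From [simulate_reference()].
#' @param variants Optional result of [simulate_variants()].
#' @param edits Optional data.frame from [simulate_edit_sites()].
#' @param condition Condition name (selects the `frac_<condition>`
#'   column; also part of read ids).
#' @param seed_offset Added to `cfg$seed` so several read sets from one
#'   configuration differ.
#' @return List: `reads` (per-read records), `truth` (data.frame).
#' @export
simulate_reads <- function(cfg, ref, variants = NULL, edits = NULL,
                           condition = "sample", seed_offset = 0L) {
  set.seed(cfg$seed + 303L + seed_offset)
  chr <- strsplit(as.character(ref$genome[[ref$chrom]]), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  reads <- list(); truth <- list()
  nread <- 0L
  for (tx in ref$transcripts) {
    L <- tx_length(tx)
    gmap <- unlist(lapply(seq_len(nrow(tx$exons)), function(i)
      tx$exons[i, 1]:(tx$exons[i, 2] - 1L)))
    if (tx$strand == "-") gmap <- rev(gmap)
    tx_edits <- NULL
    if (!is.null(edits)) {
      keep <- edits$chrom == tx$chrom & !is.na(genome_to_tx(tx, edits$pos0)) &
        edits$strand == tx$strand
      tx_edits <- edits[keep, , drop = FALSE]
    }
    tx_vars <- NULL
    if (!is.null(variants)) {
      vp <- as.integer(names(variants$allele_map))
      vsel <- vp[vapply(vp, function(p)
        variants$allele_map[[as.character(p)]]$gene == tx$gene_id &&
          !is.na(genome_to_tx(tx, p)), logical(1))]
      tx_vars <- vsel
    }
    for (r in seq_len(cfg$reads_per_transcript)) {
      nread <- nread + 1L
      rid <- sprintf("%s_read%05d", condition, nread)
      hap <- if (!is.null(variants)) ((r - 1L) %% 2L) + 1L else NA_integer_
      s <- 0L; e <- L
      if (stats::runif(1) < cfg$truncation_prob) {
        ext <- sample(seq_len(max(1L, floor(cfg$truncation_max_frac * L))), 1)
        if (stats::runif(1) < 0.75) s <- min(ext, L - 50L) else
          e <- max(L - ext, 50L)
      }
      gpos <- gmap[(s + 1L):e]  # genome positions, transcript order
      # genome-orientation overrides: hap alleles, then edits, then errors
      g_mm <- character(0)
      edited <- integer(0)
      if (!is.null(tx_vars) && length(tx_vars)) {
        for (p in intersect(tx_vars, gpos)) {
          b <- variants$allele_map[[as.character(p)]]$bases[hap]
          if (b != chr[p + 1L]) g_mm[as.character(p)] <- b
        }
      }
      if (!is.null(tx_edits) && nrow(tx_edits)) {
        fr <- tx_edits[[paste0("frac_", condition)]]
        hitpos <- tx_edits$pos0[tx_edits$pos0 %in% gpos &
                                  stats::runif(nrow(tx_edits)) < fr]
        for (p in hitpos) {
          g_mm[as.character(p)] <- if (tx$strand == "+") "G" else "C"
          edited <- c(edited, p)
        }
      }
      n_err <- stats::rbinom(1, length(gpos), cfg$error_rate)
      err_pos <- if (n_err > 0) sort(sample(gpos, n_err)) else integer(0)
      for (p in err_pos) {
        cur <- if (!is.na(g_mm[as.character(p)])) g_mm[[as.character(p)]] else
          chr[p + 1L]
        g_mm[as.character(p)] <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      }
      # drop overrides that ended up equal to the reference
      if (length(g_mm)) {
        same <- vapply(names(g_mm), function(p)
          identical(g_mm[[p]], chr[as.integer(p) + 1L]), logical(1))
        g_mm <- g_mm[!same]
      }
      reads[[nread]] <- list(read_id = rid, tx_id = tx$transcript_id,
                             gene_id = tx$gene_id, chrom = tx$chrom,
                             strand = tx$strand, hap = hap, s = s, e = e,
                             g_mm = g_mm, edited = edited, err = err_pos,
                             condition = condition)
      truth[[nread]] <- data.frame(
        read_id = rid, transcript_id = tx$transcript_id,
        gene_id = tx$gene_id, haplotype = hap, condition = condition,
        tx_start = s, tx_end = e,
        edited_pos = paste(edited, collapse = ","),
        n_errors = length(err_pos), stringsAsFactors = FALSE)
    }
  }
  list(reads = reads, truth = do.call(rbind, truth))
}

.md_string <- function(ref_bases, mm_flags) {
  # canonical MD over matched/mismatched reference bases (no deletions)
  out <- character(0)
  run <- 0L
  for (i in seq_along(ref_bases)) {
    if (mm_flags[i]) {
      out <- c(out, as.character(run), ref_bases[i])
      run <- 0L
    } else run <- run + 1L
  }
  paste(c(out, as.character(run)), collapse = "")
}

#' Write truth-derived genome and transcriptome alignments
#'
#' Emits perfect-knowledge SAM records from the simulation truth, so no
#' external aligner is needed: genome records have M/N CIGARs with MD
#' tags (and HP/PS tags in haplotype simulations); transcriptome records
#' are ungapped single-M alignments to each read's source transcript.
#'
#' @param sim From [simulate_reads()].
#' @param ref From [simulate_reference()].
#' @param genome_sam,tx_sam Output SAM paths (NULL to skip either).
#' @param phase_sets Optional named vector gene_id -> phase set id (adds
#'   HP/PS tags).
#' @return Invisibly, list of written paths.
#' @export
write_truth_alignments <- function(sim, ref, genome_sam = NULL,
                                   tx_sam = NULL, phase_sets = NULL) {
  chr <- strsplit(as.character(ref$genome[[ref$chrom]]), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  g_rows <- list(); t_rows <- list()
  for (rd in sim$reads) {
    tx <- ref$transcripts[[rd$tx_id]]
    # covered genomic window in genome order
    tx_lo <- min(rd$s, rd$e); tx_hi <- max(rd$s, rd$e)
    lens <- tx$exons[, 2] - tx$exons[, 1]
    offs <- cumsum(c(0L, lens[-length(lens)]))
    segs <- list()
    for (i in seq_len(nrow(tx$exons))) {
      # transcript-plus-orientation offsets of this exon
      t0 <- offs[i]; t1 <- offs[i] + lens[i]
      if (tx$strand == "-") { p0 <- tx_length(tx) - t1; p1 <- tx_length(tx) - t0 }
      else { p0 <- t0; p1 <- t1 }
      lo <- max(p0, rd$s); hi <- min(p1, rd$e)
      if (lo >= hi) next
      if (tx$strand == "-") {
        gs <- tx$exons[i, 1] + (p1 - hi); ge <- tx$exons[i, 1] + (p1 - lo)
      } else {
        gs <- tx$exons[i, 1] + (lo - p0); ge <- tx$exons[i, 1] + (hi - p0)
      }
      segs[[length(segs) + 1L]] <- c(gs, ge)
    }
    segs <- do.call(rbind, segs)
    segs <- segs[order(segs[, 1]), , drop = FALSE]
    gpos <- unlist(lapply(seq_len(nrow(segs)), function(i)
      segs[i, 1]:(segs[i, 2] - 1L)))
    bases <- chr[gpos + 1L]
    if (length(rd$g_mm)) {
      ov <- match(as.integer(names(rd$g_mm)), gpos)
      bases[ov[!is.na(ov)]] <- unlist(rd$g_mm)[!is.na(ov)]
    }
    mm <- bases != chr[gpos + 1L]
    cig_parts <- character(0)
    for (i in seq_len(nrow(segs))) {
      cig_parts <- c(cig_parts, paste0(segs[i, 2] - segs[i, 1], "M"))
      if (i < nrow(segs))
        cig_parts <- c(cig_parts, paste0(segs[i + 1, 1] - segs[i, 2], "N"))
    }
    tags <- paste0("MD:Z:", .md_string(chr[gpos + 1L], mm))
    if (!is.null(phase_sets) && !is.na(rd$hap))
      tags <- paste(tags, paste0("HP:i:", rd$hap),
                    paste0("PS:i:", phase_sets[[rd$gene_id]]), sep = "\t")
    g_rows[[length(g_rows) + 1L]] <- data.frame(
      qname = rd$read_id, flag = if (tx$strand == "-") 16L else 0L,
      rname = rd$chrom, pos1 = segs[1, 1] + 1L, mapq = 60L,
      cigar = paste(cig_parts, collapse = ""),
      seq = paste(bases, collapse = ""), tags = tags,
      stringsAsFactors = FALSE)
    if (!is.null(tx_sam)) {
      tx_ref <- strsplit(tx_sequence(tx, ref$genome), "")[[1]]
      rb <- bases
      if (tx$strand == "-") rb <- rev(unname(comp[rb]))
      win <- (rd$s + 1L):rd$e
      mm_t <- rb != tx_ref[win]
      t_rows[[length(t_rows) + 1L]] <- data.frame(
        qname = rd$read_id, flag = 0L, rname = rd$tx_id, pos1 = rd$s + 1L,
        mapq = 60L, cigar = paste0(length(win), "M"),
        seq = paste(rb, collapse = ""),
        tags = paste0("MD:Z:", .md_string(tx_ref[win], mm_t)),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(genome_sam)) {
    sq <- structure(Biostrings::width(ref$genome), names = names(ref$genome))
    write_sam(do.call(rbind, g_rows), sq, genome_sam)
  }
  if (!is.null(tx_sam)) {
    sq <- vapply(ref$transcripts, tx_length, integer(1))
    write_sam(do.call(rbind, t_rows), sq, tx_sam)
  }
  invisible(list(genome_sam = genome_sam, tx_sam = tx_sam))
}

#' Generate a complete simulated dataset on disk
#'
#' Writes genome FASTA, annotation GTF, per-condition genome SAM, a
#' transcriptome SAM, a phased VCF (when variants are simulated) and the
#' truth tables into `dir`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created).
#' @param edits Optional data.frame from [simulate_edit_sites()].
#' @return List of paths plus the in-memory `ref`, `variants`, truth.
#' @export
simulate_dataset <- function(cfg, dir, edits = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(cfg)
  Biostrings::writeXStringSet(ref$genome, file.path(dir, "genome.fa"))
  write_gtf(flatten_transcripts(ref$genes), file.path(dir, "annotation.gtf"))
  variants <- NULL
  phase_sets <- NULL
  if (cfg$variants_per_kb > 0) {
    variants <- simulate_variants(cfg, ref)
    write_vcf(variants$variants, file.path(dir, "variants.vcf"))
    phase_sets <- structure(as.character(seq_along(ref$genes)),
                            names = names(ref$genes))
  }
  paths <- list(genome = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "annotation.gtf"),
                vcf = if (!is.null(variants)) file.path(dir, "variants.vcf"),
                genome_sam = character(0), truth = character(0))
  truths <- list()
  for (ci in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[ci]
    sim <- simulate_reads(cfg, ref, variants = variants, edits = edits,
                          condition = cond, seed_offset = ci * 1000L)
    gsam <- file.path(dir, paste0("genome_", cond, ".sam"))
    tsam <- if (ci == 1L) file.path(dir, "transcriptome.sam") else NULL
    write_truth_alignments(sim, ref, genome_sam = gsam, tx_sam = tsam,
                           phase_sets = phase_sets)
    tpath <- file.path(dir, paste0("truth_", cond, ".tsv"))
    utils::write.table(sim$truth, tpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$genome_sam <- c(paths$genome_sam, structure(gsam, names = cond))
    paths$truth <- c(paths$truth, structure(tpath, names = cond))
    if (!is.null(tsam)) paths$tx_sam <- tsam
    truths[[cond]] <- sim$truth
  }
  c(paths, list(ref = ref, variants = variants, truth_tables = truths,
                edits = edits))
}
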