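#' Collapse configuration
#'
#' @param correction_window Max distance (bp) a read splice site may be
#'   moved to the nearest evidence site. Default 10.
#' @param end_window Single-linkage gap (bp) for clustering read 5' and
#'   3' ends into TSS/TES clusters. Default 100.
#' @param min_support Minimum supporting reads for a novel isoform, and
#'   for a long-read-only splice site to anchor correction. Default 3.
#' @param filter_subsets Drop novel isoforms fully contained in a
#'   retained isoform (same consecutive junction sub-chain, span inside
#'   its span): suppresses truncation artifacts. Default TRUE.
#' @return List of class `collapse_config`.
#' @export
collapse_config <- function(correction_window = 10L, end_window = 100L,
                            min_support = 3L, filter_subsets = TRUE) {
  structure(list(correction_window = as.integer(correction_window),
                 end_window = as.integer(end_window),
                 min_support = as.integer(min_support),
                 filter_subsets = isTRUE(filter_subsets)),
            class = "collapse_config")
}

.read_junctions <- function(aln) {
  b <- aln$blocks
  n <- nrow(b)
  if (n < 2L)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("donor", "acceptor"))))
  cbind(donor = b[-n, 2], acceptor = b[-1, 1])
}

#' Build the splice-site evidence set
#'
#' Evidence sites are donor (intron start) and acceptor (intron end)
#' positions per chromosome. Annotation and short-read sites are always
#' usable; sites seen only in long reads need `min_support` distinct
#' reads.
#'
#' @param annotation List of `transcript_model` (or NULL).
#' @param short_read data.frame from [read_junction_bed()] (or NULL).
#' @param reads List of genome `read_alignment` (or NULL).
#' @param min_support Long-read-only site support threshold.
#' @return Nested list: chrom -> list(donor = sorted positions,
#'   acceptor = sorted positions).
#' @export
junction_evidence <- function(annotation = NULL, short_read = NULL,
                              reads = NULL, min_support = 3L) {
  don <- list(); acc <- list()
  add <- function(side, chrom, pos) {
    if (side == "donor") don[[chrom]] <<- c(don[[chrom]], pos)
    else acc[[chrom]] <<- c(acc[[chrom]], pos)
  }
  for (tx in annotation) {
    jx <- junction_chain(tx)
    if (nrow(jx)) { add("donor", tx$chrom, jx[, 1]); add("acceptor", tx$chrom, jx[, 2]) }
  }
  if (!is.null(short_read) && nrow(short_read)) {
    for (ch in unique(short_read$chrom)) {
      i <- short_read$chrom == ch
      add("donor", ch, short_read$donor[i])
      add("acceptor", ch, short_read$acceptor[i])
    }
  }
  if (!is.null(reads) && length(reads)) {
    dkey <- character(0); akey <- character(0)
    for (aln in reads) {
      jx <- .read_junctions(aln)
      if (nrow(jx)) {
        dkey <- c(dkey, paste0(aln$target_id, ":", jx[, 1]))
        akey <- c(akey, paste0(aln$target_id, ":", jx[, 2]))
      }
    }
    dt <- table(dkey); at <- table(akey)
    for (k in names(dt)[dt >= min_support]) {
      p <- strsplit(k, ":", fixed = TRUE)[[1]]
      add("donor", p[1], as.integer(p[2]))
    }
    for (k in names(at)[at >= min_support]) {
      p <- strsplit(k, ":", fixed = TRUE)[[1]]
      add("acceptor", p[1], as.integer(p[2]))
    }
  }
  chroms <- union(names(don), names(acc))
  out <- lapply(chroms, function(ch)
    list(donor = sort(unique(don[[ch]])), acceptor = sort(unique(acc[[ch]]))))
  names(out) <- chroms
  out
}

.nearest_site <- function(pos, sites, window) {
  # nearest evidence site within window; ties -> smaller coordinate
  if (length(sites) == 0L) return(NA_integer_)
  d <- abs(sites - pos)
  best <- min(d)
  if (best > window) return(NA_integer_)
  min(sites[d == best])
}

#' Correct read splice sites against the evidence set
#'
#' Each donor/acceptor of each read that is not already an evidence site
#' is moved to the nearest evidence site of the same kind within
#' `correction_window` bp (ties go to the smaller coordinate). Reads with
#' any uncorrectable site are flagged and excluded from model building.
#' Corrected junctions are stored on each read as `$cjx`.
#'
#' @param reads List of genome `read_alignment`.
#' @param evidence From [junction_evidence()].
#' @param cfg A [collapse_config()].
#' @return List with `reads` (corrected, flagged ones removed) and
#'   `flagged` (read ids that could not be corrected).
#' @export
correct_splice_sites <- function(reads, evidence, cfg = collapse_config()) {
  flagged <- character(0)
  out <- list()
  for (aln in reads) {
    jx <- .read_junctions(aln)
    ev <- evidence[[aln$target_id]]
    ok <- TRUE
    if (nrow(jx)) {
      for (i in seq_len(nrow(jx))) {
        d <- .nearest_site(jx[i, 1], ev$donor, cfg$correction_window)
        a <- .nearest_site(jx[i, 2], ev$acceptor, cfg$correction_window)
        if (is.na(d) || is.na(a) || d >= a) { ok <- FALSE; break }
        jx[i, 1] <- d; jx[i, 2] <- a
      }
    }
    if (!ok) { flagged <- c(flagged, aln$read_id); next }
    aln$cjx <- jx
    out[[length(out) + 1L]] <- aln
  }
  list(reads = out, flagged = flagged)
}

#' Group corrected reads by junction chain
#'
#' Multi-exon reads group by exact equality of their corrected junction
#' chain. Single-exon reads form one group per locus, loci being defined
#' by overlap connectivity on each chromosome.
#'
#' @param reads Corrected reads from [correct_splice_sites()].
#' @return List of groups: `chrom`, `jx` (junction matrix; zero rows for
#'   mono-exon groups), `reads` (list of alignments).
#' @export
group_by_junction_chain <- function(reads) {
  multi <- Filter(function(a) nrow(a$cjx) > 0L, reads)
  mono <- Filter(function(a) nrow(a$cjx) == 0L, reads)
  groups <- list()
  if (length(multi)) {
    keys <- vapply(multi, function(a) chain_key(a$target_id, "", a$cjx),
                   character(1))
    for (k in unique(keys)) {
      members <- multi[keys == k]
      groups[[length(groups) + 1L]] <- list(
        chrom = members[[1]]$target_id, jx = members[[1]]$cjx,
        reads = members)
    }
  }
  if (length(mono)) {
    chroms <- vapply(mono, `[[`, character(1), "target_id")
    for (ch in unique(chroms)) {
      ms <- mono[chroms == ch]
      ir <- IRanges::IRanges(vapply(ms, `[[`, integer(1), "start") + 1L,
                             vapply(ms, `[[`, integer(1), "end"))
      red <- IRanges::reduce(ir)
      locus <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
      for (l in unique(locus)) {
        groups[[length(groups) + 1L]] <- list(
          chrom = ch,
          jx = matrix(integer(0), ncol = 2,
                      dimnames = list(NULL, c("donor", "acceptor"))),
          reads = ms[locus == l])
      }
    }
  }
  groups
}

.cluster_1d <- function(pos, gap) {
  # single-linkage clustering: split sorted positions where gap exceeded
  o <- order(pos)
  sp <- pos[o]
  cl <- cumsum(c(1L, as.integer(diff(sp) > gap)))
  cluster <- integer(length(pos))
  cluster[o] <- cl
  cluster
}

.modal_pos <- function(pos, outermost = c("min", "max")) {
  outermost <- match.arg(outermost)
  tb <- table(pos)
  best <- as.integer(names(tb)[tb == max(tb)])
  if (outermost == "min") min(best) else max(best)
}

#' Call transcription start/end sites for one junction-chain group
#'
#' Read 5' starts and 3' ends (genomic left/right) are clustered by
#' single-linkage with gap <= `end_window`; each occupied
#' (start-cluster, end-cluster) pair becomes one first-pass isoform whose
#' TSS/TES are the most-supported position of the pair's reads (ties go
#' outermost).
#'
#' @param group One group from [group_by_junction_chain()].
#' @param cfg A [collapse_config()].
#' @return List of first-pass isoforms: `chrom`, `jx`, `tss`, `tes`,
#'   `read_ids`, `aln_strands`.
#' @export
call_ends <- function(group, cfg = collapse_config()) {
  starts <- vapply(group$reads, `[[`, integer(1), "start")
  ends <- vapply(group$reads, `[[`, integer(1), "end")
  sc <- .cluster_1d(starts, cfg$end_window)
  ec <- .cluster_1d(ends, cfg$end_window)
  out <- list()
  combos <- unique(data.frame(sc = sc, ec = ec))
  combos <- combos[order(combos$sc, combos$ec), , drop = FALSE]
  for (i in seq_len(nrow(combos))) {
    sel <- sc == combos$sc[i] & ec == combos$ec[i]
    tss <- .modal_pos(starts[sel], "min")
    tes <- .modal_pos(ends[sel], "max")
    if (nrow(group$jx) > 0L &&
        (tss >= group$jx[1, 1] || tes <= group$jx[nrow(group$jx), 2]))
      next  # degenerate: ends inside the junction chain
    out[[length(out) + 1L]] <- list(
      chrom = group$chrom, jx = group$jx, tss = tss, tes = tes,
      read_ids = vapply(group$reads[sel], `[[`, character(1), "read_id"),
      aln_strands = vapply(group$reads[sel], `[[`, character(1), "strand"))
  }
  out
}

#' Infer the strand of a junction chain from splice dinucleotides
#'
#' Majority vote of GT..AG (plus) vs CT..AC (minus) intron boundaries;
#' falls back to the majority alignment strand when undecided.
#'
#' @param chrom_seq `DNAString`/character of the chromosome.
#' @param jx Junction matrix.
#' @param fallback_strands Character vector of alignment strands.
#' @return `"+"` or `"-"`.
#' @export
infer_strand <- function(chrom_seq, jx, fallback_strands = "+") {
  score <- 0L
  s <- as.character(chrom_seq)
  if (!is.null(jx) && nrow(jx) > 0L) {
    for (i in seq_len(nrow(jx))) {
      d <- substr(s, jx[i, 1] + 1L, jx[i, 1] + 2L)
      a <- substr(s, jx[i, 2] - 1L, jx[i, 2])
      if (d == "GT" && a == "AG") score <- score + 1L
      if (d == "CT" && a == "AC") score <- score - 1L
    }
  }
  if (score > 0L) return("+")
  if (score < 0L) return("-")
  if (sum(fallback_strands == "-") > length(fallback_strands) / 2) "-" else "+"
}

.firstpass_model <- function(fp, id, strand) {
  jx <- fp$jx
  if (nrow(jx) == 0L) ex <- cbind(fp$tss, fp$tes)
  else ex <- cbind(c(fp$tss, jx[, 2]), c(jx[, 1], fp$tes))
  transcript_model(id, paste0("locus_", fp$chrom, "_", fp$tss),
                   fp$chrom, strand, ex, source = "novel")
}

#' Build first-pass isoform models for all groups
#'
#' @param groups From [group_by_junction_chain()].
#' @param genome Named `DNAStringSet`/character (strand inference).
#' @param cfg A [collapse_config()].
#' @return List of records: `tx` (a novel `transcript_model`),
#'   `read_ids`.
#' @export
build_firstpass <- function(groups, genome, cfg = collapse_config()) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  out <- list()
  for (g in groups) {
    for (fp in call_ends(g, cfg)) {
      strand <- infer_strand(genome[[fp$chrom]], fp$jx, fp$aln_strands)
      id <- sprintf("fp_%s_%d_%d_%d", fp$chrom, fp$tss, fp$tes,
                    nrow(fp$jx))
      out[[length(out) + 1L]] <- list(
        tx = .firstpass_model(fp, id, strand), read_ids = fp$read_ids)
    }
  }
  out
}

.is_subchain <- function(sub, full) {
  # is `sub` a consecutive run of `full`'s junctions?
  if (nrow(sub) == 0L) return(TRUE)
  if (nrow(sub) > nrow(full)) return(FALSE)
  key_s <- paste(sub[, 1], sub[, 2], sep = "-")
  key_f <- paste(full[, 1], full[, 2], sep = "-")
  for (off in 0:(length(key_f) - length(key_s))) {
    if (all(key_f[off + seq_along(key_s)] == key_s)) return(TRUE)
  }
  FALSE
}

#' Re-assign reads to first-pass isoforms under the fidelity rules
#'
#' A read is compatible with a first-pass isoform when its corrected
#' junction chain is a consecutive sub-chain of the isoform's chain and
#' its aligned span stays inside the isoform's exons (overhang past the
#' isoform's ends is treated as clipped). Compatible candidates are
#' checked with the stringent and splice rules evaluated in genome
#' coordinates; among passing candidates the read supports the one
#' covering the most isoform bases (ties by transcript id).
#'
#' @param reads Corrected genome `read_alignment` list (the unassigned
#'   read set).
#' @param firstpass From [build_firstpass()].
#' @param fcfg A [fidelity_config()].
#' @return List with `supports` (named list isoform id -> read ids) and
#'   `unassigned` (read ids supporting no model).
#' @export
assign_to_firstpass <- function(reads, firstpass, fcfg = fidelity_config()) {
  supports <- lapply(firstpass, function(x) character(0))
  names(supports) <- vapply(firstpass, function(x) x$tx$transcript_id,
                            character(1))
  unassigned <- character(0)
  for (aln in reads) {
    jx <- if (!is.null(aln$cjx)) aln$cjx else .read_junctions(aln)
    best <- NULL; best_cov <- -1L
    for (fp in firstpass) {
      tx <- fp$tx
      if (tx$chrom != aln$target_id) next
      fjx <- junction_chain(tx)
      if (!.is_subchain(jx, fjx)) next
      if (nrow(jx) == 0L) {
        inside <- any(aln$start >= tx$exons[, 1] - fcfg$end_span_bp &
                        aln$end <= tx$exons[, 2] + fcfg$end_span_bp)
        if (!inside) next
      }
      if (!.check_stringent_genomic(aln, tx, fcfg)) next
      if (!.check_splice_genomic(aln, fjx, fcfg)) next
      cov <- .exonic_coverage(aln, tx)
      # ties: prefer the fuller model, then lexicographic id
      txlen <- tx_length(tx)
      better <- cov > best_cov ||
        (cov == best_cov && !is.null(best) &&
           (txlen > tx_length(best$tx) ||
              (txlen == tx_length(best$tx) &&
                 tx$transcript_id < best$tx$transcript_id)))
      if (better) { best <- fp; best_cov <- cov }
    }
    if (is.null(best)) unassigned <- c(unassigned, aln$read_id)
    else supports[[best$tx$transcript_id]] <-
        c(supports[[best$tx$transcript_id]], aln$read_id)
  }
  list(supports = supports, unassigned = unassigned)
}

.exonic_coverage <- function(aln, tx) {
  cov <- 0L
  for (i in seq_len(nrow(aln$blocks))) {
    s <- aln$blocks[i, 1]; e <- aln$blocks[i, 2]
    o <- pmin(e, tx$exons[, 2]) - pmax(s, tx$exons[, 1])
    cov <- cov + sum(o[o > 0L])
  }
  cov
}

.check_stringent_genomic <- function(aln, tx, fcfg) {
  tot <- aln_op_totals(aln)
  aligned <- tot[["match"]] + tot[["mismatch"]] + tot[["insertion"]]
  if (aligned == 0L) return(FALSE)
  if (tot[["match"]] / aligned < fcfg$min_identity) return(FALSE)
  # uncovered bases of the terminal exons (genomic left/right);
  # overhang beyond the model is treated as clipped, not as missing span
  n <- nrow(tx$exons)
  missL <- max(0L, min(aln$start, tx$exons[1, 2]) - tx$exons[1, 1])
  missR <- max(0L, tx$exons[n, 2] - max(aln$end, tx$exons[n, 1]))
  lenL <- tx$exons[1, 2] - tx$exons[1, 1]
  lenR <- tx$exons[n, 2] - tx$exons[n, 1]
  missL <= min(fcfg$end_span_bp, lenL) && missR <= min(fcfg$end_span_bp, lenR)
}

.check_splice_genomic <- function(aln, fjx, fcfg) {
  fl <- fcfg$splice_flank_bp
  if (nrow(fjx) == 0L) return(TRUE)
  rjx <- if (!is.null(aln$cjx)) aln$cjx else .read_junctions(aln)
  for (i in seq_len(nrow(fjx))) {
    hit <- nrow(rjx) > 0L && any(rjx[, 1] == fjx[i, 1] & rjx[, 2] == fjx[i, 2])
    if (!hit) next  # junction not spanned by the read
    wins <- c((fjx[i, 1] - fl):(fjx[i, 1] - 1L),
              fjx[i, 2]:(fjx[i, 2] + fl - 1L))
    states <- aln_match_profile(aln, wins)
    if (sum(states == "match") < fcfg$min_flank_matches) return(FALSE)
    ops <- aln$ops
    big <- ops$kind %in% c("insertion", "deletion") &
      ops$len > fcfg$max_splice_indel_bp
    if (any(big)) {
      lo1 <- fjx[i, 1] - fl; hi1 <- fjx[i, 1]
      lo2 <- fjx[i, 2]; hi2 <- fjx[i, 2] + fl
      ov <- function(lo, hi) (ops$kind == "deletion" & big &
                                ops$tpos < hi & ops$tpos + ops$len > lo) |
        (ops$kind == "insertion" & big & ops$tpos > lo & ops$tpos < hi)
      if (any(ov(lo1, hi1)) || any(ov(lo2, hi2))) return(FALSE)
    }
  }
  TRUE
}

#' Merge supported annotated and novel isoforms into the final set
#'
#' Novel isoforms need `min_support` reads; a novel chain identical to a
#' retained annotated isoform collapses into the annotated entry (read
#' sets merged). With `filter_subsets` on, novel isoforms fully contained
#' in a retained isoform (consecutive junction sub-chain, span inside)
#' are removed as truncation artifacts; mono-exon novels contained in any
#' retained isoform's exon are likewise removed.
#'
#' @param firstpass From [build_firstpass()].
#' @param fp_supports `supports` from [assign_to_firstpass()].
#' @param annotated Records from [supported_annotated_isoforms()].
#' @param cfg A [collapse_config()].
#' @return List of records `tx`, `support`, `read_ids`, sorted by
#'   chromosome and start.
#' @export
finalize_isoforms <- function(firstpass, fp_supports, annotated,
                              cfg = collapse_config()) {
  final <- annotated
  ann_keys <- vapply(annotated, function(r)
    chain_key(r$tx$chrom, "", junction_chain(r$tx)), character(1))
  novel <- list()
  for (fp in firstpass) {
    rids <- fp_supports[[fp$tx$transcript_id]]
    if (length(rids) < cfg$min_support) next
    key <- chain_key(fp$tx$chrom, "", junction_chain(fp$tx))
    hit <- which(ann_keys == key)
    if (length(hit)) {
      # identical chain: for mono-exon require span overlap too
      ok <- nrow(junction_chain(fp$tx)) > 0L
      if (!ok) {
        a <- final[[hit[1]]]$tx
        ok <- fp$tx$exons[1, 1] < a$exons[nrow(a$exons), 2] &&
          a$exons[1, 1] < fp$tx$exons[1, 2]
      }
      if (ok) {
        final[[hit[1]]]$read_ids <- union(final[[hit[1]]]$read_ids, rids)
        final[[hit[1]]]$support <- length(final[[hit[1]]]$read_ids)
        next
      }
    }
    novel[[length(novel) + 1L]] <- list(tx = fp$tx, support = length(rids),
                                        read_ids = rids)
  }
  if (cfg$filter_subsets && length(novel)) {
    keep <- rep(TRUE, length(novel))
    hosts <- c(final, novel)
    for (i in seq_along(novel)) {
      ntx <- novel[[i]]$tx
      njx <- junction_chain(ntx)
      span <- c(ntx$exons[1, 1], ntx$exons[nrow(ntx$exons), 2])
      for (h in hosts) {
        htx <- h$tx
        if (identical(htx$transcript_id, ntx$transcript_id)) next
        if (htx$chrom != ntx$chrom) next
        hjx <- junction_chain(htx)
        if (nrow(njx) >= nrow(hjx) && nrow(hjx) > 0L && nrow(njx) > 0L &&
            identical(dim(njx), dim(hjx)) && all(njx == hjx)) next
        if (nrow(njx) == 0L) {
          contained <- any(span[1] >= htx$exons[, 1] &
                             span[2] <= htx$exons[, 2])
          if (contained) { keep[i] <- FALSE; break }
        } else if (nrow(njx) < nrow(hjx) && .is_subchain(njx, hjx) &&
                   span[1] >= htx$exons[1, 1] &&
                   span[2] <= htx$exons[nrow(htx$exons), 2]) {
          keep[i] <- FALSE; break
        }
      }
    }
    novel <- novel[keep]
  }
  final <- c(final, novel)
  ord <- order(vapply(final, function(r) r$tx$chrom, character(1)),
               vapply(final, function(r) r$tx$exons[1, 1], integer(1)),
               vapply(final, function(r) r$tx$transcript_id, character(1)))
  final[ord]
}
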