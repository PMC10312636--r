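#' Candidate A-to-I edit sites from variant calls and known sites
#'
#' A-to-I editing reads as A>G on the plus strand and T>C on the minus
#' strand at the genome level. Candidates are the union of matching SNV
#' records and an optional user-supplied known-sites BED; the strand is
#' resolved from the host gene's annotation, and positions overlapping no
#' gene (or genes on both strands) are skipped.
#'
#' @param variants List of `variant_record` (SNVs).
#' @param genes Gene -> transcripts mapping as from [read_gtf()], or a
#'   flat list of `transcript_model`.
#' @param known_sites Optional data.frame (chrom, start, end, ...) of
#'   known editing positions (one site per row, `start` 0-based).
#' @return data.frame: chrom, pos0, strand, ref_base, known; sorted.
#' @export
edit_candidates <- function(variants, genes, known_sites = NULL) {
  txs <- if (length(genes) && !inherits(genes[[1]], "transcript_model"))
    flatten_transcripts(genes) else genes
  strand_at <- function(chrom, pos) {
    hit <- unique(vapply(Filter(function(tx)
      tx$chrom == chrom && pos >= tx$exons[1, 1] &&
        pos < tx$exons[nrow(tx$exons), 2], txs),
      `[[`, character(1), "strand"))
    if (length(hit) == 1L) hit else NA_character_
  }
  rows <- list()
  for (v in variants) {
    edit_like <- (v$ref_allele == "A" && v$alt_allele == "G") ||
      (v$ref_allele == "T" && v$alt_allele == "C")
    if (!edit_like) next
    sr <- strand_at(v$chrom, v$pos0)
    if (is.na(sr)) next
    if ((sr == "+" && v$ref_allele != "A") ||
        (sr == "-" && v$ref_allele != "T")) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = v$chrom, pos0 = v$pos0, strand = sr, ref_base = v$ref_allele,
      known = FALSE, stringsAsFactors = FALSE)
  }
  if (!is.null(known_sites) && nrow(known_sites)) {
    for (i in seq_len(nrow(known_sites))) {
      ch <- known_sites$chrom[i]; p <- known_sites$start[i]
      sr <- strand_at(ch, p)
      if (is.na(sr)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, pos0 = p, strand = sr,
        ref_base = if (sr == "+") "A" else "T", known = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), pos0 = integer(0),
                      strand = character(0), ref_base = character(0),
                      known = logical(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$pos0), , drop = FALSE]
  key <- paste(df$chrom, df$pos0)
  known_any <- tapply(df$known, key, any)
  df <- df[!duplicated(key), , drop = FALSE]
  df$known <- as.logical(known_any[paste(df$chrom, df$pos0)])
  rownames(df) <- NULL
  df
}

#' Editing state of one read at one site
#'
#' @param aln Genome `read_alignment`.
#' @param pos0 Site position.
#' @param strand Gene strand of the site.
#' @return One of `"ref"`, `"edit"`, `"other"`, `"deleted"`, `"spliced"`,
#'   `"uncovered"`.
#' @export
edit_state_at <- function(aln, pos0, strand) {
  st <- aln_state_at(aln, pos0)
  edit_base <- if (strand == "+") "G" else "C"
  switch(st$state,
         match = "ref",
         mismatch = if (identical(st$base, edit_base)) "edit" else "other",
         deletion = "deleted",
         intron = "spliced",
         "uncovered")
}

.edit_state_matrix <- function(reads, sites) {
  m <- matrix(NA_character_, nrow = length(reads), ncol = nrow(sites))
  if (length(reads)) rownames(m) <- vapply(reads, `[[`, character(1), "read_id")
  for (i in seq_along(reads)) {
    aln <- reads[[i]]
    hit <- which(sites$chrom == aln$target_id & sites$pos0 >= aln$start &
                   sites$pos0 < aln$end)
    for (j in hit)
      m[i, j] <- edit_state_at(aln, sites$pos0[j], sites$strand[j])
  }
  m
}

#' Strand-aware pileup of edit counts per condition
#'
#' Per site and condition, counts reads carrying the strand-appropriate
#' reference base (A on +, T on -) vs the edited base (G/C). Other bases
#' and deletions are counted separately and excluded from the fraction
#' denominator; spliced-out positions are counted as `spliced`.
#'
#' @param reads_by_condition Named list: condition -> genome
#'   `read_alignment` list.
#' @param sites Candidate data.frame from [edit_candidates()].
#' @return `sites` with per-condition columns `ref_<cond>`,
#'   `edit_<cond>`, `other_<cond>`, `spliced_<cond>` and
#'   `frac_<cond>` (= edit / (ref + edit), NA when uncovered).
#' @export
pileup_edit_counts <- function(reads_by_condition, sites) {
  out <- sites
  for (cond in names(reads_by_condition)) {
    m <- .edit_state_matrix(reads_by_condition[[cond]], sites)
    cnt <- function(s) if (nrow(m)) colSums(m == s, na.rm = TRUE) else
      rep(0L, nrow(sites))
    r <- cnt("ref"); e <- cnt("edit")
    out[[paste0("ref_", cond)]] <- r
    out[[paste0("edit_", cond)]] <- e
    out[[paste0("other_", cond)]] <- cnt("other") + cnt("deleted")
    out[[paste0("spliced_", cond)]] <- cnt("spliced")
    out[[paste0("frac_", cond)]] <- ifelse(r + e > 0, e / (r + e), NA_real_)
  }
  out
}

#' Differential editing between two pooled conditions
#'
#' Sites are retained when the larger of the two coverages reaches
#' `min_cov`, the edit-fraction change reaches `min_delta`, and the
#' two-sided Fisher's exact test on the edited/reference counts is below
#' `alpha`. Direction is `"down"` when the knockdown fraction is below
#' the control fraction.
#'
#' @param pileup Result of [pileup_edit_counts()] with both conditions.
#' @param control,knockdown Condition names.
#' @param min_cov Minimum coverage in either condition (inclusive).
#' @param min_delta Minimum |fraction change| (inclusive).
#' @param alpha Raw p-value threshold (strict).
#' @param type1_threshold Threshold for the `type1_in_control` flag.
#' @return data.frame of significant sites with delta, p, direction,
#'   type1_in_control.
#' @export
differential_editing <- function(pileup, control = "control",
                                 knockdown = "knockdown", min_cov = 10L,
                                 min_delta = 0.10, alpha = 0.05,
                                 type1_threshold = 0.40) {
  rc <- pileup[[paste0("ref_", control)]]
  ec <- pileup[[paste0("edit_", control)]]
  rk <- pileup[[paste0("ref_", knockdown)]]
  ek <- pileup[[paste0("edit_", knockdown)]]
  covc <- rc + ec; covk <- rk + ek
  fc <- ifelse(covc > 0, ec / covc, NA_real_)
  fk <- ifelse(covk > 0, ek / covk, NA_real_)
  keep <- pmax(covc, covk) >= min_cov & !is.na(fc) & !is.na(fk) &
    abs(fc - fk) >= min_delta
  idx <- which(keep)
  p <- vapply(idx, function(i)
    fisher_exact_two_sided(ec[i], rc[i], ek[i], rk[i]), numeric(1))
  sig <- p < alpha
  res <- pileup[idx[sig], c("chrom", "pos0", "strand", "ref_base", "known"),
                drop = FALSE]
  res$frac_control <- fc[idx[sig]]
  res$frac_knockdown <- fk[idx[sig]]
  res$delta <- fc[idx[sig]] - fk[idx[sig]]
  res$p <- p[sig]
  res$direction <- ifelse(fk[idx[sig]] < fc[idx[sig]], "down", "up")
  res$type1_in_control <- fc[idx[sig]] > type1_threshold
  rownames(res) <- NULL
  res
}

#' Type I hyperediting at a single base
#'
#' @param ref_n,edit_n Reference/edited read counts in one condition.
#' @param threshold Strict threshold; a site is type I when the edited
#'   fraction exceeds it. Default 0.40.
#' @return Logical. Errors on an uncovered site.
#' @export
classify_type1 <- function(ref_n, edit_n, threshold = 0.40) {
  if (ref_n + edit_n == 0) stop("uncovered site")
  edit_n / (ref_n + edit_n) > threshold
}

#' Detect type II hyperediting regions
#'
#' Finds maximal regions in which every member edit belongs to some
#' window of `window` bp containing at least `min_edits` edits;
#' qualifying windows sharing a member are merged.
#'
#' @param positions Sorted (or sortable) integer edit positions on one
#'   chromosome/strand.
#' @param window Window size in bp. Default 150.
#' @param min_edits Minimum edits per window (inclusive). Default 3.
#' @return data.frame: start, end (half-open, = min/max member
#'   position + 1), n_edits; plus a `members` list-column.
#' @export
detect_type2_regions <- function(positions, window = 150L, min_edits = 3L) {
  pos <- sort(unique(as.integer(positions)))
  n <- length(pos)
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_edits = integer(0))
  empty$members <- list()
  if (n < min_edits) return(empty)
  # qualifying index intervals: i..j with pos[j] - pos[i] < window,
  # j maximal, and at least min_edits members
  iv <- list()
  for (i in seq_len(n)) {
    j <- max(which(pos - pos[i] < window))
    if (j - i + 1L >= min_edits) iv[[length(iv) + 1L]] <- c(i, j)
  }
  if (length(iv) == 0L) return(empty)
  iv <- do.call(rbind, iv)
  # merge intervals sharing >= 1 member index
  ord <- order(iv[, 1])
  iv <- iv[ord, , drop = FALSE]
  merged <- list(iv[1, ])
  for (r in seq_len(nrow(iv))[-1]) {
    last <- merged[[length(merged)]]
    if (iv[r, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], iv[r, 2]))
    } else merged[[length(merged) + 1L]] <- iv[r, ]
  }
  out <- data.frame(
    start = vapply(merged, function(x) pos[x[1]], integer(1)),
    end = vapply(merged, function(x) pos[x[2]] + 1L, integer(1)),
    n_edits = vapply(merged, function(x) x[2] - x[1] + 1L, integer(1)))
  out$members <- lapply(merged, function(x) pos[x[1]:x[2]])
  out
}

#' Per-read editing summary
#'
#' Among reads overlapping at least one candidate site, the fraction
#' carrying at least one edit; among edited reads, the fraction carrying
#' more than one edit.
#'
#' @param reads Genome `read_alignment` list.
#' @param sites Candidate data.frame.
#' @return List: frac_reads_edited, frac_edited_multi, n_reads,
#'   n_edited, multi_defined (FALSE when no read is edited; the multi
#'   fraction is then reported as 0).
#' @export
summarize_read_editing <- function(reads, sites) {
  m <- .edit_state_matrix(reads, sites)
  overlaps <- rowSums(!is.na(m)) > 0
  m <- m[overlaps, , drop = FALSE]
  n <- nrow(m)
  if (n == 0L)
    return(list(frac_reads_edited = 0, frac_edited_multi = 0, n_reads = 0L,
                n_edited = 0L, multi_defined = FALSE))
  edits <- rowSums(m == "edit", na.rm = TRUE)
  n_ed <- sum(edits >= 1L)
  list(frac_reads_edited = n_ed / n,
       frac_edited_multi = if (n_ed > 0) sum(edits >= 2L) / n_ed else 0,
       n_reads = n, n_edited = n_ed, multi_defined = n_ed > 0)
}

#' Single-molecule edit-edit coordination test
#'
#' For each site, its `k_nearest` nearest candidate sites (both
#' directions, same chromosome) at genomic distance >= `min_distance`
#' are paired with it; for each unordered pair, reads covering both
#' sites exonically form a 2x2 table (both edited / only first / only
#' second / neither) tested with Fisher's exact test.
#'
#' @param sites Candidate data.frame.
#' @param reads Genome `read_alignment` list.
#' @param k_nearest Partners per site. Default 20.
#' @param min_distance Minimum pair distance in bp (inclusive).
#'   Default 50.
#' @param alpha Raw p threshold for the `significant` flag. Default 0.05.
#' @return data.frame: chrom, pos1, pos2, both, only1, only2, neither,
#'   n, p, p_adj, significant — one row per tested pair.
#' @export
edit_edit_coordination <- function(sites, reads, k_nearest = 20L,
                                   min_distance = 50L, alpha = 0.05) {
  empty <- data.frame(chrom = character(0), pos1 = integer(0),
                      pos2 = integer(0), both = integer(0),
                      only1 = integer(0), only2 = integer(0),
                      neither = integer(0), n = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(sites) < 2L) return(empty)
  m <- .edit_state_matrix(reads, sites)
  pairs <- character(0)
  plist <- list()
  for (i in seq_len(nrow(sites))) {
    same <- which(sites$chrom == sites$chrom[i])
    d <- abs(sites$pos0[same] - sites$pos0[i])
    cand <- same[d >= min_distance]
    if (length(cand) == 0L) next
    dc <- abs(sites$pos0[cand] - sites$pos0[i])
    cand <- cand[order(dc, sites$pos0[cand])]
    cand <- utils::head(cand, k_nearest)
    for (j in cand) {
      key <- paste(min(i, j), max(i, j))
      if (key %in% pairs) next
      pairs <- c(pairs, key)
      plist[[length(plist) + 1L]] <- c(min(i, j), max(i, j))
    }
  }
  rows <- list()
  for (pr in plist) {
    i <- pr[1]; j <- pr[2]
    ok <- m[, i] %in% c("ref", "edit") & m[, j] %in% c("ref", "edit")
    if (sum(ok) < 1L) next
    e1 <- m[ok, i] == "edit"; e2 <- m[ok, j] == "edit"
    a <- sum(e1 & e2); b <- sum(e1 & !e2)
    cc <- sum(!e1 & e2); d <- sum(!e1 & !e2)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = sites$chrom[i], pos1 = sites$pos0[i], pos2 = sites$pos0[j],
      both = a, only1 = b, only2 = cc, neither = d, n = a + b + cc + d,
      p = fisher_exact_two_sided(a, b, cc, d), p_adj = NA_real_,
      significant = NA, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p < alpha
  out
}

#' Mutually exclusive editing and splicing at single sites
#'
#' Reports sites that are type I hyperedited among exonically covering
#' reads, with at least `min_edited_reads` edited reads and at least
#' `min_spliced_reads` reads carrying the position inside a spliced-out
#' intron.
#'
#' @param sites Candidate data.frame.
#' @param reads Genome `read_alignment` list.
#' @param type1_threshold Strict edited-fraction threshold. Default 0.40.
#' @param min_edited_reads,min_spliced_reads Inclusive thresholds.
#'   Default 10 each.
#' @return data.frame: chrom, pos0, strand, ref_n, edit_n, spliced_n,
#'   edit_frac.
#' @export
edit_intron_coordination <- function(sites, reads, type1_threshold = 0.40,
                                     min_edited_reads = 10L,
                                     min_spliced_reads = 10L) {
  m <- .edit_state_matrix(reads, sites)
  rows <- list()
  for (j in seq_len(nrow(sites))) {
    r <- sum(m[, j] == "ref", na.rm = TRUE)
    e <- sum(m[, j] == "edit", na.rm = TRUE)
    s <- sum(m[, j] == "spliced", na.rm = TRUE)
    if (r + e == 0) next
    if (e / (r + e) <= type1_threshold) next
    if (e < min_edited_reads || s < min_spliced_reads) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = sites$chrom[j], pos0 = sites$pos0[j],
      strand = sites$strand[j], ref_n = r, edit_n = e, spliced_n = s,
      edit_frac = e / (r + e), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), pos0 = integer(0),
                      strand = character(0), ref_n = integer(0),
                      edit_n = integer(0), spliced_n = integer(0),
                      edit_frac = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
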