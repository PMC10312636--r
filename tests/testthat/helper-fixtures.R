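# In-code fixture builders and independent oracles shared by the tests.

# Build a read_alignment directly from an ops table.
# ops: list of c(kind, len, tpos) or c(kind, len, tpos, base)
make_aln <- function(read_id, target_id, ops, target_kind = "transcript",
                     mapq = 60L, strand = "+", hp = NA_integer_,
                     ps = NA_character_, secondary = FALSE) {
  df <- do.call(rbind, lapply(ops, function(o)
    data.frame(kind = o[[1]], len = as.integer(o[[2]]),
               tpos = as.integer(o[[3]]),
               qpos = NA_integer_,
               base = if (length(o) >= 4) o[[4]] else NA_character_,
               stringsAsFactors = FALSE)))
  qp <- 0L
  for (i in seq_len(nrow(df))) {
    df$qpos[i] <- qp
    if (df$kind[i] %in% c("match", "mismatch", "insertion"))
      qp <- qp + df$len[i]
  }
  cons <- df$kind %in% c("match", "mismatch", "deletion")
  bl_st <- integer(0); bl_en <- integer(0); cur_s <- NA; cur_e <- NA
  for (i in seq_len(nrow(df))) {
    if (df$kind[i] == "intron") {
      if (!is.na(cur_s)) { bl_st <- c(bl_st, cur_s); bl_en <- c(bl_en, cur_e) }
      cur_s <- NA
    } else if (cons[i]) {
      if (is.na(cur_s)) cur_s <- df$tpos[i]
      cur_e <- df$tpos[i] + df$len[i]
    }
  }
  if (!is.na(cur_s)) { bl_st <- c(bl_st, cur_s); bl_en <- c(bl_en, cur_e) }
  structure(list(read_id = read_id, target_id = target_id,
                 target_kind = target_kind, strand = strand, mapq = mapq,
                 secondary = secondary, hp = hp, ps = ps,
                 start = min(bl_st), end = max(bl_en),
                 blocks = cbind(start = bl_st, end = bl_en), ops = df),
            class = "read_alignment")
}

# Independent Fisher oracle: direct binomial-coefficient enumeration.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c; N <- m + n2
  if (m == 0 || n2 == 0 || k == 0 || k == N) return(1)
  xs <- max(0, k - n2):min(k, m)
  probs <- choose(m, xs) * choose(n2, k - xs) / choose(N, k)
  sum(probs[probs <= probs[xs == a] * (1 + 1e-7)])
}

# Independent type II oracle: enumerate every possible window start and
# count members by binary search.
oracle_type2 <- function(positions, window = 150L, min_edits = 3L) {
  pos <- sort(unique(as.integer(positions)))
  if (length(pos) < min_edits)
    return(data.frame(start = integer(0), end = integer(0),
                      n_edits = integer(0)))
  starts <- (min(pos) - window + 1L):max(pos)
  lo <- findInterval(starts - 0.5, pos)        # members are lo+1 .. hi
  hi <- findInterval(starts + window - 0.5, pos)
  ok <- (hi - lo) >= min_edits
  if (!any(ok))
    return(data.frame(start = integer(0), end = integer(0),
                      n_edits = integer(0)))
  iv <- unique(cbind(lo[ok] + 1L, hi[ok]))
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  merged <- list(iv[1, ])
  for (r in seq_len(nrow(iv))[-1]) {
    last <- merged[[length(merged)]]
    if (iv[r, 1] <= last[2])
      merged[[length(merged)]] <- c(last[1], max(last[2], iv[r, 2]))
    else merged[[length(merged) + 1L]] <- iv[r, ]
  }
  data.frame(start = vapply(merged, function(x) pos[x[1]], integer(1)),
             end = vapply(merged, function(x) pos[x[2]] + 1L, integer(1)),
             n_edits = vapply(merged, function(x) x[2] - x[1] + 1L,
                              integer(1)))
}

# Genome read covering [span) on chr1 with edited (mismatch) bases at
# given positions; `intron` marks a spliced-out [lo, hi) stretch.
ed_read <- function(id, span, edits = integer(0), intron = NULL,
                    other = integer(0), dels = integer(0),
                    edit_base = "G") {
  ops <- list()
  cur <- span[1]
  add_to <- function(to) {
    pts <- sort(c(edits[edits >= cur & edits < to],
                  other[other >= cur & other < to],
                  dels[dels >= cur & dels < to]))
    for (p in pts) {
      if (p > cur) ops[[length(ops) + 1L]] <<- c("match", p - cur, cur)
      if (p %in% dels) ops[[length(ops) + 1L]] <<- c("deletion", 1, p)
      else if (p %in% other) ops[[length(ops) + 1L]] <<- c("mismatch", 1, p, "N")
      else ops[[length(ops) + 1L]] <<- c("mismatch", 1, p, edit_base)
      cur <<- p + 1L
    }
    if (to > cur) ops[[length(ops) + 1L]] <<- c("match", to - cur, cur)
    cur <<- to
  }
  if (!is.null(intron)) {
    add_to(intron[1])
    ops[[length(ops) + 1L]] <- c("intron", intron[2] - intron[1], intron[1])
    cur <- intron[2]
  }
  add_to(span[2])
  make_aln(id, "chr1", ops, target_kind = "genome")
}

site_df <- function(pos, strand = "+") {
  data.frame(chrom = "chr1", pos0 = as.integer(pos), strand = strand,
             ref_base = ifelse(strand == "+", "A", "T"), known = FALSE,
             stringsAsFactors = FALSE)
}

# Minimal GTF writer for raw-line fixtures.
write_gtf_lines <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_exon_line <- function(chrom, start1, end1, strand, gid, tid,
                          attrs = sprintf('gene_id "%s"; transcript_id "%s";',
                                          gid, tid)) {
  paste(chrom, "test", "exon", start1, end1, ".", strand, ".", attrs,
        sep = "\t")
}
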