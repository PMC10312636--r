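#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag
NULL

.parse_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(toks) == 0L) stop("unparseable CIGAR: ", cigar)
  list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
       op = substr(toks, nchar(toks), nchar(toks)))
}

.parse_md <- function(md) {
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  out <- list()
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      n <- as.integer(t)
      if (n > 0L) out[[length(out) + 1L]] <- c("match", n)
    } else if (startsWith(t, "^")) {
      out[[length(out) + 1L]] <- c("del", nchar(t) - 1L)
    } else {
      out[[length(out) + 1L]] <- c("mismatch", 1L)
    }
  }
  out
}

#' Decode one alignment record into per-base edit operations
#'
#' Resolves mismatch positions from the MD tag (or from extended `=`/`X`
#' CIGAR operations). Soft clips are excluded from the operations but
#' shift query offsets; `N` becomes an `intron` op.
#'
#' @param cigar CIGAR string.
#' @param md MD tag value or `NA`.
#' @param seq Read sequence (SAM orientation) or `NA`.
#' @param pos0 0-based leftmost target position.
#' @return List with `ops` (data.frame kind/len/tpos/qpos/base) and
#'   `blocks` (target intervals split at introns, 0-based half-open).
#' @export
decode_alignment <- function(cigar, md, seq, pos0) {
  cg <- .parse_cigar(cigar)
  # extended-op dialect (=/X) resolves mismatches in the CIGAR itself;
  # otherwise M runs need the MD tag
  extended <- any(cg$op %in% c("=", "X"))
  md_ev <- NULL
  if (any(cg$op == "M") && !extended) {
    if (is.na(md) || !nzchar(md))
      stop("cannot resolve mismatches: CIGAR has M ops but no MD tag")
    md_ev <- .parse_md(md)
  }
  md_i <- 1L
  md_left <- if (length(md_ev)) as.integer(md_ev[[1]][2]) else 0L
  take_md <- function(n) {
    # consume n reference bases of match/mismatch events
    runs <- list()
    while (n > 0L) {
      if (md_i > length(md_ev)) stop("MD tag shorter than CIGAR")
      ev <- md_ev[[md_i]]
      if (ev[1] == "del") { md_i <<- md_i + 1L
        md_left <<- if (md_i <= length(md_ev)) as.integer(md_ev[[md_i]][2]) else 0L
        next }
      use <- min(n, md_left)
      runs[[length(runs) + 1L]] <- c(ev[1], use)
      md_left <<- md_left - use
      n <- n - use
      if (md_left == 0L) { md_i <<- md_i + 1L
        md_left <<- if (md_i <= length(md_ev)) as.integer(md_ev[[md_i]][2]) else 0L }
    }
    runs
  }
  skip_md_del <- function(n) {
    while (n > 0L && md_i <= length(md_ev)) {
      ev <- md_ev[[md_i]]
      if (ev[1] != "del") break
      n <- n - as.integer(ev[2])
      md_i <<- md_i + 1L
      md_left <<- if (md_i <= length(md_ev)) as.integer(md_ev[[md_i]][2]) else 0L
    }
  }
  kind <- character(0); len <- integer(0); tpos <- integer(0)
  qpos <- integer(0); base <- character(0)
  emit <- function(k, l, tp, qp, b = NA_character_) {
    kind[length(kind) + 1L] <<- k; len[length(len) + 1L] <<- l
    tpos[length(tpos) + 1L] <<- tp; qpos[length(qpos) + 1L] <<- qp
    base[length(base) + 1L] <<- b
  }
  tp <- as.integer(pos0); qp <- 0L
  seq_chr <- if (is.na(seq)) NULL else as.character(seq)
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; l <- cg$len[i]
    if (op %in% c("S")) { qp <- qp + l
    } else if (op == "H" || op == "P") {
    } else if (op == "I") { emit("insertion", l, tp, qp); qp <- qp + l
    } else if (op == "D") { emit("deletion", l, tp, qp); skip_md_del(l); tp <- tp + l
    } else if (op == "N") { emit("intron", l, tp, qp); tp <- tp + l
    } else if (op == "=") { emit("match", l, tp, qp); tp <- tp + l; qp <- qp + l
    } else if (op == "X") {
      for (j in seq_len(l)) {
        b <- if (!is.null(seq_chr)) substr(seq_chr, qp + j, qp + j) else NA_character_
        emit("mismatch", 1L, tp + j - 1L, qp + j - 1L, b)
      }
      tp <- tp + l; qp <- qp + l
    } else if (op == "M" && extended) {
      emit("match", l, tp, qp); tp <- tp + l; qp <- qp + l
    } else if (op == "M") {
      for (r in take_md(l)) {
        rl <- as.integer(r[2])
        if (r[1] == "match") { emit("match", rl, tp, qp); tp <- tp + rl; qp <- qp + rl
        } else {
          for (j in seq_len(rl)) {
            b <- if (!is.null(seq_chr)) substr(seq_chr, qp + 1L, qp + 1L) else NA_character_
            emit("mismatch", 1L, tp, qp, b)
            tp <- tp + 1L; qp <- qp + 1L
          }
        }
      }
    } else stop("unsupported CIGAR op: ", op)
  }
  ops <- data.frame(kind = kind, len = len, tpos = tpos, qpos = qpos,
                    base = base, stringsAsFactors = FALSE)
  # blocks: target-consuming stretches split at introns
  consuming <- ops$kind %in% c("match", "mismatch", "deletion")
  bl_st <- integer(0); bl_en <- integer(0)
  cur_s <- NA_integer_; cur_e <- NA_integer_
  for (i in seq_len(nrow(ops))) {
    if (ops$kind[i] == "intron") {
      if (!is.na(cur_s)) { bl_st <- c(bl_st, cur_s); bl_en <- c(bl_en, cur_e) }
      cur_s <- NA_integer_
    } else if (consuming[i]) {
      if (is.na(cur_s)) cur_s <- ops$tpos[i]
      cur_e <- ops$tpos[i] + ops$len[i]
    }
  }
  if (!is.na(cur_s)) { bl_st <- c(bl_st, cur_s); bl_en <- c(bl_en, cur_e) }
  list(ops = ops, blocks = cbind(start = bl_st, end = bl_en))
}

#' Read long-read alignments from SAM or BAM
#'
#' SAM input is converted with [Rsamtools::asBam()] on the fly. Unmapped
#' records are dropped; secondary/supplementary records are retained and
#' flagged. Per-base operations are reconstructed from CIGAR + MD.
#'
#' @param path SAM or BAM file.
#' @param target_kind `"genome"` or `"transcript"`. Transcriptome
#'   alignments must be ungapped: an `N` op is a hard error.
#' @return List of `read_alignment` objects: read_id, target_id,
#'   target_kind, strand, mapq, secondary, hp/ps tags, start, end, blocks,
#'   ops.
#' @export
read_alignments <- function(path, target_kind = c("genome", "transcript")) {
  target_kind <- match.arg(target_kind)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- suppressMessages(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                              indexDestination = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("MD", "HP", "PS"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  n <- length(b$qname)
  out <- vector("list", n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (bitwAnd(b$flag[i], 4L) != 0L || is.na(b$pos[i])) next
    cigar <- b$cigar[i]
    if (target_kind == "transcript" && "N" %in% .parse_cigar(cigar)$op)
      stop("intron (N) op in transcriptome alignment of read ", b$qname[i])
    md <- b$tag$MD[i]
    if (is.null(md)) md <- NA_character_
    dec <- decode_alignment(cigar, md, as.character(b$seq[i]), b$pos[i] - 1L)
    hp <- if (!is.null(b$tag$HP)) b$tag$HP[i] else NA_integer_
    ps <- if (!is.null(b$tag$PS)) b$tag$PS[i] else NA_integer_
    out[[i]] <- structure(list(
      read_id = b$qname[i],
      target_id = as.character(b$rname[i]),
      target_kind = target_kind,
      strand = if (bitwAnd(b$flag[i], 16L) != 0L) "-" else "+",
      mapq = b$mapq[i],
      secondary = bitwAnd(b$flag[i], 256L) != 0L ||
        bitwAnd(b$flag[i], 2048L) != 0L,
      hp = hp, ps = if (is.na(ps)) NA_character_ else as.character(ps),
      start = min(dec$blocks[, 1]),
      end = max(dec$blocks[, 2]),
      blocks = dec$blocks,
      ops = dec$ops), class = "read_alignment")
    keep[i] <- TRUE
  }
  out[keep]
}

#' Number of matched / mismatched / inserted bases of an alignment
#' @param aln A `read_alignment`.
#' @return Named integer vector (match, mismatch, insertion, deletion).
#' @export
aln_op_totals <- function(aln) {
  v <- c(match = 0L, mismatch = 0L, insertion = 0L, deletion = 0L)
  tab <- tapply(aln$ops$len, aln$ops$kind, sum)
  common <- intersect(names(v), names(tab))
  v[common] <- as.integer(tab[common])
  v
}

#' Classify the base a read carries at one target position
#'
#' @param aln A `read_alignment`.
#' @param pos 0-based target position.
#' @return List with `state` in match/mismatch/deletion/intron/uncovered
#'   and `base` (the read base for mismatches, else `NA`).
#' @export
aln_state_at <- function(aln, pos) {
  if (pos < aln$start || pos >= aln$end)
    return(list(state = "uncovered", base = NA_character_))
  ops <- aln$ops
  cons <- ops$kind != "insertion"
  i <- which(cons & ops$tpos <= pos & pos < ops$tpos + ops$len)
  if (length(i) == 0L) return(list(state = "uncovered", base = NA_character_))
  i <- i[1]
  list(state = ops$kind[i],
       base = if (ops$kind[i] == "mismatch") ops$base[i] else NA_character_)
}

#' Per-position match profile of an alignment
#'
#' @param aln A `read_alignment`.
#' @param positions 0-based target positions.
#' @return Character vector of states (as [aln_state_at()]).
#' @export
aln_match_profile <- function(aln, positions) {
  vapply(positions, function(p) aln_state_at(aln, p)$state, character(1))
}

#' Write alignment records to a SAM file
#'
#' Minimal SAM 1.6 writer used by the simulator's truth-alignment mode.
#'
#' @param recs data.frame with columns qname, flag, rname, pos1, mapq,
#'   cigar, seq and optionally tags (character, pre-formatted, tab-joined).
#' @param sq Named integer vector of reference lengths.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(recs, sq, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  body <- character(nrow(recs))
  has_tags <- "tags" %in% names(recs)
  for (i in seq_len(nrow(recs))) {
    ln <- paste(recs$qname[i], recs$flag[i], recs$rname[i], recs$pos1[i],
                recs$mapq[i], recs$cigar[i], "*", 0, 0, recs$seq[i], "*",
                sep = "\t")
    if (has_tags && nzchar(recs$tags[i])) ln <- paste(ln, recs$tags[i], sep = "\t")
    body[i] <- ln
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
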