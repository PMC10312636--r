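#' Fidelity configuration for read-to-isoform assignment
#'
#' Thresholds of the stringent and splice-checking rules used when
#' assigning long reads to transcript models.
#'
#' @param min_identity Minimum fraction of aligned read bases that must
#'   match the transcript (soft-clipped bases excluded from the
#'   denominator). Default 0.80, inclusive.
#' @param end_span_bp The alignment must span into this many bp of the
#'   first and last exons, i.e. it may leave at most
#'   `min(end_span_bp, exon_length)` bases of each terminal exon
#'   uncovered. Default 25, inclusive.
#' @param splice_flank_bp Bases examined on each side of a splice
#'   junction. Default 3 (6 bases total).
#' @param min_flank_matches Minimum matched bases among the
#'   `2 * splice_flank_bp` window bases. Default 4.
#' @param max_splice_indel_bp Largest insertion/deletion tolerated at a
#'   splice-site window. Default 3, inclusive (a 3 bp indel passes).
#' @param min_support Minimum supporting reads for an isoform to be
#'   reported. Default 3, inclusive.
#' @return List of class `fidelity_config`.
#' @export
fidelity_config <- function(min_identity = 0.80, end_span_bp = 25L,
                            splice_flank_bp = 3L, min_flank_matches = 4L,
                            max_splice_indel_bp = 3L, min_support = 3L) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_flank_matches <= 2L * splice_flank_bp)
  structure(list(min_identity = min_identity,
                 end_span_bp = as.integer(end_span_bp),
                 splice_flank_bp = as.integer(splice_flank_bp),
                 min_flank_matches = as.integer(min_flank_matches),
                 max_splice_indel_bp = as.integer(max_splice_indel_bp),
                 min_support = as.integer(min_support)),
            class = "fidelity_config")
}

#' Rank a read's transcriptome alignments
#'
#' Candidates are ordered by mapping quality (descending), with ties
#' broken by fewer mismatches + indels, then lexicographic transcript id —
#' fully deterministic.
#'
#' @param alignments List of `read_alignment` (target_kind "transcript")
#'   for any number of reads.
#' @return Named list: read_id -> ordered list of candidate alignments.
#' @export
select_best_transcript_alignments <- function(alignments) {
  if (length(alignments) == 0L) return(structure(list(), names = character(0)))
  rid <- vapply(alignments, `[[`, character(1), "read_id")
  out <- lapply(split(alignments, rid), function(alns) {
    mapq <- vapply(alns, `[[`, integer(1), "mapq")
    ed <- vapply(alns, function(a) {
      t <- aln_op_totals(a)
      t[["mismatch"]] + t[["insertion"]] + t[["deletion"]]
    }, integer(1))
    tid <- vapply(alns, `[[`, character(1), "target_id")
    alns[order(-mapq, ed, tid)]
  })
  out
}

#' Stringent coverage/identity check of a transcriptome alignment
#'
#' Passes iff the fraction of matched bases among aligned read bases is at
#' least `min_identity`, and the alignment spans into the first and last
#' `end_span_bp` bases of the terminal exons: at most
#' `min(end_span_bp, exon_length)` bases of the first (and last) exon may
#' be left uncovered.
#'
#' @param aln Transcriptome `read_alignment` to `tx`.
#' @param tx The assigned `transcript_model`.
#' @param cfg A [fidelity_config()].
#' @param transcript_length Optional; cross-checked against the exon chain
#'   (hard error on mismatch).
#' @return Logical.
#' @export
check_stringent <- function(aln, tx, cfg = fidelity_config(),
                            transcript_length = NULL) {
  L <- tx_length(tx)
  if (!is.null(transcript_length) && as.integer(transcript_length) != L)
    stop("transcript_length inconsistent with exon chain of ",
         tx$transcript_id)
  tot <- aln_op_totals(aln)
  aligned <- tot[["match"]] + tot[["mismatch"]] + tot[["insertion"]]
  if (aligned == 0L) return(FALSE)
  if (tot[["match"]] / aligned < cfg$min_identity) return(FALSE)
  lens <- tx$exons[, 2] - tx$exons[, 1]
  if (tx$strand == "-") lens <- rev(lens)  # transcript 5' -> 3'
  len_first <- lens[1]; len_last <- lens[length(lens)]
  miss5 <- aln$start
  miss3 <- L - aln$end
  miss5 <= min(cfg$end_span_bp, len_first) &&
    miss3 <= min(cfg$end_span_bp, len_last)
}

#' Splice-site fidelity check of a transcriptome alignment
#'
#' For every junction whose full `2 * splice_flank_bp` window is covered
#' by the alignment: at least `min_flank_matches` of the window bases must
#' be matches, and no insertion/deletion longer than
#' `max_splice_indel_bp` may touch the window. Junctions not fully
#' covered impose no constraint (a truncated read can still pass on the
#' junctions it covers).
#'
#' @param aln Transcriptome `read_alignment`.
#' @param junction_positions_tx Exon-exon boundary offsets in transcript
#'   coordinates (see [tx_junction_offsets()]).
#' @param cfg A [fidelity_config()].
#' @return Logical.
#' @export
check_splice <- function(aln, junction_positions_tx, cfg = fidelity_config()) {
  fl <- cfg$splice_flank_bp
  for (j in junction_positions_tx) {
    w_lo <- j - fl; w_hi <- j + fl  # window = target positions [w_lo, w_hi)
    if (w_lo < aln$start || w_hi > aln$end) next  # junction not covered
    states <- aln_match_profile(aln, w_lo:(w_hi - 1L))
    if (sum(states == "match") < cfg$min_flank_matches) return(FALSE)
    ops <- aln$ops
    big <- ops$kind %in% c("insertion", "deletion") &
      ops$len > cfg$max_splice_indel_bp
    if (any(big)) {
      del_hit <- ops$kind == "deletion" & big &
        ops$tpos < w_hi & (ops$tpos + ops$len) > w_lo
      ins_hit <- ops$kind == "insertion" & big &
        ops$tpos > w_lo & ops$tpos < w_hi
      if (any(del_hit) || any(ins_hit)) return(FALSE)
    }
  }
  TRUE
}

#' Assign reads to annotated transcripts
#'
#' Walks each read's ranked candidate list and assigns the read to the
#' first candidate passing both the stringent and the splice checks.
#' Reads with no passing candidate are returned as the unassigned set and
#' feed novel isoform detection.
#'
#' @param candidates Output of [select_best_transcript_alignments()].
#' @param transcripts Named list transcript_id -> `transcript_model`.
#' @param cfg A [fidelity_config()].
#' @return List with `assignments` (data.frame read_id, transcript_id,
#'   passed_stringent, passed_check_splice) and `unassigned` (character
#'   read ids).
#' @export
assign_reads <- function(candidates, transcripts, cfg = fidelity_config()) {
  rows <- list()
  unassigned <- character(0)
  for (rid in names(candidates)) {
    hit <- NULL
    for (aln in candidates[[rid]]) {
      tx <- transcripts[[aln$target_id]]
      if (is.null(tx)) next
      if (!check_stringent(aln, tx, cfg)) next
      if (!check_splice(aln, tx_junction_offsets(tx), cfg)) next
      hit <- aln$target_id
      break
    }
    if (is.null(hit)) unassigned <- c(unassigned, rid)
    else rows[[length(rows) + 1L]] <- data.frame(
      read_id = rid, transcript_id = hit, passed_stringent = TRUE,
      passed_check_splice = TRUE, stringsAsFactors = FALSE)
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), transcript_id = character(0),
               passed_stringent = logical(0), passed_check_splice = logical(0),
               stringsAsFactors = FALSE)
  list(assignments = assignments, unassigned = unassigned)
}

#' Annotated isoforms with sufficient read support
#'
#' @param assignments Assignment data.frame from [assign_reads()].
#' @param transcripts Named list transcript_id -> `transcript_model`.
#' @param cfg A [fidelity_config()]; `min_support` is inclusive.
#' @return List of records: `tx`, `support`, `read_ids`.
#' @export
supported_annotated_isoforms <- function(assignments, transcripts,
                                         cfg = fidelity_config()) {
  if (nrow(assignments) == 0L) return(list())
  out <- list()
  for (tid in sort(unique(assignments$transcript_id))) {
    rids <- assignments$read_id[assignments$transcript_id == tid]
    if (length(rids) >= cfg$min_support)
      out[[length(out) + 1L]] <- list(tx = transcripts[[tid]],
                                      support = length(rids),
                                      read_ids = rids)
  }
  out
}
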