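#' Match predicted against truth transcripts with terminal wiggle
#'
#' A predicted transcript matches a truth transcript when their splice
#' junction chains are identical at exact coordinates and both terminal
#' ends differ by at most `end_wiggle` bp; mono-exon transcripts match
#' on overlap with both ends within the wiggle. Matching is greedy
#' 1-to-1 by smallest total end distance (ties by transcript id pair),
#' mirroring transcript-level benchmarking with end tolerance flags.
#'
#' @param predicted,truth Lists of `transcript_model`.
#' @param end_wiggle Terminal tolerance in bp, inclusive. Default 50.
#' @return List of class `match_report`: tp, fp, fn, sensitivity and
#'   precision (percent), and `pairs` (data.frame predicted_id,
#'   truth_id, end_distance).
#' @export
match_transcripts <- function(predicted, truth, end_wiggle = 50L) {
  cand <- list()
  for (i in seq_along(predicted)) for (j in seq_along(truth)) {
    p <- predicted[[i]]; t <- truth[[j]]
    if (p$chrom != t$chrom) next
    pj <- junction_chain(p); tj <- junction_chain(t)
    if (nrow(pj) != nrow(tj)) next
    if (nrow(pj) > 0L && !all(pj == tj)) next
    d1 <- abs(p$exons[1, 1] - t$exons[1, 1])
    d2 <- abs(p$exons[nrow(p$exons), 2] - t$exons[nrow(t$exons), 2])
    if (d1 > end_wiggle || d2 > end_wiggle) next
    if (nrow(pj) == 0L) {  # mono-exon: require overlap too
      if (p$exons[1, 1] >= t$exons[1, 2] || t$exons[1, 1] >= p$exons[1, 2])
        next
    }
    cand[[length(cand) + 1L]] <- data.frame(
      pi = i, ti = j, dist = d1 + d2,
      pid = p$transcript_id, tid = t$transcript_id,
      stringsAsFactors = FALSE)
  }
  pairs <- data.frame(predicted_id = character(0), truth_id = character(0),
                      end_distance = integer(0), stringsAsFactors = FALSE)
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$dist, cand$pid, cand$tid), , drop = FALSE]
    used_p <- logical(length(predicted)); used_t <- logical(length(truth))
    for (r in seq_len(nrow(cand))) {
      if (used_p[cand$pi[r]] || used_t[cand$ti[r]]) next
      used_p[cand$pi[r]] <- TRUE; used_t[cand$ti[r]] <- TRUE
      pairs <- rbind(pairs, data.frame(predicted_id = cand$pid[r],
                                       truth_id = cand$tid[r],
                                       end_distance = cand$dist[r],
                                       stringsAsFactors = FALSE))
    }
  }
  tp <- nrow(pairs)
  fp <- length(predicted) - tp
  fn <- length(truth) - tp
  structure(list(
    tp = tp, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    pairs = pairs), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report> TP=%d FP=%d FN=%d | sensitivity %.1f%% precision %.1f%%\n",
    x$tp, x$fp, x$fn, x$sensitivity, x$precision))
  invisible(x)
}
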