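# Fixtures: t_mono = 100 bp single exon; t_two = 200+200 bp two-exon
# transcript whose junction sits at transcript offset 200.
t_mono <- transcript_model("t_mono", "g1", "chr1", "+", cbind(0L, 100L))
t_two <- transcript_model("t_two", "g1", "chr1", "+",
                          cbind(c(0L, 400L), c(200L, 600L)))

test_that("check_stringent applies the 80% identity rule inclusively", {
  pass <- make_aln("r", "t_mono", list(c("match", 80, 0),
                                       c("mismatch", 20, 80)))
  fail <- make_aln("r", "t_mono", list(c("match", 79, 0),
                                       c("mismatch", 21, 79)))
  expect_true(check_stringent(pass, t_mono))
  expect_false(check_stringent(fail, t_mono))
  expect_error(check_stringent(pass, t_mono, transcript_length = 120),
               "inconsistent")
})

test_that("check_stringent requires spanning into 25 bp of terminal exons", {
  # alignment missing the first `miss` bases of a 400 bp transcript
  for (case in list(c(24, TRUE), c(25, TRUE), c(26, FALSE), c(30, FALSE))) {
    miss <- case[1]
    aln <- make_aln("r", "t_two", list(c("match", 400 - miss, miss)))
    expect_equal(check_stringent(aln, t_two), as.logical(case[2]),
                 info = paste("5' miss", miss))
    aln3 <- make_aln("r", "t_two", list(c("match", 400 - miss, 0)))
    expect_equal(check_stringent(aln3, t_two), as.logical(case[2]),
                 info = paste("3' miss", miss))
  }
  # exon shorter than 25 bp: requirement shrinks to the exon length
  t_short <- transcript_model("t_short", "g1", "chr1", "+",
                              cbind(c(0L, 400L), c(20L, 600L)))
  aln <- make_aln("r", "t_short", list(c("match", 220 - 20, 20)))
  expect_true(check_stringent(aln, t_short))
})

test_that("check_splice enforces 4-of-6 flank matches and the 3 bp
           indel cap", {
  jx <- tx_junction_offsets(t_two)
  expect_equal(jx, 200L)
  clean <- make_aln("r", "t_two", list(c("match", 400, 0)))
  expect_true(check_splice(clean, jx))
  two_mm <- make_aln("r", "t_two", list(
    c("match", 197, 0), c("mismatch", 1, 197, "G"),
    c("mismatch", 1, 198, "G"), c("match", 201, 199)))
  expect_true(check_splice(two_mm, jx))  # 4 of 6 matched
  three_mm <- make_aln("r", "t_two", list(
    c("match", 197, 0), c("mismatch", 1, 197, "G"),
    c("mismatch", 1, 198, "G"), c("mismatch", 1, 199, "G"),
    c("match", 200, 200)))
  expect_false(check_splice(three_mm, jx))  # 3 of 6 matched
  del4 <- make_aln("r", "t_two", list(
    c("match", 197, 0), c("deletion", 4, 197), c("match", 199, 201)))
  expect_false(check_splice(del4, jx))  # 4 bp deletion at the site
  del3 <- make_aln("r", "t_two", list(
    c("match", 195, 0), c("deletion", 3, 195), c("match", 202, 198)))
  expect_true(check_splice(del3, jx))  # 3 bp deletion, 5 window matches
  # junction not covered by the alignment imposes no constraint
  trunc <- make_aln("r", "t_two", list(c("match", 150, 250)))
  expect_true(check_splice(trunc, jx))
})

test_that("candidate ranking is by mapq, then edit distance, then id", {
  a_hi <- make_aln("r1", "tA", list(c("match", 100, 0)), mapq = 60L)
  a_lo <- make_aln("r1", "tB", list(c("match", 100, 0)), mapq = 0L)
  cand <- select_best_transcript_alignments(list(a_lo, a_hi))
  expect_equal(vapply(cand$r1, `[[`, character(1), "target_id"),
               c("tA", "tB"))
  b1 <- make_aln("r2", "tC", list(c("match", 95, 0), c("mismatch", 5, 95)),
                 mapq = 60L)
  b2 <- make_aln("r2", "tD", list(c("match", 97, 0), c("mismatch", 3, 97)),
                 mapq = 60L)
  cand2 <- select_best_transcript_alignments(list(b1, b2))
  expect_equal(cand2$r2[[1]]$target_id, "tD")
  expect_length(select_best_transcript_alignments(list()), 0)
})

test_that("assign_reads falls back to a later candidate that passes", {
  txs <- list(t_two = t_two,
              t_alt = transcript_model("t_alt", "g1", "chr1", "+",
                                       cbind(c(0L, 400L), c(200L, 600L))))
  bad <- make_aln("r1", "t_two", list(
    c("match", 197, 0), c("mismatch", 1, 197, "G"),
    c("mismatch", 1, 198, "G"), c("mismatch", 1, 199, "G"),
    c("match", 200, 200)), mapq = 60L)
  good <- make_aln("r1", "t_alt", list(c("match", 400, 0)), mapq = 50L)
  res <- assign_reads(select_best_transcript_alignments(list(bad, good)), txs)
  expect_equal(res$assignments$transcript_id, "t_alt")
  lost <- make_aln("r2", "t_two", list(c("match", 100, 0),
                                       c("mismatch", 100, 100)), mapq = 60L)
  res2 <- assign_reads(select_best_transcript_alignments(list(lost)), txs)
  expect_equal(res2$unassigned, "r2")
  expect_equal(nrow(res2$assignments), 0L)
})

test_that("assignment and unassigned partition the read set", {
  set.seed(5)
  txs <- list(t_two = t_two)
  alns <- lapply(1:30, function(i) {
    n_mm <- sample(0:60, 1)
    make_aln(sprintf("r%02d", i), "t_two",
             list(c("match", 400 - n_mm, 0),
                  c("mismatch", n_mm, 400 - n_mm)))
  })
  res <- assign_reads(select_best_transcript_alignments(alns), txs)
  ids <- sprintf("r%02d", 1:30)
  expect_setequal(c(res$assignments$read_id, res$unassigned), ids)
  expect_length(intersect(res$assignments$read_id, res$unassigned), 0)
})

test_that("tightening thresholds never increases assignments", {
  set.seed(8)
  txs <- list(t_two = t_two)
  alns <- lapply(1:40, function(i) {
    mm_pos <- sort(sample(0:399, sample(0:90, 1)))
    ops <- list()
    cur <- 0L
    for (p in mm_pos) {
      if (p > cur) ops[[length(ops) + 1L]] <- c("match", p - cur, cur)
      ops[[length(ops) + 1L]] <- c("mismatch", 1, p, "G")
      cur <- p + 1L
    }
    if (cur < 400L) ops[[length(ops) + 1L]] <- c("match", 400 - cur, cur)
    make_aln(sprintf("r%02d", i), "t_two", ops)
  })
  cand <- select_best_transcript_alignments(alns)
  n_assigned <- function(cfg) nrow(assign_reads(cand, txs, cfg)$assignments)
  base <- n_assigned(fidelity_config())
  expect_lte(n_assigned(fidelity_config(min_identity = 0.9)), base)
  expect_lte(n_assigned(fidelity_config(min_flank_matches = 6)), base)
})

test_that("error-free simulated reads all pass both checks", {
  cfg <- sim_config(seed = 3, n_genes = 3, transcripts_per_gene = 2,
                    reads_per_transcript = 4, error_rate = 0,
                    truncation_prob = 0)
  d <- simulate_dataset(cfg, file.path(tempdir(), "asg_clean"))
  t_alns <- read_alignments(d$tx_sam, "transcript")
  txs <- d$ref$transcripts
  res <- assign_reads(select_best_transcript_alignments(t_alns), txs)
  expect_length(res$unassigned, 0)
  expect_equal(nrow(res$assignments), length(t_alns))
  # truth agreement: every read assigned to its source transcript
  truth <- d$truth_tables[[1]]
  m <- merge(res$assignments, truth, by = "read_id",
             suffixes = c(".got", ".true"))
  expect_true(all(m$transcript_id.got == m$transcript_id.true))
})

test_that("supported_annotated_isoforms applies the inclusive
           min-support rule", {
  txs <- list(t_mono = t_mono, t_two = t_two)
  asg <- data.frame(read_id = sprintf("r%d", 1:5),
                    transcript_id = c("t_mono", "t_mono", "t_mono",
                                      "t_two", "t_two"),
                    stringsAsFactors = FALSE)
  got <- supported_annotated_isoforms(asg, txs)
  expect_length(got, 1)
  expect_equal(got[[1]]$tx$transcript_id, "t_mono")
  expect_equal(got[[1]]$support, 3L)
  expect_length(supported_annotated_isoforms(asg[0, ], txs), 0)
})
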