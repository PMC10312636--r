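# Genome-alignment builders for collapse fixtures: reads with exact
# block structure, all-match ops.
g_read <- function(id, blocks, chrom = "chr1", strand = "+") {
  ops <- list()
  for (i in seq_len(nrow(blocks))) {
    ops[[length(ops) + 1L]] <- c("match", blocks[i, 2] - blocks[i, 1],
                                 blocks[i, 1])
    if (i < nrow(blocks))
      ops[[length(ops) + 1L]] <- c("intron", blocks[i + 1, 1] - blocks[i, 2],
                                   blocks[i, 2])
  }
  make_aln(id, chrom, ops, target_kind = "genome", strand = strand)
}

ev_fix <- list(chr1 = list(donor = c(1000L, 1006L, 2000L),
                           acceptor = c(1500L, 2500L)))

test_that("splice correction snaps to the nearest evidence site with
           smaller-coordinate tie-break", {
  cfg <- collapse_config(correction_window = 10)
  r1 <- g_read("r1", cbind(c(500L, 1503L), c(1003L, 1900L)))
  got <- correct_splice_sites(list(r1), ev_fix, cfg)
  expect_length(got$flagged, 0)
  expect_equal(unname(got$reads[[1]]$cjx), cbind(1000L, 1500L))
  # donor 1003 is equidistant from 1000 and 1006: smaller wins
  expect_equal(got$reads[[1]]$cjx[1, 1], 1000L)
  r2 <- g_read("r2", cbind(c(500L, 1500L), c(1020L, 1900L)))
  got2 <- correct_splice_sites(list(r2), ev_fix, cfg)
  expect_equal(got2$flagged, "r2")
  expect_length(got2$reads, 0)
  # already-supported site is untouched
  r3 <- g_read("r3", cbind(c(500L, 1500L), c(1006L, 1900L)))
  got3 <- correct_splice_sites(list(r3), ev_fix, cfg)
  expect_equal(got3$reads[[1]]$cjx[1, 1], 1006L)
})

test_that("long-read-only evidence sites require min_support reads", {
  reads <- lapply(1:3, function(i)
    g_read(paste0("x", i), cbind(c(100L, 900L), c(700L, 1200L))))
  ev3 <- junction_evidence(reads = reads, min_support = 3)
  expect_equal(ev3$chr1$donor, 700L)
  ev4 <- junction_evidence(reads = reads, min_support = 4)
  expect_null(ev4$chr1)
  tx <- transcript_model("t", "g", "chr1", "+",
                         cbind(c(0L, 800L), c(600L, 1000L)))
  ev_ann <- junction_evidence(annotation = list(tx))
  expect_equal(ev_ann$chr1$donor, 600L)
  expect_equal(ev_ann$chr1$acceptor, 800L)
})

test_that("grouping is by exact junction chain; prefixes stay separate", {
  mk <- function(id, blocks) {
    a <- g_read(id, blocks)
    a$cjx <- cbind(donor = blocks[-nrow(blocks), 2],
                   acceptor = blocks[-1, 1])
    a
  }
  b3 <- cbind(c(0L, 300L, 700L, 1100L), c(200L, 500L, 900L, 1300L))
  r1 <- mk("a", b3); r2 <- mk("b", b3)
  r3 <- mk("c", cbind(c(0L, 300L, 700L, 1150L), c(200L, 500L, 900L, 1300L)))
  r4 <- mk("d", b3[1:3, ])  # strict prefix chain
  groups <- group_by_junction_chain(list(r1, r2, r3, r4))
  expect_length(groups, 3)
  sizes <- sort(vapply(groups, function(g) length(g$reads), integer(1)))
  expect_equal(sizes, c(1L, 1L, 2L))
  # mono-exon reads form one group per overlap locus
  m1 <- mk2 <- g_read("m1", cbind(100L, 500L)); m1$cjx <- r1$cjx[0, ]
  m2 <- g_read("m2", cbind(400L, 800L)); m2$cjx <- r1$cjx[0, ]
  m3 <- g_read("m3", cbind(5000L, 5400L)); m3$cjx <- r1$cjx[0, ]
  mono <- group_by_junction_chain(list(m1, m2, m3))
  expect_length(mono, 2)
})

test_that("end calling clusters starts/ends by single linkage", {
  mk <- function(id, s, e) {
    a <- g_read(id, cbind(c(s, 1500L), c(1000L, e)))
    a$cjx <- cbind(donor = 1000L, acceptor = 1500L)
    a
  }
  g1 <- list(chrom = "chr1", jx = cbind(donor = 1000L, acceptor = 1500L),
             reads = list(mk("a", 100L, 2000L), mk("b", 105L, 2000L),
                          mk("c", 107L, 2000L)))
  fp1 <- call_ends(g1)
  expect_length(fp1, 1)
  expect_equal(fp1[[1]]$tss, 100L)  # modal tie -> outermost
  g2 <- list(chrom = "chr1", jx = g1$jx,
             reads = list(mk("a", 100L, 2000L), mk("b", 600L, 2000L)))
  fp2 <- call_ends(g2)
  expect_length(fp2, 2)
  expect_setequal(vapply(fp2, `[[`, integer(1), "tss"), c(100L, 600L))
  g3 <- list(chrom = "chr1", jx = g1$jx, reads = list(mk("solo", 42L, 1800L)))
  fp3 <- call_ends(g3)
  expect_length(fp3, 1)
  expect_equal(fp3[[1]]$tss, 42L)
  expect_equal(fp3[[1]]$tes, 1800L)
})

test_that("strand inference votes on splice dinucleotides with
           alignment fallback", {
  s <- strrep("A", 300)
  substr(s, 101, 102) <- "GT"; substr(s, 199, 200) <- "AG"
  expect_equal(infer_strand(s, cbind(100L, 200L)), "+")
  s2 <- strrep("A", 300)
  substr(s2, 101, 102) <- "CT"; substr(s2, 199, 200) <- "AC"
  expect_equal(infer_strand(s2, cbind(100L, 200L)), "-")
  none <- strrep("A", 300)
  expect_equal(infer_strand(none, cbind(100L, 200L),
                            fallback_strands = c("-", "-", "+")), "-")
})

test_that("reads re-assign to first-pass models; truncated reads follow
           their covered junctions", {
  blocks_full <- cbind(c(100L, 400L, 800L), c(300L, 600L, 1000L))
  full <- lapply(1:3, function(i) {
    a <- g_read(paste0("f", i), blocks_full)
    a$cjx <- cbind(donor = c(300L, 600L), acceptor = c(400L, 800L))
    a
  })
  trunc <- g_read("t1", cbind(c(450L, 800L), c(600L, 1000L)))
  trunc$cjx <- cbind(donor = 600L, acceptor = 800L)
  groups <- group_by_junction_chain(c(full, list(trunc)))
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 2000)))
  fp <- build_firstpass(groups, genome)
  expect_length(fp, 2)
  res <- assign_to_firstpass(c(full, list(trunc)), fp)
  # every read supports a model; the truncated read supports the model
  # whose covered junctions it matches and whose stringent check passes
  # (the full model fails: the read misses its entire first exon)
  expect_length(res$unassigned, 0)
  njx <- vapply(fp, function(x) nrow(junction_chain(x$tx)), integer(1))
  full_id <- fp[[which(njx == 2)]]$tx$transcript_id
  sub_id <- fp[[which(njx == 1)]]$tx$transcript_id
  expect_setequal(res$supports[[full_id]], c("f1", "f2", "f3"))
  expect_setequal(res$supports[[sub_id]], "t1")
})

test_that("finalize keeps supported novels, dedupes against annotation
           and filters contained truncations", {
  ann_tx <- transcript_model("ann1", "g1", "chr1", "+",
                             cbind(c(100L, 400L, 800L), c(300L, 600L, 1000L)))
  annotated <- list(list(tx = ann_tx, support = 5L,
                         read_ids = sprintf("a%d", 1:5)))
  mk_fp <- function(id, exons) list(
    tx = transcript_model(id, "gX", "chr1", "+", exons, source = "novel"),
    read_ids = character(0))
  fp_same <- mk_fp("fp_same", cbind(c(120L, 400L, 800L), c(300L, 600L, 980L)))
  fp_sub <- mk_fp("fp_sub", cbind(c(450L, 800L), c(600L, 990L)))
  fp_new <- mk_fp("fp_new", cbind(c(100L, 700L), c(500L, 900L)))
  fp_weak <- mk_fp("fp_weak", cbind(c(2000L, 2500L), c(2200L, 2700L)))
  sup <- list(fp_same = sprintf("s%d", 1:4), fp_sub = sprintf("u%d", 1:3),
              fp_new = sprintf("n%d", 1:3), fp_weak = c("w1", "w2"))
  final <- finalize_isoforms(list(fp_same, fp_sub, fp_new, fp_weak), sup,
                             annotated)
  ids <- vapply(final, function(r) r$tx$transcript_id, character(1))
  expect_setequal(ids, c("ann1", "fp_new"))
  # identical-chain novel merged into the annotated record
  ann <- final[[which(ids == "ann1")]]
  expect_equal(ann$support, 9L)
  expect_true(all(sprintf("s%d", 1:4) %in% ann$read_ids))
  expect_length(finalize_isoforms(list(), list(), list()), 0)
})

test_that("novel detection recovers simulated truth without annotation
           assignment", {
  cfg <- sim_config(seed = 21, n_genes = 10, transcripts_per_gene = 2,
                    reads_per_transcript = 10, error_rate = 0.01,
                    truncation_prob = 0)
  d <- simulate_dataset(cfg, file.path(tempdir(), "collapse_novel"))
  res <- run_collapse(d$genome, d$gtf, d$genome_sam[[1]], tx_aln = NULL,
                      out_dir = file.path(tempdir(), "collapse_novel_run"))
  truth <- flatten_transcripts(read_gtf(d$gtf))
  final <- lapply(res$final, `[[`, "tx")
  rep <- match_transcripts(final, truth, end_wiggle = 50)
  expect_gte(rep$sensitivity, 90)
  expect_gte(rep$precision, 95)
  # every junction of every final model is in the evidence set
  ev <- junction_evidence(truth)
  for (tx in final) {
    jx <- junction_chain(tx)
    if (nrow(jx) == 0) next
    expect_true(all(jx[, 1] %in% ev[[tx$chrom]]$donor))
    expect_true(all(jx[, 2] %in% ev[[tx$chrom]]$acceptor))
  }
  # support conservation
  expect_lte(sum(vapply(res$final, `[[`, integer(1), "support")),
             res$manifest$n_reads)
})
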