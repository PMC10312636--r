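# A 2-exon plus-strand isoform on a tiny genome, with two het sites.
ph_genome <- local({
  s <- strrep("ACGT", 250)  # 1000 bp
  Biostrings::DNAStringSet(c(chr1 = s))
})
ph_tx <- transcript_model("iso1", "g1", "chr1", "+",
                          cbind(c(100L, 400L), c(300L, 600L)))
v1 <- variant_record("chr1", 150L, "C", "T", 30, caller = "a")
v2 <- variant_record("chr1", 500L, "A", "G", 40, caller = "b")

# read covering the whole isoform carrying given alt positions
ph_read <- function(id, alts = integer(0), hp = NA_integer_,
                    ps = NA_character_, span = c(100L, 600L)) {
  ops <- list()
  cur <- span[1]
  seg <- function(from, to) {
    for (p in sort(alts[alts >= from & alts < to])) {
      if (p > cur) ops[[length(ops) + 1L]] <<- c("match", p - cur, cur)
      ops[[length(ops) + 1L]] <<- c("mismatch", 1, p, "X")
      cur <<- p + 1L
    }
    if (to > cur) ops[[length(ops) + 1L]] <<- c("match", to - cur, cur)
    cur <<- to
  }
  seg(span[1], min(300L, span[2]))
  if (span[2] > 400L) {
    ops[[length(ops) + 1L]] <- c("intron", 100L, 300L)
    cur <- 400L
    seg(400L, span[2])
  }
  a <- make_aln(id, "chr1", ops, target_kind = "genome", hp = hp, ps = ps)
  # patch mismatch bases to the real alt alleles
  for (i in seq_len(nrow(a$ops))) {
    if (a$ops$kind[i] != "mismatch") next
    a$ops$base[i] <- if (a$ops$tpos[i] == 150L) "T" else "G"
  }
  a
}

test_that("combine_variant_calls dedupes callers and filters by coverage", {
  reads <- lapply(1:12, function(i) ph_read(paste0("r", i)))
  dup <- variant_record("chr1", 150L, "C", "T", 50, caller = "b")
  got <- combine_variant_calls(list(list(v1), list(dup, v2)), reads,
                               min_coverage = 10)
  expect_length(got, 2)
  expect_equal(got[[1]]$caller, "a,b")
  expect_equal(got[[1]]$qual, 50)
  # site covered by only 9 reads is dropped
  few <- lapply(1:9, function(i) ph_read(paste0("f", i)))
  expect_length(combine_variant_calls(list(list(v1)), few, 10), 0)
  expect_error(combine_variant_calls(list(), reads), "no variant input")
})

test_that("read_allele_at classifies ref, alt, other and uncovered", {
  expect_equal(read_allele_at(ph_read("r", integer(0)), v1), "ref")
  expect_equal(read_allele_at(ph_read("r", c(150L)), v1), "alt")
  other <- ph_read("r", c(150L))
  other$ops$base[other$ops$kind == "mismatch"] <- "G"  # not the alt T
  expect_equal(read_allele_at(other, v1), "other")
  short <- ph_read("r", span = c(100L, 140L))
  expect_equal(read_allele_at(short, v1), "uncovered")
  # spliced-over position is uncovered for phasing
  expect_equal(read_allele_at(ph_read("r"),
                              variant_record("chr1", 350L, "A", "G")),
               "uncovered")
})

test_that("tabulate_haplotypes recovers a clean diploid and applies
           thresholds", {
  reads <- c(lapply(1:10, function(i) ph_read(paste0("h1_", i),
                                              c(150L, 500L))),
             lapply(1:10, function(i) ph_read(paste0("h2_", i))))
  haps <- tabulate_haplotypes(ph_tx, reads, list(v1, v2))
  expect_length(haps, 2)
  expect_equal(haps[[1]]$support, 10L)
  expect_equal(haps[[2]]$support, 10L)
  vecs <- vapply(haps, function(h) paste(h$alleles, collapse = ","),
                 character(1))
  expect_setequal(vecs, c("alt,alt", "ref,ref"))
  expect_equal(haps[[1]]$haplotype_index, 1L)

  # fraction threshold: 18/2 at 10% keeps both, a 5% minor is dropped
  mix <- c(lapply(1:18, function(i) ph_read(paste0("a", i), c(150L))),
           lapply(1:2, function(i) ph_read(paste0("b", i), c(150L, 500L))))
  # absorb_errors off so the 2-read vector must stand on its own
  cfg <- phasing_config(min_haplotype_support = 2, absorb_errors = FALSE)
  expect_length(tabulate_haplotypes(ph_tx, mix, list(v1, v2), cfg), 2)
  mix19 <- c(lapply(1:19, function(i) ph_read(paste0("a", i), c(150L))),
             list(ph_read("b1", c(150L, 500L))))
  expect_length(tabulate_haplotypes(ph_tx, mix19, list(v1, v2),
                                    phasing_config(min_haplotype_support = 1,
                                                   absorb_errors = FALSE)),
                1)
  # no overlapping variants: isoform passes through unhaplotyped
  far <- variant_record("chr1", 900L, "A", "G")
  expect_length(tabulate_haplotypes(ph_tx, reads, list(far)), 0)
})

test_that("single-position deviants are absorbed and partial reads
           credited to the unique consistent haplotype", {
  reads <- c(lapply(1:10, function(i) ph_read(paste0("h1_", i),
                                              c(150L, 500L))),
             lapply(1:10, function(i) ph_read(paste0("h2_", i))),
             list(ph_read("err1", c(150L))),        # 1 step from h1 and h2
             list(ph_read("part1", c(150L), span = c(100L, 300L))))
  haps <- tabulate_haplotypes(ph_tx, reads, list(v1, v2))
  expect_length(haps, 2)
  # err1 is 1 position from both survivors: ambiguous, not absorbed;
  # part1 covers only site 1 with alt: consistent only with (alt,alt)
  h_alt <- haps[[which(vapply(haps, function(h)
    h$alleles[["150"]], character(1)) == "alt")]]
  expect_true("part1" %in% h_alt$read_ids)
  expect_false(any(vapply(haps, function(h) "err1" %in% h$read_ids,
                          logical(1))))
  # support never exceeds the read count
  expect_lte(sum(vapply(haps, `[[`, integer(1), "support")), length(reads))
})

test_that("tabulation is invariant to read order", {
  reads <- c(lapply(1:7, function(i) ph_read(paste0("x", i), c(150L, 500L))),
             lapply(1:5, function(i) ph_read(paste0("y", i))))
  h1 <- tabulate_haplotypes(ph_tx, reads, list(v1, v2))
  set.seed(2); h2 <- tabulate_haplotypes(ph_tx, sample(reads), list(v1, v2))
  expect_equal(lapply(h1, `[[`, "alleles"), lapply(h2, `[[`, "alleles"))
  expect_equal(lapply(h1, `[[`, "read_ids"), lapply(h2, `[[`, "read_ids"))
})

test_that("phase-set mode partitions reads by tag and agrees with
           tabulation", {
  pv1 <- variant_record("chr1", 150L, "C", "T", 30, phase_set = "7",
                        genotype = "1|0")
  pv2 <- variant_record("chr1", 500L, "A", "G", 30, phase_set = "7",
                        genotype = "1|0")
  reads <- c(lapply(1:14, function(i)
    ph_read(paste0("p1_", i), c(150L, 500L), hp = 1L, ps = "7")),
    lapply(1:16, function(i) ph_read(paste0("p2_", i), hp = 2L, ps = "7")))
  haps <- phase_by_phase_set(ph_tx, reads, list(pv1, pv2))
  expect_length(haps, 2)
  expect_setequal(vapply(haps, `[[`, integer(1), "support"), c(14L, 16L))
  tab <- tabulate_haplotypes(ph_tx, reads, list(pv1, pv2))
  expect_setequal(
    vapply(haps, function(h) paste(h$alleles, collapse = ","), character(1)),
    vapply(tab, function(h) paste(h$alleles, collapse = ","), character(1)))
  # all reads on one haplotype
  one <- phase_by_phase_set(ph_tx, reads[1:14], list(pv1, pv2))
  expect_length(one, 1)
  # a read whose carried allele conflicts with its tag follows the tag
  confl <- ph_read("c1", integer(0), hp = 1L, ps = "7")  # ref but tagged h1
  haps2 <- phase_by_phase_set(ph_tx, c(reads, list(confl)),
                              list(pv1, pv2))
  h1 <- haps2[[which(vapply(haps2, function(h)
    h$alleles[["150"]] == "alt", logical(1)))]]
  expect_true("c1" %in% h1$read_ids)
  expect_gte(attr(haps2, "n_conflict"), 1L)
  # untagged reads are counted and excluded
  haps3 <- phase_by_phase_set(ph_tx, c(reads, list(ph_read("u1"))),
                              list(pv1, pv2))
  expect_equal(attr(haps3, "n_untagged"), 1L)
})

test_that("hst_bias_test builds the within-gene 2x2 tables", {
  tab <- data.frame(
    gene_id = "g", isoform_id = rep(c("A", "B"), each = 2),
    haplotype_key = rep(c("h1", "h2"), 2),
    support = c(20L, 0L, 0L, 20L), stringsAsFactors = FALSE)
  res <- hst_bias_test(tab)
  expect_equal(nrow(res), 4)
  r <- res[res$isoform_id == "A" & res$haplotype_key == "h1", ]
  expect_equal(c(r$a, r$b, r$c, r$d), c(20L, 0L, 0L, 20L))
  expect_equal(r$p, fisher_exact_two_sided(20, 0, 0, 20))
  expect_true(r$significant)
  bal <- data.frame(gene_id = "g", isoform_id = rep(c("A", "B"), each = 2),
                    haplotype_key = rep(c("h1", "h2"), 2),
                    support = rep(10L, 4), stringsAsFactors = FALSE)
  expect_equal(hst_bias_test(bal)$p, rep(1, 4), tolerance = 1e-9)
  solo <- data.frame(gene_id = "g", isoform_id = "A",
                     haplotype_key = c("h1", "h2"), support = c(5L, 5L),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(hst_bias_test(solo)), 0)
})

test_that("HST sequences substitute alleles in transcript orientation", {
  haps <- list(iso1 = list(
    list(isoform_id = "iso1", haplotype_index = 1L,
         alleles = c("150" = "alt", "500" = "ref"), support = 10L),
    list(isoform_id = "iso1", haplotype_index = 2L,
         alleles = c("150" = "ref", "500" = "ref"), support = 10L)))
  out <- emit_hst_outputs(haps, list(iso1 = ph_tx), list(v1, v2), ph_genome,
                          fasta_path = tempfile(fileext = ".fa"),
                          vcf_path = tempfile(fileext = ".vcf"))
  ref_seq <- tx_sequence(ph_tx, ph_genome)
  s1 <- out$sequences[["iso1_1_g1"]]
  s2 <- out$sequences[["iso1_2_g1"]]
  expect_equal(s2, ref_seq)  # ref-only haplotype unchanged
  diffs <- which(strsplit(s1, "")[[1]] != strsplit(ref_seq, "")[[1]])
  expect_equal(diffs, genome_to_tx(ph_tx, 150L) + 1L)
  expect_equal(substr(s1, diffs, diffs), "T")

  # minus-strand isoform: genome T>C appears as A>G in the transcript
  neg_tx <- transcript_model("isoN", "g2", "chr1", "-",
                             cbind(c(100L, 400L), c(300L, 600L)))
  gpos <- 500L
  refb <- substr(as.character(ph_genome[[1]]), gpos + 1L, gpos + 1L)
  genome2 <- ph_genome
  if (refb != "T") {  # force a T at the site for the fixture
    ss <- strsplit(as.character(ph_genome[[1]]), "")[[1]]
    ss[gpos + 1L] <- "T"
    genome2 <- Biostrings::DNAStringSet(c(chr1 = paste(ss, collapse = "")))
  }
  vneg <- variant_record("chr1", gpos, "T", "C")
  hapsN <- list(isoN = list(list(isoform_id = "isoN", haplotype_index = 1L,
                                 alleles = c("500" = "alt"), support = 5L)))
  outN <- emit_hst_outputs(hapsN, list(isoN = neg_tx), list(vneg), genome2)
  refN <- tx_sequence(neg_tx, genome2)
  sN <- outN$sequences[["isoN_1_g2"]]
  dN <- which(strsplit(sN, "")[[1]] != strsplit(refN, "")[[1]])
  expect_equal(dN, genome_to_tx(neg_tx, gpos) + 1L)
  expect_equal(substr(refN, dN, dN), "A")
  expect_equal(substr(sN, dN, dN), "G")
})
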