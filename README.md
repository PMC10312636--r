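# loriso

Variant-aware isoform detection, haplotype phasing and A-to-I RNA editing
analysis for long cDNA reads.

## What it does, and for whom

High-accuracy long-read cDNA protocols (rolling-circle consensus reads at
~99% identity) make it possible to analyse full-length transcripts one
molecule at a time. `loriso` is aimed at transcriptomics researchers who
want three things from such data:

1. **Isoform detection with splice-site fidelity.** Reads are first
   aligned (ungapped) to annotated transcripts and assigned under two
   explicit rules: a *stringent* rule — at least 80% of aligned read
   bases must match the transcript and the alignment must span into the
   first and last 25 bp of the terminal exons — and a *splice-check*
   rule — at least 4 of the 6 bases flanking every covered splice
   junction must match, with no indel larger than 3 bp at the junction.
   Unassigned reads feed novel isoform detection: splice sites are
   corrected against annotation/short-read evidence, reads are grouped
   by splice-junction chain, each group is collapsed into first-pass
   models by clustering transcription start/end sites, reads are
   re-assigned under the same fidelity rules, and models with at least
   3 supporting reads (inclusive) join the supported annotated isoforms
   in the final set.

2. **Haplotype-specific transcripts (HSTs) without assuming diploidy.**
   Sequence variants (one or several VCFs, combined with a coverage
   filter) are intersected with each isoform's exons, and the variant
   combinations carried by the isoform's supporting reads are tabulated
   into haplotypes — any number of them, which matters for aneuploid
   cancer genomes. A diploid phase-set mode driven by caller `PS`/`HP`
   tags is also provided. Within each gene, isoform-haplotype coupling
   is tested with a two-sided Fisher's exact test
   (BH-adjusted p < 0.05).

3. **Single-molecule A-to-I editing analysis.** Inosine reads as a G
   (or C on the minus strand), so editing appears as strand-resolved
   A>G / T>C mismatches. The package piles up edited vs reference reads
   per candidate site and condition, tests differential editing between
   a control and an ADAR-knockdown-style condition (coverage >= 10 in
   either condition, |edited-fraction change| >= 10%, Fisher p < 0.05),
   flags type I hyperediting (> 40% of residues edited), detects type II
   hyperedited regions (>= 3 edits within every 150 bp), and runs
   single-molecule coordination tests: edit-edit co-occurrence among the
   20 nearest sites at least 50 bp apart, and mutually exclusive
   editing-vs-splicing at single sites.

A seeded simulator (`sim_config()`, `simulate_dataset()`) generates every
input the pipeline consumes — genome, annotation, reads with errors and
truncation, diploid haplotypes, condition-dependent edit sites, and
truth-derived SAM alignments — so the entire workflow runs and is tested
fully offline.

## The statistics at the core

For a 2x2 table with fixed margins, the two-sided Fisher p-value is

    p = sum over tables T with the observed margins of P(T),
        restricted to P(T) <= P(observed) * (1 + 1e-7),

with P(T) hypergeometric. Transcript-set benchmarking uses the standard
transcript-level definition: a prediction matches a truth transcript iff
their junction chains are identical and both terminal ends agree within a
50 bp wiggle; sensitivity = 100·TP/(TP+FN), precision = 100·TP/(TP+FP).

## Worked example

```r
library(loriso)
cfg <- sim_config(seed = 7, n_genes = 4, transcripts_per_gene = 2,
                  reads_per_transcript = 12, error_rate = 0.01,
                  truncation_prob = 0.3, variants_per_kb = 2)
d <- simulate_dataset(cfg, "example_data")
res <- run_collapse(d$genome, d$gtf, d$genome_sam[[1]], tx_aln = d$tx_sam,
                    vcfs = d$vcf, out_dir = "example_run",
                    pcfg = phasing_config(min_coverage = 5))
truth <- flatten_transcripts(read_gtf(d$gtf))
match_transcripts(lapply(res$final, `[[`, "tx"), truth)
#> <match_report> TP=8 FP=0 FN=0 | sensitivity 100.0% precision 100.0%
str(res$manifest[c("n_reads", "n_assigned", "n_unassigned",
                   "n_final", "n_haplotyped_isoforms")])
#> List of 5
#>  $ n_reads              : int 96
#>  $ n_assigned           : int 69
#>  $ n_unassigned         : int 27
#>  $ n_final              : int 8
#>  $ n_haplotyped_isoforms: int 8
head(res$hst[, c("gene_id", "isoform_id", "a", "b", "c", "d", "p")], 3)
#>   gene_id isoform_id a b c d          p
#> 1  gene01  gene01.t1 6 0 4 4 0.08491508
#> 2  gene01  gene01.t1 0 6 4 4 0.08491508
#> 3  gene01  gene01.t2 4 4 6 0 0.08491508
```

Of 96 simulated reads, 69 pass the fidelity rules against the annotation
and 27 (mostly truncated reads) go through novel-model detection; all 8
true isoforms are recovered with no false positives, every isoform is
phased into haplotypes, and the per-gene Fisher tables show the expected
mild (non-significant at this depth) isoform-haplotype coupling. The run
directory contains `isoforms.bed/gtf/fa`, `read_map.tsv`, HST outputs
(`hst.fa/bed/vcf`, `hst_tests.tsv`) and a `manifest.json` with per-stage
counts.

A command-line wrapper is installed as `exec/loriso` with subcommands
`collapse`, `editing` and `evaluate` mirroring `run_collapse()`,
`run_editing()` and `run_evaluate()`.

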