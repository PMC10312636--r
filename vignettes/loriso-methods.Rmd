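---
title: "loriso: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{loriso: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models
and rules it implements, the parameters that matter, the numerical
choices behind them, and what the bundled simulator does and does not
emulate. All coordinates inside the package are 0-based half-open (BED
convention); GTF and VCF coordinates are converted at the I/O boundary
and nowhere else.

## 1. Read-to-isoform assignment under splice-site fidelity

High-accuracy consensus long reads (~99% identity) still carry enough
substitution error, and enough 5'/3' truncation from cDNA synthesis,
that naive best-hit assignment against a transcriptome produces wrong
isoform calls concentrated around splice sites. Assignment therefore
applies two rules to each read's ranked transcriptome alignments
(ranked by mapping quality, ties by fewer mismatches+indels, then
lexicographic transcript id, so the ranking is fully deterministic):

* **Stringent** (`fidelity_config()`): at least `min_identity` (default
  0.80, inclusive) of the aligned read bases must match the transcript
  — soft-clipped bases are excluded from the denominator because clips
  reflect adapters and poly(A), not transcript disagreement — and the
  alignment must span *into* the first and last `end_span_bp` (default
  25) bases of the terminal exons.

  The end-span rule deserves a precise statement, because "spans into
  25 bp of the first exon" admits two readings. We require that the
  alignment leaves at most `min(end_span_bp, exon_length)` bases of the
  first exon uncovered at the 5' end, and symmetrically at the 3' end.
  Under this reading an alignment that starts 30 bp into a 200 bp first
  exon fails (it missed more than 25 bp of the transcript start), which
  is the behaviour the rule exists for: rejecting badly truncated
  reads. The alternative reading ("covers at least 25 bp of the first
  exon somewhere") would accept arbitrarily truncated reads whenever
  the first exon is long, defeating the purpose. The `min(...)` guard
  keeps the rule satisfiable for exons shorter than 25 bp. Boundaries
  are inclusive: missing exactly 25 bp passes.

* **Splice check**: for every junction whose full window (3 bases each
  side, 6 total) is covered by the alignment, at least
  `min_flank_matches` (default 4) of the 6 window bases must be
  matches, and no insertion or deletion longer than
  `max_splice_indel_bp` (default 3, inclusive — a 3 bp indel passes)
  may touch the window. "4 of 6" is evaluated over the pooled window,
  not per side. Junctions not fully covered impose no constraint, so a
  truncated read can still be assigned on the junctions it does cover.
  Insertions are counted against a window only when strictly inside it
  (an insertion is an event between two reference bases, so a window
  boundary insertion is ambiguous; we resolve the ambiguity toward
  leniency and document it here).

A read is assigned to the first ranked candidate passing both rules;
annotated isoforms with at least `min_support` (default 3, inclusive)
assigned reads are reported. Mono-exon transcripts have no junctions,
so the splice check passes vacuously and assignment rests on the
stringent rule alone — we deliberately allow mono-exon assignment
rather than requiring junction coverage, and record the choice here.

Mismatch positions are reconstructed from SAM `MD` tags (or directly
from extended `=`/`X` CIGAR operations when the aligner emits them);
an alignment with `M` runs and neither an MD tag nor extended ops is a
hard error, because the fidelity rules cannot be evaluated without
per-base match information.

## 2. Novel isoform detection (collapse)

Reads that no annotated transcript accepts are collapsed from their
genome alignments:

1. **Splice-site correction.** Donor and acceptor positions are snapped
   to the nearest evidence site within `correction_window` bp (default
   10; the window is a package choice — typical for this read accuracy
   class — and configurable). Evidence sites come from the annotation
   and optional short-read junction BED (always usable) and from the
   long reads themselves (usable once seen in `min_support` distinct
   reads, our concrete reading of "more evidence"). Ties go to the
   smaller coordinate; a read with any uncorrectable site is excluded
   from model building but still participates in re-assignment.
2. **Grouping by junction chain.** Exact chain equality; a chain that
   is a strict prefix of another is a different group. Mono-exon reads
   form one group per overlap-connected locus.
3. **End calling.** Within a group, read starts (and independently
   ends) are clustered by single linkage with gap `end_window`
   (default 100 bp — chosen once to match the end variability of cDNA
   reads; no algorithm is canonical here, and single linkage is simple
   and deterministic). Each occupied (start-cluster, end-cluster) pair
   becomes one first-pass model; its TSS/TES are the pair's
   most-supported positions, ties resolved outermost.
4. **Re-assignment.** Every unassigned read is scored against every
   compatible first-pass model (its corrected chain must be a
   consecutive sub-chain of the model's) with the same stringent and
   splice rules, evaluated in genome coordinates; overhang past a
   model's ends is treated as clipped. Among passing candidates the
   read supports the model covering most of its bases, ties broken
   toward the fuller model, then lexicographically.
5. **Finalisation.** Novel models need `min_support` reads; a novel
   chain identical to a retained annotated isoform merges into the
   annotated record. With `filter_subsets = TRUE` (default), a novel
   model whose chain is a consecutive sub-chain of a retained isoform
   and whose span lies inside it is dropped, and a mono-exon novel
   contained in any retained isoform's exon is dropped. This is the
   package's guard against 5'-truncation artifacts: with ~30% of cDNA
   reads truncated, prefix-chain models otherwise accumulate enough
   support to pass the threshold and dominate the false-positive count.
   The filter mirrors the default subset filtering of mature collapse
   tools and is switchable for degradation-aware analyses.

The strand of a novel model is inferred by majority vote over its
intron boundary dinucleotides (GT..AG forward, CT..AC reverse at the
genome level), falling back to the majority alignment strand, because
cDNA strandness itself is unreliable.

## 3. Haplotypes and haplotype-specific transcripts

Variant call sets are combined as a union of single-nucleotide records
(multi-allelic records are split per ALT; non-SNVs are skipped and
counted), deduplicated keeping the maximum quality and concatenated
caller provenance, and filtered to sites with read coverage at least
`min_coverage` (default 10).

**Ploidy-agnostic tabulation** maps each supporting read of an isoform
to its allele vector over the variant positions inside the isoform's
exons. Complete vectors are counted; vectors with support at least
`min_haplotype_support` (default 3) *and* at least
`min_haplotype_fraction` (default 0.10, inclusive) of the isoform's
reads become haplotypes, indexed by descending support (ties broken on
the allele string). Two post-passes keep 1% sequencing error from
fragmenting haplotypes, both switchable: a complete low-support vector
differing from exactly one surviving haplotype at exactly one position
is absorbed into it, and a read not covering all positions is credited
to the unique surviving haplotype consistent with the positions it does
cover (ambiguous reads are held out). More than two haplotypes per
isoform are deliberately allowed — aneuploid tumour genomes and
RNA-level variation motivate the mode.

**Phase-set mode** partitions an isoform's reads by caller-assigned
(`PS`, `HP`) tags and takes each partition's allele vector from the
phased VCF genotypes; reads without tags are counted and excluded, and
a read whose carried allele conflicts with its tag follows the tag
(with a conflict counter), since the tag integrates evidence along the
whole molecule.

**HST bias test.** Within a gene with at least two isoforms and two
haplotypes, every (isoform, haplotype) pair is tested on the 2x2 table
(reads of this isoform on this haplotype / on others; reads of other
isoforms on this haplotype / on others) with the two-sided Fisher's
exact test. Adjustment is Benjamini-Hochberg across *all* genes
(transcriptome-wide): the alternative — per-gene adjustment — is
defensible but weaker for genome-scale discovery lists, and the choice
is recorded here. "Adjusted p-value" is BH by default with Bonferroni
as an option; the underlying workflow this package models does not name
its procedure, and BH is the field default for discovery lists.

HST outputs duplicate each isoform per haplotype under the name
`<transcript_id>_<haplotype_index>_<gene_id>` (a package convention,
stated here because no standard exists), substitute alt alleles into
the spliced sequence in transcript orientation (a genome-level T>C on a
minus-strand isoform appears as A>G in the transcript), and annotate
the VCF with an `ISO` INFO key listing carrying isoforms.

## 4. Editing analyses

Candidate sites are the union of A>G / T>C SNV calls and an optional
user-supplied known-sites BED; each site's strand comes from the host
gene's annotation, and sites overlapping no gene, or genes on both
strands, are skipped (reads from unannotated loci cannot be
strand-resolved, so they are excluded rather than guessed).

* **Pileup**: per site and condition, reads carrying the strand-sense
  reference base vs the edited base. Other bases and deletions are
  excluded from the fraction denominator; spliced-out positions are
  tracked separately for the editing-vs-splicing test.
* **Differential editing**: conditions are pooled (replicate-aware
  testing is out of scope); a site is reported when the *larger* of
  the two coverages reaches `min_cov` = 10 — the literal reading of
  "coverage of 10 in either condition"; requiring both is defensible
  and available by filtering the pileup —, the edited-fraction change
  reaches `min_delta` = 0.10, and the Fisher p-value is below 0.05.
* **Type I hyperediting**: edited fraction strictly above 0.40.
* **Type II hyperediting**: maximal regions in which every member edit
  lies in some 150 bp window containing at least 3 edits; qualifying
  windows sharing a member merge. The window rule defines windows, not
  regions, so the merging rule is declared here; region bounds are the
  outermost member positions. A stricter per-read criterion (a fraction
  of the read length edited) exists in the hyperediting literature; we
  implement only the positional rule and leave per-read filtering to
  the caller via the per-read summaries.
* **Coordination**: for each site, its 20 nearest candidate sites at
  distance >= 50 bp are paired with it; unordered pairs are tested once
  on the 2x2 of doubly-covering reads (both edited / first only /
  second only / neither). Raw p-values carry the significance flag, as
  in the workflow this package models; a BH column is emitted
  alongside. The editing-vs-splicing test reports sites that are type I
  hyperedited among exonic reads, with >= 10 edited reads and >= 10
  reads splicing the position out. The orchestration runs these
  single-condition analyses on the control (editing-intact) condition;
  the choice is a package decision, stated here.

## 5. Statistical primitives

`fisher_exact_two_sided()` enumerates the hypergeometric distribution
over the table's support (via `stats::dhyper`) and sums probabilities
not exceeding the observed one with a `1 + 1e-7` relative tie
tolerance — the convention of the widely used implementations, so that
boundary tables agree to floating-point precision. A table with an
empty margin returns p = 1. The test suite verifies the function
against an independent binomial-coefficient enumeration on every 2x2
table with N <= 40 (about 1.4e5 tables) and against
`stats::fisher.test`. `bh_adjust()` delegates to `stats::p.adjust`.

## 6. The simulator: what it emulates, and what it does not

`sim_config()` defaults are the package's reference study conditions:
substitution error 0.01 (the ~99% consensus-accuracy regime), 30%
truncation incidence (5'-biased, 3:1), 100 reads per transcript, genes
of 4-6 exons (120-300 bp) on alternating strands with canonical GT..AG
intron boundaries, het variant density 2 per kb of shared exonic
sequence, Bernoulli per-read edits at per-site, per-condition
fractions. The same seed yields byte-identical artifacts.

Alignments are *truth-derived*: SAM records are written directly from
the simulation's knowledge of each read's origin, with exact junctions,
MD tags and (for variant simulations) `PS`/`HP` tags. This keeps the
whole pipeline testable with no aligner in the loop, and it is also the
simulator's main fidelity limitation: alignment artifacts — spurious
junction wobble, misplaced indels near splice sites, multimapping,
reference bias at variant sites — are absent. Passing tests therefore
demonstrate the correctness of the package's logic under its stated
error model, not robustness to aligner pathology. Indel sequencing
error is likewise off by default (consensus reads are
substitution-dominated); the splice-indel rule is exercised with
constructed fixtures instead. Single-cell barcode structure, intron
retention from incomplete splicing, and expression-level variation
between isoforms are not modelled.

## 7. Verification sizes and estimator choices

The test suite runs everything at desk scale, sizes chosen as the
smallest that exercise the claimed property: exhaustive 2x2 enumeration
to N = 40; single-factor perturbation fixtures for every fidelity
boundary (79/80/81% identity, 24/25/26 bp end span, 3/4/5 of 6 flank
matches, 3/4 bp splice indels); a 20-transcript, 2000-read collapse
recovery run benchmarked with the 50 bp-wiggle matcher; 500 random
instances against a window-enumeration oracle for type II regions; 50
diploid isoforms at 30 reads per haplotype for phasing recovery and
cross-mode agreement; replicated 200-site differential-editing panels
at coverage 30 per condition.

One estimator choice is worth recording. At coverage 30 and fractions
0.5 vs 0.1, the exact test with the delta filter has a per-site
detection probability of about 0.91, so a single 50-site panel
estimates sensitivity with a binomial SD near 0.04 — coarser than the
margin between the true value and the 0.90 bound being checked. The
differential-editing recovery test therefore pools 20 replicate panels
(1000 true sites) generated under identical per-panel conditions, and
`scripts/acceptance.R` pools 5; the per-panel design, thresholds and
filters are unchanged. That fixture also uses error-free reads so that
the pileup denominator is exactly the stated coverage of 30 —
substitution errors would silently shrink it.

## 8. Known limitations

* Fusion/chimeric reads, CRAM input and GFF3 are unsupported.
* Quantification and differential isoform usage are out of scope; the
  read map and per-isoform supports are exported for downstream tools.
* The coverage filter for variant combination counts reads from one
  alignment set; callers with private realignments may disagree.
* The coordination tests report raw p-values by design; at
  transcriptome scale users should read the emitted BH column.
* Mono-exon novel models contained in longer isoforms are filtered by
  default, which will also remove genuine short RNAs processed out of
  host transcripts; disable `filter_subsets` to keep them.
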