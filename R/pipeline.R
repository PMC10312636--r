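.read_models_any <- function(path, source = "annotated") {
  if (grepl("\\.(bed|bed12)$", path, ignore.case = TRUE))
    read_bed12(path, source = source)
  else flatten_transcripts(read_gtf(path))
}

.load_genome <- function(path) Biostrings::readDNAStringSet(path)

.primary <- function(alns) Filter(function(a) !a$secondary, alns)

#' Run the collapse workflow: assignment, novel detection, phasing
#'
#' Executes the annotation-reliant assignment stage (when a
#' transcriptome alignment file is given), collapses the unassigned
#' reads into novel isoform models, merges and filters the final set,
#' and optionally integrates variants into haplotype-specific
#' transcripts. All artifacts plus a JSON run manifest with per-stage
#' counts are written to `out_dir`.
#'
#' @param genome_fa Genome FASTA.
#' @param gtf Annotation GTF.
#' @param genome_aln Genome SAM/BAM of all reads.
#' @param tx_aln Optional transcriptome SAM/BAM (enables the
#'   annotation-reliant stage).
#' @param vcfs Optional character vector of VCF paths (enables phasing).
#' @param junctions_bed Optional short-read junction BED.
#' @param out_dir Output directory.
#' @param fcfg,ccfg,pcfg Fidelity / collapse / phasing configurations.
#' @param phase_mode `"tabulate"` (ploidy-agnostic) or `"phaseset"`
#'   (diploid, requires HP/PS tags and phased genotypes).
#' @return Invisibly, a list with the final isoform records, the read
#'   map, haplotypes, HST test table and the manifest.
#' @export
run_collapse <- function(genome_fa, gtf, genome_aln, tx_aln = NULL,
                         vcfs = NULL, junctions_bed = NULL,
                         out_dir = ".", fcfg = fidelity_config(),
                         ccfg = collapse_config(), pcfg = phasing_config(),
                         phase_mode = c("tabulate", "phaseset")) {
  phase_mode <- match.arg(phase_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- .load_genome(genome_fa)
  genes <- read_gtf(gtf)
  ann_tx <- flatten_transcripts(genes)
  names(ann_tx) <- vapply(ann_tx, `[[`, character(1), "transcript_id")
  g_alns <- .primary(read_alignments(genome_aln, "genome"))
  all_ids <- vapply(g_alns, `[[`, character(1), "read_id")
  manifest <- list(stage = "load", n_reads = length(g_alns),
                   n_annotated_transcripts = length(ann_tx))
  assignments <- data.frame(read_id = character(0),
                            transcript_id = character(0),
                            stringsAsFactors = FALSE)
  annotated_supported <- list()
  unassigned_ids <- all_ids
  if (!is.null(tx_aln)) {
    t_alns <- read_alignments(tx_aln, "transcript")
    cands <- select_best_transcript_alignments(t_alns)
    asg <- assign_reads(cands, ann_tx, fcfg)
    assignments <- asg$assignments
    annotated_supported <- supported_annotated_isoforms(assignments, ann_tx,
                                                        fcfg)
    unassigned_ids <- setdiff(all_ids, assignments$read_id)
  }
  manifest$n_assigned <- nrow(assignments)
  manifest$n_unassigned <- length(unassigned_ids)
  un_reads <- g_alns[all_ids %in% unassigned_ids]
  sr <- if (!is.null(junctions_bed)) read_junction_bed(junctions_bed) else NULL
  evidence <- junction_evidence(ann_tx, sr, un_reads,
                                min_support = ccfg$min_support)
  corr <- correct_splice_sites(un_reads, evidence, ccfg)
  manifest$n_uncorrectable <- length(corr$flagged)
  groups <- group_by_junction_chain(corr$reads)
  firstpass <- build_firstpass(groups, genome, ccfg)
  manifest$n_firstpass <- length(firstpass)
  fpa <- assign_to_firstpass(corr$reads, firstpass, fcfg)
  final <- finalize_isoforms(firstpass, fpa$supports, annotated_supported,
                             ccfg)
  manifest$n_final <- length(final)
  manifest$n_final_novel <- sum(vapply(final, function(r)
    r$tx$source == "novel", logical(1)))
  final_models <- lapply(final, `[[`, "tx")
  write_isoforms(final_models, bed_path = file.path(out_dir, "isoforms.bed"),
                 gtf_path = file.path(out_dir, "isoforms.gtf"),
                 fasta_path = file.path(out_dir, "isoforms.fa"),
                 genome = genome)
  read_map <- do.call(rbind, c(list(data.frame(read_id = character(0),
                                               isoform_id = character(0),
                                               stringsAsFactors = FALSE)),
                               lapply(final, function(r)
                                 if (length(r$read_ids) == 0L) NULL else
                                   data.frame(read_id = r$read_ids,
                                              isoform_id = r$tx$transcript_id,
                                              stringsAsFactors = FALSE))))
  utils::write.table(read_map, file.path(out_dir, "read_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  haplotypes <- NULL; hst <- NULL
  if (!is.null(vcfs) && length(vcfs) > 0L) {
    vlists <- lapply(vcfs, function(p)
      read_vcf(p, caller = tools::file_path_sans_ext(basename(p))))
    combined <- combine_variant_calls(vlists, g_alns,
                                      min_coverage = pcfg$min_coverage)
    manifest$n_variants <- length(combined)
    aln_by_id <- g_alns
    names(aln_by_id) <- all_ids
    iso_models <- list()
    haplotypes <- list()
    hap_rows <- list()
    for (r in final) {
      iso_models[[r$tx$transcript_id]] <- r$tx
      sup <- aln_by_id[intersect(r$read_ids, names(aln_by_id))]
      haps <- if (phase_mode == "phaseset")
        phase_by_phase_set(r$tx, sup, combined, pcfg)
      else tabulate_haplotypes(r$tx, sup, combined, pcfg)
      if (length(haps) == 0L) next
      haplotypes[[r$tx$transcript_id]] <- haps
      for (h in haps)
        hap_rows[[length(hap_rows) + 1L]] <- data.frame(
          gene_id = r$tx$gene_id, isoform_id = r$tx$transcript_id,
          haplotype_key = paste(names(h$alleles), h$alleles, sep = ":",
                                collapse = ","),
          support = h$support, stringsAsFactors = FALSE)
    }
    manifest$n_haplotyped_isoforms <- length(haplotypes)
    if (length(haplotypes)) {
      emit_hst_outputs(haplotypes, iso_models, combined, genome,
                       fasta_path = file.path(out_dir, "hst.fa"),
                       bed_path = file.path(out_dir, "hst.bed"),
                       vcf_path = file.path(out_dir, "hst.vcf"))
      hap_table <- do.call(rbind, hap_rows)
      hst <- hst_bias_test(hap_table)
      utils::write.table(hst, file.path(out_dir, "hst_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$n_hst_significant <- sum(hst$significant)
    }
  }
  manifest$config <- list(fidelity = unclass(fcfg), collapse = unclass(ccfg),
                          phasing = unclass(pcfg), phase_mode = phase_mode)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(final = final, read_map = read_map,
                 haplotypes = haplotypes, hst = hst, manifest = manifest))
}

.read_sites_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(f, `[`, character(1), 1),
             start = as.integer(vapply(f, `[`, character(1), 2)),
             end = as.integer(vapply(f, `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}

#' Run the editing workflow: pileup, differential, hyperediting,
#' coordination
#'
#' @param genome_fa Genome FASTA (reserved; strand is annotation-based).
#' @param gtf Annotation GTF (gene strands).
#' @param alns Named character vector/list: condition -> genome SAM/BAM.
#' @param vcfs Character vector of VCF paths providing candidate sites.
#' @param known_bed Optional known-editing-sites BED.
#' @param out_dir Output directory.
#' @param control,knockdown Condition names; differential testing is
#'   skipped (with a warning) unless both are present in `alns`.
#' @param min_cov,min_delta,alpha Differential-editing thresholds.
#' @param type1_threshold,type2_window,type2_min_edits Hyperediting
#'   parameters.
#' @param k_nearest,min_pair_distance Coordination parameters.
#' @return Invisibly, list with pileup, differential, type2 regions,
#'   coordination tables, edit-intron table, read summary, manifest.
#' @export
run_editing <- function(genome_fa, gtf, alns, vcfs, known_bed = NULL,
                        out_dir = ".", control = "control",
                        knockdown = "knockdown", min_cov = 10L,
                        min_delta = 0.10, alpha = 0.05,
                        type1_threshold = 0.40, type2_window = 150L,
                        type2_min_edits = 3L, k_nearest = 20L,
                        min_pair_distance = 50L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- read_gtf(gtf)
  variants <- do.call(c, lapply(vcfs, function(p)
    read_vcf(p, caller = tools::file_path_sans_ext(basename(p)))))
  known <- if (!is.null(known_bed)) .read_sites_bed(known_bed) else NULL
  sites <- edit_candidates(variants, genes, known)
  reads_by_cond <- lapply(alns, function(p)
    .primary(read_alignments(p, "genome")))
  names(reads_by_cond) <- names(alns)
  pu <- pileup_edit_counts(reads_by_cond, sites)
  manifest <- list(n_candidate_sites = nrow(sites),
                   conditions = names(alns),
                   n_reads = vapply(reads_by_cond, length, integer(1)))
  diff <- NULL
  if (all(c(control, knockdown) %in% names(alns))) {
    diff <- differential_editing(pu, control, knockdown, min_cov, min_delta,
                                 alpha, type1_threshold)
    utils::write.table(diff, file.path(out_dir, "differential_editing.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$n_differential <- nrow(diff)
  } else {
    warning("both conditions not present; differential stage skipped")
  }
  # analyses of the editing-intact (control) condition
  base_cond <- if (control %in% names(alns)) control else names(alns)[1]
  ed_col <- paste0("edit_", base_cond)
  edited_sites <- pu[pu[[ed_col]] >= 1L, , drop = FALSE]
  regions <- list()
  for (ch in unique(edited_sites$chrom)) for (sr in c("+", "-")) {
    sel <- edited_sites$chrom == ch & edited_sites$strand == sr
    if (!any(sel)) next
    r <- detect_type2_regions(edited_sites$pos0[sel], type2_window,
                              type2_min_edits)
    if (nrow(r)) {
      r$chrom <- ch; r$strand <- sr
      regions[[length(regions) + 1L]] <- r[, c("chrom", "start", "end",
                                               "n_edits", "strand")]
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_edits = integer(0), strand = character(0))
  utils::write.table(regions, file.path(out_dir, "hyperedited_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$n_type2_regions <- nrow(regions)
  base_reads <- reads_by_cond[[base_cond]]
  summary <- summarize_read_editing(base_reads, sites)
  coord <- edit_edit_coordination(sites, base_reads, k_nearest,
                                  min_pair_distance, alpha)
  utils::write.table(
    coord[, setdiff(names(coord), "members")],
    file.path(out_dir, "edit_coordination.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$n_coordinated_pairs <- sum(coord$significant)
  ei <- edit_intron_coordination(sites, base_reads, type1_threshold)
  utils::write.table(ei, file.path(out_dir, "edit_intron.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$n_edit_intron_sites <- nrow(ei)
  manifest$read_summary <- summary
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(pileup = pu, differential = diff, regions = regions,
                 coordination = coord, edit_intron = ei,
                 read_summary = summary, manifest = manifest))
}

#' Compare a predicted isoform set against a truth set
#'
#' @param predicted_path,truth_path BED12 or GTF files.
#' @param end_wiggle Terminal tolerance in bp. Default 50.
#' @param out_tsv Optional TSV of matched pairs.
#' @return The [match_transcripts()] report.
#' @export
run_evaluate <- function(predicted_path, truth_path, end_wiggle = 50L,
                         out_tsv = NULL) {
  pred <- .read_models_any(predicted_path)
  truth <- .read_models_any(truth_path)
  rep <- match_transcripts(pred, truth, end_wiggle)
  if (!is.null(out_tsv))
    utils::write.table(rep$pairs, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  rep
}
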