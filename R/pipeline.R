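#' Configuration for an end-to-end pipeline run
#'
#' Bundles every stage's parameters and seeds. All stage seeds are derived
#' deterministically from the single `seed`, so one integer fixes the whole
#' run; reruns with the same configuration produce byte-identical
#' summaries.
#'
#' @param out_dir Run directory (created if needed).
#' @param seed Master integer seed.
#' @param reference Optional named character vector to use as the
#'   reference; when `NULL` a random genome of `ref_length` bp is drawn.
#' @param ref_length Length of the generated reference (default 40000).
#' @param organelle Optional organelle reference; when `NULL` and
#'   `organelle_fraction > 0`, a random 2 kb organelle stand-in is drawn.
#' @param enzymes Restriction enzyme set (default [default_enzyme_set()]).
#' @param size_window Inclusive fragment-size window (default
#'   `c(100, 150)`).
#' @param snp_rate,depth_target,error_rate,organelle_fraction,read_start
#'   Passed to [sim_config()].
#' @param modes Filter cascades to evaluate (default all four).
#' @param ril_n_lines,ril_generation RIL population size and generation
#'   (defaults 470 F5-derived lines, the mapping population this pipeline
#'   models).
#' @param ril_cm_per_kb Genetic-to-physical scale for the demo marker map
#'   (default 0.5 cM/kb, chosen so the small demo genomes carry measurable
#'   recombination; real genomes are orders of magnitude denser in bp/cM).
#' @param ril_max_markers Markers carried into the RIL stage (default 60).
#' @param n_scaffolds Scaffolds the reference is shredded into for the
#'   anchoring stage (default 8).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed,
                            reference = NULL, ref_length = 40000L,
                            organelle = NULL,
                            enzymes = default_enzyme_set(),
                            size_window = c(100L, 150L),
                            snp_rate = 1 / 425, depth_target = 10,
                            error_rate = 0.002, organelle_fraction = 0.05,
                            read_start = "end",
                            modes = c("GMAP", "VMS", "VSS", "PRODUCTION"),
                            ril_n_lines = 470L, ril_generation = 5L,
                            ril_cm_per_kb = 0.5, ril_max_markers = 60L,
                            n_scaffolds = 8L) {
  seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = seed, reference = reference,
                 ref_length = as.integer(ref_length), organelle = organelle,
                 enzymes = enzymes, size_window = size_window,
                 snp_rate = snp_rate, depth_target = depth_target,
                 error_rate = error_rate,
                 organelle_fraction = organelle_fraction,
                 read_start = read_start, modes = modes,
                 ril_n_lines = as.integer(ril_n_lines),
                 ril_generation = as.integer(ril_generation),
                 ril_cm_per_kb = ril_cm_per_kb,
                 ril_max_markers = as.integer(ril_max_markers),
                 n_scaffolds = as.integer(n_scaffolds)),
            class = "pipeline_config")
}

# Deterministic per-stage seeds derived from the master seed.
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 131L + stage) %% 2147483587L
}

#' Run the full pipeline
#'
#' Stages, in order: reference (given or generated) -> divergent accession
#' with known SNPs -> in-silico digest and size selection -> read
#' simulation with errors and organelle contamination -> 33-mer occurrence
#' table and occurrence-300 exclusion -> organelle screen -> seeded
#' ungapped alignment, placement classification and pileup -> candidate
#' SNPs and the configured filter cascades with VCF/ledger output ->
#' RIL-population simulation over a marker map built from the passing SNPs
#' -> scaffold anchoring on the shredded reference. Writes per-stage files
#' into `config$out_dir` plus `summary.json`; identical configurations
#' yield byte-identical summaries.
#'
#' @param config A [pipeline_config()].
#' @return The summary (a named list), invisibly; side effect: run
#'   directory populated.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  seed <- config$seed
  summary <- list(seed = seed)

  reference <- if (is.null(config$reference)) {
    random_genome(config$ref_length, stage_seed(seed, 1L))
  } else config$reference
  organelle <- config$organelle
  if (is.null(organelle) && config$organelle_fraction > 0) {
    organelle <- random_genome(2000L, stage_seed(seed, 2L), id = "organelle")
  }
  write_fasta(reference, out("reference.fasta"))

  mut <- mutate_genome(reference, config$snp_rate, stage_seed(seed, 3L))
  write_fasta(mut$genome, out("accession.fasta"))
  write_truth_tsv(mut$truth, out("truth.tsv"))
  summary$genome <- list(reference_bp = sum(nchar(reference)),
                         n_truth_snps = nrow(mut$truth))

  frags <- size_select(digest_reference(mut$genome, config$enzymes),
                       config$size_window[1], config$size_window[2])
  write.table(frags[, c("source_id", "start", "end", "length")],
              out("fragments.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  summary$rrl <- list(n_selected_fragments = nrow(frags),
                      selected_bp = sum(frags$length))

  sim <- sim_config(snp_rate = config$snp_rate,
                    depth_target = config$depth_target,
                    error_rate = config$error_rate,
                    organelle_fraction = config$organelle_fraction,
                    seed = stage_seed(seed, 4L),
                    read_start = config$read_start)
  sr <- sample_reads(frags, sim, organelle = organelle)
  write_fastq(sr$reads, out("reads.fastq"))
  summary$reads <- list(n_reads = nrow(sr$reads),
                        n_organelle = sum(sr$provenance$origin == "organelle"))

  counts <- count_kmers(sr$reads)
  occ_tab <- build_occurrence_table(counts)
  write.table(occ_tab, out("occurrence.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  occ_split <- filter_reads_by_occurrence(sr$reads, counts)
  org_split <- screen_organelle(occ_split$kept, organelle)
  kept <- org_split$kept
  summary$screening <- list(
    n_unique_kmers = length(counts),
    n_excluded_occurrence = nrow(occ_split$excluded),
    n_discarded_organelle = nrow(org_split$discarded),
    n_kept = nrow(kept))

  index <- build_index(reference, seed_len = 11L)
  hits <- align_reads(kept, index, max_mismatch = 1L)
  placements <- classify_placements(hits, kept$id)
  aln_dump <- placements[placements$placement == "unique",
                         c("read_id", "target_id", "pos", "strand",
                           "mismatches", "mapping_score")]
  aln_dump$pos <- aln_dump$pos + 1L
  write.table(aln_dump, out("alignments.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pile <- pileup(placements, kept, reference)
  cov <- coverage_stats(pile)
  summary$alignment <- list(
    n_unique = sum(placements$placement == "unique"),
    n_multiple = sum(placements$placement == "multiple"),
    n_unmapped = sum(placements$placement == "unmapped"),
    covered_bases = cov$covered_bases,
    fold_coverage = round(cov$fold_coverage, 4))

  cands <- candidate_snps(pile, reference)
  index8 <- build_index(reference, seed_len = 8L)
  truth_key <- paste(mut$truth$source_id, mut$truth$pos)
  covered_truth <- sum(truth_key %in% paste(pile$target_id, pile$pos))
  summary$snp <- list(n_candidates = nrow(cands),
                      n_truth_covered = covered_truth)
  for (mode in config$modes) {
    cfg <- filter_config(mode)
    res <- if (mode == "GMAP") {
      gmap_cascade(cands, pile, kept, reference, cfg, index8)
    } else {
      maq_cascade(cands, pile, placements, reference, cfg, index8)
    }
    write_snp_report(res$all, out(sprintf("snps_%s.vcf", tolower(mode))),
                     ledger = res$ledger)
    tp <- sum(paste(res$pass$target_id, res$pass$pos) %in% truth_key)
    summary$snp[[mode]] <- list(
      n_pass = nrow(res$pass), n_true_positive = tp,
      precision = if (nrow(res$pass)) round(tp / nrow(res$pass), 4) else NA,
      recall_covered = if (covered_truth) round(tp / covered_truth, 4)
        else NA)
  }

  # genetic-map stage: markers from the most supported passing SNPs of the
  # first configured cascade, genetic positions on a uniform cM/kb scale
  first_mode <- config$modes[1]
  cfg1 <- filter_config(first_mode)
  res1 <- if (first_mode == "GMAP") {
    gmap_cascade(cands, pile, kept, reference, cfg1, index8)
  } else {
    maq_cascade(cands, pile, placements, reference, cfg1, index8)
  }
  mk <- res1$pass
  if (nrow(mk) > config$ril_max_markers) {
    mk <- mk[order(-mk$support, mk$target_id, mk$pos), , drop = FALSE]
    mk <- mk[seq_len(config$ril_max_markers), , drop = FALSE]
  }
  mk <- mk[order(mk$target_id, mk$pos), , drop = FALSE]
  summary$ril <- list(n_markers = nrow(mk))
  if (nrow(mk) >= 2L) {
    ref_offsets <- cumsum(c(0L, unname(nchar(reference))[-length(reference)]))
    gpos <- ref_offsets[match(mk$target_id, names(reference))] + mk$pos
    map <- marker_map(marker_id = sprintf("M%03d", seq_len(nrow(mk))),
                      linkage_group = "LG1",
                      cm_pos = gpos / 1000 * config$ril_cm_per_kb)
    geno <- simulate_ril_population(map, config$ril_n_lines,
                                    config$ril_generation,
                                    stage_seed(seed, 5L))
    qc <- qc_filter(geno)
    write_genotypes_tsv(qc$kept, out("genotypes.tsv"))
    summary$ril$n_lines <- config$ril_n_lines
    summary$ril$n_lines_kept <- nrow(qc$kept)
    summary$ril$mean_het_pct <- round(100 * mean(heterozygosity(geno)), 3)

    # anchoring stage: shred the reference into scaffolds, place the
    # markers physically, anchor with the simulated map positions
    total_bp <- sum(nchar(reference))
    cuts <- round(seq(0, total_bp, length.out = config$n_scaffolds + 1L))
    scafs <- data.frame(scaffold_id = sprintf("scaf%02d",
                                              seq_len(config$n_scaffolds)),
                        length = as.integer(diff(cuts)),
                        stringsAsFactors = FALSE)
    si <- findInterval(gpos, cuts[-length(cuts)])
    markers <- data.frame(marker_id = map$marker_id,
                          scaffold_id = scafs$scaffold_id[si],
                          phys_pos = as.integer(gpos - cuts[si]),
                          cm_pos = map$cm_pos,
                          linkage_group = "LG1",
                          stringsAsFactors = FALSE)
    anchors <- anchor_scaffolds(scafs, markers)
    write_anchor_tsv(anchors, out("anchors.tsv"))
    irep <- integration_report(anchors)
    summary$anchoring <- list(counts = as.list(irep$counts),
                              anchored_fraction =
                                round(irep$anchored_fraction, 4))
  }

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}

#' A small built-in demonstration run
#'
#' A 20 kb reference at the default accession divergence and error rate;
#' finishes in well under a minute and exercises every stage.
#'
#' @param out_dir Run directory.
#' @param seed Master seed (default 1).
#' @param modes Cascades to run (default `"VMS"` and `"VSS"`).
#' @return The run summary, invisibly.
#' @export
run_demo <- function(out_dir, seed = 1L, modes = c("VMS", "VSS")) {
  cfg <- pipeline_config(out_dir, seed = seed, ref_length = 20000L,
                         modes = modes, ril_n_lines = 200L,
                         n_scaffolds = 5L)
  run_all(cfg)
}
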