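#' Filter-cascade configuration
#'
#' Fixes the thresholds of one of the four SNP filter cascades. `GMAP` is
#' the quality-score-free cascade (base-quality read screen, unique
#' placement, conflict-free support by two or more reads, both-flank
#' repetitiveness test). `VMS`, `VSS` and `PRODUCTION` are the
#' consensus-quality cascades: density screen, unambiguous consensus,
#' minimum consensus quality (20 for VMS/VSS, 27 for the production run),
#' exact read-copy 1.00, mapping score of at least 30, two supporting reads
#' for VMS only, and per-mode flank-repetitiveness rules (VMS/VSS: 121 nt
#' N-free centre and both immediate 25-mer flanks repetitive excludes;
#' PRODUCTION: 601 nt N-free centre and more than 1/3 repetitive 25-mer
#' windows across the 300 nt flanks excludes).
#'
#' @param mode One of `"GMAP"`, `"VMS"`, `"VSS"`, `"PRODUCTION"`.
#' @param min_base_q Read-level minimum base quality (GMAP cascade).
#' @param min_consensus_q Minimum consensus quality (VMS/VSS 20,
#'   PRODUCTION 27).
#' @param min_support Minimum supporting reads (2 for GMAP/VMS, 1 for
#'   VSS/PRODUCTION).
#' @param min_map_score Minimum mapping score of every supporting read.
#' @param density_window SNP-density window in bp (default 25).
#' @param flank_len Flank length scanned in PRODUCTION mode (default 300;
#'   120 gives the shorter published reading of the rule). The N-free
#'   centre region is `2 * flank_len + 1` nt in PRODUCTION and 121 nt
#'   otherwise.
#' @param flank_min_hits Other-locus hits that make a 25-mer repetitive
#'   (1 in the single-flank modes; 5 in PRODUCTION).
#' @param flank_max_mismatch Mismatch tolerance of the flank scan
#'   (default 2).
#' @param max_rep_fraction Maximum tolerated repetitive-window fraction in
#'   PRODUCTION (default 1/3, pooled over both flanks).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(mode = c("GMAP", "VMS", "VSS", "PRODUCTION"),
                          min_base_q = 10L,
                          min_consensus_q = NULL,
                          min_support = NULL,
                          min_map_score = 30L,
                          density_window = 25L,
                          flank_len = 300L,
                          flank_min_hits = NULL,
                          flank_max_mismatch = 2L,
                          max_rep_fraction = 1 / 3) {
  mode <- match.arg(mode)
  if (is.null(min_consensus_q)) {
    min_consensus_q <- switch(mode, GMAP = 0L, VMS = 20L, VSS = 20L,
                              PRODUCTION = 27L)
  }
  if (is.null(min_support)) {
    min_support <- switch(mode, GMAP = 2L, VMS = 2L, VSS = 1L,
                          PRODUCTION = 1L)
  }
  if (is.null(flank_min_hits)) {
    flank_min_hits <- if (mode == "PRODUCTION") 5L else 1L
  }
  center_n_len <- if (mode == "PRODUCTION") 2L * flank_len + 1L else 121L
  structure(list(mode = mode, min_base_q = min_base_q,
                 min_consensus_q = min_consensus_q,
                 min_support = min_support, min_map_score = min_map_score,
                 density_window = density_window, flank_len = flank_len,
                 center_n_len = center_n_len,
                 flank_min_hits = flank_min_hits,
                 flank_max_mismatch = flank_max_mismatch,
                 max_rep_fraction = max_rep_fraction),
            class = "filter_config")
}

#' Call the consensus base of one pileup column
#'
#' The consensus is the quality-weighted modal base; its quality is the
#' quality-sum margin of the winning base over all discordant observations,
#' floored at 0 and capped at 60. This capped quality-sum difference is the
#' package's deterministic stand-in for a Bayesian consensus quality: it is
#' monotone in support and in opposition, which is all the downstream
#' threshold rules require. A quality-sum tie yields the ambiguous base
#' `"N"` with quality 0, which the ambiguity rule then eliminates.
#'
#' @param column Pileup rows of a single position (columns `base`, `qual`),
#'   or a list with `base` and `qual` vectors.
#' @return List with `consensus_base` and `consensus_quality`.
#' @examples
#' call_consensus(list(base = c("G", "G", "G"), qual = c(35, 35, 35)))
#' @export
call_consensus <- function(column) {
  base <- column$base
  qual <- column$qual
  if (length(base) == 0L) stop("call_consensus(): empty column")
  sums <- tapply(as.numeric(qual), base, sum)
  top <- max(sums)
  winners <- names(sums)[sums == top]
  if (length(winners) > 1L) {
    return(list(consensus_base = "N", consensus_quality = 0L))
  }
  q <- max(0, min(60, top - sum(sums[names(sums) != winners])))
  list(consensus_base = winners, consensus_quality = as.integer(round(q)))
}

#' Derive candidate SNPs from a pileup
#'
#' One candidate per pileup column whose consensus base differs from the
#' reference base (including ambiguous `"N"` consensus calls, which are
#' recorded so the cascades can eliminate and ledger them). `support`
#' counts reads showing the consensus base (for `"N"` calls, the modal
#' non-reference base), `conflict` all other observations, and
#' `avg_read_copy` the mean placement multiplicity of the supporting reads.
#'
#' @param pile Long-form pileup from [pileup()].
#' @param reference Named character vector (unused directly — the pileup
#'   carries `ref_base` — but kept so callers hold the pair together).
#' @return `data.frame(target_id, pos, ref_base, consensus_base,
#'   consensus_quality, support, conflict, depth, avg_read_copy)`, sorted
#'   by (target, pos).
#' @export
candidate_snps <- function(pile, reference = NULL) {
  empty <- data.frame(target_id = character(), pos = integer(),
                      ref_base = character(), consensus_base = character(),
                      consensus_quality = integer(), support = integer(),
                      conflict = integer(), depth = integer(),
                      avg_read_copy = numeric(), stringsAsFactors = FALSE)
  if (nrow(pile) == 0L) return(empty)
  dt <- as.data.table(pile)
  out <- dt[, {
    cc <- call_consensus(list(base = base, qual = qual))
    supp_base <- cc$consensus_base
    if (supp_base == "N") {
      nonref <- base[base != ref_base[1]]
      supp_base <- if (length(nonref)) names(sort(-table(nonref)))[1] else
        ref_base[1]
    }
    list(ref_base = ref_base[1],
         consensus_base = cc$consensus_base,
         consensus_quality = cc$consensus_quality,
         support = sum(base == supp_base),
         conflict = sum(base != supp_base),
         depth = .N,
         avg_read_copy = mean(read_copy[base == supp_base]))
  }, by = .(target_id, pos)]
  out <- out[consensus_base != ref_base]
  setorder(out, target_id, pos)
  as.data.frame(out)
}

#' Eliminate clustered candidates
#'
#' Two or more candidates within a 25-base window are all eliminated:
#' "within a window" is read as pairwise distance strictly below
#' `window` bp (positions 100 and 124 fall in one 25-base window and both
#' go; 100 and 125 do not, and both stay).
#'
#' @param candidates Candidate `data.frame` sorted by (target, pos).
#' @param window Window size in bp (default 25).
#' @return Logical vector: `TRUE` where the candidate survives.
#' @export
density_pass <- function(candidates, window = 25L) {
  n <- nrow(candidates)
  if (n == 0L) return(logical(0))
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    same <- candidates$target_id == candidates$target_id[i]
    near <- same & abs(candidates$pos - candidates$pos[i]) < window
    if (sum(near) > 1L) ok[i] <- FALSE
  }
  ok
}

#' @rdname density_pass
#' @return `density_filter()` returns the surviving rows.
#' @export
density_filter <- function(candidates, window = 25L) {
  candidates[density_pass(candidates, window), , drop = FALSE]
}

# Does a 25-mer at 0-based `wstart` on `target` hit >= min_hits OTHER
# genome locations with <= max_mismatch mismatches (ungapped, both strands)?
# The window's own locus (same target and start, either strand) is excluded.
window_is_repetitive <- function(window, target, wstart, index,
                                 max_mismatch = 2L, min_hits = 1L) {
  hits <- ungapped_hits(window, index, max_mismatch = max_mismatch)
  other <- !(hits$target_id == target & hits$pos == wstart)
  sum(other) >= min_hits
}

#' Flank-repetitiveness test around a candidate SNP
#'
#' In the single-flank modes (`GMAP`, `VMS`, `VSS`) the 25-mer immediately
#' upstream and the 25-mer immediately downstream of the SNP are each
#' scanned against the whole genome (ungapped, both strands, up to
#' `flank_max_mismatch` mismatches, the window's own locus excluded); a
#' flank is repetitive when it hits at least one other location. In
#' `PRODUCTION` mode every 25-mer window across the `flank_len` nt upstream
#' and downstream regions is scanned; a window is repetitive when it hits
#' `flank_min_hits` (five) or more other positions, and the pooled fraction
#' of repetitive windows is returned. Flanks truncated by a sequence end
#' are evaluated over the available windows and flagged.
#'
#' @param reference Named character vector.
#' @param target_id Target sequence id.
#' @param pos 0-based SNP position.
#' @param config A [filter_config()]; its `mode` selects the protocol.
#' @param index Optional 8-mer [build_index()] over `reference` (built on
#'   the fly when absent — pass one when testing many candidates).
#' @return Single-flank modes: list with logical `upstream`, `downstream`
#'   (`NA` when fully truncated) and `truncated`. PRODUCTION: list with
#'   `repetitive_fraction`, `n_windows`, `n_repetitive`, `truncated`.
#' @export
flank_repetitive <- function(reference, target_id, pos, config,
                             index = NULL) {
  seqstr <- reference[[target_id]]
  L <- nchar(seqstr)
  if (pos < 0L || pos >= L) stop("flank_repetitive(): pos outside reference")
  if (is.null(index)) index <- build_index(reference, seed_len = 8L)
  P <- pos + 1L   # 1-based
  if (config$mode != "PRODUCTION") {
    up_ok <- P - 25L >= 1L
    dn_ok <- P + 25L <= L
    up <- if (up_ok) {
      window_is_repetitive(substr(seqstr, P - 25L, P - 1L), target_id,
                           pos - 25L, index, config$flank_max_mismatch,
                           config$flank_min_hits)
    } else NA
    dn <- if (dn_ok) {
      window_is_repetitive(substr(seqstr, P + 1L, P + 25L), target_id,
                           pos + 1L, index, config$flank_max_mismatch,
                           config$flank_min_hits)
    } else NA
    return(list(upstream = up, downstream = dn,
                truncated = !(up_ok && dn_ok)))
  }
  fl <- config$flank_len
  up_region <- c(max(1L, P - fl), P - 1L)
  dn_region <- c(P + 1L, min(L, P + fl))
  truncated <- (P - fl < 1L) || (P + fl > L)
  starts <- integer(0)
  for (reg in list(up_region, dn_region)) {
    if (reg[2] - reg[1] + 1L >= 25L) {
      starts <- c(starts, seq(reg[1], reg[2] - 24L))
    }
  }
  if (length(starts) == 0L) {
    return(list(repetitive_fraction = NA_real_, n_windows = 0L,
                n_repetitive = 0L, truncated = truncated))
  }
  rep_flags <- vapply(starts, function(s) {
    window_is_repetitive(substr(seqstr, s, s + 24L), target_id, s - 1L,
                         index, config$flank_max_mismatch,
                         config$flank_min_hits)
  }, logical(1))
  list(repetitive_fraction = mean(rep_flags), n_windows = length(starts),
       n_repetitive = sum(rep_flags), truncated = truncated)
}

# Ledger helper: one row per candidate per rule, in evaluation order.
ledger_row <- function(cand, rule, pass) {
  data.frame(target_id = cand$target_id, pos = cand$pos, rule = rule,
             pass = pass, stringsAsFactors = FALSE)
}

# Attach final filter status: "PASS" or the first failing rule.
finalize_filters <- function(candidates, ledger) {
  status <- vapply(seq_len(nrow(candidates)), function(i) {
    rows <- ledger[ledger$target_id == candidates$target_id[i] &
                     ledger$pos == candidates$pos[i], , drop = FALSE]
    failed <- rows$rule[!rows$pass]
    if (length(failed)) failed[1] else "PASS"
  }, character(1))
  candidates$filter <- if (nrow(candidates)) status else character(0)
  candidates
}

#' The quality-score-free (GMAP-style) filter cascade
#'
#' Applies, in order and with every decision ledgered per candidate:
#' reads carrying any base with quality below 10 are removed and the
#' column support re-evaluated; all supporting reads must be uniquely
#' placed; supporting alignments must agree on a single substituted base
#' (no conflicting nucleotides, no ambiguous consensus); candidates whose
#' two immediate 25-mer flanks are both repetitive are eliminated; at least
#' two supporting reads are required; and no `N` may appear in the read
#' observations or the emitted 25 bp reference context.
#'
#' @param candidates Output of [candidate_snps()].
#' @param pile The pileup the candidates came from.
#' @param reads Read `data.frame` (`id`, `seq`, `qual`) for the base-quality
#'   screen.
#' @param reference Named character vector.
#' @param config A [filter_config()] with `mode == "GMAP"`.
#' @param index Optional 8-mer index over `reference`.
#' @return List with `pass` (surviving candidates), `all` (every candidate
#'   with a `filter` column: `"PASS"` or first failing rule) and `ledger`
#'   (one row per candidate per rule evaluated).
#' @export
gmap_cascade <- function(candidates, pile, reads, reference,
                         config = filter_config("GMAP"), index = NULL) {
  stopifnot(config$mode == "GMAP")
  if (is.null(index)) index <- build_index(reference, seed_len = 8L)
  min_q_of_read <- vapply(reads$qual, function(q) min(utf8ToInt(q) - 33L),
                          integer(1), USE.NAMES = FALSE)
  lowq_ids <- reads$id[min_q_of_read < config$min_base_q]
  pile_dt <- as.data.table(pile)
  ledger <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    obs <- pile_dt[target_id == cand$target_id & pos == cand$pos]
    kept <- obs[!(read_id %in% lowq_ids)]
    alt_obs <- kept[base != ref_base]
    # 1: base-quality screen (candidate must retain alt support afterwards)
    ledger[[length(ledger) + 1L]] <-
      ledger_row(cand, "read_quality", nrow(alt_obs) > 0L)
    # 2: unique placement of every remaining supporting read
    uniq_ok <- nrow(kept) > 0L && all(kept$read_copy == 1L)
    ledger[[length(ledger) + 1L]] <-
      ledger_row(cand, "unique_placement", uniq_ok)
    # 3: no conflicting nucleotides among the alignments
    alts <- unique(alt_obs$base)
    conflict_ok <- length(alts) == 1L && !("N" %in% alt_obs$base)
    ledger[[length(ledger) + 1L]] <-
      ledger_row(cand, "no_conflict", conflict_ok)
    # 4: both immediate 25-mer flanks repetitive -> eliminated
    fr <- flank_repetitive(reference, cand$target_id, cand$pos, config, index)
    flank_ok <- !(isTRUE(fr$upstream) && isTRUE(fr$downstream))
    ledger[[length(ledger) + 1L]] <-
      ledger_row(cand, "flank_repetitive", flank_ok)
    # 5: at least two supporting short reads
    ledger[[length(ledger) + 1L]] <-
      ledger_row(cand, "min_support", nrow(alt_obs) >= config$min_support)
    # 6: no N in reads or emitted reference context
    ctx <- substr(reference[[cand$target_id]],
                  max(1L, cand$pos + 1L - 25L),
                  min(nchar(reference[[cand$target_id]]), cand$pos + 1L + 25L))
    n_ok <- !grepl("N", ctx, fixed = TRUE) && !("N" %in% kept$base)
    ledger[[length(ledger) + 1L]] <- ledger_row(cand, "no_N", n_ok)
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(target_id = character(), pos = integer(), rule = character(),
               pass = logical(), stringsAsFactors = FALSE)
  all_cand <- finalize_filters(candidates, ledger)
  list(pass = all_cand[all_cand$filter == "PASS", , drop = FALSE],
       all = all_cand, ledger = ledger)
}

#' The consensus-quality (Maq-style) filter cascades: VMS, VSS, PRODUCTION
#'
#' Applies, with every decision ledgered: the 25-base density screen (both
#' members of a close pair go); elimination of ambiguous consensus bases;
#' the minimum consensus quality (20 for VMS/VSS, 27 for the production
#' run); an average read-copy of exactly 1.00 (the SNP maps to one place);
#' a mapping score of at least 30 on every supporting read; at least two
#' supporting reads for VMS only; an N-free centre region (121 nt for
#' VMS/VSS, 601 nt for PRODUCTION); and the per-mode flank-repetitiveness
#' rule (VMS/VSS: both immediate 25-mer flanks repetitive excludes;
#' PRODUCTION: more than 1/3 repetitive 25-mer windows across the flanks
#' excludes). Organelle-matching reads are assumed removed upstream
#' ([screen_organelle()]).
#'
#' @param candidates Output of [candidate_snps()].
#' @param pile The pileup the candidates came from.
#' @param placements Output of [classify_placements()] (mapping scores).
#' @param reference Named character vector.
#' @param config A [filter_config()] with mode `VMS`, `VSS` or `PRODUCTION`.
#' @param index Optional 8-mer index over `reference`.
#' @return As [gmap_cascade()]: list with `pass`, `all`, `ledger`.
#' @export
maq_cascade <- function(candidates, pile, placements, reference, config,
                        index = NULL) {
  if (!config$mode %in% c("VMS", "VSS", "PRODUCTION")) {
    stop("maq_cascade(): config mode must be VMS, VSS or PRODUCTION")
  }
  if (is.null(index)) index <- build_index(reference, seed_len = 8L)
  dens_ok <- density_pass(candidates, config$density_window)
  pile_dt <- as.data.table(pile)
  half_center <- (config$center_n_len - 1L) %/% 2L
  ledger <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    add <- function(rule, pass) {
      ledger[[length(ledger) + 1L]] <<- ledger_row(cand, rule, pass)
    }
    add("density", dens_ok[i])
    add("ambiguous_consensus", cand$consensus_base %in% c("A", "C", "G", "T"))
    add("consensus_quality",
        cand$consensus_quality >= config$min_consensus_q)
    add("read_copy", !is.na(cand$avg_read_copy) && cand$avg_read_copy == 1)
    obs <- pile_dt[target_id == cand$target_id & pos == cand$pos &
                     base == cand$consensus_base]
    scores <- placements$mapping_score[match(obs$read_id, placements$read_id)]
    add("mapping_score",
        length(scores) > 0L && all(scores >= config$min_map_score))
    add("min_support", cand$support >= config$min_support)
    ctx <- substr(reference[[cand$target_id]],
                  max(1L, cand$pos + 1L - half_center),
                  min(nchar(reference[[cand$target_id]]),
                      cand$pos + 1L + half_center))
    add("center_N_free", !grepl("N", ctx, fixed = TRUE))
    if (config$mode == "PRODUCTION") {
      fr <- flank_repetitive(reference, cand$target_id, cand$pos, config,
                             index)
      add("flank_repetitive",
          is.na(fr$repetitive_fraction) ||
            fr$repetitive_fraction <= config$max_rep_fraction)
    } else {
      fr <- flank_repetitive(reference, cand$target_id, cand$pos, config,
                             index)
      add("flank_repetitive",
          !(isTRUE(fr$upstream) && isTRUE(fr$downstream)))
    }
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(target_id = character(), pos = integer(), rule = character(),
               pass = logical(), stringsAsFactors = FALSE)
  all_cand <- finalize_filters(candidates, ledger)
  list(pass = all_cand[all_cand$filter == "PASS", , drop = FALSE],
       all = all_cand, ledger = ledger)
}

#' Write candidates as VCF plus a per-rule ledger TSV
#'
#' Emits VCF 4.2 (1-based `POS`; `QUAL` is the consensus quality; `FILTER`
#' is `PASS` or the first failing rule; `INFO` carries depth, supporting
#' reads and mean read copy) and, when a ledger is supplied, a TSV with one
#' row per candidate per rule.
#'
#' @param candidates Candidate `data.frame` carrying a `filter` column
#'   (the `all` element of a cascade result).
#' @param path Output VCF path.
#' @param ledger Optional ledger `data.frame` from a cascade.
#' @param ledger_path Output TSV path (default: `path` with a
#'   `.ledger.tsv` suffix).
#' @return `path`, invisibly.
#' @export
write_snp_report <- function(candidates, path, ledger = NULL,
                             ledger_path = paste0(path, ".ledger.tsv")) {
  filt <- if ("filter" %in% names(candidates)) candidates$filter else
    rep("PASS", nrow(candidates))
  rules <- setdiff(unique(filt), "PASS")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=rrlsnp",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pileup depth\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Reads supporting the alternate allele\">",
    "##INFO=<ID=READCOPY,Number=1,Type=Float,Description=\"Mean placement multiplicity of supporting reads\">",
    sprintf("##FILTER=<ID=%s,Description=\"Failed cascade rule %s\">",
            rules, rules),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(candidates)) {
    sprintf("%s\t%d\t.\t%s\t%s\t%d\t%s\tDP=%d;SUPPORT=%d;READCOPY=%.2f",
            candidates$target_id, candidates$pos + 1L, candidates$ref_base,
            candidates$consensus_base, candidates$consensus_quality, filt,
            candidates$depth, candidates$support, candidates$avg_read_copy)
  } else character(0)
  writeLines(c(hdr, body), path)
  if (!is.null(ledger)) {
    out <- ledger
    out$pos <- out$pos + 1L   # user-facing coordinates are 1-based
    write.table(out, ledger_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' SNP validation-rate arithmetic
#'
#' The fraction of tested assays that confirmed the predicted SNP,
#' as a percentage. `effective_validation_rate()` deflates an
#' assay-conversion rate by the known conversion rate of already-validated
#' SNPs (for GoldenGate assays in soybean, 89% of validated SNPs convert
#' into working assays), giving the validation rate the conversion implies.
#'
#' @param n_confirmed Assays confirming the SNP.
#' @param n_tested Assays yielding interpretable product.
#' @return Percentage (0-100), unrounded.
#' @examples
#' validation_rate(37, 40)   # 92.5
#' @export
validation_rate <- function(n_confirmed, n_tested) {
  if (n_tested <= 0) stop("validation_rate(): n_tested must be positive")
  100 * n_confirmed / n_tested
}

#' @rdname validation_rate
#' @param conversion_pct Observed assay-conversion percentage.
#' @param assay_conversion_pct Conversion percentage expected of validated
#'   SNPs (default 89).
#' @export
effective_validation_rate <- function(conversion_pct,
                                      assay_conversion_pct = 89) {
  100 * conversion_pct / assay_conversion_pct
}
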