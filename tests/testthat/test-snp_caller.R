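# -- local helpers -----------------------------------------------------------

# A 33 bp read copied from `ref` at 0-based start, optionally with the base
# at genome position `alt_at` replaced by `alt`.
mk_read <- function(ref, start0, alt_at = NULL, alt = NULL, qual = 35L,
                    id = "r") {
  s <- substr(ref[[1]], start0 + 1L, start0 + 33L)
  if (!is.null(alt_at)) {
    off <- alt_at - start0 + 1L
    stopifnot(off >= 1, off <= 33)
    substr(s, off, off) <- alt
  }
  data.frame(id = id, seq = s,
             qual = intToUtf8(rep(qual + 33L, 33L)),
             stringsAsFactors = FALSE)
}

# Align constructed reads and derive pileup + candidates.
call_setup <- function(ref, reads, include_multiple = FALSE) {
  idx <- build_index(ref, 11)
  hits <- align_reads(reads, idx)
  pl <- classify_placements(hits, reads$id)
  pile <- pileup(pl, reads, ref, include_multiple = include_multiple,
                 hits = hits)
  list(hits = hits, placements = pl, pile = pile,
       cands = candidate_snps(pile, ref))
}

other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

# -- consensus ---------------------------------------------------------------

test_that("consensus is the quality-weighted modal base with capped margin", {
  expect_equal(call_consensus(list(base = c("G", "G", "G"),
                                   qual = c(35, 35, 35))),
               list(consensus_base = "G", consensus_quality = 60L))
  expect_equal(call_consensus(list(base = c("G", "A"), qual = c(25, 25))),
               list(consensus_base = "N", consensus_quality = 0L))
  expect_equal(call_consensus(list(base = "G", qual = 15)),
               list(consensus_base = "G", consensus_quality = 15L))
  # discordant observations subtract from the margin
  expect_equal(call_consensus(list(base = c("G", "G", "A"),
                                   qual = c(30, 30, 25))),
               list(consensus_base = "G", consensus_quality = 35L))
  expect_error(call_consensus(list(base = character(), qual = numeric())),
               "empty")
})

test_that("candidates appear exactly where the consensus deviates", {
  ref <- fixture_genome(5000, 91)
  alt <- other_base(substr(ref[[1]], 997, 997))   # SNP at 0-based 996
  reads <- do.call(rbind, lapply(1:3, function(i) {
    mk_read(ref, 970 + 5 * i, alt_at = 996, alt = alt,
            id = paste0("r", i))
  }))
  cs <- call_setup(ref, reads)
  expect_equal(nrow(cs$cands), 1L)
  expect_equal(cs$cands$pos, 996L)
  expect_equal(cs$cands$consensus_base, alt)
  expect_equal(cs$cands$support, 3L)
  expect_equal(cs$cands$conflict, 0L)
  expect_equal(cs$cands$avg_read_copy, 1)
  # error-free reads, no SNP -> no candidates
  clean <- do.call(rbind, lapply(1:3, function(i) {
    mk_read(ref, 970 + 5 * i, id = paste0("c", i))
  }))
  expect_equal(nrow(call_setup(ref, clean)$cands), 0L)
  # a lone miscalled base still surfaces as a (weak) candidate
  one_err <- mk_read(ref, 2000, alt_at = 2016,
                     alt = other_base(substr(ref[[1]], 2017, 2017)))
  expect_equal(call_setup(ref, one_err)$cands$support, 1L)
})

# -- density -----------------------------------------------------------------

test_that("the 25-base density screen removes close pairs, both members", {
  cands <- data.frame(target_id = "t", pos = c(100L, 124L, 300L),
                      stringsAsFactors = FALSE)
  expect_equal(density_filter(cands)$pos, 300L)
  cands2 <- data.frame(target_id = "t", pos = c(100L, 125L),
                       stringsAsFactors = FALSE)
  expect_equal(density_filter(cands2)$pos, c(100L, 125L))
  # same positions on different targets do not interact
  cands3 <- data.frame(target_id = c("a", "b"), pos = c(100L, 110L),
                       stringsAsFactors = FALSE)
  expect_equal(nrow(density_filter(cands3)), 2L)
})

# -- flank repetitiveness ----------------------------------------------------

test_that("flank tests agree with the brute-force scan", {
  # genome with a 120 bp block copied three times
  block <- fixture_genome(120, 92, id = "b")[[1]]
  ref <- c(chr1 = paste0(fixture_genome(1500, 93)[[1]], block,
                         fixture_genome(1500, 94)[[1]], block,
                         fixture_genome(1500, 95)[[1]], block,
                         fixture_genome(1500, 96)[[1]]))
  idx8 <- build_index(ref, 8)
  cfg <- filter_config("VMS")
  # SNP inside the first block copy: both flanks land in copied sequence
  pos_in_block <- 1500 + 60
  fr <- flank_repetitive(ref, "chr1", pos_in_block, cfg, idx8)
  expect_true(fr$upstream)
  expect_true(fr$downstream)
  # SNP in unique sequence: neither flank repetitive
  fr_u <- flank_repetitive(ref, "chr1", 700, cfg, idx8)
  expect_false(fr_u$upstream)
  expect_false(fr_u$downstream)
  expect_false(fr_u$truncated)
  # SNP right after the block: the upstream flank is its final 25-mer
  fr_e <- flank_repetitive(ref, "chr1", 1500 + 120, cfg, idx8)
  expect_true(fr_e$upstream)
  expect_false(fr_e$downstream)
  # brute-force equivalence of the single-flank calls at assorted positions
  for (pos in c(700, 1560, 1500 + 120, 1500 + 120 + 10, 3000, 3120 + 60)) {
    fr_p <- flank_repetitive(ref, "chr1", pos, cfg, idx8)
    expect_equal(fr_p$upstream,
                 oracle_window_repetitive(ref, "chr1", pos - 25L))
    expect_equal(fr_p$downstream,
                 oracle_window_repetitive(ref, "chr1", pos + 1L))
  }
})

test_that("the production flank rule counts repetitive windows by fraction", {
  cfg <- filter_config("PRODUCTION", flank_len = 120L)
  # unique genome: fraction 0
  ref_u <- fixture_genome(4000, 97)
  idx_u <- build_index(ref_u, 8)
  fr0 <- flank_repetitive(ref_u, "chr1", 2000, cfg, idx_u)
  expect_equal(fr0$repetitive_fraction, 0)
  expect_equal(fr0$n_windows, 2 * (120 - 24))
  # flank region copied 10x elsewhere: fraction 1 -> excluded
  region <- fixture_genome(265, 98, id = "r")[[1]]
  ref_r <- c(chr1 = paste0(fixture_genome(1000, 99)[[1]], region,
                           paste(replicate(10, paste0(
                             fixture_genome(40, 100)[[1]], region)),
                             collapse = ""),
                           fixture_genome(1000, 101)[[1]]))
  idx_r <- build_index(ref_r, 8)
  snp_pos <- 1000 + 132   # centre of the first region copy
  frr <- flank_repetitive(ref_r, "chr1", snp_pos, cfg, idx_r)
  expect_equal(frr$repetitive_fraction, 1)
  # brute-force agreement on the full window set of one production call
  starts <- c(seq(snp_pos + 1 - 120, snp_pos - 24),
              seq(snp_pos + 2, snp_pos + 121 - 24)) - 1L  # 0-based
  brute <- vapply(starts, function(s) {
    oracle_window_repetitive(ref_r, "chr1", s, min_hits = 5)
  }, logical(1))
  expect_equal(frr$n_repetitive, sum(brute))
})

test_that("a window with only four other copies is not production-repetitive", {
  cfg <- filter_config("PRODUCTION")
  w <- fixture_genome(25, 102, id = "w")[[1]]
  ref <- c(chr1 = paste0(
    fixture_genome(600, 103)[[1]],
    paste(replicate(5, paste0(w, fixture_genome(50, 104)[[1]])),
          collapse = "")))
  idx <- build_index(ref, 8)
  # each copy has 4 other copies: below the five-hit rule
  expect_false(rrlsnp:::window_is_repetitive(w, "chr1", 600L, idx,
                                             min_hits = cfg$flank_min_hits))
  # but at the single-flank rule (>= 1 other hit) it is repetitive
  expect_true(rrlsnp:::window_is_repetitive(w, "chr1", 600L, idx,
                                            min_hits = 1L))
})

# -- cascades ----------------------------------------------------------------

test_that("the quality-free cascade enforces support, agreement and flanks", {
  ref <- fixture_genome(6000, 105)
  ref_base <- substr(ref[[1]], 3001, 3001)
  alt <- other_base(ref_base)                      # SNP at 0-based 3000
  conf <- setdiff(c("A", "C", "G", "T"), c(ref_base, alt))[1]
  two_good <- rbind(
    mk_read(ref, 2980, 3000, alt, id = "g1"),
    mk_read(ref, 2990, 3000, alt, id = "g2"))
  cfg <- filter_config("GMAP")
  # two agreeing reads pass
  cs <- call_setup(ref, two_good)
  res <- gmap_cascade(cs$cands, cs$pile, two_good, ref, cfg)
  expect_equal(nrow(res$pass), 1L)
  expect_true(all(res$ledger$pass))
  # single supporting read fails the two-read rule (and only that rule)
  one <- two_good[1, ]
  cs1 <- call_setup(ref, one)
  res1 <- gmap_cascade(cs1$cands, cs1$pile, one, ref, cfg)
  expect_equal(nrow(res1$pass), 0L)
  expect_equal(res1$all$filter, "min_support")
  # conflicting alternate alleles are eliminated
  disagree <- rbind(two_good,
                    mk_read(ref, 2985, 3000, conf, id = "b1"))
  cs2 <- call_setup(ref, disagree)
  res2 <- gmap_cascade(cs2$cands, cs2$pile, disagree, ref, cfg)
  expect_equal(nrow(res2$pass), 0L)
  ledger2 <- res2$ledger
  expect_false(ledger2$pass[ledger2$rule == "no_conflict"])
  # a read carrying any base below quality 10 is discarded before calling
  lowq <- rbind(two_good[1, ],
                mk_read(ref, 2990, 3000, alt, qual = 9L, id = "lq"))
  cs3 <- call_setup(ref, lowq)
  res3 <- gmap_cascade(cs3$cands, cs3$pile, lowq, ref, cfg)
  expect_equal(nrow(res3$pass), 0L)
  expect_equal(res3$all$filter, "min_support")
})

test_that("both flanking 25-mers repetitive eliminates; one does not", {
  # duplicating only the 25-mer flanks (not the read windows) makes the
  # flanks repetitive while the reads still place uniquely
  base <- fixture_genome(4000, 107)[[1]]
  pos <- 2000L   # 0-based SNP position, 1-based 2001
  up25 <- substr(base, pos + 1L - 25L, pos)
  dn25 <- substr(base, pos + 2L, pos + 26L)
  sp <- function(seed) fixture_genome(80, seed)[[1]]
  cfg <- filter_config("GMAP")
  for (case in list(list(extra = paste0(sp(108), up25, sp(109), dn25),
                         n_pass = 0L),      # both flanks duplicated
                    list(extra = paste0(sp(110), up25),
                         n_pass = 1L))) {   # upstream only
    ref <- c(chr1 = paste0(base, case$extra, sp(111)))
    alt <- other_base(substr(ref[[1]], pos + 1L, pos + 1L))
    reads <- rbind(mk_read(ref, pos - 20L, pos, alt, id = "a"),
                   mk_read(ref, pos - 12L, pos, alt, id = "b"))
    cs <- call_setup(ref, reads)
    expect_true(all(cs$placements$placement == "unique"))
    cands <- cs$cands[cs$cands$pos == pos, ]
    res <- gmap_cascade(cands, cs$pile, reads, ref, cfg)
    expect_equal(nrow(res$pass), case$n_pass)
    flank_led <- res$ledger[res$ledger$rule == "flank_repetitive", ]
    expect_equal(flank_led$pass, case$n_pass == 1L)
  }
})

test_that("the consensus-quality cascades apply their mode thresholds", {
  ref <- fixture_genome(6000, 110)
  alt <- other_base(substr(ref[[1]], 3001, 3001))
  # 27-quality single read: consensus quality 27
  one27 <- mk_read(ref, 2980, 3000, alt, qual = 27L, id = "q27")
  cs27 <- call_setup(ref, one27)
  expect_equal(cs27$cands$consensus_quality, 27L)
  # 26-quality single read
  one26 <- mk_read(ref, 2980, 3000, alt, qual = 26L, id = "q26")
  cs26 <- call_setup(ref, one26)
  prod <- filter_config("PRODUCTION")
  r27 <- maq_cascade(cs27$cands, cs27$pile, cs27$placements, ref, prod)
  r26 <- maq_cascade(cs26$cands, cs26$pile, cs26$placements, ref, prod)
  expect_equal(nrow(r27$pass), 1L)   # 27 retained in the production run
  expect_equal(nrow(r26$pass), 0L)   # 26 eliminated
  expect_equal(r26$all$filter, "consensus_quality")
  # single-read candidate: eliminated under VMS, retained under VSS
  rv <- maq_cascade(cs27$cands, cs27$pile, cs27$placements, ref,
                    filter_config("VMS"))
  rs <- maq_cascade(cs27$cands, cs27$pile, cs27$placements, ref,
                    filter_config("VSS"))
  expect_equal(nrow(rv$pass), 0L)
  expect_equal(rv$all$filter, "min_support")
  expect_equal(nrow(rs$pass), 1L)
})

test_that("clustered candidates are jointly eliminated by the Maq cascade", {
  ref <- fixture_genome(6000, 111)
  p1 <- 3000L
  p2 <- 3020L   # 20 bp apart: inside one 25-base window
  a1 <- other_base(substr(ref[[1]], p1 + 1L, p1 + 1L))
  a2 <- other_base(substr(ref[[1]], p2 + 1L, p2 + 1L))
  reads <- rbind(
    mk_read(ref, 2995, p1, a1, id = "x1"),
    mk_read(ref, 2990, p1, a1, id = "x2"),
    mk_read(ref, 3010, p2, a2, id = "y1"),
    mk_read(ref, 3015, p2, a2, id = "y2"))
  # reads carrying only one of the two SNPs still align (1 mismatch)
  cs <- call_setup(ref, reads)
  expect_equal(nrow(cs$cands), 2L)
  res <- maq_cascade(cs$cands, cs$pile, cs$placements, ref,
                     filter_config("VSS"))
  expect_equal(nrow(res$pass), 0L)
  expect_true(all(res$all$filter == "density"))
})

test_that("repeat-borne candidates fail the read-copy and score rules", {
  unit <- fixture_genome(300, 112, id = "u")[[1]]
  ref <- c(chr1 = paste0(fixture_genome(2000, 113)[[1]], unit,
                         fixture_genome(2000, 114)[[1]], unit,
                         fixture_genome(1000, 115)[[1]]))
  pos_in_unit <- 2000L + 150L
  alt <- other_base(substr(ref[[1]], pos_in_unit + 1L, pos_in_unit + 1L))
  reads <- rbind(mk_read(ref, pos_in_unit - 16L, pos_in_unit, alt, id = "m1"),
                 mk_read(ref, pos_in_unit - 10L, pos_in_unit, alt, id = "m2"))
  cs <- call_setup(ref, reads, include_multiple = TRUE)
  # the reads place ambiguously (two best hits each)
  expect_true(all(cs$placements$placement == "multiple"))
  cand <- cs$cands[cs$cands$pos == pos_in_unit, ]
  expect_equal(nrow(cand), 1L)
  expect_gt(cand$avg_read_copy, 1)
  res <- maq_cascade(cand, cs$pile, cs$placements, ref,
                     filter_config("VSS"))
  expect_equal(nrow(res$pass), 0L)
  ledger <- res$ledger
  expect_false(ledger$pass[ledger$rule == "read_copy"])
  expect_false(ledger$pass[ledger$rule == "mapping_score"])
})

# -- planted-SNP recovery and monotonicity -----------------------------------

test_that("clean simulation: full recall of recoverable SNPs, no false calls", {
  cs <- clean_sim()
  ref <- cs$reference
  cands <- candidate_snps(cs$pile, ref)
  idx8 <- build_index(ref, 8)
  res <- maq_cascade(cands, cs$pile, cs$placements, ref,
                     filter_config("VMS"), idx8)
  truth_key <- paste(cs$truth$source_id, cs$truth$pos)
  # precision: every passing candidate is a planted SNP with the right allele
  expect_true(all(paste(res$pass$target_id, res$pass$pos) %in% truth_key))
  ti <- match(paste(res$pass$target_id, res$pass$pos), truth_key)
  expect_equal(res$pass$consensus_base, cs$truth$alt_allele[ti])
  # recall: every planted SNP covered by >= 2 unique reads and not within
  # 25 bp of another planted SNP passes
  pile_dt <- data.table::as.data.table(cs$pile)
  depth_at <- pile_dt[, .N, by = .(target_id, pos)]
  covered2 <- paste(depth_at$target_id[depth_at$N >= 2],
                    depth_at$pos[depth_at$N >= 2])
  isolated <- density_pass(data.frame(target_id = cs$truth$source_id,
                                      pos = cs$truth$pos))
  expected_keys <- truth_key[isolated & truth_key %in% covered2]
  expect_gt(length(expected_keys), 0)
  expect_true(all(expected_keys %in%
                    paste(res$pass$target_id, res$pass$pos)))
})

test_that("cascade stringency is monotone: VMS and PRODUCTION within VSS", {
  noisy <- clean_sim(n = 30000L, seed = 131L, depth = 8, error_rate = 0.004)
  ref <- noisy$reference
  cands <- candidate_snps(noisy$pile, ref)
  idx8 <- build_index(ref, 8)
  key <- function(res) paste(res$pass$target_id, res$pass$pos)
  vss <- maq_cascade(cands, noisy$pile, noisy$placements, ref,
                     filter_config("VSS"), idx8)
  vms <- maq_cascade(cands, noisy$pile, noisy$placements, ref,
                     filter_config("VMS"), idx8)
  # identical flank rules, one extra support rule: strict subset relation
  expect_true(all(key(vms) %in% key(vss)))
  # production at its VSS-comparable flank geometry: only thresholds differ
  prod <- maq_cascade(cands, noisy$pile, noisy$placements, ref,
                      filter_config("PRODUCTION"), idx8)
  expect_true(all(key(prod) %in% key(vss)))
  # error singletons: false VSS survivors are all single-read candidates
  truth_key <- paste(noisy$truth$source_id, noisy$truth$pos)
  false_pass <- vss$pass[!(key(vss) %in% truth_key), ]
  if (nrow(false_pass)) expect_true(all(false_pass$support == 1L))
  # and VMS eliminates them all
  expect_true(all(key(vms) %in% truth_key))
})

# -- reporting ---------------------------------------------------------------

test_that("the VCF report round-trips through an independent reader", {
  ref <- fixture_genome(6000, 116)
  alt <- other_base(substr(ref[[1]], 3001, 3001))
  reads <- rbind(mk_read(ref, 2980, 3000, alt, id = "g1"),
                 mk_read(ref, 2990, 3000, alt, id = "g2"))
  cs <- call_setup(ref, reads)
  res <- maq_cascade(cs$cands, cs$pile, cs$placements, ref,
                     filter_config("VMS"))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_snp_report(res$all, p, ledger = res$ledger)
  skip_if_not_installed("vcfR")
  v <- suppressWarnings(vcfR::read.vcfR(p, verbose = FALSE))
  fix <- as.data.frame(rbind(vcfR::getFIX(v)), stringsAsFactors = FALSE)
  expect_equal(as.integer(fix$POS), 3001L)   # 0-based 3000 -> VCF 3001
  expect_equal(fix$REF, substr(ref[[1]], 3001, 3001))
  expect_equal(fix$ALT, alt)
  expect_equal(fix$FILTER, "PASS")
  led <- read.table(paste0(p, ".ledger.tsv"), header = TRUE, sep = "\t")
  expect_setequal(unique(led$rule),
                  c("density", "ambiguous_consensus", "consensus_quality",
                    "read_copy", "mapping_score", "min_support",
                    "center_N_free", "flank_repetitive"))
})

test_that("validation-rate arithmetic matches the published counts", {
  expect_equal(round(validation_rate(456, 535)), 85)
  expect_equal(validation_rate(37, 40), 92.5)
  expect_equal(round(validation_rate(34, 43)), 79)
  expect_equal(round(validation_rate(1254, 1536), 1), 81.6)
  expect_equal(round(effective_validation_rate(81.6), 1), 91.7)
})
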