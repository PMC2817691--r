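test_that("the seed index matches brute-force position lists", {
  idx <- build_index(c(g = "ACGT"), seed_len = 2)
  expect_equal(sort(unname(unlist(as.list(idx$env)))), 1:3)
  g <- fixture_genome(1000, 71)
  idx <- build_index(g, seed_len = 11)
  starts <- 1:(1000 - 10)
  seeds <- substring(g[[1]], starts, starts + 10)
  for (s in sample(unique(seeds), 25)) {
    expect_equal(sort(idx$env[[s]]), which(seeds == s))
  }
  # N-containing seeds are not indexed
  gn <- c(g = paste0("ACGTACGTACGT", "N", "ACGTACGTACGT"))
  idxn <- build_index(gn, seed_len = 11)
  expect_false(any(grepl("N", ls(idxn$env))))
})

test_that("align_read finds exactly the placements the oracle finds", {
  ref <- fixture_genome(20000, 72)
  idx <- build_index(ref, 11)
  set.seed(73)
  n_checked <- 0
  for (i in 1:200) {
    start <- sample(20000 - 32, 1)
    read <- substr(ref[[1]], start, start + 32)
    n_mm <- sample(0:2, 1)
    if (n_mm > 0) {
      at <- sample(33, n_mm)
      ch <- strsplit(read, "")[[1]]
      for (a in at) ch[a] <- setdiff(c("A", "C", "G", "T"), ch[a])[sample(3, 1)]
      read <- paste(ch, collapse = "")
    }
    if (sample(c(TRUE, FALSE), 1)) read <- revcomp(read)
    got <- align_read(read, idx, max_mismatch = 1)
    got <- got[order(got$target_id, got$pos, got$strand), ]
    expect_equal(got[, c("target_id", "pos", "strand")],
                 oracle_hits(read, ref, max_mismatch = 1),
                 ignore_attr = TRUE)
    n_checked <- n_checked + nrow(got)
  }
  expect_gt(n_checked, 100)   # the oracle found plenty to compare against
})

test_that("alignment works across multiple targets and respects boundaries", {
  ref <- c(a = fixture_genome(3000, 74)[[1]], b = fixture_genome(3000, 75)[[1]])
  idx <- build_index(ref, 11)
  # a read spanning the a/b concatenation boundary must not be placed
  straddle <- paste0(substr(ref[["a"]], 2985, 3000), substr(ref[["b"]], 1, 17))
  expect_equal(nrow(align_read(straddle, idx)), 0L)
  rb <- substr(ref[["b"]], 101, 133)
  hit <- align_read(rb, idx)
  expect_equal(hit$target_id, "b")
  expect_equal(hit$pos, 100L)
})

test_that("reads matching a two-copy repeat get two hits", {
  unit <- fixture_genome(200, 76, id = "u")[[1]]
  ref <- c(chr1 = paste0(fixture_genome(2000, 77)[[1]], unit,
                         fixture_genome(2000, 78)[[1]], unit,
                         fixture_genome(1000, 79)[[1]]))
  idx <- build_index(ref, 11)
  read <- substr(unit, 50, 82)
  hits <- align_read(read, idx)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$pos, c(2049L, 4249L))
  cls <- classify_placement(hits)
  expect_equal(cls$placement, "multiple")
  expect_equal(cls$mapping_score, 0L)
  expect_equal(cls$read_copy, 2L)
})

test_that("a read with two mismatches is unmapped at tolerance one", {
  ref <- fixture_genome(5000, 80)
  idx <- build_index(ref, 11)
  read <- substr(ref[[1]], 1001, 1033)
  ch <- strsplit(read, "")[[1]]
  ch[5] <- setdiff(c("A", "C", "G", "T"), ch[5])[1]
  ch[20] <- setdiff(c("A", "C", "G", "T"), ch[20])[1]
  read2 <- paste(ch, collapse = "")
  expect_equal(nrow(align_read(read2, idx, max_mismatch = 1)), 0L)
  expect_equal(nrow(align_read(read2, idx, max_mismatch = 2)), 1L)
  cls <- classify_placement(align_read(read2, idx, max_mismatch = 1))
  expect_equal(cls$placement, "unmapped")
  expect_equal(cls$read_copy, 0L)
})

test_that("mapping scores reflect placement competition", {
  # unique, no competitor at all
  h1 <- data.frame(read_id = "r", target_id = "t", pos = 0L, strand = "+",
                   mismatches = 0L, stringsAsFactors = FALSE)
  expect_equal(classify_placement(h1),
               list(placement = "unique", mapping_score = 37L, read_copy = 1L))
  # unique best with one suboptimal competitor: drops below the 30 cutoff
  h2 <- rbind(h1, data.frame(read_id = "r", target_id = "t", pos = 500L,
                             strand = "+", mismatches = 1L))
  cls <- classify_placement(h2)
  expect_equal(cls$placement, "unique")
  expect_equal(cls$mapping_score, 27L)
  # many suboptimal competitors: capped, never negative
  h5 <- rbind(h1, h2[2, ][rep(1, 6), ])
  expect_equal(classify_placement(h5)$mapping_score, 7L)
})

test_that("clean simulated reads all place uniquely at their truth coordinates", {
  cs <- clean_sim()
  expect_true(all(cs$placements$placement == "unique"))
  prov <- cs$provenance
  pl <- cs$placements[match(prov$id, cs$placements$read_id), ]
  # accession fragments came from the unmutated coordinate system, so the
  # truth position on the reference equals the provenance position
  expect_equal(pl$pos, prov$ref_start)
  expect_equal(pl$strand, prov$strand)
  expect_true(all(pl$mismatches <= 1))
})

test_that("pileup conserves observations and complements minus-strand reads", {
  ref <- c(chr1 = fixture_genome(200, 81)[[1]])
  reads <- data.frame(
    id = c("f", "r"),
    seq = c(substr(ref[[1]], 11, 43), revcomp(substr(ref[[1]], 31, 63))),
    qual = strrep("I", 33), stringsAsFactors = FALSE)
  idx <- build_index(ref, 11)
  hits <- align_reads(reads, idx)
  pl <- classify_placements(hits, reads$id)
  pile <- pileup(pl, reads, ref)
  expect_equal(nrow(pile), 66L)   # conservation: 2 reads x 33 bases
  # error-free: every observation equals the reference base (incl. minus)
  expect_true(all(pile$base == pile$ref_base))
  overlap <- pile[pile$pos >= 30 & pile$pos <= 42, ]
  expect_true(all(table(overlap$pos) == 2))
  cov <- coverage_stats(pile)
  expect_equal(cov$covered_bases, 53L)   # 10..62 covered
  expect_equal(cov$fold_coverage, 66 / 53)
})

test_that("coverage statistics handle edge cases", {
  empty <- data.frame(target_id = character(), pos = integer())
  cov <- coverage_stats(empty)
  expect_equal(cov$covered_bases, 0L)
  expect_equal(cov$fold_coverage, 0)
  cs <- clean_sim()
  cov2 <- coverage_stats(cs$pile)
  expect_gt(cov2$fold_coverage, 1)
  expect_equal(cov2$covered_bases,
               nrow(unique(cs$pile[, c("target_id", "pos")])))
})
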