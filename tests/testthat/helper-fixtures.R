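# Shared fixtures and independent oracles.
# Oracles deliberately use Biostrings (C code, no shared logic with the
# package's seed-and-verify aligner or IUPAC scanner).

# A repeat-free random genome as a named character vector.
fixture_genome <- function(n, seed, id = "chr1") {
  random_genome(n, seed, id)
}

# Independent digest oracle: 0-based cut positions of one enzyme found by
# Biostrings pattern matching on both strands. Genomes must be N-free
# (Biostrings' fixed = FALSE ambiguity semantics differ for N subjects).
oracle_cut_positions <- function(seq, enzyme) {
  subj <- Biostrings::DNAString(seq)
  k <- nchar(enzyme$site)
  fwd <- Biostrings::start(Biostrings::matchPattern(
    enzyme$site, subj, fixed = FALSE)) - 1L + enzyme$cut_offset
  rc <- revcomp(enzyme$site)
  rev <- Biostrings::start(Biostrings::matchPattern(
    rc, subj, fixed = FALSE)) - 1L + (k - enzyme$cut_offset)
  sort(unique(c(fwd, rev)))
}

# Independent ungapped-placement oracle: all full-length hits of `query`
# on both strands of every target with <= max_mismatch mismatches.
oracle_hits <- function(query, reference, max_mismatch) {
  out <- list()
  for (id in names(reference)) {
    subj <- Biostrings::DNAString(reference[[id]])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else revcomp(query)
      m <- Biostrings::matchPattern(q, subj, max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      if (length(m)) {
        out[[length(out) + 1L]] <- data.frame(
          target_id = id, pos = Biostrings::start(m) - 1L, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(target_id = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$target_id, res$pos, res$strand), , drop = FALSE]
}

# Is the 25-mer starting at 0-based `wstart` repetitive, by brute force?
oracle_window_repetitive <- function(reference, target, wstart,
                                     max_mismatch = 2, min_hits = 1) {
  w <- substr(reference[[target]], wstart + 1L, wstart + 25L)
  h <- oracle_hits(w, reference, max_mismatch)
  sum(!(h$target_id == target & h$pos == wstart)) >= min_hits
}

# Clean simulated dataset: reference, accession truth, selected fragments,
# error-free reads, alignment products. Cached per (n, seed) within a run.
clean_sim <- local({
  cache <- list()
  function(n = 30000L, seed = 101L, depth = 8, error_rate = 0) {
    key <- paste(n, seed, depth, error_rate)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ref <- fixture_genome(n, seed)
    mut <- mutate_genome(ref, 1 / 425, seed + 1L)
    frags <- size_select(digest_reference(mut$genome))
    sim <- sim_config(depth_target = depth, error_rate = error_rate,
                      seed = seed + 2L)
    sr <- sample_reads(frags, sim)
    idx <- build_index(ref, 11L)
    hits <- align_reads(sr$reads, idx)
    pl <- classify_placements(hits, sr$reads$id)
    pile <- pileup(pl, sr$reads, ref)
    out <- list(reference = ref, truth = mut$truth, accession = mut$genome,
                fragments = frags, reads = sr$reads,
                provenance = sr$provenance, index = idx, hits = hits,
                placements = pl, pile = pile)
    cache[[key]] <<- out
    out
  }
})
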