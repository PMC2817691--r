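N_INT <- utf8ToInt("N")

#' Build a seed index over a reference
#'
#' Exact-match lookup from every `seed_len`-mer of the reference (forward
#' strand) to its positions, backing the seeded ungapped aligner. Seeds
#' containing `N` are not indexed — `N` never matches anything, so a
#' mismatch-free block of a query can never contain one (see
#' [ungapped_hits()] for the completeness argument).
#'
#' @param reference Named character vector of sequences.
#' @param seed_len Seed k-mer length (default 11, sized for 33 bp queries at
#'   one mismatch; use 8 for the 25-mer/2-mismatch flank scans).
#' @return An object of class `seed_index` (also caches the reference as
#'   integer codes for fast mismatch counting).
#' @export
build_index <- function(reference, seed_len = 11L) {
  stopifnot(is.character(reference), !is.null(names(reference)))
  seed_len <- as.integer(seed_len)
  if (seed_len < 2L) stop("build_index(): seed_len too small")
  lens <- nchar(reference)
  if (seed_len > max(lens)) stop("build_index(): seed_len exceeds every target")
  offsets <- cumsum(c(0L, unname(lens[-length(lens)])))  # 0-based global start
  concat <- paste(reference, collapse = "")
  gint <- utf8ToInt(concat)
  keys <- character(0)
  gpos <- integer(0)
  for (i in seq_along(reference)) {
    L <- lens[i]
    if (L < seed_len) next
    starts <- seq_len(L - seed_len + 1L)
    seeds <- substring(reference[[i]], starts, starts + seed_len - 1L)
    ok <- !grepl("N", seeds, fixed = TRUE)
    keys <- c(keys, seeds[ok])
    gpos <- c(gpos, offsets[i] + starts[ok])   # 1-based global
  }
  env <- list2env(split(gpos, keys), hash = TRUE,
                  size = max(1L, length(gpos)))
  structure(list(targets = names(reference), target_len = unname(lens),
                 offsets = offsets, gint = gint, seed_len = seed_len,
                 env = env),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("seed_index: %d target(s), %d bp, seed_len %d\n",
              length(x$targets), length(x$gint), x$seed_len))
  invisible(x)
}

# Mismatches between query ints and the reference window starting at global
# position g (1-based). N on either side never matches, so aligned N/N pairs
# (equal ints) are added back as mismatches.
count_mm <- function(gint, g, qint) {
  w <- gint[g:(g + length(qint) - 1L)]
  sum(w != qint) + sum(w == N_INT & qint == N_INT)
}

#' All ungapped full-length placements of a query on a reference
#'
#' Seed-and-verify search for every placement of `query` on either strand
#' with at most `max_mismatch` mismatches. Completeness argument: partition
#' the query into `max_mismatch + 1` contiguous blocks; any placement with
#' `<= max_mismatch` mismatches leaves at least one block mismatch-free
#' (pigeonhole), and the exact `seed_len`-mer at that block's start is then
#' an indexed seed, so the candidate is generated and verified. This
#' requires `nchar(query) >= (max_mismatch + 1) * seed_len` (33 bp at one
#' mismatch with 11-mers: two blocks of 16 and 17; 25 bp at two mismatches
#' with 8-mers: blocks of 8, 8, 9).
#'
#' @param query Query sequence (any length satisfying the seed constraint).
#' @param index A [build_index()] object.
#' @param max_mismatch Mismatch tolerance.
#' @param max_hits Stop after this many hits (default unlimited); with a
#'   finite cap the hit list may be truncated but its emptiness is exact.
#' @param query_id Id recorded on the hits (default `"query"`).
#' @return `data.frame(read_id, target_id, pos, strand, mismatches)` with
#'   0-based `pos`, sorted by (mismatches, target, pos, strand).
#' @export
ungapped_hits <- function(query, index, max_mismatch = 1L, max_hits = Inf,
                          query_id = "query") {
  stopifnot(inherits(index, "seed_index"))
  k <- index$seed_len
  qlen <- nchar(query)
  m <- as.integer(max_mismatch)
  if (qlen < (m + 1L) * k) {
    stop("ungapped_hits(): query too short for ", m, " mismatch(es) with ",
         k, "-mer seeds")
  }
  # block starts: m+1 contiguous blocks of near-equal length
  block_starts <- 1L + floor((seq_len(m + 1L) - 1L) * qlen / (m + 1L))
  glen <- length(index$gint)
  out_t <- character(0); out_p <- integer(0); out_s <- character(0)
  out_m <- integer(0)
  tstart <- index$offsets + 1L                 # 1-based global target starts
  tend <- index$offsets + index$target_len
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") query else revcomp(query)
    qint <- utf8ToInt(qs)
    cand <- integer(0)
    for (b in block_starts) {
      seed <- substr(qs, b, b + k - 1L)
      hitpos <- index$env[[seed]]
      if (!is.null(hitpos)) cand <- c(cand, hitpos - b + 1L)
    }
    cand <- unique(cand[cand >= 1L & cand + qlen - 1L <= glen])
    for (g in cand) {
      ti <- findInterval(g, tstart)
      if (g + qlen - 1L > tend[ti]) next       # would span a target boundary
      mm <- count_mm(index$gint, g, qint)
      if (mm <= m) {
        out_t <- c(out_t, index$targets[ti])
        out_p <- c(out_p, g - tstart[ti])      # 0-based local
        out_s <- c(out_s, strand)
        out_m <- c(out_m, mm)
        if (length(out_m) >= max_hits) break
      }
    }
    if (length(out_m) >= max_hits) break
  }
  hits <- data.frame(read_id = rep(query_id, length(out_m)), target_id = out_t,
                     pos = out_p, strand = out_s, mismatches = out_m,
                     stringsAsFactors = FALSE)
  hits[order(hits$mismatches, hits$target_id, hits$pos, hits$strand), ,
       drop = FALSE]
}

#' Align one 33 bp read
#'
#' All full-length ungapped placements on both strands with at most
#' `max_mismatch` mismatches ("32 or 33 matching nucleotides" at the
#' default of one). An empty result means unmapped.
#'
#' @param read Read sequence, or one row of a read `data.frame`.
#' @param index A [build_index()] object over the reference.
#' @param max_mismatch Mismatch tolerance (default 1).
#' @return Hit `data.frame` as in [ungapped_hits()].
#' @export
align_read <- function(read, index, max_mismatch = 1L) {
  if (is.data.frame(read)) {
    ungapped_hits(read$seq[1], index, max_mismatch, query_id = read$id[1])
  } else {
    ungapped_hits(read, index, max_mismatch)
  }
}

#' Align a read set
#'
#' @param reads Read `data.frame` (`id`, `seq`).
#' @param index A [build_index()] object.
#' @param max_mismatch Mismatch tolerance (default 1).
#' @return Row-bound hit `data.frame`; reads with no placement contribute
#'   no rows.
#' @export
align_reads <- function(reads, index, max_mismatch = 1L) {
  hits <- lapply(seq_len(nrow(reads)), function(i) {
    ungapped_hits(reads$seq[i], index, max_mismatch, query_id = reads$id[i])
  })
  out <- data.table::rbindlist(hits)
  as.data.frame(out)
}

#' Classify the placement of one read from its hit list
#'
#' `read_copy` is the number of equally best placements (minimal mismatch
#' count). The mapping score is this package's deterministic stand-in for an
#' aligner's mapping quality: 37 for a unique placement with no competing
#' hit at all, minus 10 per suboptimal competitor (capped at three), and 0
#' for multiple or unmapped reads. It is monotone in uniqueness, so the
#' downstream "mapping score >= 30" rule passes exactly the reads whose
#' placement has no competition.
#'
#' @param hits Hit `data.frame` for a single read (possibly 0 rows).
#' @param max_mismatch Unused bound kept for interface symmetry.
#' @return List with `placement` (`"unique"`, `"multiple"`, `"unmapped"`),
#'   `mapping_score` and `read_copy`.
#' @export
classify_placement <- function(hits, max_mismatch = 1L) {
  if (nrow(hits) == 0L) {
    return(list(placement = "unmapped", mapping_score = 0L, read_copy = 0L))
  }
  best <- min(hits$mismatches)
  read_copy <- sum(hits$mismatches == best)
  if (read_copy > 1L) {
    return(list(placement = "multiple", mapping_score = 0L,
                read_copy = read_copy))
  }
  subopt <- nrow(hits) - 1L
  list(placement = "unique",
       mapping_score = 37L - 10L * min(subopt, 3L),
       read_copy = 1L)
}

#' Classify placements for a whole hit table
#'
#' @param hits Hit `data.frame` from [align_reads()].
#' @param read_ids All read ids that were aligned (so unmapped reads appear).
#' @return `data.frame(read_id, placement, mapping_score, read_copy,
#'   target_id, pos, strand, mismatches)`; the last four columns are the
#'   best hit for uniquely placed reads and `NA` otherwise.
#' @export
classify_placements <- function(hits, read_ids) {
  dt <- as.data.table(hits)
  if (nrow(dt)) {
    cls <- dt[, {
      best <- min(mismatches)
      rc <- sum(mismatches == best)
      i <- which.min(mismatches)
      list(placement = if (rc > 1L) "multiple" else "unique",
           mapping_score = if (rc > 1L) 0L else 37L - 10L * min(.N - 1L, 3L),
           read_copy = rc,
           target_id = if (rc == 1L) target_id[i] else NA_character_,
           pos = if (rc == 1L) pos[i] else NA_integer_,
           strand = if (rc == 1L) strand[i] else NA_character_,
           mismatches = if (rc == 1L) best else NA_integer_)
    }, by = read_id]
  } else {
    cls <- data.table(read_id = character(), placement = character(),
                      mapping_score = integer(), read_copy = integer(),
                      target_id = character(), pos = integer(),
                      strand = character(), mismatches = integer())
  }
  missing <- setdiff(read_ids, cls$read_id)
  if (length(missing)) {
    cls <- rbind(cls, data.table(
      read_id = missing, placement = "unmapped", mapping_score = 0L,
      read_copy = 0L, target_id = NA_character_, pos = NA_integer_,
      strand = NA_character_, mismatches = NA_integer_))
  }
  out <- as.data.frame(cls[match(read_ids, cls$read_id)])
  rownames(out) <- NULL
  out
}

#' Build the pileup from placed reads
#'
#' Expands every uniquely placed read into one observation per covered
#' reference position. Reverse-strand reads contribute their complemented
#' bases (and reversed qualities) at the correct offsets. By default only
#' unique placements contribute; `include_multiple = TRUE` additionally
#' spreads multiply-placed reads over each of their best placements, which
#' lets the downstream read-copy filter act on repeat-borne candidates.
#'
#' @param placements Output of [classify_placements()] (must carry hit
#'   coordinates), or with `include_multiple`, also pass `hits`.
#' @param reads Read `data.frame` (`id`, `seq`, `qual`).
#' @param reference Named character vector the reads were aligned to.
#' @param include_multiple Include best placements of multiply-placed reads
#'   (default `FALSE`).
#' @param hits Full hit table; required when `include_multiple = TRUE`.
#' @return `data.frame(target_id, pos, ref_base, base, qual, read_id,
#'   strand, read_copy)` — the long-form pileup, 0-based positions, sorted.
#' @export
pileup <- function(placements, reads, reference, include_multiple = FALSE,
                   hits = NULL) {
  uni <- placements[placements$placement == "unique", , drop = FALSE]
  src <- data.frame(read_id = uni$read_id, target_id = uni$target_id,
                    pos = uni$pos, strand = uni$strand,
                    read_copy = uni$read_copy, stringsAsFactors = FALSE)
  if (include_multiple) {
    if (is.null(hits)) stop("pileup(): include_multiple requires `hits`")
    mult <- placements[placements$placement == "multiple", , drop = FALSE]
    if (nrow(mult)) {
      h <- as.data.table(hits)[read_id %in% mult$read_id]
      h <- h[, .SD[mismatches == min(mismatches)], by = read_id]
      src <- rbind(src, data.frame(
        read_id = h$read_id, target_id = h$target_id, pos = h$pos,
        strand = h$strand,
        read_copy = mult$read_copy[match(h$read_id, mult$read_id)],
        stringsAsFactors = FALSE))
    }
  }
  if (nrow(src) == 0L) {
    return(data.frame(target_id = character(), pos = integer(),
                      ref_base = character(), base = character(),
                      qual = integer(), read_id = character(),
                      strand = character(), read_copy = integer(),
                      stringsAsFactors = FALSE))
  }
  ri <- match(src$read_id, reads$id)
  seqs <- reads$seq[ri]
  quals <- reads$qual[ri]
  rl <- nchar(seqs)
  neg <- src$strand == "-"
  seqs[neg] <- revcomp(seqs[neg])
  quals[neg] <- vapply(quals[neg], function(q) intToUtf8(rev(utf8ToInt(q))),
                       character(1), USE.NAMES = FALSE)
  n <- nrow(src)
  obs <- data.table(
    target_id = rep(src$target_id, rl),
    pos = unlist(lapply(seq_len(n), function(i) src$pos[i] + 0:(rl[i] - 1L))),
    base = unlist(strsplit(seqs, "", fixed = TRUE)),
    qual = utf8ToInt(paste(quals, collapse = "")) - 33L,
    read_id = rep(src$read_id, rl),
    strand = rep(src$strand, rl),
    read_copy = rep(src$read_copy, rl))
  ref_chars <- lapply(reference, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  obs[, ref_base := ref_chars[[target_id[1]]][pos + 1L], by = target_id]
  setorder(obs, target_id, pos, read_id)
  as.data.frame(obs[, .(target_id, pos, ref_base, base, qual, read_id,
                        strand, read_copy)])
}

#' Coverage of the reference by uniquely placed reads
#'
#' @param pile Long-form pileup from [pileup()].
#' @return List with `covered_bases` (positions with at least one
#'   observation) and `fold_coverage` (aligned bases / covered bases; 0 when
#'   nothing is covered).
#' @export
coverage_stats <- function(pile) {
  if (nrow(pile) == 0L) {
    return(list(covered_bases = 0L, fold_coverage = 0))
  }
  covered <- nrow(unique(pile[, c("target_id", "pos")]))
  list(covered_bases = covered, fold_coverage = nrow(pile) / covered)
}
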