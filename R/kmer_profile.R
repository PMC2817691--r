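#' Count k-mer occurrences across a read set
#'
#' Counting is strand-literal — 33-mers are counted exactly as sequenced,
#' with no canonicalisation — so the total count over all k-mers equals the
#' number of reads when `read_len == k`, matching how the occurrence summary
#' of a tag library is tallied. Reads shorter than `k` are skipped and
#' reported via the `n_skipped` attribute.
#'
#' @param reads Read `data.frame` (columns `id`, `seq`) or character vector
#'   of sequences.
#' @param k K-mer length (default 33). Reads longer than `k` contribute
#'   their first `k` bases (every read in this pipeline has length `k`).
#' @return Named integer vector of occurrence counts, with attribute
#'   `n_skipped`.
#' @export
count_kmers <- function(reads, k = 33L) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  short <- nchar(seqs) < k
  n_skipped <- sum(short)
  if (n_skipped > 0) {
    message("count_kmers(): skipped ", n_skipped, " read(s) shorter than k")
  }
  kmers <- substr(seqs[!short], 1L, k)
  tab <- table(kmers)
  counts <- setNames(as.integer(tab), names(tab))
  attr(counts, "n_skipped") <- n_skipped
  counts
}

#' Occurrence bins of the published 33-mer tag summary
#'
#' The occurrence categories used to summarise a deep RRL tag library:
#' single hits up to a `"500 plus"` class. Bins are contiguous and
#' non-overlapping (`min_occ`..`max_occ`, inclusive; `Inf` is open-ended).
#'
#' @return `data.frame(label, min_occ, max_occ)`.
#' @export
default_occurrence_bins <- function() {
  data.frame(
    label = c("1", "2", "3", "4", "5", "6", "7-8", "9-10", "11-14", "15-20",
              "20-34", "35-99", "100-299", "300-500", "500 plus"),
    min_occ = c(1, 2, 3, 4, 5, 6, 7, 9, 11, 15, 21, 35, 100, 300, 501),
    max_occ = c(1, 2, 3, 4, 5, 6, 8, 10, 14, 20, 34, 99, 299, 500, Inf),
    stringsAsFactors = FALSE
  )
}

#' Build an occurrence table from k-mer counts
#'
#' For each occurrence bin: the number of distinct k-mers whose count falls
#' in the bin, the number of reads they account for (sum of counts), and the
#' bases those reads carry (`k` times the reads). A `TOTAL` row holds the
#' column sums. The identity `bases == k * reads` holds in every row.
#'
#' @param counts Named integer vector from [count_kmers()], or a
#'   pre-tabulated `data.frame(occurrence, unique_kmers)` when only the
#'   spectrum is known.
#' @param bins Bin definition as in [default_occurrence_bins()].
#' @param k K-mer/read length used for the base count (default 33).
#' @return `data.frame(label, min_occ, max_occ, unique_kmers, reads, bases)`
#'   with the totals row last (`label == "TOTAL"`).
#' @export
build_occurrence_table <- function(counts, bins = default_occurrence_bins(),
                                   k = 33L) {
  o <- order(bins$min_occ)
  bins <- bins[o, , drop = FALSE]
  if (any(bins$min_occ[-1] <= bins$max_occ[-nrow(bins)])) {
    stop("build_occurrence_table(): occurrence bins overlap")
  }
  if (is.data.frame(counts)) {
    occ <- counts$occurrence
    nkmer <- counts$unique_kmers
  } else {
    if (length(counts) == 0L) stop("build_occurrence_table(): empty counts")
    spec <- table(counts)
    occ <- as.integer(names(spec))
    nkmer <- as.integer(spec)
  }
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    inbin <- occ >= bins$min_occ[i] & occ <= bins$max_occ[i]
    uk <- sum(nkmer[inbin])
    rd <- sum(as.numeric(occ[inbin]) * nkmer[inbin])
    data.frame(label = bins$label[i], min_occ = bins$min_occ[i],
               max_occ = bins$max_occ[i], unique_kmers = uk, reads = rd,
               bases = k * rd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$min_occ), , drop = FALSE]   # high-occurrence first
  total <- data.frame(label = "TOTAL", min_occ = NA_real_, max_occ = NA_real_,
                      unique_kmers = sum(out$unique_kmers),
                      reads = sum(out$reads), bases = sum(out$bases),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  rbind(out, total)
}

#' Exclude reads whose 33-mer was sequenced too many times
#'
#' Tags observed 300 or more times in a deep RRL library are repetitive
#' nuclear DNA or organellar DNA and are removed before alignment. The
#' partition is exact: a read is excluded iff its k-mer occurrence is
#' `> max_occ` (default `max_occ = 299`, i.e. occurrence >= 300 excluded).
#'
#' @param reads Read `data.frame`.
#' @param counts Counts from [count_kmers()] over the same read set.
#' @param max_occ Highest occurrence kept (default 299).
#' @return List with `kept` and `excluded` read `data.frame`s.
#' @export
filter_reads_by_occurrence <- function(reads, counts, max_occ = 299L) {
  occ <- unname(counts[match(substr(reads$seq, 1L, 33L), names(counts))])
  occ[is.na(occ)] <- 0L
  drop <- occ > max_occ
  list(kept = reads[!drop, , drop = FALSE],
       excluded = reads[drop, , drop = FALSE])
}

#' Discard reads matching organelle sequence
#'
#' "Matches" is formalised as an ungapped full-length alignment to either
#' strand of any organelle record with at most `max_mismatch` mismatches
#' (the chloroplast/mitochondrion screen of the discovery protocol states
#' no threshold; one mismatch tolerates a sequencing error).
#'
#' @param reads Read `data.frame`.
#' @param organelle_refs Named character vector of organelle sequences.
#' @param max_mismatch Mismatch tolerance (default 1).
#' @return List with `kept` and `discarded` read `data.frame`s.
#' @export
screen_organelle <- function(reads, organelle_refs, max_mismatch = 1L) {
  if (is.null(organelle_refs) || length(organelle_refs) == 0L ||
      nrow(reads) == 0L) {
    return(list(kept = reads, discarded = reads[0, , drop = FALSE]))
  }
  idx <- build_index(organelle_refs, seed_len = 11L)
  hitcount <- vapply(reads$seq, function(s) {
    nrow(ungapped_hits(s, idx, max_mismatch = max_mismatch, max_hits = 1L))
  }, integer(1), USE.NAMES = FALSE)
  drop <- hitcount > 0L
  list(kept = reads[!drop, , drop = FALSE],
       discarded = reads[drop, , drop = FALSE])
}

#' Published 33-mer occurrence summary of the G. soja RRL library
#'
#' The per-occurrence-category tag summary of the deep Genome Analyzer
#' sequencing run of the *Glycine soja* PI 468916 reduced representation
#' library (8,671,165 reads of 33 bp), shipped with the package as the
#' reference point for the occurrence-table arithmetic: per-category unique
#' 33-mers, reads and bases.
#'
#' @return `data.frame(label, unique_kmers, reads, bases)`, highest
#'   occurrence category first (no totals row).
#' @export
published_occurrence_summary <- function() {
  path <- system.file("extdata", "soja_rrl_occurrence.tsv",
                      package = "rrlsnp", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c("character", "numeric", "numeric", "numeric"))
}
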