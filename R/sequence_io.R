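#' @importFrom data.table data.table := setorder setkey rbindlist as.data.table
#' @importFrom stats rbinom rpois runif setNames uniroot cor dbinom
#' @importFrom utils write.table read.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

# IUPAC nucleotide codes mapped to the set of unambiguous bases they stand for.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA sequence
#'
#' Complements over the full IUPAC alphabet (so restriction-site patterns can
#' be reverse-complemented as well as plain sequence) and reverses. `N` maps
#' to `N`; the operation is an involution.
#'
#' @param seq Character scalar (or vector) over the IUPAC DNA alphabet.
#' @return Character of the same length with each element reverse-complemented.
#' @examples
#' revcomp("AAC")   # "GTT"
#' revcomp("ACGT")  # "ACGT" (self-complementary)
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  bad <- grepl("[^ACGTNRYSWKMBDHV]", seq)
  if (any(bad)) {
    stop("revcomp(): sequence contains characters outside the IUPAC DNA alphabet")
  }
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", seq)
  vapply(comp, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Match an IUPAC pattern against an equal-length sequence window
#'
#' A window base matches a pattern position when it belongs to that IUPAC
#' code's base set. An `N` in the *window* (i.e. in genomic sequence) matches
#' nothing, not even pattern `N`: assembly gaps never satisfy a recognition
#' site, so no cut or alignment can land inside a gap.
#'
#' @param pattern Character scalar over IUPAC codes.
#' @param window Character scalar, same length, over `{A,C,G,T,N}`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' iupac_match("CAYNNNNRTG", "CACAATTGTG")  # TRUE: Y={C,T}, R={A,G}
#' @export
iupac_match <- function(pattern, window) {
  if (nchar(pattern) != nchar(window)) {
    stop("iupac_match(): pattern and window lengths differ")
  }
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  if (!all(p %in% names(IUPAC_SETS))) {
    stop("iupac_match(): pattern contains non-IUPAC characters")
  }
  all(vapply(seq_along(p), function(i) {
    w[i] != "N" && w[i] %in% IUPAC_SETS[[p[i]]]
  }, logical(1)))
}

# Vectorised IUPAC scan: all 1-based start positions in `seq_chars` (a split
# character vector) where `pattern` matches. Same N-in-genome rule as
# iupac_match(). Used by the digest and never exposed directly.
iupac_scan <- function(seq_chars, pattern) {
  k <- nchar(pattern)
  L <- length(seq_chars)
  if (L < k) return(integer(0))
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  n_starts <- L - k + 1L
  ok <- rep(TRUE, n_starts)
  for (j in seq_len(k)) {
    win <- seq_chars[j:(n_starts + j - 1L)]
    ok <- ok & (win %in% IUPAC_SETS[[p[j]]]) & (win != "N")
  }
  which(ok)
}

#' Read a multi-record FASTA file
#'
#' Parsing is delegated to [Biostrings::readDNAStringSet()]; a light
#' validation pass first reports malformed headers or empty records with
#' their line numbers. Sequences are uppercased; only `{A,C,G,T,N}` are
#' accepted (RNA `U` is rejected — this is a DNA pipeline).
#'
#' @param path Path to a FASTA file (plain text or gzip).
#' @return Named character vector: names are record ids (first whitespace
#'   token of each header), values the uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta(): no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("read_fasta(): empty file: ", path)
  headers <- grep("^>", lines)
  if (length(headers) == 0L || headers[1] != 1L) {
    stop("read_fasta(): line 1: expected a '>' header")
  }
  empty_hdr <- headers[nchar(sub("^>", "", lines[headers])) == 0L]
  if (length(empty_hdr)) {
    stop("read_fasta(): line ", empty_hdr[1], ": header has no id")
  }
  ends <- c(headers[-1] - 1L, length(lines))
  for (i in seq_along(headers)) {
    body <- lines[seq(headers[i] + 1L, length.out = max(0L, ends[i] - headers[i]))]
    if (sum(nchar(body)) == 0L) {
      stop("read_fasta(): line ", headers[i], ": record '",
           sub("^>", "", lines[headers[i]]), "' has an empty sequence")
    }
  }
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("read_fasta(): duplicated record id: ", ids[duplicated(ids)][1])
  }
  if (any(grepl("U", seqs, fixed = TRUE))) {
    stop("read_fasta(): sequence contains 'U'; RNA input is not supported")
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("read_fasta(): record '", ids[bad][1],
         "' contains characters outside {A,C,G,T,N}")
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap column, fixed at 80 by default.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Decode / encode Phred+33 quality strings
#'
#' Per-base quality scores are carried as Phred+33 strings (the only FASTQ
#' dialect supported). Scores are capped at 40, the scale used by the 33 bp
#' Genome Analyzer tags this pipeline models.
#'
#' @param qual Phred+33 quality string.
#' @return `phred_decode()`: integer vector of scores. `phred_encode()`:
#'   quality string.
#' @examples
#' phred_decode("I!")  # 40 0
#' @export
phred_decode <- function(qual) {
  utf8ToInt(qual) - 33L
}

#' @rdname phred_decode
#' @param scores Integer vector of quality scores in `[0, 40]`.
#' @export
phred_encode <- function(scores) {
  if (any(scores < 0L | scores > 40L)) {
    stop("phred_encode(): quality scores must lie in [0, 40]")
  }
  intToUtf8(as.integer(scores) + 33L)
}

#' Read a 4-line-record FASTQ file of quality-scored reads
#'
#' @param path Path to a FASTQ file (Phred+33; plain text or gzip).
#' @return A `data.frame` with columns `id`, `seq` (uppercase) and `qual`
#'   (Phred+33 string, same length as `seq`) — the package's read container.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("read_fastq(): no such file: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  seq <- as.character(x)
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  if (any(nchar(seq) != nchar(qual))) {
    stop("read_fastq(): sequence/quality length mismatch in ", path)
  }
  q <- utf8ToInt(paste(qual, collapse = "")) - 33L
  if (length(q) && (min(q) < 0L || max(q) > 40L)) {
    stop("read_fastq(): quality scores outside [0, 40]; only Phred+33 with ",
         "max 40 is supported")
  }
  data.frame(id = sub("\\s.*$", "", names(x)), seq = seq, qual = qual,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write quality reads to FASTQ (Phred+33)
#'
#' Round-trips with [read_fastq()]: `read_fastq(write_fastq(x, p))` is
#' identical to `x` for canonical input.
#'
#' @param reads Read `data.frame` with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("write_fastq(): sequence/quality length mismatch")
  }
  out <- character(4L * nrow(reads))
  out[seq(1, by = 4, length.out = nrow(reads))] <- paste0("@", reads$id)
  out[seq(2, by = 4, length.out = nrow(reads))] <- reads$seq
  out[seq(3, by = 4, length.out = nrow(reads))] <- "+"
  out[seq(4, by = 4, length.out = nrow(reads))] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]
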