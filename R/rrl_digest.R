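#' Define a blunt-cutting restriction enzyme
#'
#' @param name Enzyme name.
#' @param site Recognition site as an IUPAC pattern.
#' @param cut_offset Blunt cut position on the top strand: the cut falls
#'   between `site[cut_offset]` and `site[cut_offset + 1]`, so
#'   `0 < cut_offset < nchar(site)`.
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("HaeIII", "GGCC", 2)
#' @export
restriction_enzyme <- function(name, site, cut_offset) {
  site <- toupper(site)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", site)) {
    stop("restriction_enzyme(): site must be an IUPAC pattern")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset <= 0L || cut_offset >= nchar(site)) {
    stop("restriction_enzyme(): cut_offset must satisfy 0 < offset < site length")
  }
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("%s  %s^%s\n", x$name,
              substr(x$site, 1, x$cut_offset),
              substr(x$site, x$cut_offset + 1, nchar(x$site))))
  invisible(x)
}

#' The five-enzyme blunt-cutter set used to build the RRL
#'
#' HaeIII (GG^CC), PsiI (TTA^TAA), SspI (AAT^ATT), RsaI (GT^AC) and MslI
#' (CAYNN^NNRTG) — the combination chosen for the soybean reduced
#' representation library because it produced the least banding (fewest
#' high-copy fragments) in the 100-150 bp size window. All five sites are
#' palindromic, so top- and bottom-strand recognition coincide.
#'
#' @return Named list of [restriction_enzyme()] objects.
#' @export
default_enzyme_set <- function() {
  list(
    HaeIII = restriction_enzyme("HaeIII", "GGCC", 2),
    PsiI   = restriction_enzyme("PsiI",   "TTATAA", 3),
    SspI   = restriction_enzyme("SspI",   "AATATT", 3),
    RsaI   = restriction_enzyme("RsaI",   "GTAC", 2),
    MslI   = restriction_enzyme("MslI",   "CAYNNNNRTG", 5)
  )
}

# All top-strand cut positions (number of bases left of the cut, i.e. cut
# between position p and p+1, 1-based) produced by one enzyme on `seq_chars`.
# Both strands are scanned; for a site found on the bottom strand at
# top-strand span [s, s+k-1], the blunt cut sits at s + (k - cut_offset) - 1
# bases from the span start. Duplicate positions (palindromes) collapse.
enzyme_cut_positions <- function(seq_chars, enzyme) {
  k <- nchar(enzyme$site)
  fwd <- iupac_scan(seq_chars, enzyme$site) + enzyme$cut_offset - 1L
  rc_site <- revcomp(enzyme$site)
  rev <- iupac_scan(seq_chars, rc_site) + (k - enzyme$cut_offset) - 1L
  sort(unique(c(fwd, rev)))
}

#' Digest a sequence with a set of restriction enzymes
#'
#' Simulates complete digestion: every recognition-site occurrence on either
#' strand is cut (overlapping sites all cut; duplicate cut positions are
#' collapsed). Sites overlapping assembly gaps (`N`) never match, so no cut
#' falls inside a gap. The returned fragments tile the input exactly.
#'
#' @param seq Sequence string, or a length-1 named character vector.
#' @param enzymes List of [restriction_enzyme()] objects
#'   (default [default_enzyme_set()]).
#' @param source_id Id recorded on the fragments; defaults to the name of
#'   `seq` or `"seq"`.
#' @return `data.frame` with columns `source_id`, `start` (0-based
#'   inclusive), `end` (0-based exclusive), `length`, `seq`, ordered by
#'   `start`; the concatenation of `seq` equals the input.
#' @examples
#' digest("AAGGCCTT", list(restriction_enzyme("HaeIII", "GGCC", 2)))
#' @export
digest <- function(seq, enzymes = default_enzyme_set(), source_id = NULL) {
  if (is.null(source_id)) {
    source_id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  }
  seq <- unname(seq[1])
  if (!nzchar(seq)) stop("digest(): empty sequence")
  if (length(enzymes) == 0L) stop("digest(): need at least one enzyme")
  sc <- seq_chars(seq)
  cuts <- sort(unique(unlist(lapply(enzymes, function(e) {
    enzyme_cut_positions(sc, e)
  }))))
  L <- nchar(seq)
  cuts <- cuts[cuts > 0L & cuts < L]
  starts <- c(0L, cuts)            # 0-based inclusive
  ends <- c(cuts, L)               # 0-based exclusive
  data.frame(
    source_id = source_id,
    start = starts,
    end = ends,
    length = ends - starts,
    seq = substring(seq, starts + 1L, ends),
    stringsAsFactors = FALSE
  )
}

#' Digest every record of a reference
#'
#' @param reference Named character vector of sequences (see [read_fasta()]).
#' @inheritParams digest
#' @return Row-bound fragment `data.frame` over all records.
#' @export
digest_reference <- function(reference, enzymes = default_enzyme_set()) {
  do.call(rbind, lapply(names(reference), function(id) {
    digest(reference[[id]], enzymes, source_id = id)
  }))
}

#' Size-select fragments
#'
#' Keeps fragments whose length lies in the inclusive window
#' `[min_len, max_len]` — the in-silico equivalent of excising the
#' 100-150 bp region from the gel.
#'
#' @param fragments Fragment `data.frame` from [digest()].
#' @param min_len,max_len Inclusive length bounds (default 100 and 150).
#' @return The selected rows, input order preserved.
#' @export
size_select <- function(fragments, min_len = 100L, max_len = 150L) {
  if (min_len > max_len) stop("size_select(): min_len > max_len")
  fragments[fragments$length >= min_len & fragments$length <= max_len, ,
            drop = FALSE]
}

#' Rank candidate enzyme sets by banding in the size window
#'
#' A visible "band" on the gel is modelled as a distinct fragment sequence
#' occurring at high copy number within the size window: a single-copy
#' fragment contributes too little DNA to show. For each candidate set the
#' band count is the number of distinct in-window fragment sequences with
#' copy number `>= band_copy_threshold`; sets are ranked ascending (least
#' banding first, the selection criterion for the library enzymes), with
#' ties broken by set name.
#'
#' @param reference Named character vector of sequences.
#' @param candidate_sets Named list; each element a list of
#'   [restriction_enzyme()] objects.
#' @param window Length-2 inclusive size window (default `c(100, 150)`).
#' @param band_copy_threshold Copies of an identical fragment needed to call
#'   a band (default 10; the gel-visibility model is a configuration knob,
#'   not something the wet-lab protocol quantifies).
#' @return `data.frame` with columns `set_name`, `band_count`, ranked.
#' @export
rank_enzyme_sets <- function(reference, candidate_sets,
                             window = c(100L, 150L),
                             band_copy_threshold = 10L) {
  if (length(candidate_sets) == 0L) stop("rank_enzyme_sets(): no candidate sets")
  if (is.null(names(candidate_sets))) {
    names(candidate_sets) <- paste0("set", seq_along(candidate_sets))
  }
  counts <- vapply(candidate_sets, function(enzymes) {
    frags <- size_select(digest_reference(reference, enzymes),
                         window[1], window[2])
    if (nrow(frags) == 0L) return(0L)
    tab <- table(frags$seq)
    sum(tab >= band_copy_threshold)
  }, integer(1))
  out <- data.frame(set_name = names(candidate_sets),
                    band_count = unname(counts),
                    stringsAsFactors = FALSE)
  out[order(out$band_count, out$set_name), , drop = FALSE]
}
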