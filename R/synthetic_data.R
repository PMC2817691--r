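#' Simulation configuration for the synthetic RRL study
#'
#' Bundles the knobs of the read simulator. Defaults encode the study this
#' package models: a wild-relative accession diverged from the reference at
#' about one SNP per 425 bp (nucleotide diversity ~0.00235), sequenced as
#' 33 bp tags whose per-base qualities are capped at 40.
#'
#' @param snp_rate Per-base substitution probability between accession and
#'   reference (default `1/425`).
#' @param read_len Read length in bp (default 33).
#' @param depth_target Mean fold-coverage of the sequenced fragment bases.
#' @param error_rate Per-base miscall probability (default 0.002).
#' @param organelle_fraction Proportion of reads drawn from organelle
#'   sequence (default 0).
#' @param seed Integer seed; mandatory for every stochastic run.
#' @param read_start `"end"` (default): reads are the first 33 bp of each
#'   fragment end, both strands — short-insert libraries sequence fragment
#'   ends, which is what makes RRLs recover the same loci from different
#'   genotypes. `"uniform"`: uniform offsets within the fragment.
#' @param qual_profile `"constant"` (default) or `"decay"` (linear 3'
#'   error-rate increase, qualities falling accordingly).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(snp_rate = 1 / 425, read_len = 33L, depth_target = 10,
                       error_rate = 0.002, organelle_fraction = 0,
                       seed = NULL, read_start = c("end", "uniform"),
                       qual_profile = c("constant", "decay")) {
  read_start <- match.arg(read_start)
  qual_profile <- match.arg(qual_profile)
  for (r in c(snp_rate, error_rate, organelle_fraction)) {
    if (r < 0 || r > 1) stop("sim_config(): rates must lie in [0, 1]")
  }
  if (is.null(seed)) stop("sim_config(): an explicit seed is required")
  structure(list(snp_rate = snp_rate, read_len = as.integer(read_len),
                 depth_target = depth_target, error_rate = error_rate,
                 organelle_fraction = organelle_fraction,
                 seed = as.integer(seed), read_start = read_start,
                 qual_profile = qual_profile),
            class = "sim_config")
}

#' Generate a random reference sequence
#'
#' Uniform base composition; a stand-in for a repeat-free nuclear genome
#' (repeats are added explicitly with [spike_repeats()]).
#'
#' @param length Sequence length in bp.
#' @param seed Integer seed.
#' @param id Record id (default `"chr1"`).
#' @return Named character vector of length 1.
#' @export
random_genome <- function(length, seed, id = "chr1") {
  withr::with_seed(seed, {
    setNames(paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                   collapse = ""), id)
  })
}

COMPLEMENTARY_ALTS <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                           G = c("A", "C", "T"), T = c("A", "C", "G"))

#' Derive a divergent accession genome with known SNPs
#'
#' Every non-`N` base is substituted independently with probability
#' `snp_rate` to a uniformly chosen different base — the simulated
#' accession whose RRL is sequenced against the unmutated reference.
#'
#' @param reference Named character vector of sequences.
#' @param snp_rate Per-base substitution probability (default `1/425`).
#' @param seed Integer seed.
#' @return List with `genome` (same structure and lengths as `reference`)
#'   and `truth`: `data.frame(source_id, pos, ref_allele, alt_allele)` with
#'   0-based positions, sorted, complete.
#' @export
mutate_genome <- function(reference, snp_rate = 1 / 425, seed) {
  stopifnot(snp_rate >= 0, snp_rate <= 1)
  withr::with_seed(seed, {
    truth <- list()
    genome <- reference
    for (id in names(reference)) {
      chars <- seq_chars(reference[[id]])
      eligible <- chars != "N"
      hit <- which(eligible & runif(length(chars)) < snp_rate)
      if (length(hit)) {
        ref_al <- chars[hit]
        alt_al <- vapply(ref_al, function(b) sample(COMPLEMENTARY_ALTS[[b]], 1),
                         character(1), USE.NAMES = FALSE)
        chars[hit] <- alt_al
        genome[[id]] <- paste(chars, collapse = "")
        truth[[id]] <- data.frame(source_id = id, pos = hit - 1L,
                                  ref_allele = ref_al, alt_allele = alt_al,
                                  stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(source_id = character(), pos = integer(),
                 ref_allele = character(), alt_allele = character(),
                 stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(genome = genome, truth = truth)
  })
}

# Per-base miscall probabilities for one read under the config's profile.
read_error_profile <- function(config) {
  p <- rep(config$error_rate, config$read_len)
  if (config$qual_profile == "decay" && config$read_len > 1L) {
    p <- p * seq(0.5, 1.5, length.out = config$read_len)
  }
  p
}

# Quality score implied by a per-base error probability:
# q = round(-10 log10 p), capped at 40 (error-free bases report the cap).
error_prob_to_qual <- function(p) {
  q <- ifelse(p <= 0, 40L, as.integer(round(-10 * log10(p))))
  pmin(pmax(q, 0L), 40L)
}

#' Sample quality-scored short reads from RRL fragments
#'
#' Draws 33 bp reads from size-selected fragments of the accession genome,
#' applies independent per-base miscalls at `config$error_rate`, and assigns
#' each base the quality implied by its error probability
#' (`q = round(-10*log10(p))`, capped at 40). In `"end"` mode each read is
#' the first `read_len` bases of one fragment end (either strand), with
#' per-fragment read counts `~ Poisson(2 * depth_target)` so that fragment-end
#' bases are covered `depth_target`-fold on average; in `"uniform"` mode
#' offsets are uniform and counts scale with fragment length. An optional
#' organelle reference contaminates the library with reads drawn uniformly
#' from it.
#'
#' Fragments shorter than `read_len` are skipped; their number is recorded
#' in the `n_skipped` attribute of the result.
#'
#' @param fragments Fragment `data.frame` from [digest()] / [size_select()].
#' @param config A [sim_config()].
#' @param organelle Optional named character vector of organelle sequences.
#' @return List with `reads` (`data.frame(id, seq, qual)`) and `provenance`
#'   (`data.frame(id, origin, source_id, ref_start, strand, n_errors)`;
#'   `ref_start` is the 0-based start of the read's window on its source
#'   record, always given for the forward strand of the source).
#' @export
sample_reads <- function(fragments, config, organelle = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rl <- config$read_len
  usable <- fragments[fragments$length >= rl, , drop = FALSE]
  n_skipped <- nrow(fragments) - nrow(usable)
  withr::with_seed(config$seed, {
    recs <- list()
    if (nrow(usable)) {
      lambda <- if (config$read_start == "end") {
        rep(2 * config$depth_target, nrow(usable))
      } else {
        config$depth_target * usable$length / rl
      }
      n_per_frag <- rpois(nrow(usable), lambda)
      idx <- rep(seq_len(nrow(usable)), n_per_frag)
      n_nuc <- length(idx)
      if (n_nuc) {
        strand <- sample(c("+", "-"), n_nuc, replace = TRUE)
        offset <- if (config$read_start == "end") {
          # '+' reads the left fragment end, '-' the right end (its 5' end).
          ifelse(strand == "+", 0L, usable$length[idx] - rl)
        } else {
          floor(runif(n_nuc) * (usable$length[idx] - rl + 1))
        }
        window <- substring(usable$seq[idx], offset + 1L, offset + rl)
        seqv <- ifelse(strand == "-", revcomp(window), window)
        recs[[1]] <- data.frame(
          origin = "nuclear",
          source_id = usable$source_id[idx],
          ref_start = usable$start[idx] + as.integer(offset),
          strand = strand, seq = seqv, stringsAsFactors = FALSE)
      }
      f <- config$organelle_fraction
      if (f > 0 && !is.null(organelle) && n_nuc > 0) {
        n_org <- rpois(1, n_nuc * f / (1 - f))
        if (n_org > 0) {
          src <- sample(names(organelle), n_org, replace = TRUE,
                        prob = nchar(organelle))
          olen <- nchar(organelle)[match(src, names(organelle))]
          opos <- floor(runif(n_org) * (olen - rl + 1))
          ostrand <- sample(c("+", "-"), n_org, replace = TRUE)
          owin <- substring(organelle[match(src, names(organelle))],
                            opos + 1L, opos + rl)
          oseq <- ifelse(ostrand == "-", revcomp(owin), owin)
          recs[[2]] <- data.frame(
            origin = "organelle", source_id = src,
            ref_start = as.integer(opos), strand = ostrand, seq = oseq,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(recs) == 0L) {
      reads <- data.frame(id = character(), seq = character(),
                          qual = character(), stringsAsFactors = FALSE)
      prov <- data.frame(id = character(), origin = character(),
                         source_id = character(), ref_start = integer(),
                         strand = character(), n_errors = integer(),
                         stringsAsFactors = FALSE)
      out <- list(reads = reads, provenance = prov)
      attr(out, "n_skipped") <- n_skipped
      return(out)
    }
    prov <- do.call(rbind, recs)
    n <- nrow(prov)
    # shuffle so organelle reads are interleaved, then apply miscalls
    prov <- prov[sample.int(n), , drop = FALSE]
    p_profile <- read_error_profile(config)
    qual_str <- intToUtf8(error_prob_to_qual(p_profile) + 33L)
    seqs <- prov$seq
    n_err <- integer(n)
    if (config$error_rate > 0) {
      err <- matrix(runif(n * rl) < rep(p_profile, each = n), nrow = n)
      for (i in which(rowSums(err) > 0)) {
        chars <- seq_chars(seqs[i])
        at <- which(err[i, ] & chars != "N")
        if (length(at)) {
          chars[at] <- vapply(chars[at], function(b) {
            sample(COMPLEMENTARY_ALTS[[b]], 1)
          }, character(1), USE.NAMES = FALSE)
          seqs[i] <- paste(chars, collapse = "")
          n_err[i] <- length(at)
        }
      }
    }
    ids <- sprintf("r%06d", seq_len(n))
    reads <- data.frame(id = ids, seq = seqs,
                        qual = rep(qual_str, n), stringsAsFactors = FALSE)
    prov <- data.frame(id = ids, origin = prov$origin,
                       source_id = prov$source_id,
                       ref_start = prov$ref_start, strand = prov$strand,
                       n_errors = n_err, stringsAsFactors = FALSE)
    out <- list(reads = reads, provenance = prov)
    attr(out, "n_skipped") <- n_skipped
    out
  })
}

#' Insert a repeat family into a reference
#'
#' Plants `copies` exact copies of `repeat_unit` at uniformly chosen
#' positions, emulating a high-copy repetitive element whose internal
#' 33-mers will later exceed the occurrence-300 screen in deep read sets.
#'
#' @param reference Named character vector.
#' @param repeat_unit Repeat monomer sequence.
#' @param copies Number of copies to insert (0 returns the input unchanged).
#' @param seed Integer seed.
#' @return List with `reference` (lengths grown by `copies * nchar(unit)`)
#'   and `insertions`: `data.frame(source_id, pos_original, pos_new)` of
#'   0-based insertion points in input and output coordinates.
#' @export
spike_repeats <- function(reference, repeat_unit, copies, seed) {
  copies <- as.integer(copies)
  empty <- data.frame(source_id = character(), pos_original = integer(),
                      pos_new = integer(), stringsAsFactors = FALSE)
  if (copies == 0L) return(list(reference = reference, insertions = empty))
  if (copies < 0L) stop("spike_repeats(): copies must be >= 0")
  ulen <- nchar(repeat_unit)
  withr::with_seed(seed, {
    src <- sample(names(reference), copies, replace = TRUE,
                  prob = nchar(reference))
    ins <- list()
    for (id in unique(src)) {
      k <- sum(src == id)
      L <- nchar(reference[[id]])
      pts <- sort(floor(runif(k) * (L + 1)))    # 0-based insertion points
      pieces <- substring(reference[[id]],
                          c(0L, pts) + 1L, c(pts, L))
      out <- paste(pieces, collapse = repeat_unit)
      reference[[id]] <- out
      ins[[id]] <- data.frame(source_id = id, pos_original = as.integer(pts),
                              pos_new = as.integer(pts + (seq_len(k) - 1L) * ulen),
                              stringsAsFactors = FALSE)
    }
    insertions <- do.call(rbind, ins)
    rownames(insertions) <- NULL
    list(reference = reference, insertions = insertions)
  })
}

#' Write the truth SNP table as a VCF-like TSV
#'
#' @param truth Truth table from [mutate_genome()].
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  out <- data.frame(CHROM = truth$source_id, POS = truth$pos + 1L,
                    REF = truth$ref_allele, ALT = truth$alt_allele)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
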