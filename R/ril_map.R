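#' Kosambi mapping function and its inverse
#'
#' `kosambi()` converts a recombination fraction to map distance,
#' `cM = 25 * ln((1 + 2r) / (1 - 2r))`; `kosambi_inverse()` is its closed
#' form inverse `r = tanh(d / 50) / 2`. The function is strictly increasing
#' on `[0, 0.5)` and `kosambi(r) >= 100 r` (map distance is never shorter
#' than the recombination fraction expressed in cM), reflecting the
#' positive crossover interference the function encodes.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance in centimorgans.
#' @examples
#' kosambi(0.25)           # 25 * log(3) = 27.465...
#' kosambi_inverse(10)     # 0.0987...
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    stop("kosambi(): r must lie in [0, 0.5)")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @param cm Map distance(s) in centimorgans, `>= 0`.
#' @export
kosambi_inverse <- function(cm) {
  if (any(cm < 0)) stop("kosambi_inverse(): distances must be >= 0")
  tanh(cm / 50) / 2
}

#' Define a marker map
#'
#' @param marker_id Marker names.
#' @param linkage_group Linkage-group label per marker.
#' @param cm_pos Genetic position in cM (non-decreasing within each group).
#' @param scaffold_id,phys_pos Optional physical placement (used by the
#'   anchoring module).
#' @return `data.frame` ordered by (linkage_group, cm_pos).
#' @export
marker_map <- function(marker_id, linkage_group, cm_pos,
                       scaffold_id = NA_character_, phys_pos = NA_integer_) {
  if (length(linkage_group) == 1L) {
    linkage_group <- rep(linkage_group, length(marker_id))
  }
  stopifnot(length(marker_id) == length(linkage_group),
            length(marker_id) == length(cm_pos))
  m <- data.frame(marker_id = marker_id, linkage_group = linkage_group,
                  cm_pos = cm_pos, scaffold_id = scaffold_id,
                  phys_pos = phys_pos, stringsAsFactors = FALSE)
  m <- m[order(m$linkage_group, m$cm_pos), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Per-interval recombination probabilities along the ordered map: Kosambi
# inverse of adjacent distances within a linkage group, 0.5 across groups.
interval_recomb <- function(map) {
  n <- nrow(map)
  if (n < 2L) return(numeric(0))
  r <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    if (map$linkage_group[i + 1L] == map$linkage_group[i]) {
      d <- map$cm_pos[i + 1L] - map$cm_pos[i]
      if (d < 0) stop("interval_recomb(): map not ordered within group")
      r[i] <- kosambi_inverse(d)
    } else {
      r[i] <- 0.5
    }
  }
  r
}

# One round of meiosis for a whole population, vectorised over lines:
# given two haplotype matrices (n x m, founder origin 0/1), return one
# gamete per line. Crossovers occur independently in each adjacent-marker
# interval with probability r[j]; markers on different linkage groups
# segregate independently (r = 0.5).
meiose <- function(hapA, hapB, r) {
  n <- nrow(hapA); m <- ncol(hapA)
  pick <- matrix(0L, n, m)   # 0 = hapA, 1 = hapB
  pick[, 1L] <- rbinom(n, 1L, 0.5)
  if (m > 1L) {
    for (j in 2:m) {
      swap <- rbinom(n, 1L, r[j - 1L])
      pick[, j] <- (pick[, j - 1L] + swap) %% 2L
    }
  }
  hapA * (1L - pick) + hapB * pick
}

#' Simulate an F-generation RIL population by single-seed descent
#'
#' Starting from a fully heterozygous F1, each line is advanced by
#' `generation - 1` rounds of self-pollination with one offspring kept per
#' generation (single-seed descent, the plant-to-row protocol). Meiosis
#' places crossovers independently in each adjacent-marker interval at the
#' frequency given by the Kosambi inverse of the interval's map distance;
#' markers on different linkage groups segregate independently. An
#' F5-derived population retains `(1/2)^4 = 6.25%` expected heterozygosity.
#'
#' @param map Marker map from [marker_map()].
#' @param n_lines Number of RILs.
#' @param generation Filial generation (default 5; must be `>= 2`).
#' @param seed Integer seed.
#' @param missing_rate Per-call probability of a missing genotype
#'   (default 0).
#' @return Character matrix `n_lines x n_markers` over
#'   `{"AA", "BB", "AB", NA}`, with line ids as row names and marker ids as
#'   column names.
#' @export
simulate_ril_population <- function(map, n_lines, generation = 5L, seed,
                                    missing_rate = 0) {
  generation <- as.integer(generation)
  if (generation < 2L) stop("simulate_ril_population(): generation must be >= 2")
  if (n_lines < 1L) stop("simulate_ril_population(): n_lines must be >= 1")
  r <- interval_recomb(map)
  m <- nrow(map)
  withr::with_seed(seed, {
    hapA <- matrix(0L, n_lines, m)   # founder A haplotype
    hapB <- matrix(1L, n_lines, m)   # founder B haplotype
    for (g in seq_len(generation - 1L)) {
      g1 <- meiose(hapA, hapB, r)
      g2 <- meiose(hapA, hapB, r)
      hapA <- g1
      hapB <- g2
    }
    geno <- matrix("AB", n_lines, m)
    geno[hapA == 0L & hapB == 0L] <- "AA"
    geno[hapA == 1L & hapB == 1L] <- "BB"
    if (missing_rate > 0) {
      geno[matrix(runif(n_lines * m) < missing_rate, n_lines, m)] <- NA
    }
    dimnames(geno) <- list(sprintf("RIL%04d", seq_len(n_lines)),
                           map$marker_id)
    geno
  })
}

#' Marker heterozygosity of RIL lines
#'
#' @param geno Genotype matrix from [simulate_ril_population()] (or one
#'   line of it as a vector).
#' @return Numeric vector: fraction of `AB` calls among non-missing calls
#'   per line (`NaN` for all-missing lines).
#' @export
heterozygosity <- function(geno) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  apply(geno, 1L, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(NaN)
    mean(g == "AB")
  })
}

#' Exclude lines with excess heterozygosity
#'
#' Lines whose marker heterozygosity strictly exceeds `max_het` are
#' excluded — residual heterozygosity far above the F-generation
#' expectation indicates an outcross during generation advance, not a true
#' inbred line (a line at exactly the threshold is kept). All-missing
#' lines are excluded with reason `"no_data"`.
#'
#' @param geno Genotype matrix.
#' @param max_het Exclusion threshold (default 0.20).
#' @return List with `kept` and `excluded` genotype matrices and
#'   `reasons`: `data.frame(line_id, het, reason)` for the excluded lines.
#' @export
qc_filter <- function(geno, max_het = 0.20) {
  het <- heterozygosity(geno)
  no_data <- is.nan(het)
  drop <- no_data | het > max_het
  reasons <- data.frame(
    line_id = rownames(geno)[drop],
    het = het[drop],
    reason = ifelse(no_data[drop], "no_data", "heterozygosity"),
    stringsAsFactors = FALSE)
  list(kept = geno[!drop, , drop = FALSE],
       excluded = geno[drop, , drop = FALSE],
       reasons = reasons)
}

#' Expected recombinant fraction among homozygous RILs
#'
#' Exact two-locus recurrence for a selfing pedigree (after Haldane and
#' Waddington): tracks the joint distribution of the two haplotypes of one
#' individual over the four two-locus gametes, iterates `generation - 1`
#' rounds of selfing from the F1, and returns the probability that a line
#' homozygous at both loci carries a recombinant haplotype. As
#' `generation` grows this approaches the classic `2r / (1 + 2r)`.
#'
#' @param r True per-meiosis recombination fraction.
#' @param generation Filial generation of the lines.
#' @return Expected proportion of recombinants among doubly homozygous
#'   lines.
#' @export
expected_ril_recombinant_fraction <- function(r, generation = 5L) {
  vapply(r, function(rr) {
    # haplotypes: 1 = (A,A), 2 = (B,B), 3 = (A,B), 4 = (B,A)
    gamete_dist <- function(h1, h2) {
      out <- numeric(4)
      rec1 <- c(h1[1], h2[2])
      rec2 <- c(h2[1], h1[2])
      idx <- function(h) {
        if (h[1] == 0 && h[2] == 0) 1L else if (h[1] == 1 && h[2] == 1) 2L
        else if (h[1] == 0) 3L else 4L
      }
      out[idx(h1)] <- out[idx(h1)] + (1 - rr) / 2
      out[idx(h2)] <- out[idx(h2)] + (1 - rr) / 2
      out[idx(rec1)] <- out[idx(rec1)] + rr / 2
      out[idx(rec2)] <- out[idx(rec2)] + rr / 2
      out
    }
    haps <- list(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
    # state: 4x4 matrix of P(hap pair), ordered
    state <- matrix(0, 4, 4)
    state[1, 2] <- 1   # F1 = (AA-haplotype, BB-haplotype)
    for (g in seq_len(generation - 1L)) {
      nxt <- matrix(0, 4, 4)
      for (i in 1:4) for (j in 1:4) {
        p <- state[i, j]
        if (p > 0) {
          gd <- gamete_dist(haps[[i]], haps[[j]])
          nxt <- nxt + p * outer(gd, gd)
        }
      }
      state <- nxt
    }
    hom <- diag(state)             # both haplotypes identical
    sum(hom[3:4]) / sum(hom)
  }, numeric(1))
}

#' Two-point recombination fraction and LOD between two markers
#'
#' Lines heterozygous or missing at either marker are skipped; among the
#' remaining (homozygous-informative) lines, the observed recombinant
#' fraction is the proportion carrying a non-parental genotype pair. For a
#' RIL population that observed fraction overstates the per-meiosis
#' recombination fraction (recombinants accumulate over the selfing
#' generations), so the estimate is mapped back through the exact selfing
#' recurrence ([expected_ril_recombinant_fraction()]) for the stated
#' generation. The LOD is the base-10 likelihood ratio of the observed
#' recombinant count under the observed fraction versus free recombination
#' (binomial model). Markers are declared linked when `lod >= 10` and the
#' Kosambi distance is at most 50 cM — the two-point linkage criteria used
#' for high-resolution map construction.
#'
#' @param geno Genotype matrix.
#' @param marker_a,marker_b Marker (column) names.
#' @param generation Filial generation of the lines (default 5).
#' @param min_lod,max_cm Linkage declaration thresholds (defaults 10, 50).
#' @return List with `r_obs` (observed recombinant fraction), `r_hat`
#'   (per-meiosis estimate), `cm` (Kosambi distance of `r_hat`), `lod`,
#'   `n_informative` and `linked`. All `NA` (and a warning) when no line
#'   is informative.
#' @export
recombination_fraction <- function(geno, marker_a, marker_b,
                                   generation = 5L, min_lod = 10,
                                   max_cm = 50) {
  a <- geno[, marker_a]
  b <- geno[, marker_b]
  inf <- !is.na(a) & !is.na(b) & a != "AB" & b != "AB"
  n <- sum(inf)
  if (n == 0L) {
    warning("recombination_fraction(): no informative lines")
    return(list(r_obs = NA_real_, r_hat = NA_real_, cm = NA_real_,
                lod = NA_real_, n_informative = 0L, linked = NA))
  }
  k <- sum(a[inf] != b[inf])       # recombinant homozygous lines
  r_obs <- k / n
  # invert the selfing recurrence; observed fractions >= the F-infinity
  # asymptote saturate at r just below 0.5
  r_hat <- if (r_obs <= 0) 0 else {
    upper <- 0.5 - 1e-9
    if (expected_ril_recombinant_fraction(upper, generation) <= r_obs) upper
    else uniroot(function(x) {
      expected_ril_recombinant_fraction(x, generation) - r_obs
    }, c(1e-12, upper), tol = 1e-10)$root
  }
  cm <- kosambi(min(r_hat, 0.5 - 1e-9))
  lod <- if (k == 0L) n * log10(2) else {
    k * log10(r_obs / 0.5) + (n - k) * log10((1 - r_obs) / 0.5)
  }
  list(r_obs = r_obs, r_hat = r_hat, cm = cm, lod = lod,
       n_informative = n, linked = (lod >= min_lod) && (cm <= max_cm))
}

#' Write a genotype matrix as TSV
#'
#' @param geno Genotype matrix (lines x markers).
#' @param path Output path. Missing calls are written as `NA`.
#' @export
write_genotypes_tsv <- function(geno, path) {
  write.table(geno, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
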