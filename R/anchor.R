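#' Anchor and orient scaffolds with mapped markers
#'
#' A scaffold with no mapped marker stays `unanchored`; one or more
#' markers anchor it to their linkage group; and when its markers span at
#' least 1 cM (`cm_span = max(cM) - min(cM)`, threshold inclusive) it can
#' also be oriented — with a single marker, or markers too close on the
#' genetic map, there is no recombination information to fix direction.
#' Orientation is the sign of the rank correlation between physical and
#' genetic marker positions (`forward` when cM increases with bp), which
#' tolerates one noisy marker better than comparing only the two extreme
#' markers; a zero correlation leaves orientation `unknown`. Markers
#' mapping to different linkage groups yield status `conflict`, the signal
#' this kind of map provides for a misassembled scaffold.
#'
#' @param scaffolds `data.frame(scaffold_id, length)`.
#' @param markers `data.frame(marker_id, scaffold_id, phys_pos, cm_pos,
#'   linkage_group)`; rows with missing `cm_pos` count as unmapped.
#' @return `data.frame(scaffold_id, length, n_markers, status,
#'   linkage_group, orientation, cm_span)`, one row per scaffold; `status`
#'   is one of `unanchored`, `anchored`, `oriented`, `conflict` and
#'   `orientation` one of `forward`, `reverse`, `unknown`.
#' @export
anchor_scaffolds <- function(scaffolds, markers) {
  mk <- markers[!is.na(markers$cm_pos), , drop = FALSE]
  if (nrow(scaffolds) == 0L) {
    return(data.frame(scaffold_id = character(), length = integer(),
                      n_markers = integer(), status = character(),
                      linkage_group = character(), orientation = character(),
                      cm_span = numeric(), stringsAsFactors = FALSE))
  }
  res <- lapply(seq_len(nrow(scaffolds)), function(i) {
    sid <- scaffolds$scaffold_id[i]
    slen <- scaffolds$length[i]
    m <- mk[mk$scaffold_id == sid, , drop = FALSE]
    row <- data.frame(scaffold_id = sid, length = slen,
                      n_markers = nrow(m), status = "unanchored",
                      linkage_group = NA_character_,
                      orientation = "unknown", cm_span = NA_real_,
                      stringsAsFactors = FALSE)
    if (nrow(m) == 0L) return(row)
    if (any(!is.na(m$phys_pos) & m$phys_pos >= slen)) {
      stop("anchor_scaffolds(): marker beyond scaffold end on ", sid)
    }
    if (length(unique(m$linkage_group)) > 1L) {
      row$status <- "conflict"
      return(row)
    }
    row$linkage_group <- m$linkage_group[1]
    row$cm_span <- max(m$cm_pos) - min(m$cm_pos)
    if (nrow(m) >= 2L && row$cm_span >= 1.0) {
      rho <- suppressWarnings(cor(m$phys_pos, m$cm_pos, method = "spearman"))
      if (is.na(rho) || rho == 0) {
        row$status <- "anchored"      # no usable direction signal
      } else {
        row$status <- "oriented"
        row$orientation <- if (rho > 0) "forward" else "reverse"
      }
    } else {
      row$status <- "anchored"
    }
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarise an anchoring run
#'
#' @param results Output of [anchor_scaffolds()].
#' @return List with `counts` (named vector over the four statuses),
#'   `anchored_fraction` (fraction of total scaffold length that is
#'   anchored or oriented) and `total_length`.
#' @export
integration_report <- function(results) {
  statuses <- c("unanchored", "anchored", "oriented", "conflict")
  counts <- vapply(statuses, function(s) sum(results$status == s),
                   integer(1))
  total <- sum(results$length)
  placed <- sum(results$length[results$status %in% c("anchored", "oriented")])
  list(counts = counts,
       anchored_fraction = if (total > 0) placed / total else 0,
       total_length = total)
}

#' Write anchoring results as an AGP-like TSV
#'
#' @param results Output of [anchor_scaffolds()].
#' @param path Output path.
#' @export
write_anchor_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
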