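#' Monomer scan parameters
#'
#' @param max_divergence Maximum percent divergence (of the consensus length)
#'   for a reported hit.  Default 25: wide enough to capture old, dispersed
#'   monomer relics while excluding random matches against a ~1.6-kb
#'   consensus.
#' @param min_hit_length_fraction Minimum aligned genomic length as a
#'   fraction of the consensus length (default 0.8).
#' @param both_strands Also scan the reverse complement (default FALSE; the
#'   NBPF use case is single-strand).
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(max_divergence = 25, min_hit_length_fraction = 0.8,
                        both_strands = FALSE) {
  if (!is.numeric(max_divergence) || max_divergence <= 0 || max_divergence >= 100)
    abort_param("max_divergence must be in (0, 100)")
  if (!is.numeric(min_hit_length_fraction) ||
      min_hit_length_fraction <= 0 || min_hit_length_fraction > 1)
    abort_param("min_hit_length_fraction must be in (0, 1]")
  structure(list(max_divergence = max_divergence,
                 min_hit_length_fraction = min_hit_length_fraction,
                 both_strands = isTRUE(both_strands)),
            class = "scan_params")
}

#' Scan a sequence for approximate consensus monomer occurrences
#'
#' For each consensus monomer, finds all locally optimal infix (semi-global)
#' alignments with divergence (100 * edit distance / consensus length) at
#' most `params$max_divergence`, by an exhaustive column-wise dynamic
#' program over the whole sequence.  Each alignment becomes a hit with its
#' genomic interval, label and divergence; hits are reported in coordinate
#' order.  Overlapping hits from different consensuses are *not* resolved
#' here — see [resolve_overlaps].
#'
#' @param seq A [named_sequence] or DNA string.
#' @param cset A [monomer_consensus_set].
#' @param params A [scan_params].
#' @return A `monomer_hits` data frame with columns `seq_id`, `start`, `end`
#'   (0-based half-open), `strand`, `label`, `divergence`, `length`, `seq`
#'   (the matched genomic sequence, reverse-complemented for minus-strand
#'   hits).
#' @export
scan_genome <- function(seq, cset, params = scan_params()) {
  if (!inherits(cset, "monomer_consensus_set"))
    abort_param("cset must be a monomer_consensus_set")
  if (!inherits(params, "scan_params")) abort_param("params must be scan_params")
  seq <- as_named_sequence(seq)
  if (seq$length < min(cset$lengths) * params$min_hit_length_fraction)
    abort_param("sequence shorter than the minimum scannable length")
  scan_one_strand <- function(subject, strand) {
    res <- lapply(seq_along(cset$labels), function(i) {
      m <- cset$lengths[i]
      cutoff <- floor(params$max_divergence / 100 * m)
      df <- semiglobal_scan_cpp(cset$seqs[i], subject, cutoff,
                                params$min_hit_length_fraction,
                                suppress = max(1L, m %/% 2L))
      if (nrow(df) == 0) return(NULL)
      data.frame(seq_id = seq$id, start = df$start, end = df$end,
                 strand = strand, label = cset$labels[i],
                 divergence = 100 * df$edits / m,
                 length = df$end - df$start,
                 seq = substring(subject, df$start + 1L, df$end),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  out <- scan_one_strand(seq$seq, "+")
  if (params$both_strands) {
    rc <- reverse_complement(seq$seq)
    neg <- scan_one_strand(rc, "-")
    if (!is.null(neg)) {
      s <- neg$start
      neg$start <- seq$length - neg$end
      neg$end <- seq$length - s
      out <- rbind(out, neg)
    }
  }
  if (is.null(out)) return(empty_hits())
  out <- out[out$divergence <= params$max_divergence, , drop = FALSE]
  out <- out[order(out$start, out$end, out$label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("monomer_hits", "data.frame")
  out
}

#' Resolve overlapping monomer hits
#'
#' Greedy selection by ascending divergence: a hit is kept when it overlaps
#' no already-kept hit by more than 10% of its own length.  Ties on
#' divergence are broken by leftmost start, then label order.
#'
#' @param hits A `monomer_hits` data frame.
#' @param max_overlap_frac Overlap tolerance as a fraction of the candidate
#'   hit's length (default 0.10).
#' @return The retained hits, sorted by start.
#' @export
resolve_overlaps <- function(hits, max_overlap_frac = 0.10) {
  if (is.null(hits) || nrow(hits) <= 1) return(hits)
  ord <- order(hits$divergence, hits$start, hits$label)
  kept <- integer(0)
  for (i in ord) {
    len_i <- hits$end[i] - hits$start[i]
    ov <- pmax(0L, pmin(hits$end[kept], hits$end[i]) -
                    pmax(hits$start[kept], hits$start[i]))
    if (all(ov <= max_overlap_frac * len_i)) kept <- c(kept, i)
  }
  out <- hits[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("monomer_hits", "data.frame")
  out
}
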