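#' Monomer consensus set
#'
#' Ordered set of labelled consensus monomers (e.g. the three ~1.6-kb NBPF
#' monomer consensuses m1/m2/m3) used for classification and scanning.  The
#' label order defines both the classification tie-break and the cyclic
#' monomer order of a HOR copy.
#'
#' @param seqs Named character vector, or list of [named_sequence] objects.
#' @return An object of class `monomer_consensus_set` with fields `labels`,
#'   `seqs` (named character) and `lengths`.
#' @export
monomer_consensus_set <- function(seqs) {
  if (is.list(seqs))
    seqs <- stats::setNames(
      vapply(seqs, function(s) as_named_sequence(s)$seq, character(1)),
      vapply(seqs, function(s) as_named_sequence(s)$id, character(1)))
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(!nzchar(names(seqs))))
    abort_param("consensus monomers must be named")
  if (anyDuplicated(names(seqs))) abort_param("monomer labels must be unique")
  if (length(seqs) == 0) abort_param("consensus set is empty")
  seqs <- vapply(seqs, normalize_seq, character(1))
  structure(list(labels = names(seqs), seqs = seqs, lengths = nchar(seqs)),
            class = "monomer_consensus_set")
}

#' @export
print.monomer_consensus_set <- function(x, ...) {
  cat(sprintf("<monomer_consensus_set> %s\n",
              paste(sprintf("%s (%d bp)", x$labels, x$lengths), collapse = ", ")))
  invisible(x)
}

#' Pairwise percent divergence between two sequences
#'
#' 100 * edit (Levenshtein) distance / max of the two lengths — the
#' normalization used for copy-versus-copy and monomer-versus-monomer
#' comparisons.  (Classification against a consensus divides by the
#' consensus length instead; see [classify_monomer].)
#'
#' @param a,b DNA strings.
#' @return Percent divergence.
#' @export
pairwise_divergence <- function(a, b) {
  100 * edit_distance_cpp(a, b) / max(nchar(a), nchar(b))
}

#' Edit (Levenshtein) distance
#'
#' Unit-cost global edit distance; `N` matches nothing (including `N`).
#'
#' @param a,b Strings.
#' @return Integer edit distance.
#' @export
edit_distance <- function(a, b) edit_distance_cpp(a, b)

#' Classify a monomer segment against a consensus set
#'
#' Computes the global edit distance of the segment to every consensus
#' monomer; divergence is 100 * distance / consensus length.  The label with
#' the smallest divergence wins; ties are broken by consensus list order.
#'
#' @param segment DNA string (non-empty).
#' @param cset A [monomer_consensus_set].
#' @return List with `label` and `divergence` (percent).
#' @export
classify_monomer <- function(segment, cset) {
  if (!inherits(cset, "monomer_consensus_set"))
    abort_param("cset must be a monomer_consensus_set")
  if (!is.character(segment) || length(segment) != 1 || nchar(segment) == 0)
    abort_param("segment must be a non-empty DNA string")
  segment <- normalize_seq(segment)
  divs <- 100 * vapply(cset$seqs, edit_distance_cpp, 0L, b = segment) /
    cset$lengths
  i <- which.min(divs) # ties resolved to the first = consensus list order
  list(label = cset$labels[i], divergence = unname(divs[i]))
}

empty_hits <- function() {
  df <- data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                   strand = character(0), label = character(0),
                   divergence = numeric(0), length = integer(0),
                   seq = character(0), stringsAsFactors = FALSE)
  class(df) <- c("monomer_hits", "data.frame")
  df
}

next_in_cycle <- function(label, cycle) {
  cycle[(match(label, cycle) %% length(cycle)) + 1L]
}

new_hor_copy <- function(hits, pattern_ok, candidate, reason) {
  structure(list(
    hits = hits,
    start = as.integer(min(hits$start)), end = as.integer(max(hits$end)),
    labels = hits$label, divergences = hits$divergence,
    n_monomers = nrow(hits),
    monomer_seqs = hits$seq,
    seq = paste(hits$seq, collapse = ""),
    pattern_ok = pattern_ok, candidate = candidate,
    canonical = FALSE, reason = reason
  ), class = "hor_copy")
}

#' @export
print.hor_copy <- function(x, ...) {
  cat(sprintf("<hor_copy> [%d, %d) %s%s (%s)\n", x$start, x$end,
              paste(x$labels, collapse = "+"),
              if (x$canonical) " canonical" else "", x$reason))
  invisible(x)
}

#' Call HOR copies from a stream of monomer hits
#'
#' Scans maximal runs of adjacent hits (inter-hit gap at most `max_gap`)
#' left to right.  Three consecutive hits whose labels follow the cyclic
#' monomer order (any starting phase: m1-m2-m3, m2-m3-m1, m3-m1-m2) form a
#' HOR copy; it is a *candidate* for canonical when every monomer diverges
#' from its consensus by less than `div_threshold` percent.  Leftover hits
#' form noncanonical copies tagged by reason: `above_threshold` (correct
#' pattern, divergence too high), `out_of_order` (all three labels, wrong
#' cyclic order), `partial` (1-2 monomers in a run), `isolated` (single hit
#' alone in its run).
#'
#' @param hits A `monomer_hits` data frame sorted by `start` (re-sorted if
#'   needed).
#' @param max_gap Maximum gap (bp) between adjacent hits in a run
#'   (default 100).
#' @param div_threshold Canonical divergence threshold in percent
#'   (default 5).
#' @param cycle Cyclic label order; defaults to the sorted unique hit labels.
#' @return List of `hor_copy` objects (class `hor_copies`), sorted by start.
#' @export
call_hor_copies <- function(hits, max_gap = 100L, div_threshold = 5,
                            cycle = NULL) {
  copies <- list()
  if (is.null(hits) || nrow(hits) == 0)
    return(structure(copies, class = "hor_copies"))
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  if (is.null(cycle)) cycle <- sort(unique(hits$label))
  gaps <- hits$start[-1L] - hits$end[-nrow(hits)]
  run_id <- cumsum(c(1L, as.integer(gaps > max_gap)))
  for (run in split(seq_len(nrow(hits)), run_id)) {
    k <- length(run)
    i <- 1L
    while (i <= k) {
      rows <- function(idx) hits[run[idx], , drop = FALSE]
      lab <- hits$label[run]
      div <- hits$divergence[run]
      if (length(cycle) >= 3L && i + 2L <= k &&
          lab[i + 1L] == next_in_cycle(lab[i], cycle) &&
          lab[i + 2L] == next_in_cycle(lab[i + 1L], cycle)) {
        ok <- all(div[i:(i + 2L)] < div_threshold)
        copies[[length(copies) + 1L]] <- new_hor_copy(
          rows(i:(i + 2L)), pattern_ok = TRUE, candidate = ok,
          reason = if (ok) "candidate" else "above_threshold")
        i <- i + 3L
      } else if (length(cycle) >= 3L && i + 2L <= k &&
                 setequal(lab[i:(i + 2L)], cycle) &&
                 !anyDuplicated(lab[i:(i + 2L)])) {
        copies[[length(copies) + 1L]] <- new_hor_copy(
          rows(i:(i + 2L)), pattern_ok = FALSE, candidate = FALSE,
          reason = "out_of_order")
        i <- i + 3L
      } else if (i + 1L <= k && lab[i + 1L] == next_in_cycle(lab[i], cycle)) {
        copies[[length(copies) + 1L]] <- new_hor_copy(
          rows(i:(i + 1L)), pattern_ok = FALSE, candidate = FALSE,
          reason = "partial")
        i <- i + 2L
      } else {
        copies[[length(copies) + 1L]] <- new_hor_copy(
          rows(i), pattern_ok = FALSE, candidate = FALSE,
          reason = if (k == 1L) "isolated" else "partial")
        i <- i + 1L
      }
    }
  }
  ord <- order(vapply(copies, `[[`, 0L, "start"))
  structure(copies[ord], class = "hor_copies")
}

#' Mark canonical HOR copies
#'
#' A candidate copy (correct cyclic pattern, all divergences below the
#' threshold) is canonical only when it belongs to a tandem run of at least
#' `min_tandem` candidate copies, consecutive copies separated by at most
#' `max_gap` bp.  The default `min_tandem = 3` encodes "in tandem with two
#' or more further copies"; whether doublets qualify is left configurable.
#'
#' @param copies A `hor_copies` list from [call_hor_copies].
#' @param min_tandem Minimum copies in a tandem run (default 3).
#' @param max_gap Maximum gap (bp) between consecutive copies in a run.
#' @return The copies with `canonical` flags set.
#' @export
mark_canonical <- function(copies, min_tandem = 3L, max_gap = 100L) {
  cand <- which(vapply(copies, `[[`, FALSE, "candidate"))
  if (length(cand) == 0) return(copies)
  st <- vapply(copies[cand], `[[`, 0L, "start")
  en <- vapply(copies[cand], `[[`, 0L, "end")
  run_id <- cumsum(c(1L, as.integer(st[-1L] - en[-length(en)] > max_gap)))
  for (run in split(seq_along(cand), run_id)) {
    if (length(run) >= min_tandem)
      for (i in cand[run]) copies[[i]]$canonical <- TRUE
  }
  copies
}

#' Group canonical copies into tandem arrays
#'
#' Partitions canonical copies into maximal tandem runs (consecutive copies
#' separated by at most `max_gap` bp).  When a region annotation is supplied
#' (BED-like data frame with `seq_id`, `start`, `end`, `name`), an array
#' whose midpoint falls inside a region inherits that region's name as
#' `region_label`.
#'
#' @param copies A `hor_copies` list with canonical flags set.
#' @param max_gap Maximum gap (bp) between consecutive copies in an array.
#' @param regions Optional region data frame for labelling.
#' @param divergences Compute per-array divergence statistics via
#'   [array_divergences] (default TRUE; requires >= 2 copies per array).
#' @return List of `hor_array` objects (class `hor_arrays`), each with
#'   fields `copies`, `start`, `end`, `n_copies`, `region_label`,
#'   `inter_copy_divergence`, `intra_copy_divergence`.
#' @export
group_arrays <- function(copies, max_gap = 100L, regions = NULL,
                         divergences = TRUE) {
  canon <- which(vapply(copies, `[[`, FALSE, "canonical"))
  arrays <- list()
  if (length(canon) == 0) return(structure(arrays, class = "hor_arrays"))
  st <- vapply(copies[canon], `[[`, 0L, "start")
  en <- vapply(copies[canon], `[[`, 0L, "end")
  run_id <- cumsum(c(1L, as.integer(st[-1L] - en[-length(en)] > max_gap)))
  for (run in split(seq_along(canon), run_id)) {
    cps <- copies[canon[run]]
    arr <- structure(list(
      copies = cps,
      start = min(st[run]), end = max(en[run]),
      n_copies = length(cps),
      region_label = NA_character_,
      inter_copy_divergence = NA_real_,
      intra_copy_divergence = NA_real_
    ), class = "hor_array")
    if (!is.null(regions) && nrow(regions) > 0) {
      mid <- (arr$start + arr$end) / 2
      inside <- which(regions$start <= mid & mid < regions$end)
      if (length(inside)) arr$region_label <- as.character(regions$name[inside[1]])
    }
    if (divergences && arr$n_copies >= 2) {
      dv <- array_divergences(arr)
      arr$inter_copy_divergence <- dv$inter_copy
      arr$intra_copy_divergence <- dv$intra_copy
    }
    arrays[[length(arrays) + 1L]] <- arr
  }
  structure(arrays, class = "hor_arrays")
}

#' @export
print.hor_array <- function(x, ...) {
  cat(sprintf("<hor_array> [%d, %d) %d copies%s inter %.2f%% / intra %.2f%%\n",
              x$start, x$end, x$n_copies,
              if (is.na(x$region_label)) "" else paste0(" (", x$region_label, ")"),
              x$inter_copy_divergence, x$intra_copy_divergence))
  invisible(x)
}

#' Inter- and intra-copy divergence of a tandem array
#'
#' Inter-copy divergence: mean over all unordered copy pairs of
#' 100 * edit distance / max of the two copy lengths, on full HOR-copy
#' sequences.  Intra-copy divergence: mean over copies of the mean pairwise
#' divergence (same normalization) among each copy's constituent monomer
#' sequences.  For genuine HOR arrays the former is an order of magnitude
#' smaller than the latter.
#'
#' @param array A `hor_array` (or a list of `hor_copy` objects) with at
#'   least two copies.
#' @return List with `inter_copy` and `intra_copy` (percent).
#' @export
array_divergences <- function(array) {
  cps <- if (inherits(array, "hor_array")) array$copies else array
  if (length(cps) < 2L) abort_param("need at least 2 copies")
  seqs <- vapply(cps, `[[`, "", "seq")
  D <- pairwise_edit_cpp(seqs)
  lens <- nchar(seqs)
  maxlen <- outer(lens, lens, pmax)
  ut <- upper.tri(D)
  inter <- mean(100 * D[ut] / maxlen[ut])
  intras <- vapply(cps, function(cp) {
    ms <- cp$monomer_seqs
    if (length(ms) < 2L) return(NA_real_)
    Dm <- pairwise_edit_cpp(ms)
    lm <- nchar(ms)
    ml <- outer(lm, lm, pmax)
    utm <- upper.tri(Dm)
    mean(100 * Dm[utm] / ml[utm])
  }, numeric(1))
  list(inter_copy = inter, intra_copy = mean(intras, na.rm = TRUE))
}
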