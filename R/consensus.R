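#' Build an iterative majority-vote consensus from repeat copies
#'
#' The medoid copy (minimum summed edit distance to all others) seeds the
#' template; every copy is globally aligned to the template with unit edit
#' costs and a per-column majority vote is taken over the aligned symbols.
#' Columns where gaps hold the strict majority are deleted; insertions
#' relative to the template are retained only when a strict majority of
#' copies insert there (the most frequent inserted string wins, ties broken
#' lexicographically).  Base ties are broken by the fixed order A < C < G < T.
#' The vote repeats with the new consensus until it no longer changes or
#' `max_rounds` is reached.
#'
#' @param copies A `repeat_copies` data frame (from [segment_copies]) or a
#'   character vector of at least two copy sequences.
#' @param max_rounds Maximum refinement rounds (default 5).
#' @return An object of class `consensus_repeat` with fields `seq`, `length`,
#'   `copies` (with `divergence` = 100 * edit distance / consensus length
#'   filled in), `internal_peaks`, `monomer_boundaries`, `monomers` (the last
#'   three filled by [internal_structure]).
#' @export
build_consensus <- function(copies, max_rounds = 5L) {
  if (is.character(copies))
    copies <- data.frame(start = NA_integer_, end = NA_integer_,
                         length = nchar(copies), seq = copies,
                         divergence = NA_real_, stringsAsFactors = FALSE)
  seqs <- copies$seq
  n <- length(seqs)
  if (n < 2L) abort_param("need at least 2 copies to build a consensus")
  D <- pairwise_edit_cpp(seqs)
  template <- seqs[which.min(rowSums(D))]
  for (round in seq_len(max_rounds)) {
    new_template <- vote_consensus(template, seqs)
    if (identical(new_template, template)) break
    template <- new_template
  }
  copies$divergence <- 100 * vapply(seqs, edit_distance_cpp, 0L, b = template) /
    nchar(template)
  structure(list(seq = template, length = nchar(template), copies = copies,
                 internal_peaks = numeric(0),
                 monomer_boundaries = integer(0), monomers = NULL),
            class = "consensus_repeat")
}

# One round of star-alignment majority voting against `template`.
vote_consensus <- function(template, seqs) {
  n <- length(seqs)
  L <- nchar(template)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = 5L, ncol = L,
                   dimnames = list(c(bases, "-"), NULL))
  ins <- vector("list", n) # per copy: named char vector anchor -> inserted string
  for (ci in seq_len(n)) {
    al <- align_global_cpp(template, seqs[ci])
    ta <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
    ca <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
    tpos <- cumsum(ta != "-")
    on_t <- ta != "-"
    sym <- ca[on_t]
    sym[!sym %in% c(bases, "-")] <- "-" # N votes count as gaps
    idx <- cbind(match(sym, rownames(counts)), tpos[on_t])
    for (r in seq_len(nrow(idx)))
      counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + 1L
    ins_cols <- !on_t & ca != "-"
    if (any(ins_cols)) {
      anc <- tpos[ins_cols]
      ins[[ci]] <- vapply(split(ca[ins_cols], anc), paste, character(1),
                          collapse = "")
    } else {
      ins[[ci]] <- character(0)
    }
  }
  gap_majority <- counts["-", ] > n / 2
  base_counts <- counts[bases, , drop = FALSE]
  best <- max.col(t(base_counts), ties.method = "first") # ties: A < C < G < T
  col_base <- bases[best]
  col_base[gap_majority] <- ""
  anchors <- sort(unique(as.integer(unlist(lapply(ins, names)))))
  ins_at <- rep("", L + 1L) # slot a+1 = insertion after template position a
  for (a in anchors) {
    strs <- vapply(ins, function(v) {
      val <- v[as.character(a)]
      if (length(val) == 0 || is.na(val)) "" else val
    }, character(1))
    nz <- strs[nzchar(strs)]
    if (length(nz) > n / 2) {
      tab <- table(nz)
      winners <- names(tab)[tab == max(tab)]
      ins_at[a + 1L] <- sort(winners)[1]
    }
  }
  paste0(paste0(ins_at[seq_len(L)], col_base, collapse = ""), ins_at[L + 1L])
}

#' @export
print.consensus_repeat <- function(x, ...) {
  cat(sprintf("<consensus_repeat> %d bp from %d copies (mean divergence %.2f%%)\n",
              x$length, nrow(x$copies), mean(x$copies$divergence)))
  if (length(x$internal_peaks))
    cat(sprintf("  internal peaks at %s bp; %d monomer boundaries\n",
                paste(x$internal_peaks, collapse = ", "),
                length(x$monomer_boundaries)))
  invisible(x)
}

#' Discover internal sub-repeat (monomer) structure of a consensus
#'
#' Runs the GRM spectrum on the consensus concatenated with itself (doubling
#' exposes periodicity across the junction, which a single short sequence
#' would truncate) with the full-length trivial recurrence excluded.  If the
#' smallest internal peak `p` divides the consensus into `n ~ length/p >= 2`
#' parts, the consensus is segmented at the occurrences of that peak's key
#' string, yielding monomer boundaries and monomer sequences (reported as a
#' rotation of the consensus when the first boundary is not position 0).
#'
#' @param consensus A [build_consensus] result.
#' @param K K-string length for the internal spectrum.  Default 12: long
#'   enough that random recurrence inside a doubled consensus of a few kb is
#'   negligible, short enough that monomers diverged by ~20% still share
#'   many exact K-strings.
#' @param min_mass,smoothing_window,min_separation,window_frac Passed to
#'   [detect_peaks].
#' @return The consensus with `internal_peaks` (ascending bp), and — when a
#'   dividing peak exists — `monomer_boundaries` (0-based cut positions,
#'   strictly increasing within `[0, length]`) and `monomers` (character
#'   vector of monomer sequences) filled in.  A consensus with no internal
#'   homology keeps empty fields (monomeric repeat).
#' @export
internal_structure <- function(consensus, K = 12L, min_mass = 10,
                               smoothing_window = 5L, min_separation = 50L,
                               window_frac = 0.10) {
  if (!inherits(consensus, "consensus_repeat"))
    abort_param("consensus must be a consensus_repeat")
  L <- consensus$length
  if (K >= L) abort_param("K must be smaller than the consensus length")
  doubled <- named_sequence("doubled_consensus",
                            paste0(consensus$seq, consensus$seq))
  idx <- build_kstring_index(doubled, K)
  diag <- compute_grm_diagram(idx, max_distance = L - 1L)
  peaks <- detect_peaks(diag, min_mass = min_mass,
                        smoothing_window = smoothing_window,
                        min_separation = min_separation,
                        window_frac = window_frac)
  consensus$internal_peaks <- sort(as.numeric(peaks$center))
  consensus$monomer_boundaries <- integer(0)
  consensus$monomers <- NULL
  if (nrow(peaks) == 0) return(consensus)
  divides <- round(L / peaks$center) >= 2
  if (!any(divides)) return(consensus)
  cand <- peaks[divides, , drop = FALSE]
  prow <- cand[which.min(cand$center), , drop = FALSE]
  # Monomer lengths inside a HOR differ by a few percent, so the spacings of
  # a K-string conserved across all monomers spread around the peak center;
  # select the key string over the same +/-15% window used for copy
  # segmentation rather than the (much narrower) detected peak window.
  wide <- list(lo = floor(0.85 * prow$center), hi = ceiling(1.15 * prow$center))
  key <- select_key_string(idx, wide)
  occ <- BiocGenerics::start(
    Biostrings::matchPattern(key, Biostrings::DNAString(doubled$seq))) - 1L
  b1 <- occ[occ < L][1]
  cuts <- occ[occ >= b1 & occ < b1 + L]
  consensus$monomer_boundaries <- sort(unique(cuts %% L))
  ends <- c(cuts[-1L], b1 + L)
  consensus$monomers <- substring(doubled$seq, cuts + 1L, ends)
  consensus
}
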