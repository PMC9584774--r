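#' Build the complete K-string index of a sequence
#'
#' Indexes every window of length `K` whose bases are all in `{A,C,G,T}`
#' (windows containing `N` are skipped) at its 0-based start position.  The
#' complete ensemble of K-strings is kept; no statistical selection of
#' individual K-strings is performed.
#'
#' @param seq A [named_sequence] or DNA string.
#' @param K Window length in bp (`1 <= K <= length(seq)`).
#' @return An object of class `kstring_index` with fields `K`, `occurrences`
#'   (named list mapping each distinct K-string to its strictly increasing
#'   0-based start positions), `n_windows` and `source_length`.
#' @export
build_kstring_index <- function(seq, K) {
  seq <- as_named_sequence(seq)
  K <- as.integer(K)
  if (is.na(K) || K < 1L || K > seq$length)
    abort_param(sprintf("K must be in [1, %d], got %s", seq$length, K))
  starts <- seq_len(seq$length - K + 1L)
  wins <- substring(seq$seq, starts, starts + K - 1L)
  ok <- !grepl("N", wins, fixed = TRUE)
  occ <- split(starts[ok] - 1L, wins[ok])
  structure(list(K = K, occurrences = occ, n_windows = sum(ok),
                 source_length = seq$length),
            class = "kstring_index")
}

#' @export
print.kstring_index <- function(x, ...) {
  cat(sprintf("<kstring_index> K=%d, %d distinct K-strings, %d windows over %d bp\n",
              x$K, length(x$occurrences), x$n_windows, x$source_length))
  invisible(x)
}

#' Compute the GRM recurrence-distance diagram
#'
#' For every K-string with occurrences `p1 < p2 < ... < pm`, each consecutive
#' difference `p[i+1] - p[i]` not exceeding `max_distance` increments the
#' frequency at that distance.  Peaks of the resulting spectrum mark repeat
#' unit and higher-order repeat lengths.
#'
#' @param index A [build_kstring_index] result.
#' @param max_distance Distance cap in bp (bounds memory and excludes
#'   inter-array recurrences); default 20000.
#' @return An object of class `grm_diagram` with parallel vectors `distances`
#'   (sorted) and `counts`, plus `K`, `source_length`, `max_distance`.
#' @export
compute_grm_diagram <- function(index, max_distance = 20000L) {
  if (!inherits(index, "kstring_index")) abort_param("index must be a kstring_index")
  max_distance <- as.integer(max_distance)
  if (is.na(max_distance) || max_distance < 1L)
    abort_param("max_distance must be >= 1")
  occ <- index$occurrences
  occ <- occ[lengths(occ) >= 2L]
  d <- unlist(lapply(occ, diff), use.names = FALSE)
  d <- d[d >= 1L & d <= max_distance]
  if (length(d)) {
    tab <- table(d)
    distances <- as.integer(names(tab))
    counts <- as.integer(tab)
  } else {
    distances <- integer(0)
    counts <- integer(0)
  }
  structure(list(K = index$K, distances = distances, counts = counts,
                 source_length = index$source_length,
                 max_distance = max_distance),
            class = "grm_diagram")
}

#' @export
print.grm_diagram <- function(x, ...) {
  cat(sprintf("<grm_diagram> K=%d, %d distinct distances, total count %d (cap %d bp)\n",
              x$K, length(x$distances), sum(x$counts), x$max_distance))
  invisible(x)
}

merge_grm_diagrams <- function(diagrams) {
  stopifnot(length(diagrams) >= 1)
  if (length(diagrams) == 1) return(diagrams[[1]])
  all_d <- sort(unique(unlist(lapply(diagrams, `[[`, "distances"))))
  cnt <- integer(length(all_d))
  for (dg in diagrams) {
    i <- match(dg$distances, all_d)
    cnt[i] <- cnt[i] + dg$counts
  }
  structure(list(K = diagrams[[1]]$K, distances = all_d, counts = cnt,
                 source_length = sum(vapply(diagrams, `[[`, 0L, "source_length")),
                 max_distance = diagrams[[1]]$max_distance),
            class = "grm_diagram")
}

dense_counts <- function(diagram) {
  maxd <- max(diagram$distances)
  v <- integer(maxd)
  v[diagram$distances] <- diagram$counts
  v
}

#' Detect repeat-length peaks in a GRM diagram
#'
#' Local maxima of the smoothed spectrum are reported as peaks.  Each peak's
#' window expands from the raw modal distance while raw counts stay at or
#' above `window_frac` of the modal count; the peak mass is the summed raw
#' count inside the window.  Peaks are returned sorted by descending mass.
#'
#' @param diagram A [compute_grm_diagram] result.
#' @param min_mass Minimum window mass for a reported peak (default 10).
#' @param smoothing_window Width (bp) of the moving-average smoother
#'   (default 5).
#' @param min_separation Minimum distance (bp) between reported peak modes
#'   (default 50); within that radius only the strongest survives.
#' @param window_frac Fraction of the modal count at which the window stops
#'   expanding (default 0.10).
#' @return A data frame of class `grm_peaks` with columns `center`, `lo`,
#'   `hi`, `mass`, `key_string` (`NA` until [select_key_string] is applied).
#' @export
detect_peaks <- function(diagram, min_mass = 10, smoothing_window = 5L,
                         min_separation = 50L, window_frac = 0.10) {
  empty <- data.frame(center = integer(0), lo = integer(0), hi = integer(0),
                      mass = integer(0), key_string = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("grm_peaks", "data.frame")
  if (!inherits(diagram, "grm_diagram")) abort_param("diagram must be a grm_diagram")
  if (length(diagram$distances) == 0) return(empty)
  v <- dense_counts(diagram)
  maxd <- length(v)
  half <- smoothing_window %/% 2L
  cs <- cumsum(c(0L, v))
  i <- seq_len(maxd)
  a <- pmax(i - half, 1L)
  b <- pmin(i + half, maxd)
  s <- (cs[b + 1L] - cs[a]) / (b - a + 1L)
  nz <- which(v > 0L)
  cand <- nz[vapply(nz, function(j) {
    nb <- max(1L, j - min_separation):min(maxd, j + min_separation)
    s[j] >= max(s[nb])
  }, logical(1))]
  if (length(cand) == 0) return(empty)
  rows <- lapply(cand, function(j) {
    nb <- max(1L, j - min_separation):min(maxd, j + min_separation)
    mode <- nb[which.max(v[nb])]
    thr <- window_frac * v[mode]
    lo <- mode
    while (lo > 1L && v[lo - 1L] >= thr) lo <- lo - 1L
    hi <- mode
    while (hi < maxd && v[hi + 1L] >= thr) hi <- hi + 1L
    c(center = mode, lo = lo, hi = hi, mass = sum(v[lo:hi]))
  })
  pk <- unique(as.data.frame(do.call(rbind, rows)))
  pk <- pk[pk$mass >= min_mass, , drop = FALSE]
  if (nrow(pk) == 0) return(empty)
  # within min_separation of a stronger mode, drop the weaker
  pk <- pk[order(-pk$mass, pk$center), , drop = FALSE]
  keep <- rep(TRUE, nrow(pk))
  for (r in seq_len(nrow(pk))) {
    if (!keep[r]) next
    close_by <- keep & abs(pk$center - pk$center[r]) < min_separation
    close_by[r] <- FALSE
    keep[close_by & seq_len(nrow(pk)) > r] <- FALSE
  }
  pk <- pk[keep, , drop = FALSE]
  pk$key_string <- NA_character_
  rownames(pk) <- NULL
  class(pk) <- c("grm_peaks", "data.frame")
  pk
}

#' Select the key string of a peak
#'
#' Returns the K-string with the greatest number of consecutive-occurrence
#' pairs whose spacing lies inside the peak window; ties are broken
#' lexicographically.  The key string is subsequently used to cut the
#' sequence into repeat copies.
#'
#' @param index The [build_kstring_index] the peak was derived from.
#' @param peak One row of a [detect_peaks] result (or a list with `lo`, `hi`).
#' @return The key K-string (character scalar).
#' @export
select_key_string <- function(index, peak) {
  lo <- as.integer(peak$lo[1]); hi <- as.integer(peak$hi[1])
  occ <- index$occurrences
  occ <- occ[lengths(occ) >= 2L]
  if (length(occ) == 0) abort_notfound("no recurring K-string in index")
  npairs <- vapply(occ, function(p) {
    d <- diff(p)
    sum(d >= lo & d <= hi)
  }, integer(1))
  best <- max(npairs)
  if (best < 1L) abort_notfound("no K-string has consecutive pairs inside the peak window")
  # split() ordered keys lexicographically, so the first maximum is the
  # lexicographically smallest key string
  names(npairs)[which.max(npairs)]
}

#' Cut a sequence into repeat copies at key-string occurrences
#'
#' Fragments between consecutive key-string occurrences are kept when their
#' length lies within `len_tol` times the peak center (default
#' `[0.85, 1.15]`, absorbing the indel-driven length spread seen between
#' monomer variants).  Terminal partial fragments are discarded.
#'
#' @param seq A [named_sequence] or DNA string.
#' @param key_string Exact K-string to cut at (must occur at least twice).
#' @param peak Peak row providing the expected copy length (`center`).
#' @param len_tol Length-two numeric: multiplicative tolerance on `center`.
#' @return A data frame of class `repeat_copies` with columns `start`, `end`
#'   (0-based half-open), `length`, `seq`, `divergence` (filled by
#'   [build_consensus]); non-overlapping and sorted by `start`.
#' @export
segment_copies <- function(seq, key_string, peak, len_tol = c(0.85, 1.15)) {
  seq <- as_named_sequence(seq)
  hits <- Biostrings::matchPattern(key_string, Biostrings::DNAString(seq$seq))
  pos0 <- BiocGenerics::start(hits) - 1L
  if (length(pos0) < 2L)
    abort_notfound(sprintf("key string occurs %d time(s); need >= 2", length(pos0)))
  center <- as.numeric(peak$center[1])
  lo <- floor(len_tol[1] * center); hi <- ceiling(len_tol[2] * center)
  lens <- diff(pos0)
  keep <- lens >= lo & lens <= hi
  if (sum(keep) < 2L)
    abort_notfound("fewer than 2 fragments inside the copy-length window")
  st <- pos0[-length(pos0)][keep]
  en <- pos0[-1L][keep]
  out <- data.frame(start = st, end = en, length = en - st,
                    seq = substring(seq$seq, st + 1L, en),
                    divergence = NA_real_, stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("repeat_copies", "data.frame")
  out
}
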