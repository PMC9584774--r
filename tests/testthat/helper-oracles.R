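# Independent brute-force oracles and fixture builders.  The oracles share no
# code with the implementation: the recurrence census walks the sequence with
# an environment hash, and edit distances come from utils::adist.

random_dna_str <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Insertion-order hash walk over all K-windows; counts consecutive
# same-K-string distances under the cap.
oracle_grm_counts <- function(seq, K, max_distance) {
  s <- if (inherits(seq, "named_sequence")) seq$seq else seq
  n <- nchar(s)
  last <- new.env(hash = TRUE, parent = emptyenv())
  counts <- new.env(hash = TRUE, parent = emptyenv())
  if (n >= K) {
    for (i in seq_len(n - K + 1L)) {
      w <- substr(s, i, i + K - 1L)
      if (grepl("N", w, fixed = TRUE)) next
      p <- last[[w]]
      if (!is.null(p)) {
        d <- i - p
        if (d <= max_distance) {
          key <- as.character(d)
          cur <- counts[[key]]
          counts[[key]] <- if (is.null(cur)) 1L else cur + 1L
        }
      }
      last[[w]] <- i
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0) return(stats::setNames(integer(0), character(0)))
  v <- vapply(keys, function(k) counts[[k]], integer(1))
  ord <- order(as.integer(keys))
  stats::setNames(as.integer(v[ord]), keys[ord])
}

# Same walk, but returns the full position dictionary (1-based starts).
oracle_kstring_dict <- function(seq, K) {
  s <- if (inherits(seq, "named_sequence")) seq$seq else seq
  n <- nchar(s)
  dict <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n - K + 1L)) {
    w <- substr(s, i, i + K - 1L)
    if (grepl("N", w, fixed = TRUE)) next
    dict[[w]] <- c(dict[[w]], i)
  }
  keys <- sort(ls(dict))
  stats::setNames(lapply(keys, function(k) dict[[k]]), keys)
}

diagram_as_named <- function(diagram) {
  stats::setNames(diagram$counts, as.character(diagram$distances))
}

oracle_edit <- function(a, b) as.integer(utils::adist(a, b))

# Reference greedy overlap resolution, written independently: double loop,
# ascending divergence with leftmost-start then label tie-breaks.
oracle_resolve <- function(hits, frac = 0.10) {
  ord <- order(hits$divergence, hits$start, hits$label)
  kept <- logical(nrow(hits))
  for (i in ord) {
    ok <- TRUE
    for (j in which(kept)) {
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      if (ov > frac * (hits$end[i] - hits$start[i])) { ok <- FALSE; break }
    }
    kept[i] <- ok
  }
  out <- hits[kept, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# Substitute `k` bases of `seq` at distinct random positions.
substitute_at <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# Minimal monomer-hit frame for copy-calling tests.
make_hits <- function(labels, divergences, len = 100L, gaps = 0L,
                      seq_id = "chr") {
  n <- length(labels)
  if (n == 0) {
    df <- data.frame(seq_id = character(0), start = integer(0),
                     end = integer(0), strand = character(0),
                     label = character(0), divergence = numeric(0),
                     length = integer(0), seq = character(0),
                     stringsAsFactors = FALSE)
    class(df) <- c("monomer_hits", "data.frame")
    return(df)
  }
  gaps <- rep_len(gaps, n)
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + len
  }
  df <- data.frame(seq_id = seq_id, start = starts, end = starts + len,
                   strand = "+", label = labels, divergence = divergences,
                   length = len, seq = strrep("A", 10), stringsAsFactors = FALSE)
  class(df) <- c("monomer_hits", "data.frame")
  df
}
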