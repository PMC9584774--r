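#' Named DNA sequence
#'
#' Lightweight container for a DNA sequence over the alphabet `{A,C,G,T,N}`.
#' On construction the sequence is uppercased and every IUPAC code outside
#' A/C/G/T (ambiguity codes, U, gaps, ...) is mapped to `N`.  Soft-masking
#' (lowercase) is deliberately ignored: masked bases are treated as ordinary
#' bases so that repeats overlapping masked genic sequence are still seen.
#'
#' @param id Character identifier.
#' @param seq DNA string; any case, any IUPAC codes.
#' @return An object of class `named_sequence` with fields `id`, `seq`
#'   (normalized string) and `length` (bp).
#' @examples
#' named_sequence("x", "acgtR")$seq  # "ACGTN"
#' @export
named_sequence <- function(id, seq) {
  seq <- normalize_seq(seq)
  structure(list(id = as.character(id)[1], seq = seq, length = nchar(seq)),
            class = "named_sequence")
}

normalize_seq <- function(seq) {
  seq <- toupper(gsub("[[:space:]]", "", as.character(seq)[1]))
  gsub("[^ACGTN]", "N", seq)
}

as_named_sequence <- function(x, id = "seq") {
  if (inherits(x, "named_sequence")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (!is.null(names(x))) id <- names(x)
    return(named_sequence(id, x))
  }
  abort_param("cannot interpret object as a named_sequence")
}

#' @export
print.named_sequence <- function(x, ...) {
  cat(sprintf("<named_sequence> %s (%d bp)\n", x$id, x$length))
  invisible(x)
}

#' Genomic interval
#'
#' 0-based half-open interval on a named sequence.  All human-readable report
#' writers convert to 1-based inclusive coordinates; BED output keeps the
#' 0-based convention.
#'
#' @param seq_id Sequence identifier.
#' @param start 0-based inclusive start (bp).
#' @param end 0-based exclusive end (bp).
#' @param strand `"+"` or `"-"`.
#' @return An object of class `interval`.
#' @export
interval <- function(seq_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    abort_param(sprintf("invalid interval [%s, %s)", start, end))
  if (!strand %in% c("+", "-")) abort_param("strand must be '+' or '-'")
  structure(list(seq_id = as.character(seq_id), start = start, end = end,
                 strand = strand), class = "interval")
}

#' Read a FASTA file
#'
#' Reads all records (plain or conventionally compressed, wrapped or
#' unwrapped), uppercases sequences and maps non-ACGTN letters to `N`.
#'
#' @param path Path to a FASTA file.
#' @return A list of [named_sequence] objects in file order.
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    abort_input(sprintf("FASTA file not found: %s", path))
  if (!grepl("\\.(gz|bz2|xz)$", path)) {
    head_lines <- tryCatch(readLines(path, n = 50L, warn = FALSE),
                           error = function(e) character(0))
    head_lines <- head_lines[nzchar(trimws(head_lines))]
    if (length(head_lines) == 0)
      abort_format(sprintf("empty FASTA file: %s", path))
    if (!startsWith(head_lines[1], ">"))
      abort_format(sprintf("malformed FASTA (sequence before header): %s", path))
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort_format(
                    sprintf("malformed FASTA file %s: %s", path, conditionMessage(e))))
  if (length(set) == 0) abort_format(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  lapply(seq_along(set), function(i) named_sequence(ids[i], seqs[i]))
}

#' Write sequences to FASTA
#'
#' Writer wraps sequence lines at 60 columns.  `write_fasta` then
#' [read_fasta] round-trips ids and sequences exactly.
#'
#' @param seqs A [named_sequence], a list of them, or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "named_sequence")) seqs <- list(seqs)
  if (is.character(seqs)) {
    ids <- names(seqs)
    chars <- unname(seqs)
  } else {
    ids <- vapply(seqs, function(s) as_named_sequence(s)$id, character(1))
    chars <- vapply(seqs, function(s) as_named_sequence(s)$seq, character(1))
  }
  set <- Biostrings::BStringSet(stats::setNames(chars, ids))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Reverse complement
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement string (`N` maps to `N`).
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract a region from a sequence
#'
#' Returns the subsequence `[start, end)`; for minus-strand intervals the
#' reverse complement is returned.
#'
#' @param seq A [named_sequence] (or plain string).
#' @param iv An [interval].
#' @return A [named_sequence] for the extracted region.
#' @export
extract_region <- function(seq, iv) {
  seq <- as_named_sequence(seq)
  if (iv$end > seq$length)
    abort_bounds(sprintf("interval [%d, %d) out of bounds for %s (%d bp)",
                         iv$start, iv$end, seq$id, seq$length))
  sub <- substr(seq$seq, iv$start + 1L, iv$end)
  if (iv$strand == "-") sub <- reverse_complement(sub)
  named_sequence(sprintf("%s:%d-%d(%s)", seq$id, iv$start + 1L, iv$end, iv$strand),
                 sub)
}

#' Write intervals as BED6
#'
#' @param df Data frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open) and optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @param extra Optional character vector of extra column names in `df` to
#'   append after the six BED fields (e.g. a divergence column).
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, extra = character(0)) {
  n <- nrow(df)
  out <- data.frame(
    chrom = df$seq_id,
    start = as.integer(df$start),
    end = as.integer(df$end),
    name = if ("name" %in% names(df)) df$name else rep(".", n),
    score = if ("score" %in% names(df)) df$score else rep(0L, n),
    strand = if ("strand" %in% names(df)) df$strand else rep("+", n),
    stringsAsFactors = FALSE
  )
  for (col in extra) out[[col]] <- df[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_bed <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("BED file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[seq_len(min(6, ncol(df)))] <-
    c("seq_id", "start", "end", "name", "score", "strand")[seq_len(min(6, ncol(df)))]
  df
}
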