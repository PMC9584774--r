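# Report writers.  Human-readable tables use 1-based inclusive coordinates
# and dot-decimal divergences with 2 decimals; BED output stays 0-based.

#' Write a GRM diagram as two-column TSV
#' @param diagram A `grm_diagram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grm_tsv <- function(diagram, path) {
  utils::write.table(
    data.frame(distance_bp = diagram$distances, count = diagram$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write detected peaks as TSV
#' @param peaks A `grm_peaks` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_tsv <- function(peaks, path) {
  utils::write.table(
    data.frame(center = peaks$center, lo = peaks$lo, hi = peaks$hi,
               mass = peaks$mass, key_string = peaks$key_string),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-monomer report table
#'
#' One row per monomer hit: ordinal number, 1-based start, length, monomer
#' type and percent divergence with two decimals.
#'
#' @param hits A `monomer_hits` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_monomer_table <- function(hits, path) {
  df <- data.frame(
    mon_no = seq_len(nrow(hits)),
    seq_id = hits$seq_id,
    start_bp = hits$start + 1L,
    length_bp = hits$length,
    mon_type = hits$label,
    div_pct = sprintf("%.2f", hits$divergence),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

arrays_summary <- function(copies, arrays) {
  canonical_total <- sum(vapply(copies, `[[`, FALSE, "canonical"))
  noncanonical <- copies[!vapply(copies, `[[`, FALSE, "canonical")]
  reason_tab <- table(vapply(noncanonical, `[[`, "", "reason"))
  list(
    n_arrays = length(arrays),
    canonical_total = canonical_total,
    noncanonical_total = length(noncanonical),
    noncanonical_by_reason = as.list(stats::setNames(as.integer(reason_tab),
                                                     names(reason_tab))),
    arrays = lapply(arrays, function(a) list(
      region_label = a$region_label,
      start_bp = a$start + 1L,
      end_bp = a$end,
      n_copies = a$n_copies,
      inter_copy_divergence_pct = round(a$inter_copy_divergence, 4),
      intra_copy_divergence_pct = round(a$intra_copy_divergence, 4)
    ))
  )
}

#' Write the per-array JSON summary
#' @param copies `hor_copies` (all copies, canonical flags set).
#' @param arrays `hor_arrays`.
#' @param path Output path.
#' @param config Optional resolved run configuration to embed.
#' @return `path`, invisibly.
#' @export
write_arrays_json <- function(copies, arrays, path, config = NULL) {
  obj <- arrays_summary(copies, arrays)
  if (!is.null(config)) obj$config <- config
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 8, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Plot a GRM diagram
#'
#' Distance versus frequency with a log-scaled y axis.
#'
#' @param diagram A `grm_diagram`.
#' @param path Optional output image path (written with `ggplot2::ggsave`).
#' @return The ggplot object (requires the ggplot2 package).
#' @export
plot_grm_diagram <- function(diagram, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    abort_param("ggplot2 is required for plotting")
  df <- data.frame(distance_bp = diagram$distances, count = diagram$counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = distance_bp, y = count)) +
    ggplot2::geom_segment(ggplot2::aes(xend = distance_bp, yend = 1)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "recurrence distance (bp)", y = "frequency",
                  title = sprintf("GRM diagram (K = %d)", diagram$K)) +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 8, height = 4)
  p
}

hits_to_bed_df <- function(hits) {
  data.frame(seq_id = hits$seq_id, start = hits$start, end = hits$end,
             name = hits$label, score = rep(0L, nrow(hits)),
             strand = hits$strand,
             divergence = sprintf("%.2f", hits$divergence),
             stringsAsFactors = FALSE)
}

copies_to_bed_df <- function(copies, seq_id) {
  if (length(copies) == 0)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0)))
  data.frame(
    seq_id = seq_id,
    start = vapply(copies, `[[`, 0L, "start"),
    end = vapply(copies, `[[`, 0L, "end"),
    name = vapply(copies, function(cp)
      if (cp$canonical) "canonical" else cp$reason, ""),
    score = 0L, strand = "+", stringsAsFactors = FALSE)
}
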