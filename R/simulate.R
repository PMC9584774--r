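#' Parameters for the planted-HOR simulator
#'
#' Defaults emulate the statistical regime of the human NBPF 3mer HOR
#' arrays: three monomer consensuses of 1623, 1593 and 1554 bp at ~18%
#' mutual divergence; HOR copies mutated from the m1+m2+m3 unit at a 0.8%
#' per-copy substitution rate (about 1.6% expected pairwise copy
#' divergence) plus rare single-base indels; four tandem arrays of
#' 19/13/11/7 copies (50 in total) separated by non-repetitive gaps and
#' flanked by random sequence.
#'
#' @param monomer_lengths Monomer consensus lengths in bp.
#' @param intra_divergence_target Target pairwise divergence (percent)
#'   between the monomer consensuses.
#' @param copy_substitution_rate Per-base substitution probability applied
#'   independently to every HOR copy.
#' @param copy_indel_rate Per-base probability of a single-base indel
#'   (insertions and deletions equally likely).
#' @param array_sizes Copy counts of the planted tandem arrays.
#' @param inter_array_gap Random-sequence gap between arrays (bp).
#' @param flank_length Random-sequence flank on each side (bp).
#' @param gc_content GC fraction of random sequence (flanks, gaps, ancestor).
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @return An object of class `hor_sim_params`.
#' @export
hor_sim_params <- function(monomer_lengths = c(1623L, 1593L, 1554L),
                           intra_divergence_target = 18,
                           copy_substitution_rate = 0.008,
                           copy_indel_rate = 5e-4,
                           array_sizes = c(19L, 13L, 11L, 7L),
                           inter_array_gap = 3000L,
                           flank_length = 5000L,
                           gc_content = 0.42,
                           seed = 1L) {
  rates <- c(copy_substitution_rate, copy_indel_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates >= 0.5))
    abort_param("mutation rates must lie in [0, 0.5)")
  if (intra_divergence_target < 0 || intra_divergence_target >= 100)
    abort_param("intra_divergence_target must be in [0, 100)")
  if (gc_content <= 0 || gc_content >= 1) abort_param("gc_content must be in (0, 1)")
  if (length(monomer_lengths) < 1 || any(monomer_lengths < 10))
    abort_param("monomer_lengths must all be >= 10 bp")
  structure(list(monomer_lengths = as.integer(monomer_lengths),
                 intra_divergence_target = intra_divergence_target,
                 copy_substitution_rate = copy_substitution_rate,
                 copy_indel_rate = copy_indel_rate,
                 array_sizes = as.integer(array_sizes),
                 inter_array_gap = as.integer(inter_array_gap),
                 flank_length = as.integer(flank_length),
                 gc_content = gc_content,
                 seed = as.integer(seed)),
            class = "hor_sim_params")
}

random_dna <- function(n, gc = 0.42) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Substitutions at `sub_rate`, single-base indels at `indel_rate` (half
# insertions, half deletions).  Returns the mutated sequence plus realized
# event counts; substitutions landing on deleted bases are not counted.
mutate_sequence <- function(seq, sub_rate, indel_rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  del <- stats::runif(L) < indel_rate / 2
  sub <- stats::runif(L) < sub_rate
  out <- chars
  sub_idx <- which(sub & !del)
  if (length(sub_idx)) {
    alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                  nrow = 3, dimnames = list(NULL, c("A", "C", "G", "T")))
    pick <- sample.int(3L, length(sub_idx), replace = TRUE)
    out[sub_idx] <- alt[cbind(pick, match(chars[sub_idx], colnames(alt)))]
  }
  out[del] <- ""
  ins_slot <- stats::runif(L + 1L) < indel_rate / 2
  ins_chars <- rep("", L + 1L)
  n_ins <- sum(ins_slot)
  if (n_ins)
    ins_chars[ins_slot] <- sample(c("A", "C", "G", "T"), n_ins, replace = TRUE)
  body <- paste0(ins_chars[seq_len(L)], out, collapse = "")
  list(seq = paste0(body, ins_chars[L + 1L]),
       n_sub = length(sub_idx), n_ins = n_ins, n_del = sum(del))
}

#' Generate a set of divergent monomer consensuses
#'
#' Draws an ancestral sequence of the maximum monomer length, then derives
#' each monomer by independent substitutions plus random internal deletions
#' down to its target length.  The per-branch substitution rate is tuned by
#' iterative mutate-and-measure (at most 50 retries) until every realized
#' pairwise divergence (100 * edit distance / max length) falls within
#' 2 points of `intra_divergence_target` and the mean is within 0.75 of it.
#' Targeting the measurement, not the nominal rate, is deliberate: the
#' measured divergence is what downstream modules see.
#'
#' @param params A [hor_sim_params].
#' @return A [monomer_consensus_set] labelled `m1`, `m2`, ... with attribute
#'   `realized_divergences` (the measured pairwise divergence matrix).
#' @export
make_monomer_consensuses <- function(params) {
  withr::with_seed(params$seed, {
    lens <- params$monomer_lengths
    k <- length(lens)
    L0 <- max(lens)
    target <- params$intra_divergence_target
    anc <- strsplit(random_dna(L0, params$gc_content), "", fixed = TRUE)[[1]]
    b <- target / 100 * 0.55
    for (try in seq_len(50L)) {
      mono <- vapply(seq_len(k), function(i) {
        chars <- anc
        sub_idx <- which(stats::runif(L0) < b)
        if (length(sub_idx)) {
          alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                        nrow = 3, dimnames = list(NULL, c("A", "C", "G", "T")))
          pick <- sample.int(3L, length(sub_idx), replace = TRUE)
          chars[sub_idx] <- alt[cbind(pick, match(anc[sub_idx], colnames(alt)))]
        }
        ndel <- L0 - lens[i]
        if (ndel > 0) chars <- chars[-sample.int(L0, ndel)]
        paste(chars, collapse = "")
      }, character(1))
      D <- pairwise_edit_cpp(mono)
      ml <- outer(lens, lens, pmax)
      divs <- 100 * D[upper.tri(D)] / ml[upper.tri(ml)]
      if (all(abs(divs - target) <= 2) && abs(mean(divs) - target) <= 0.75) {
        cset <- monomer_consensus_set(stats::setNames(mono, paste0("m", seq_len(k))))
        attr(cset, "realized_divergences") <- divs
        return(cset)
      }
      if (mean(divs) > 0)
        b <- min(0.45, max(0, b * target / mean(divs)))
      else
        b <- min(0.45, b + 0.01)
    }
    grm_error("grm_generation_error",
              "could not reach the divergence target within 50 retries")
  })
}

#' Simulate one tandem HOR array
#'
#' The HOR unit is the concatenation of the consensus monomers in label
#' order; each copy is an independently mutated unit (substitutions at
#' `copy_substitution_rate`, single-base indels at `copy_indel_rate`),
#' and copies are concatenated head to tail.  Monomers are mutated
#' segment-wise so the ground-truth monomer boundaries track every
#' indel-induced coordinate shift exactly.
#'
#' Uses the current RNG state; seed via [withr::with_seed] or call through
#' [simulate_genome] for reproducible output.
#'
#' @param cset A [monomer_consensus_set].
#' @param n_copies Number of copies (>= 1).
#' @param params A [hor_sim_params].
#' @return List with `seq` (the array string) and `truth`, a list of data
#'   frames `monomers` (`start`, `end`, `label`, `copy`, `n_sub`, `n_ins`,
#'   `n_del`; 0-based, tiling the array exactly, labels cycling) and
#'   `copies` (`start`, `end`, `copy`, `n_sub`, `n_ins`, `n_del`).
#' @export
simulate_hor_array <- function(cset, n_copies, params) {
  if (n_copies < 1) abort_param("n_copies must be >= 1")
  mono_rows <- list()
  copy_rows <- list()
  pieces <- character(n_copies)
  pos <- 0L
  for (cp in seq_len(n_copies)) {
    copy_start <- pos
    csub <- 0L; cins <- 0L; cdel <- 0L
    copy_pieces <- character(length(cset$labels))
    for (mi in seq_along(cset$labels)) {
      mut <- mutate_sequence(cset$seqs[mi], params$copy_substitution_rate,
                             params$copy_indel_rate)
      mlen <- nchar(mut$seq)
      mono_rows[[length(mono_rows) + 1L]] <- data.frame(
        start = pos, end = pos + mlen, label = cset$labels[mi], copy = cp,
        n_sub = mut$n_sub, n_ins = mut$n_ins, n_del = mut$n_del,
        stringsAsFactors = FALSE)
      copy_pieces[mi] <- mut$seq
      pos <- pos + mlen
      csub <- csub + mut$n_sub; cins <- cins + mut$n_ins; cdel <- cdel + mut$n_del
    }
    pieces[cp] <- paste(copy_pieces, collapse = "")
    copy_rows[[cp]] <- data.frame(start = copy_start, end = pos, copy = cp,
                                  n_sub = csub, n_ins = cins, n_del = cdel,
                                  stringsAsFactors = FALSE)
  }
  list(seq = paste(pieces, collapse = ""),
       truth = list(monomers = do.call(rbind, mono_rows),
                    copies = do.call(rbind, copy_rows)))
}

#' Simulate a genome with planted HOR arrays
#'
#' Random flanks and inter-array gaps (at the configured GC content) around
#' tandem arrays of the sizes in `params$array_sizes`, with full ground
#' truth in genome coordinates.  Fully deterministic given `params$seed`
#' (the monomer consensuses reuse the seed itself; the assembly stage uses
#' seed + 1).
#'
#' @param params A [hor_sim_params].
#' @return List with `seq` (a [named_sequence]), `cset` (the
#'   [monomer_consensus_set] used), `truth` (class `truth_annotation`: data
#'   frames `monomers`, `copies`, `arrays`, all 0-based half-open with
#'   `seq_id`), and `params`.
#' @export
simulate_genome <- function(params = hor_sim_params()) {
  cset <- make_monomer_consensuses(params)
  seq_id <- sprintf("synthetic_hor_genome_seed%d", params$seed)
  withr::with_seed(params$seed + 1L, {
    pieces <- character(0)
    pos <- 0L
    mono <- list(); cops <- list(); arrs <- list()
    add_piece <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    add_piece(random_dna(params$flank_length, params$gc_content))
    for (ai in seq_along(params$array_sizes)) {
      if (ai > 1)
        add_piece(random_dna(params$inter_array_gap, params$gc_content))
      arr <- simulate_hor_array(cset, params$array_sizes[ai], params)
      m <- arr$truth$monomers
      m$start <- m$start + pos; m$end <- m$end + pos; m$array <- ai
      cpd <- arr$truth$copies
      cpd$start <- cpd$start + pos; cpd$end <- cpd$end + pos; cpd$array <- ai
      arrs[[ai]] <- data.frame(start = pos, end = pos + nchar(arr$seq),
                               array = ai, n_copies = params$array_sizes[ai])
      mono[[ai]] <- m; cops[[ai]] <- cpd
      add_piece(arr$seq)
    }
    add_piece(random_dna(params$flank_length, params$gc_content))
    genome <- named_sequence(seq_id, paste(pieces, collapse = ""))
    bind_id <- function(lst) {
      if (length(lst) == 0)
        return(data.frame(seq_id = character(0), start = integer(0),
                          end = integer(0)))
      df <- do.call(rbind, lst)
      cbind(data.frame(seq_id = seq_id, stringsAsFactors = FALSE), df)
    }
    truth <- structure(list(monomers = bind_id(mono), copies = bind_id(cops),
                            arrays = bind_id(arrs)),
                       class = "truth_annotation")
    list(seq = genome, cset = cset, truth = truth, params = params)
  })
}
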