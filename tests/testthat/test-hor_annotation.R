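make_cset <- function(lens = c(m1 = 300L, m2 = 290L, m3 = 280L), seed = 31) {
  withr::with_seed(seed, monomer_consensus_set(
    vapply(lens, random_dna_str, character(1))))
}

test_that("classification is the argmin of consensus-normalized edit distance", {
  cset <- make_cset()
  r <- classify_monomer(cset$seqs[["m2"]], cset)
  expect_equal(r$label, "m2")
  expect_equal(r$divergence, 0)

  withr::local_seed(32)
  seg <- substitute_at(cset$seqs[["m1"]], 12)
  r <- classify_monomer(seg, cset)
  expect_equal(r$label, "m1")
  # oracle: full DP edit distance, divided by the consensus length
  expect_equal(r$divergence, 100 * oracle_edit(cset$seqs[["m1"]], seg) / 300)

  # ties resolved by consensus list order
  dup <- monomer_consensus_set(c(ma = "ACGTACGT", mb = "ACGTACGT"))
  expect_equal(classify_monomer("ACGTACGT", dup)$label, "ma")
  expect_error(classify_monomer("", cset), class = "grm_parameter_error")
})

test_that("copy calling follows the cyclic pattern and divergence threshold", {
  cyc <- c("m1", "m2", "m3")
  copies <- call_hor_copies(make_hits(cyc, c(1, 1, 1)), cycle = cyc)
  expect_length(copies, 1)
  expect_true(copies[[1]]$candidate)
  expect_equal(copies[[1]]$reason, "candidate")

  copies <- call_hor_copies(make_hits(cyc, c(1, 6, 1)), cycle = cyc)
  expect_length(copies, 1)
  expect_false(copies[[1]]$candidate)
  expect_equal(copies[[1]]$reason, "above_threshold")

  # any cyclic phase qualifies; the array keeps its observed first label
  copies <- call_hor_copies(make_hits(c("m3", "m1", "m2"), c(1, 1, 1)),
                            cycle = cyc)
  expect_true(copies[[1]]$candidate)
  expect_equal(copies[[1]]$labels, c("m3", "m1", "m2"))

  # wrong cyclic order with all three labels
  copies <- call_hor_copies(make_hits(c("m1", "m3", "m2"), c(1, 1, 1)),
                            cycle = cyc)
  expect_equal(vapply(copies, `[[`, "", "reason")[1], "out_of_order")

  # partial copies and isolated hits
  copies <- call_hor_copies(make_hits(c("m1", "m2"), c(1, 1)), cycle = cyc)
  expect_equal(copies[[1]]$reason, "partial")
  expect_equal(copies[[1]]$n_monomers, 2)
  copies <- call_hor_copies(make_hits("m2", 1), cycle = cyc)
  expect_equal(copies[[1]]$reason, "isolated")

  # a gap beyond max_gap splits runs and breaks the triple
  hits <- make_hits(cyc, c(1, 1, 1), gaps = c(0L, 500L, 0L))
  copies <- call_hor_copies(hits, max_gap = 100, cycle = cyc)
  expect_length(copies, 2)
  expect_false(any(vapply(copies, `[[`, FALSE, "candidate")))
  expect_length(call_hor_copies(make_hits(character(0), numeric(0))), 0)
})

test_that("raising the divergence threshold never loses candidate copies", {
  withr::local_seed(33)
  cyc <- c("m1", "m2", "m3")
  labels <- rep(cyc, 8)
  divs <- runif(24, 0, 10)
  n_cand <- vapply(c(2, 5, 8, 11), function(thr) {
    sum(vapply(call_hor_copies(make_hits(labels, divs), div_threshold = thr,
                               cycle = cyc),
               `[[`, FALSE, "candidate"))
  }, numeric(1))
  expect_true(all(diff(n_cand) >= 0))
})

test_that("canonical status requires tandem-run membership", {
  cyc <- c("m1", "m2", "m3")
  run19 <- call_hor_copies(make_hits(rep(cyc, 19), rep(1, 57)), cycle = cyc)
  run19 <- mark_canonical(run19)
  expect_equal(sum(vapply(run19, `[[`, FALSE, "canonical")), 19)

  single <- mark_canonical(call_hor_copies(make_hits(cyc, rep(1, 3)),
                                           cycle = cyc))
  expect_false(single[[1]]$canonical)

  two <- call_hor_copies(make_hits(rep(cyc, 2), rep(1, 6)), cycle = cyc)
  expect_false(any(vapply(mark_canonical(two, min_tandem = 3),
                          `[[`, FALSE, "canonical")))
  expect_true(all(vapply(mark_canonical(two, min_tandem = 2),
                         `[[`, FALSE, "canonical")))
})

test_that("arrays are maximal tandem runs of canonical copies", {
  cyc <- c("m1", "m2", "m3")
  hits <- make_hits(rep(cyc, 19), rep(1, 57))
  copies <- mark_canonical(call_hor_copies(hits, cycle = cyc))
  arrays <- group_arrays(copies, divergences = FALSE)
  expect_length(arrays, 1)
  expect_equal(arrays[[1]]$n_copies, 19)

  # two runs separated by more than max_gap
  gaps <- rep(0L, 36); gaps[19] <- 5000L
  hits2 <- make_hits(rep(cyc, 12), rep(1, 36), gaps = gaps)
  copies2 <- mark_canonical(call_hor_copies(hits2, cycle = cyc))
  arrays2 <- group_arrays(copies2, divergences = FALSE)
  expect_length(arrays2, 2)
  expect_equal(vapply(arrays2, `[[`, 0L, "n_copies"), c(6L, 6L))

  # region labelling by midpoint containment
  regions <- data.frame(seq_id = "chr", start = 0L, end = 10000L,
                        name = "GENE1", stringsAsFactors = FALSE)
  arrays3 <- group_arrays(copies, regions = regions, divergences = FALSE)
  expect_equal(arrays3[[1]]$region_label, "GENE1")
})

test_that("every canonical copy satisfies the definitional predicate", {
  sim <- simulate_genome(hor_sim_params(array_sizes = c(5L, 4L),
                                        flank_length = 1000L,
                                        inter_array_gap = 1200L, seed = 9L))
  hits <- resolve_overlaps(scan_genome(sim$seq, sim$cset, scan_params()))
  copies <- mark_canonical(call_hor_copies(hits, cycle = sim$cset$labels))
  canon <- copies[vapply(copies, `[[`, FALSE, "canonical")]
  expect_gt(length(canon), 0)
  cyc <- sim$cset$labels
  for (cp in canon) {
    expect_equal(cp$n_monomers, 3)
    expect_setequal(cp$labels, cyc)
    expect_equal(cp$labels[2], next_lab <- cyc[(match(cp$labels[1], cyc) %% 3) + 1])
    expect_true(all(cp$divergences < 5))
  }
})

test_that("array divergences separate inter-copy from intra-copy scales", {
  withr::local_seed(34)
  U <- random_dna_str(900)
  mk_copy <- function(seq) list(seq = seq, monomer_seqs = substring(
    seq, c(1, 301, 601), c(300, 600, 900)))
  same <- lapply(rep(U, 4), mk_copy)
  dv <- array_divergences(same)
  expect_equal(dv$inter_copy, 0)
  expect_error(array_divergences(same[1]), class = "grm_parameter_error")

  sim <- simulate_genome(hor_sim_params(array_sizes = 10L,
                                        flank_length = 500L, seed = 10L))
  hits <- resolve_overlaps(scan_genome(sim$seq, sim$cset, scan_params()))
  copies <- mark_canonical(call_hor_copies(hits, cycle = sim$cset$labels))
  arrays <- group_arrays(copies)
  a <- arrays[[1]]
  expect_lt(abs(a$inter_copy_divergence - 1.6), 0.6)
  expect_lt(abs(a$intra_copy_divergence - 18), 2.5)
  # the defining order-of-magnitude contrast
  expect_lt(a$inter_copy_divergence, a$intra_copy_divergence / 5)
})
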