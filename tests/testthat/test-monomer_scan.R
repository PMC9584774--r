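plant <- function(core, flank_left = 3000, flank_right = 3000) {
  list(seq = named_sequence("g", paste0(random_dna_str(flank_left), core,
                                        random_dna_str(flank_right))),
       start = flank_left, end = flank_left + nchar(core))
}

test_that("an exact planted monomer is recovered at its exact coordinates", {
  withr::local_seed(41)
  cset <- monomer_consensus_set(c(m1 = random_dna_str(1000)))
  g <- plant(cset$seqs[["m1"]])
  hits <- scan_genome(g$seq, cset, scan_params())
  expect_equal(nrow(hits), 1)
  expect_equal(hits$label, "m1")
  expect_equal(hits$divergence, 0)
  expect_equal(hits$start, g$start)
  expect_equal(hits$end, g$end)
  expect_equal(hits$seq, cset$seqs[["m1"]])
})

test_that("divergence of a mutated planted copy matches the DP oracle", {
  withr::local_seed(42)
  cset <- monomer_consensus_set(c(m1 = random_dna_str(1000)))
  core <- substitute_at(cset$seqs[["m1"]], 50) # ~5% substitutions
  g <- plant(core)
  hits <- scan_genome(g$seq, cset, scan_params())
  expect_equal(nrow(hits), 1)
  oracle_div <- 100 * oracle_edit(cset$seqs[["m1"]], core) / 1000
  # free text ends may trim a boundary mismatch or two, never add cost
  expect_lte(hits$divergence, oracle_div)
  expect_gt(hits$divergence, oracle_div - 0.5)
  expect_lte(abs(hits$start - g$start), 3)
  expect_lte(abs(hits$end - g$end), 3)
})

test_that("a planted triple tandem yields ordered, correctly labelled hits", {
  sim_params <- hor_sim_params(array_sizes = 5L, flank_length = 2000L,
                               seed = 43L)
  sim <- simulate_genome(sim_params)
  hits <- resolve_overlaps(scan_genome(sim$seq, sim$cset, scan_params()))
  truth <- sim$truth$monomers
  expect_equal(nrow(hits), nrow(truth))
  expect_equal(hits$label, truth$label)
  expect_true(all(abs(hits$start - truth$start) <= 5))
  expect_true(all(hits$divergence < 5))
})

test_that("no hits exceed max_divergence and random sequence yields none", {
  withr::local_seed(44)
  cset <- monomer_consensus_set(c(m1 = random_dna_str(800)))
  hits <- scan_genome(named_sequence("r", random_dna_str(20000)), cset,
                      scan_params())
  expect_equal(nrow(hits), 0)
  expect_error(scan_genome(named_sequence("r", "ACGT"), cset, scan_params()),
               class = "grm_parameter_error")
})

test_that("both-strand scanning mirrors coordinates and flips strand", {
  withr::local_seed(45)
  cset <- monomer_consensus_set(c(m1 = random_dna_str(600)))
  g <- plant(reverse_complement(cset$seqs[["m1"]]), 1500, 1500)
  expect_equal(nrow(scan_genome(g$seq, cset, scan_params())), 0)
  hits <- scan_genome(g$seq, cset, scan_params(both_strands = TRUE))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, g$start)
  expect_equal(hits$end, g$end)
  expect_equal(hits$divergence, 0)
})

test_that("overlap resolution equals the brute-force greedy reference", {
  withr::local_seed(46)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    starts <- sort(sample(0:400, n))
    lens <- sample(50:150, n, replace = TRUE)
    hits <- data.frame(seq_id = "chr", start = starts, end = starts + lens,
                       strand = "+",
                       label = sample(c("m1", "m2", "m3"), n, replace = TRUE),
                       divergence = round(runif(n, 0, 20), 1),
                       length = lens, seq = "A", stringsAsFactors = FALSE)
    got <- resolve_overlaps(hits)
    want <- oracle_resolve(hits)
    expect_equal(got$start, want$start)
    expect_equal(got$label, want$label)
  }
})

test_that("overlap resolution prefers the less divergent of coincident hits", {
  hits <- data.frame(seq_id = "chr", start = c(100L, 100L), end = c(200L, 200L),
                     strand = "+", label = c("m2", "m1"),
                     divergence = c(9, 3), length = 100L, seq = "A",
                     stringsAsFactors = FALSE)
  out <- resolve_overlaps(hits)
  expect_equal(nrow(out), 1)
  expect_equal(out$label, "m1")

  apart <- make_hits(c("m1", "m2"), c(3, 9), gaps = c(0L, 50L))
  expect_equal(nrow(resolve_overlaps(apart)), 2)
})
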