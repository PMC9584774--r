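test_that("K-string index matches direct window enumeration", {
  idx <- build_kstring_index(named_sequence("t", "AAAA"), 2)
  expect_equal(idx$occurrences, list(AA = c(0L, 1L, 2L)))
  expect_equal(idx$n_windows, 3L)

  idx <- build_kstring_index(named_sequence("t", "ACGNT"), 2)
  expect_equal(idx$occurrences, list(AC = 0L, CG = 1L))
  expect_equal(idx$n_windows, 2L)

  withr::local_seed(101)
  s <- random_dna_str(1000)
  idx <- build_kstring_index(named_sequence("r", s), 8)
  dict <- oracle_kstring_dict(s, 8)
  expect_equal(names(idx$occurrences), names(dict))
  expect_equal(lapply(idx$occurrences, `+`, 1L), dict,
               ignore_attr = TRUE)
  expect_equal(sum(lengths(idx$occurrences)), idx$n_windows)

  expect_error(build_kstring_index(named_sequence("t", "ACGT"), 0),
               class = "grm_parameter_error")
  expect_error(build_kstring_index(named_sequence("t", "ACGT"), 5),
               class = "grm_parameter_error")
})

test_that("recurrence diagram counts consecutive same-K-string pairs", {
  # 10 exact tandem copies of a 5-bp unit: 9 pairs in the unit phase,
  # 8 in each of the other four phases
  d <- compute_grm_diagram(
    build_kstring_index(named_sequence("t", strrep("ACGTT", 10)), 5), 100)
  expect_equal(diagram_as_named(d), c("5" = 41L))
  expect_equal(oracle_grm_counts(strrep("ACGTT", 10), 5, 100), c("5" = 41L))

  # all K-strings unique -> empty diagram
  d <- compute_grm_diagram(
    build_kstring_index(named_sequence("t", "ACGTAGCTTACG"), 6), 100)
  expect_length(d$distances, 0)
})

test_that("diagram equals the brute-force census on mixed random sequences", {
  withr::local_seed(202)
  for (rep in 1:6) {
    s <- switch(1 + rep %% 3,
                random_dna_str(sample(300:2000, 1)),
                random_dna_str(sample(300:2000, 1), alphabet = c("A", "C")),
                paste0(random_dna_str(200),
                       strrep(random_dna_str(sample(40:120, 1)), 8),
                       random_dna_str(200)))
    for (K in c(5, 12)) {
      d <- compute_grm_diagram(build_kstring_index(named_sequence("r", s), K),
                               500)
      expect_equal(diagram_as_named(d), oracle_grm_counts(s, K, 500))
    }
  }
})

test_that("flanking sequence does not perturb repeat recurrences", {
  withr::local_seed(303)
  core <- paste0(random_dna_str(300), strrep(random_dna_str(80), 6),
                 random_dna_str(300))
  flank <- random_dna_str(100)
  d1 <- compute_grm_diagram(build_kstring_index(named_sequence("a", core), 21), 2000)
  d2 <- compute_grm_diagram(
    build_kstring_index(named_sequence("b", paste0(flank, core)), 21), 2000)
  expect_equal(diagram_as_named(d1), diagram_as_named(d2))
})

test_that("perfect tandem with unit-unique K-strings is supported on {L} only", {
  withr::local_seed(404)
  unit <- random_dna_str(200)
  # construction guard: all 21-mers inside one unit period must be unique
  reps <- strrep(unit, 2)
  wins <- substring(reps, 1:200, 1:200 + 20)
  stopifnot(!anyDuplicated(wins))
  d <- compute_grm_diagram(
    build_kstring_index(named_sequence("t", strrep(unit, 6)), 21), 5000)
  expect_equal(d$distances, 200L)
})

test_that("peak detection finds the modal distance with its mass", {
  d <- compute_grm_diagram(
    build_kstring_index(named_sequence("t", strrep("ACGTT", 10)), 5), 100)
  pk <- detect_peaks(d)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$center, 5L)
  expect_equal(pk$mass, 41L)
  expect_true(pk$lo <= pk$center && pk$center <= pk$hi)

  empty <- compute_grm_diagram(
    build_kstring_index(named_sequence("t", "ACGTAGCTTACG"), 6), 100)
  expect_equal(nrow(detect_peaks(empty)), 0)
})

test_that("peak window covers a planted HOR length despite indels", {
  sim <- simulate_genome(hor_sim_params(array_sizes = c(8L, 6L),
                                        flank_length = 1500L,
                                        inter_array_gap = 1500L, seed = 5L))
  d <- compute_grm_diagram(build_kstring_index(sim$seq, 21), 20000)
  pk <- detect_peaks(d, min_mass = 100)
  realized <- mean(sim$truth$copies$end - sim$truth$copies$start)
  expect_gt(nrow(pk), 0)
  expect_true(pk$lo[1] <= realized && realized <= pk$hi[1])
})

test_that("key-string selection maximizes in-window pairs with lexicographic ties", {
  # exact tandem: the unit-phase string has one more pair than other phases
  idx <- build_kstring_index(named_sequence("t", strrep("ACGTT", 10)), 5)
  pk <- detect_peaks(compute_grm_diagram(idx, 100))
  expect_equal(select_key_string(idx, pk[1, ]), "ACGTT")

  # ACGTACGTA: ACGT at {0,4} and CGTA at {1,5} tie with one pair each
  idx2 <- build_kstring_index(named_sequence("t", "ACGTACGTA"), 4)
  expect_equal(select_key_string(idx2, list(lo = 4, hi = 4)), "ACGT")

  idx3 <- build_kstring_index(named_sequence("t", "ACGTTT"), 3)
  expect_error(select_key_string(idx3, list(lo = 2, hi = 2)),
               class = "grm_notfound_error")
})

test_that("segmentation cuts at key-string occurrences and keeps in-window copies", {
  withr::local_seed(505)
  U <- random_dna_str(100)
  key <- substr(U, 1, 20)
  copies <- segment_copies(named_sequence("t", strrep(U, 5)), key,
                           list(center = 100))
  expect_equal(nrow(copies), 4)  # terminal partial fragment discarded
  expect_equal(unique(copies$length), 100L)
  expect_equal(unique(copies$seq), U)
  expect_true(all(diff(copies$start) > 0))
  expect_true(all(copies$start[-1] >= copies$end[-nrow(copies)]))

  expect_error(segment_copies(named_sequence("t", random_dna_str(500)),
                              "ACGTACGTACGTACGTACGT", list(center = 100)),
               class = "grm_notfound_error")
})
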