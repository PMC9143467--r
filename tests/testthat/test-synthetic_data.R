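# The simulator: ground truth, determinism, convergence to closed forms.

test_that("zero branch lengths reproduce the ancestor at every tip", {
  tree <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  sim <- simulate_mitogenomes(sim_params(tree = tree, genome_length = 4000,
                                         seed = 8))
  seqs <- vapply(sim$records, `[[`, character(1), "sequence")
  expect_identical(seqs[["A"]], seqs[["B"]])
  expect_identical(seqs[["A"]], seqs[["C"]])
})

test_that("a fixed seed fixes the emitted files bit-for-bit", {
  p <- sim_params(n_taxa = 3, genome_length = 4000, seed = 123)
  f1 <- withr::local_tempfile(fileext = ".gb")
  f2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(simulate_mitogenomes(p)$records, f1)
  write_genbank(simulate_mitogenomes(p)$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed changes the sequences
  p2 <- sim_params(n_taxa = 3, genome_length = 4000, seed = 124)
  s1 <- simulate_mitogenomes(p)$records[[1]]$sequence
  s2 <- simulate_mitogenomes(p2)$records[[1]]$sequence
  expect_false(identical(s1, s2))
})

test_that("simulate does not disturb the caller's RNG stream", {
  set.seed(500)
  before <- runif(1)
  set.seed(500)
  invisible(simulate_mitogenomes(sim_params(n_taxa = 2, genome_length = 4000,
                                            seed = 9)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("records carry the canonical census and stored base counts", {
  sim <- simulate_mitogenomes(sim_params(n_taxa = 2, seed = 4))
  for (r in sim$records) {
    expect_silent(validate_mito_record(r, complete = TRUE))
    expect_identical(sim$truth$base_counts[[r$id]], base_counts(r$sequence))
  }
})

test_that("expected_p_distance matches its closed forms", {
  expect_identical(expected_p_distance(0), 0)
  # saturation limit under JC is 3/4
  expect_equal(expected_p_distance(1e6), 0.75)
  # direct evaluation of 3/4 (1 - exp(-4 d / 3)) at d = 0.10
  expect_equal(expected_p_distance(0.10), 0.75 * (1 - exp(-0.4 / 3)))
  expect_equal(expected_p_distance(0.10), 0.09362001, tolerance = 1e-6)
  # HKY with uniform frequencies and kappa 1 collapses to JC
  pi <- c(A = .25, C = .25, G = .25, T = .25)
  expect_equal(expected_p_distance(0.3, "hky", pi = pi, kappa = 1),
               expected_p_distance(0.3), tolerance = 1e-12)
})

test_that("realized p-distance converges to the expectation with length", {
  tree <- ape::read.tree(text = "(A:0.06,B:0.06);")
  for (L in c(4000, 8000, 16000)) {
    sim <- simulate_mitogenomes(sim_params(tree = tree, genome_length = L,
                                           seed = 60 + L %/% 1000))
    aln <- vapply(sim$records, `[[`, character(1), "sequence")
    realized <- p_distance(aln[["A"]], aln[["B"]])
    expected <- sim$truth$expected_p$d["A", "B"]
    n <- nchar(aln[[1]])
    expect_lt(abs(realized - expected), 5 * sqrt(expected * (1 - expected) / n))
  }
})

test_that("third positions diverge faster than first/second positions", {
  tree <- ape::read.tree(text = "(A:0.15,B:0.15);")
  sim <- simulate_mitogenomes(sim_params(tree = tree, seed = 71))
  sm12 <- build_pcg12(sim$records, positions = c(1, 2))
  sm3 <- build_pcg12(sim$records, positions = 3)
  p12 <- p_distance(sm12$alignment[["A"]], sm12$alignment[["B"]])
  p3 <- p_distance(sm3$alignment[["A"]], sm3$alignment[["B"]])
  expect_gt(p3, p12)
})

test_that("contradictory parameters are rejected", {
  expect_error(sim_params(at_target = 0), "at_target")
  expect_error(sim_params(rate_multipliers = c(1, 0, 5)))
  expect_error(sim_params(skew_targets = c(at = -1.5, gc = 0)), "skew")
})

test_that("skew targets are approximated on the written strand", {
  sim <- simulate_mitogenomes(sim_params(n_taxa = 2, seed = 85))
  cc <- base_counts(sim$records[[1]]$sequence)
  expect_lt(abs(at_skew(cc) - (-0.083)), 0.03)
  expect_lt(abs(gc_skew(cc) - (-0.208)), 0.05)
})
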