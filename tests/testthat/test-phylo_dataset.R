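# PCG12 supermatrix construction and the NJ tree surface.

test_that("position filtering keeps the right columns", {
  blk <- list(g1 = c(a = "123456789", b = "987654321"))
  # columns 1,2,4,5,7,8 survive a {1,2} filter of a 9-column block
  sm <- build_pcg12(blk, positions = c(1, 2), genes = "g1")
  expect_identical(sm$alignment[["a"]], "124578")
  expect_identical(sm$alignment[["b"]], "986532")
  expect_identical(sm$partition$end, 6L)
})

test_that("concatenation lengths and partition table are additive", {
  blk <- list(
    ND2 = c(a = strrep("ACT", 300), b = strrep("ACT", 300)),
    COI = c(a = strrep("GGA", 150), b = strrep("GGA", 150)))
  sm <- build_pcg12(blk, positions = c(1, 2))
  expect_identical(nchar(sm$alignment[["a"]]), 900L)
  expect_identical(sm$partition$start, c(1L, 601L))
  expect_identical(sm$partition$end, c(600L, 900L))
  # canonical gene order: ND2 before COI regardless of list order
  expect_identical(sm$partition$gene, c("ND2", "COI"))
})

test_that("positions {1,2,3} is the identity on concatenation content", {
  blk <- list(ND2 = c(a = "ATGAAATAA", b = "ATGCCCTAA"))
  sm <- build_pcg12(blk, positions = 1:3)
  expect_identical(sm$alignment[["a"]], "ATGAAATAA")
})

test_that("missing taxa are gap-padded with a warning, bad frames error", {
  blk <- list(ND2 = c(a = "ATGTAA", b = "ATGTAA"), COI = c(a = "ATGTAA"))
  expect_warning(sm <- build_pcg12(blk, positions = 1:3), "padded with gaps")
  expect_identical(sm$alignment[["b"]], "ATGTAA------")
  expect_error(build_pcg12(list(ND2 = c(a = "ATGA", b = "ATGA"))),
               "divisible by 3")
})

test_that("PCG12 distances fall below PCG123 under third-position saturation", {
  sim <- simulate_mitogenomes(sim_params(n_taxa = 4, seed = 47))
  sm12 <- build_pcg12(sim$records, positions = c(1, 2))
  sm123 <- build_pcg12(sim$records, positions = 1:3)
  d12 <- summary(distance_matrix(sm12$alignment))$mean
  d123 <- summary(distance_matrix(sm123$alignment))$mean
  expect_lt(d12, d123)
})

test_that("supermatrix writers emit PHYLIP, FASTA and partition files", {
  blk <- list(ND2 = c(a = "ATGTAA", b = "ATGTAA"))
  sm <- build_pcg12(blk, positions = 1:3)
  phy <- withr::local_tempfile(fileext = ".phy")
  prt <- withr::local_tempfile(fileext = ".txt")
  write_phylip(sm, phy)
  write_partitions(sm, prt)
  expect_identical(readLines(phy)[1], "2 6")
  expect_identical(readLines(prt), "DNA, ND2 = 1-6")
})

test_that("3-taxon NJ solves the three-point equations exactly", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3)
  m <- gendist(c("a", "b", "c"), d)
  tr <- nj_tree(m)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], 2)
  expect_equal(bl[["b"]], 3)
  expect_equal(bl[["c"]], 7)
  expect_error(nj_tree(gendist(c("a", "b"), matrix(0, 2, 2))), "at least 3")
})

test_that("NJ exactly recovers random additive trees up to n = 12", {
  set.seed(2024)
  for (n in c(5, 8, 12)) {
    for (rep in 1:5) {
      tr <- random_bl_tree(n)
      d <- ape::cophenetic.phylo(tr)
      m <- gendist(rownames(d), d)
      est <- nj_tree(m)
      expect_true(same_topology(tr, est))
      # branch lengths: compare induced path distances
      d_est <- ape::cophenetic.phylo(est)[rownames(d), colnames(d)]
      expect_equal(d_est, d, tolerance = 1e-8)
    }
  }
})

test_that("NJ on the fixture puts QY outside the (CN,TL)+HM067837 group", {
  m <- vietnamella_distances()
  keep <- c("CN", "TL", "HM067837", "QY")
  sub <- gendist(keep, m$d[keep, keep])
  tr <- nj_tree(sub)
  expect_true(clade_check(tr, c("CN", "TL")))
  expect_true(clade_check(tr, c("CN", "TL", "HM067837")))
  expect_false(clade_check(tr, c("CN", "QY")))
})

test_that("clade_check handles trivial and unknown groups", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_true(clade_check(tr, "a"))
  expect_true(clade_check(tr, c("a", "b", "c", "d")))
  expect_true(clade_check(tr, c("a", "b")))
  expect_true(clade_check(tr, c("c", "d")))
  # {a, c} is no side of any edge
  expect_false(clade_check(tr, c("a", "c")))
  expect_error(clade_check(tr, "zz"), "unknown label")
})

test_that("Newick write -> read -> write is idempotent", {
  tr <- nj_tree(vietnamella_distances())
  s1 <- ape::write.tree(tr)
  s2 <- ape::write.tree(ape::read.tree(text = s1))
  expect_identical(s1, s2)
})
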