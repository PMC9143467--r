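# Codon counting, RSCU, start/stop classification, translation.

test_that("codon_counts reads in frame, drops partial codons, buckets N", {
  cc <- codon_counts("ATGAAATAA")
  expect_identical(cc[["ATG"]], 1L)
  expect_identical(cc[["AAA"]], 1L)
  expect_identical(cc[["TAA"]], 1L)
  expect_identical(attr(cc, "stop_counts")[["TAA"]], 1L)
  expect_identical(sum(cc), 3L)
  # trailing partial codon dropped; N-codons bucketed
  cc2 <- codon_counts("ATGAANTA")
  expect_identical(sum(cc2), 1L)
  expect_identical(attr(cc2, "ambiguous"), 1L)
})

test_that("codon_counts is additive over sequence splits and order-invariant", {
  a <- codon_counts(c("ATGAAA", "TAA"))
  b <- codon_counts(c("TAA", "ATGAAA"))
  expect_identical(as.integer(a), as.integer(b))
  joint <- codon_counts(c("ATGAAA"))
  expect_identical(as.integer(a),
                   as.integer(joint + codon_counts("TAA")))
})

test_that("RSCU matches the defining formula on hand-built families", {
  # two-codon family Phe (TTT/TTC) with counts (3, 1) -> 1.5, 0.5
  counts <- setNames(rep(0L, 64), names(invert_mito_code()))
  counts[c("TTT", "TTC")] <- c(3L, 1L)
  tab <- rscu(counts)
  expect_equal(tab$rscu[tab$codon == "TTT"], 1.5)
  expect_equal(tab$rscu[tab$codon == "TTC"], 0.5)
  # Leu is a 6-codon family: everything on TTA -> RSCU 6 there, 0 elsewhere
  counts[] <- 0L
  counts["TTA"] <- 10L
  tab <- rscu(counts)
  leu <- tab[tab$amino_acid == "L", ]
  expect_identical(nrow(leu), 6L)
  expect_equal(leu$rscu[leu$codon == "TTA"], 6)
  expect_equal(sum(leu$rscu), 6)
  # unobserved families are NA, not zero
  expect_true(all(is.na(tab$rscu[tab$amino_acid == "G"])))
})

test_that("RSCU family sums equal family sizes on random codon tables", {
  set.seed(77)
  code <- invert_mito_code()
  for (i in 1:25) {
    counts <- setNames(as.integer(rpois(64, 5)), names(code))
    tab <- rscu(counts)
    for (aa in unique(tab$amino_acid)) {
      fam <- tab[tab$amino_acid == aa, ]
      if (sum(fam$count) > 0) {
        expect_equal(sum(fam$rscu), nrow(fam))
      }
    }
  }
})

test_that("uniform counts within every family give RSCU 1 everywhere", {
  counts <- setNames(rep(2L, 64), names(invert_mito_code()))
  tab <- rscu(counts)
  expect_true(all(abs(tab$rscu - 1) < 1e-12))
})

test_that("start/stop classification covers canonical, incomplete, odd cases", {
  s <- classify_start_stop("ATGAAATAA")
  expect_identical(s$start_codon, "ATG")
  expect_true(s$start_canonical)
  expect_identical(s$stop_codon, "TAA")
  expect_identical(s$stop_type, "complete")

  # length = 1 mod 3 ending in T -> incomplete stop "T"
  s <- classify_start_stop("ATGAAAT")
  expect_identical(s$stop_codon, "T")
  expect_identical(s$stop_type, "incomplete")

  s <- classify_start_stop("ATGAAATA")
  expect_identical(s$stop_codon, "TA")
  expect_identical(s$stop_type, "incomplete")

  s <- classify_start_stop("GTGAAATAG")
  expect_false(s$start_canonical)
  expect_identical(s$stop_type, "complete")

  expect_error(classify_start_stop("ATGA"), "shorter")
})

test_that("translation uses the invertebrate mitochondrial code", {
  expect_identical(translate_mito("ATGTGA"), "MW")   # TGA = Trp
  expect_identical(translate_mito("AGAAGG"), "SS")   # AGR = Ser
  expect_identical(translate_mito("ATATAA"), "M*")   # ATA = Met
  expect_warning(translate_mito("ATGTAAAAA"), "internal stop")
})

test_that("translation agrees with the Biostrings table on random CDSs", {
  # independent oracle: NCBI transl_table 5 as shipped by Biostrings
  code5 <- Biostrings::getGeneticCode("5")
  set.seed(11)
  for (i in 1:10) {
    cds <- random_dna(90)
    codons <- substring(cds, seq(1, 88, 3), seq(3, 90, 3))
    want <- paste(code5[codons], collapse = "")
    expect_identical(suppressWarnings(translate_mito(cds)), want)
  }
})

test_that("simulator CDSs translate without internal stops", {
  sim <- simulate_mitogenomes(sim_params(n_taxa = 3, seed = 3))
  for (r in sim$records) {
    seqs <- lapply(PCG_genes <- r$features$name[r$features$kind == "PCG"],
                   function(g) extract_feature_seq(r, g))
    for (s in seqs) {
      expect_no_warning(translate_mito(s))
    }
  }
})

test_that("AT-rich simulation favours A/T-ending codons within families", {
  sim <- simulate_mitogenomes(sim_params(n_taxa = 2, seed = 13))
  r <- sim$records[[1]]
  seqs <- vapply(r$features$name[r$features$kind == "PCG"],
                 function(g) extract_feature_seq(r, g), character(1))
  tab <- rscu(codon_counts(seqs))
  third <- substr(tab$codon, 3, 3)
  observed <- !is.na(tab$rscu)
  expect_gt(sum(tab$count[observed & third %in% c("A", "T")]),
            sum(tab$count[observed & third %in% c("G", "C")]))
})

test_that("codon signatures of simulated records honour the stated world", {
  sim <- simulate_mitogenomes(sim_params(n_taxa = 3, seed = 19))
  for (r in sim$records) {
    sig <- codon_signatures(r)
    expect_identical(nrow(sig), 13L)
    expect_true(all(sig$start_canonical))
    inc <- sig$gene[sig$stop_type == "incomplete"]
    expect_setequal(inc, c("COII", "ND5", "CytB"))
    expect_true(all(sig$stop_type[!sig$gene %in% inc] == "complete"))
  }
})
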