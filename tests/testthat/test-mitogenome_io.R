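# Record model and GenBank / FASTA+table I/O.

test_that("extract_feature_seq returns sense sequences on both strands", {
  r <- mito_record("x", "AAACCC",
                   rbind(gene_features("h", "tRNA", 1, 3, "H"),
                         gene_features("l", "tRNA", 1, 3, "L")))
  expect_identical(extract_feature_seq(r, "h"), "AAA")
  expect_identical(extract_feature_seq(r, "l"), "TTT")
  # involution: sense of an L feature is the reverse complement of the slice
  expect_identical(revcomp(extract_feature_seq(r, "l")), "AAA")
})

test_that("wrap-around features concatenate segments before orientation", {
  # circular gene spanning the origin: written segments [9,10] then [1,2]
  r <- mito_record("x", "ACGTACGTTG",
                   gene_features("w", "tRNA", c(9, 1), c(10, 2), "H",
                                 segment = c(1, 2)))
  expect_identical(extract_feature_seq(r, "w"), "TGAC")
  rl <- mito_record("x", "ACGTACGTTG",
                    gene_features("w", "tRNA", c(9, 1), c(10, 2), "L",
                                  segment = c(1, 2)))
  expect_identical(extract_feature_seq(rl, "w"), revcomp("TGAC"))
})

test_that("record validation rejects bad coordinates, letters and frames", {
  expect_error(mito_record("x", "AAXA"), "outside")
  expect_error(mito_record("x", "AAAA", gene_features("g", "tRNA", 1, 9, "H")),
               "outside sequence")
  expect_error(mito_record("x", strrep("A", 12),
                           gene_features("g", "PCG", 1, 5, "H")),
               "divisible by 3")
  # remainder is legal with the incomplete-stop flag
  expect_s3_class(mito_record("x", strrep("A", 12),
                              gene_features("g", "PCG", 1, 7, "H",
                                            incomplete_stop = TRUE)),
                  "mito_record")
})

test_that("a record with zero features is valid for whole-genome stats only", {
  r <- mito_record("bare", "ACGTACGT")
  expect_identical(nrow(r$features), 0L)
  expect_identical(region_stats(r, "whole_genome")$length, 8L)
  expect_error(region_stats(r, "PCG", "+"), "no PCG feature")
})

test_that("GenBank write -> read is the identity on the record model", {
  set.seed(42)
  sim <- simulate_mitogenomes(sim_params(n_taxa = 3, genome_length = 5000,
                                         seed = 5))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$records, path)
  back <- read_genbank(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$id, sim$records[[i]]$id)
    expect_identical(back[[i]]$sequence, sim$records[[i]]$sequence)
    expect_true(back[[i]]$circular)
    a <- sim$records[[i]]$features[order(sim$records[[i]]$features$start), ]
    b <- back[[i]]$features[order(back[[i]]$features$start), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b, a)
  }
})

test_that("GenBank reader handles complement/join locations and name dialects", {
  gb <- c(
    "LOCUS       TESTREC                60 bp    DNA     circular INV 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             complement(1..15)",
    "                     /gene=\"NAD2\"",
    "     tRNA            join(55..60,1..3)",
    "                     /product=\"tRNA-Trp\"",
    "     rRNA            20..40",
    "                     /product=\"16S ribosomal RNA\"",
    "     D-loop          41..54",
    "ORIGIN",
    paste0("        1 ", tolower(paste(rep("acgtacgtac", 6), collapse = " "))),
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  rec <- read_genbank(path)[[1]]
  expect_identical(rec$id, "TESTREC")
  f <- rec$features
  expect_setequal(f$name, c("ND2", "trnW", "16S", "CR"))
  expect_identical(f$strand[f$name == "ND2"], "L")
  expect_identical(sort(f$segment[f$name == "trnW"]), c(1L, 2L))
  expect_identical(f$kind[f$name == "CR"], "control_region")
})

test_that("unknown gene labels warn but are kept", {
  expect_warning(out <- normalize_gene_name("ORF-foo"), "unknown gene label")
  expect_identical(out, "ORF-foo")
})

test_that("FASTA + feature table round trip matches the record model", {
  r <- toy_record()
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fasta(setNames(r$sequence, r$id), fa)
  write_feature_table(r, tsv)
  back <- read_fasta_records(fa, tsv)[[1]]
  expect_identical(back$sequence, r$sequence)
  expect_equal(back$features$name, r$features$name)
  expect_equal(back$features$start, r$features$start)
  expect_equal(back$features$strand, r$features$strand)
})

test_that("intergenic lengths are the gaps between consecutive features", {
  r <- toy_record()  # features end at 15 and 21-30 on a 60 bp circle
  g <- intergenic_lengths(r)
  expect_identical(g$ign[g$after == "toyP"], 5L)          # 16..20
  expect_identical(g$ign[g$after == "toyT"], 30L + 0L)    # 31..60 wraps to 1
  # simulated spacers are 0-5 bp between linear neighbours
  sim <- simulate_mitogenomes(sim_params(n_taxa = 2, genome_length = 5000,
                                         seed = 15))
  g2 <- intergenic_lengths(sim$records[[1]])
  linear <- head(g2$ign, -1)
  expect_true(all(linear >= 0 & linear <= 5))
})

test_that("summed PCG feature length equals the PCG region length", {
  sim <- simulate_mitogenomes(sim_params(n_taxa = 3, genome_length = 6000,
                                         seed = 9))
  r <- sim$records[[1]]
  f <- r$features[r$features$kind == "PCG", ]
  total <- sum(f$end - f$start + 1L)
  both <- region_stats(r, "PCG", "both")
  expect_identical(both$length, as.integer(total))
  plus <- region_stats(r, "PCG", "+")$length
  minus <- region_stats(r, "PCG", "-")$length
  expect_identical(plus + minus, as.integer(total))
})
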