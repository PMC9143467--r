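# Shared fixtures, all built in code.

# A tiny hand-checkable record: 60 bp, one H-strand "PCG" (toy), one
# L-strand tRNA, the rest spacer.
#   positions 1-15:  PCG  ATG AAA CCC GGA TAA  (H)
#   positions 21-30: tRNA (L)
#   rest: filler
toy_record <- function() {
  seq <- paste0("ATGAAACCCGGATAA",      # 1-15 CDS
                "TTTTT",                # 16-20
                "ACGTACGTAC",           # 21-30 tRNA (L strand)
                strrep("AT", 15))       # 31-60
  feats <- rbind(
    gene_features("toyP", "PCG", 1, 15, "H"),
    gene_features("toyT", "tRNA", 21, 30, "L", anticodon = "GAT"))
  mito_record("toy", seq, feats)
}

random_dna <- function(n, freqs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

# random rooted tree with branch lengths bounded away from ties
random_bl_tree <- function(n, min_bl = 0.02, max_bl = 0.3) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, min_bl, max_bl))
  tr
}

# unrooted-split comparison helper
same_topology <- function(t1, t2) {
  isTRUE(all.equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[[1]], 0))
}
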