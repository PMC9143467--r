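# Seeded mitogenome simulator with full ground truth.
#
# An ancestral genome is assembled in the canonical 37-gene insect order
# (trnI-trnQ-trnM-ND2-...-12S-CR) with the composition bias observed in
# AT-rich insect mitogenomes (A+T ~ 70%, negative AT and GC skew on the
# written strand), then evolved along a tree under an HKY substitution
# model whose stationary frequencies are those written-strand frequencies.
# Protein-coding genes get ATN starts, TAA stops (a configurable subset
# carries truncated "T" stops) and are kept free of internal stops by
# reverting stop-creating substitutions. Site rates differ by codon
# position (default 1, 1, 5: saturating third positions); non-coding sites
# evolve at rate 1. No indels are simulated, so emitted genomes are
# trivially aligned and every realized statistic can be compared with its
# closed-form expectation.

#' Simulation parameters
#'
#' @param n_taxa number of genomes (ignored when `tree` is given).
#' @param tree optional rooted `phylo` with branch lengths in expected
#'   substitutions/site (at rate multiplier 1); default is a random tree
#'   with uniform branch lengths in `[0.005, 0.1]`.
#' @param genome_length approximate target genome size in bases (default
#'   15600); gene lengths are scaled proportionally from typical insect
#'   values.
#' @param at_target stationary A+T fraction of the written strand (default
#'   0.705).
#' @param skew_targets named vector `c(at=, gc=)` of target AT and GC skew
#'   on the written strand (defaults -0.083, -0.208).
#' @param rate_multipliers relative substitution rates of codon positions
#'   1-3 in protein-coding genes (default `c(1, 1, 5)`).
#' @param kappa HKY transition/transversion rate ratio (default 4, a
#'   typical insect mitochondrial value).
#' @param species_partition optional named character vector tip label ->
#'   true species.
#' @param incomplete_stop_genes genes given truncated "T" stops (default
#'   COII, ND5, CytB, the set observed in mayfly mitogenomes).
#' @param seed RNG seed; fixes every output bit-for-bit.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_taxa = 6, tree = NULL, genome_length = 15600,
                       at_target = 0.705,
                       skew_targets = c(at = -0.083, gc = -0.208),
                       rate_multipliers = c(1, 1, 5), kappa = 4,
                       species_partition = NULL,
                       incomplete_stop_genes = c("COII", "ND5", "CytB"),
                       seed = 1L) {
  stopifnot(at_target > 0, at_target < 1, all(rate_multipliers > 0),
            kappa > 0, genome_length >= 3000)
  if (any(abs(skew_targets) >= 1)) {
    stop("skew targets must lie in (-1, 1)", call. = FALSE)
  }
  structure(list(n_taxa = n_taxa, tree = tree,
                 genome_length = genome_length, at_target = at_target,
                 skew_targets = skew_targets,
                 rate_multipliers = rate_multipliers, kappa = kappa,
                 species_partition = species_partition,
                 incomplete_stop_genes = incomplete_stop_genes,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Written-strand stationary base frequencies implied by composition targets
#' @noRd
target_freqs <- function(at_target, skew_targets) {
  a <- at_target * (1 + skew_targets[["at"]]) / 2
  t <- at_target * (1 - skew_targets[["at"]]) / 2
  g <- (1 - at_target) * (1 + skew_targets[["gc"]]) / 2
  c <- (1 - at_target) * (1 - skew_targets[["gc"]]) / 2
  c(A = a, C = c, G = g, T = t)
}

#' HKY rate matrix, normalized to 1 expected substitution/site
#' @noRd
hky_matrix <- function(pi, kappa) {
  bases <- c("A", "C", "G", "T")
  pi <- pi[bases]
  q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in bases) for (j in bases) {
    if (i == j) next
    ts <- paste0(i, j) %in% c("AG", "GA", "CT", "TC")
    q[i, j] <- if (ts) kappa * pi[[j]] else pi[[j]]
  }
  diag(q) <- -rowSums(q)
  rate <- -sum(pi * diag(q))
  q / rate
}

#' Transition probability matrix exp(Q t) for a reversible Q
#' @noRd
prob_matrix <- function(q, t) {
  bases <- c("A", "C", "G", "T")
  if (t == 0) {
    return(matrix(diag(4), 4, 4, dimnames = list(bases, bases)))
  }
  e <- eigen(q)
  v <- e$vectors
  p <- Re(v %*% diag(exp(e$values * t)) %*% solve(v))
  p[p < 0] <- 0
  p <- p / rowSums(p)
  dimnames(p) <- list(bases, bases)
  p
}

#' Expected p-distance at a given path length
#'
#' Closed-form expected proportion of differing sites between two sequences
#' separated by `d` expected substitutions/site. Under Jukes-Cantor this is
#' `3/4 * (1 - exp(-4 d / 3))`; under HKY it is computed from the rate
#' matrix exponential as `sum_i pi_i (1 - P_ii(d))` ... with the chain at
#' stationarity, the probability that the two ends of the path differ.
#'
#' @param d path length in expected substitutions/site (`>= 0`), vectorised.
#' @param model `"jc"` (default) or `"hky"`.
#' @param pi stationary frequencies (named A/C/G/T) for `"hky"`.
#' @param kappa transition/transversion ratio for `"hky"`.
#' @return expected differing-site proportion.
#' @export
#' @examples
#' expected_p_distance(0.10)           # 0.0902
expected_p_distance <- function(d, model = c("jc", "hky"), pi = NULL,
                                kappa = 4) {
  model <- match.arg(model)
  stopifnot(all(d >= 0))
  if (model == "jc") {
    return(0.75 * (1 - exp(-4 * d / 3)))
  }
  if (is.null(pi)) stop("pi required for HKY", call. = FALSE)
  q <- hky_matrix(pi, kappa)
  vapply(d, function(t) {
    p <- prob_matrix(q, t)
    sum(pi[c("A", "C", "G", "T")] * (1 - diag(p)))
  }, numeric(1))
}

#' A rooted two-species tree with planted intra/inter divergences
#'
#' Builds a balanced tree of two clades such that every within-species tip
#' pair is separated by path length `intra` and every between-species pair
#' by `inter` (both in expected substitutions/site).
#'
#' @param n_per_species tips per species (default 2).
#' @param intra,inter within- and between-species path lengths.
#' @param labels optional tip labels (default A1..An, B1..Bn).
#' @return list with `tree` (phylo) and `species` (named character vector).
#' @export
two_species_tree <- function(n_per_species = 2, intra = 0.01, inter = 0.15,
                             labels = NULL) {
  stopifnot(inter > intra, intra >= 0)
  labels <- labels %||% c(paste0("A", seq_len(n_per_species)),
                          paste0("B", seq_len(n_per_species)))
  x <- intra / 2
  y <- (inter - intra) / 2
  n <- n_per_species
  a <- labels[seq_len(n)]
  b <- labels[n + seq_len(n)]
  mk <- function(labs) {
    if (length(labs) == 1) sprintf("%s:%.10g", labs[1], x + y)
    else sprintf("(%s):%.10g", paste(sprintf("%s:%.10g", labs, x), collapse = ","), y)
  }
  tree <- ape::read.tree(text = sprintf("(%s,%s);", mk(a), mk(b)))
  species <- setNames(rep(c("spA", "spB"), each = n), labels)
  list(tree = tree, species = species)
}

# ---- ancestral genome -----------------------------------------------------

sample_bases <- function(n, pi) {
  if (n == 0) return(character(0))
  sample(names(pi), n, replace = TRUE, prob = pi)
}

complement_freqs <- function(pi) {
  c(A = pi[["T"]], C = pi[["G"]], G = pi[["C"]], T = pi[["A"]])
}

# sense-strand CDS: ATN start, no internal stops, complete or truncated stop
sample_cds <- function(n_codons, pi_sense, incomplete) {
  third <- sample(c("A", "T", "G", "C"), 1,
                  prob = pi_sense[c("A", "T", "G", "C")])
  start <- paste0("AT", third)
  internals <- character(max(n_codons - 2L, 1L))
  for (k in seq_along(internals)) {
    repeat {
      cod <- paste(sample_bases(3, pi_sense), collapse = "")
      if (!cod %in% MITO_STOPS) break
    }
    internals[k] <- cod
  }
  stop_part <- if (incomplete) "T" else "TAA"
  paste0(start, paste(internals, collapse = ""), stop_part)
}

build_ancestor <- function(params) {
  pi <- target_freqs(params$at_target, params$skew_targets)
  tab <- canonical_gene_table()
  scale <- params$genome_length / sum(tab$ref_len)
  seq_parts <- character(0)
  feat_rows <- list()
  pos <- 1L
  class_parts <- list()  # integer codes: 0 noncoding, 1..3 codon position
  for (i in seq_len(nrow(tab))) {
    g <- tab[i, ]
    # intergenic spacer (0-5 bp) before each gene but the first
    if (i > 1) {
      sp_len <- sample(0:5, 1)
      if (sp_len > 0) {
        seq_parts <- c(seq_parts, paste(sample_bases(sp_len, pi), collapse = ""))
        class_parts[[length(class_parts) + 1L]] <- rep(0L, sp_len)
        pos <- pos + sp_len
      }
    }
    if (g$kind == "PCG") {
      n_codons <- max(round(g$ref_len * scale / 3), 12L)
      incomplete <- g$name %in% params$incomplete_stop_genes
      pi_sense <- if (g$strand == "H") pi else complement_freqs(pi)
      sense <- sample_cds(n_codons, pi_sense, incomplete)
      len <- nchar(sense)
      written <- if (g$strand == "H") sense else revcomp(sense)
      cls <- (seq_len(len) - 1L) %% 3L + 1L     # codon position on sense
      if (g$strand == "L") cls <- rev(cls)      # map to written coordinates
      seq_parts <- c(seq_parts, written)
      class_parts[[length(class_parts) + 1L]] <- cls
      feat_rows[[length(feat_rows) + 1L]] <- gene_features(
        g$name, "PCG", pos, pos + len - 1L, g$strand,
        incomplete_stop = incomplete)
      pos <- pos + len
    } else {
      len <- if (g$name == "CR") {
        max(round(scale * sample(900:1020, 1)), 100L)
      } else {
        max(round(g$ref_len * scale), 40L)
      }
      seq_parts <- c(seq_parts, paste(sample_bases(len, pi), collapse = ""))
      class_parts[[length(class_parts) + 1L]] <- rep(0L, len)
      feat_rows[[length(feat_rows) + 1L]] <- gene_features(
        g$name, g$kind, pos, pos + len - 1L, g$strand,
        anticodon = if (g$kind == "tRNA") g$anticodon else NA_character_)
      pos <- pos + len
    }
  }
  list(sequence = paste(seq_parts, collapse = ""),
       features = do.call(rbind, feat_rows),
       site_class = unlist(class_parts),
       pi = pi)
}

# ---- evolution ------------------------------------------------------------

evolve_sequence <- function(parent_chars, t, site_class, q, rate_multipliers) {
  if (t == 0) return(parent_chars)
  child <- parent_chars
  mults <- c(1, rate_multipliers)  # class 0 -> index 1
  for (cls in sort(unique(site_class))) {
    p <- prob_matrix(q, t * mults[cls + 1L])
    idx <- which(site_class == cls)
    for (b in c("A", "C", "G", "T")) {
      at_b <- idx[parent_chars[idx] == b]
      if (length(at_b) > 0) {
        child[at_b] <- sample(c("A", "C", "G", "T"), length(at_b),
                              replace = TRUE, prob = p[b, ])
      }
    }
  }
  child
}

# purifying selection on reading frames: revert substitutions that create
# in-frame internal stops, and keep start and stop codons intact
fix_internal_stops <- function(child, parent, features) {
  pcg <- features[features$kind == "PCG", , drop = FALSE]
  for (i in seq_len(nrow(pcg))) {
    rng <- pcg$start[i]:pcg$end[i]
    sense_child <- child[rng]
    sense_parent <- parent[rng]
    if (pcg$strand[i] == "L") {
      sense_child <- rev(chartr("ACGT", "TGCA", sense_child))
      sense_parent <- rev(chartr("ACGT", "TGCA", sense_parent))
    }
    n_cod <- length(sense_child) %/% 3L
    last_complete <- if (length(sense_child) %% 3L == 0L) n_cod else n_cod + 1L
    for (k in seq_len(n_cod)) {
      at <- (3L * k - 2L):(3L * k)
      cod <- paste(sense_child[at], collapse = "")
      if (cod %in% MITO_STOPS && k < last_complete) {
        sense_child[at] <- sense_parent[at]
      }
    }
    # starts and stops are under strong selection: revert any change there
    sense_child[1:3] <- sense_parent[1:3]
    rem <- length(sense_child) %% 3L
    stop_at <- if (rem == 0L) {
      (length(sense_child) - 2L):length(sense_child)
    } else {
      (length(sense_child) - rem + 1L):length(sense_child)
    }
    sense_child[stop_at] <- sense_parent[stop_at]
    if (pcg$strand[i] == "L") {
      sense_child <- rev(chartr("ACGT", "TGCA", sense_child))
    }
    child[rng] <- sense_child
  }
  child
}

#' Simulate a set of annotated mitogenomes with ground truth
#'
#' @param params a [sim_params()] object.
#' @return list with `records` (list of `mito_record`, one per tip) and
#'   `truth`: `tree`, `path_length` (pairwise path-length matrix),
#'   `expected_p` (a `gendist` of closed-form expected p-distances,
#'   averaging the codon-position rate classes by their site share),
#'   `species` (named vector or NULL), `base_counts` (per-record tallies at
#'   generation), `pi`, `site_class`, and `params`.
#' @export
#' @examples
#' sim <- simulate_mitogenomes(sim_params(n_taxa = 4, genome_length = 4000,
#'                                        seed = 7))
#' length(sim$records)
simulate_mitogenomes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(params$seed)

  tree <- params$tree %||%
    ape::rtree(params$n_taxa, br = function(n) runif(n, 0.005, 0.1))
  if (is.null(tree$edge.length)) stop("tree needs branch lengths", call. = FALSE)

  anc <- build_ancestor(params)
  q <- hky_matrix(anc$pi, params$kappa)
  anc_chars <- seq_chars(anc$sequence)

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- anc_chars
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  edge_len <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; kid <- edges[e, 2]
    child <- evolve_sequence(seqs[[par]], edge_len[e], anc$site_class, q,
                             params$rate_multipliers)
    child <- fix_internal_stops(child, seqs[[par]], anc$features)
    seqs[[kid]] <- child
  }

  records <- lapply(seq_len(ntip), function(i) {
    mito_record(tree$tip.label[i], paste(seqs[[i]], collapse = ""),
                anc$features, circular = TRUE)
  })
  names(records) <- tree$tip.label

  pl <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  w <- table(factor(anc$site_class, levels = 0:3)) / length(anc$site_class)
  mults <- c(1, params$rate_multipliers)
  exp_p <- pl
  for (i in seq_len(nrow(pl))) for (j in seq_len(ncol(pl))) {
    exp_p[i, j] <- sum(vapply(0:3, function(cls) {
      w[[as.character(cls)]] *
        expected_p_distance(pl[i, j] * mults[cls + 1L], model = "hky",
                            pi = anc$pi, kappa = params$kappa)
    }, numeric(1)))
  }
  truth <- list(tree = tree, path_length = pl,
                expected_p = gendist(tree$tip.label, exp_p, "p"),
                species = params$species_partition,
                base_counts = lapply(records, function(r) base_counts(r$sequence)),
                pi = anc$pi, site_class = anc$site_class, params = params)
  list(records = records, truth = truth)
}
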