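# PCG12 supermatrix construction and a neighbor-joining tree surface.
#
# Third codon positions of mitochondrial protein-coding genes saturate
# quickly; phylogenetic datasets therefore often keep only positions 1-2
# ("PCG12"). build_pcg12() filters per-gene codon-aware alignments to the
# requested positions and concatenates them in the canonical genome order,
# emitting a partition table for downstream partitioned analyses.

#' Build a codon-position-filtered concatenated supermatrix
#'
#' @param blocks either a named list `gene -> named character vector` of
#'   aligned, in-frame sequences (one entry per taxon, equal lengths within
#'   a gene), or a list of `mito_record` whose protein-coding genes are
#'   equal-length across records (as the simulator guarantees; real data
#'   must be aligned externally first).
#' @param positions codon positions to keep, subset of 1:3 (default `c(1,
#'   2)`, the PCG12 dataset).
#' @param genes gene order for the concatenation; defaults to the 13
#'   protein-coding genes in genome order, restricted to those present.
#' @return a `supermatrix` object: `labels`, `alignment` (named character
#'   vector), `positions`, `partition` (data.frame gene/start/end on the
#'   filtered concatenation).
#' @export
build_pcg12 <- function(blocks, positions = c(1, 2), genes = NULL) {
  positions <- sort(unique(as.integer(positions)))
  if (!all(positions %in% 1:3) || length(positions) == 0) {
    stop("positions must be a non-empty subset of 1:3", call. = FALSE)
  }
  if (is.list(blocks) && length(blocks) > 0 && inherits(blocks[[1]], "mito_record")) {
    blocks <- records_to_gene_blocks(blocks)
  }
  genes <- genes %||% intersect(PCG_ORDER, names(blocks))
  missing_genes <- setdiff(genes, names(blocks))
  if (length(missing_genes) > 0) {
    stop("gene block(s) missing: ", paste(missing_genes, collapse = ", "),
         call. = FALSE)
  }
  labels <- sort(unique(unlist(lapply(blocks[genes], names))))
  pieces <- setNames(vector("list", length(genes)), genes)
  for (g in genes) {
    blk <- blocks[[g]]
    len <- unique(nchar(blk))
    if (length(len) != 1) {
      stop(sprintf("gene '%s': unaligned block (unequal lengths)", g),
           call. = FALSE)
    }
    if (len %% 3L != 0L) {
      stop(sprintf("gene '%s': block length %d not divisible by 3", g, len),
           call. = FALSE)
    }
    absent <- setdiff(labels, names(blk))
    if (length(absent) > 0) {
      warning(sprintf("gene '%s': missing for %s; padded with gaps",
                      g, paste(absent, collapse = ", ")), call. = FALSE)
      blk[absent] <- strrep("-", len)
    }
    keep <- which(((seq_len(len) - 1L) %% 3L + 1L) %in% positions)
    pieces[[g]] <- vapply(labels, function(l) {
      paste(seq_chars(blk[[l]])[keep], collapse = "")
    }, character(1))
  }
  widths <- vapply(pieces, function(p) nchar(p[[1]]), integer(1))
  ends <- cumsum(widths)
  partition <- data.frame(gene = genes,
                          start = c(1L, head(ends, -1) + 1L),
                          end = ends, stringsAsFactors = FALSE)
  alignment <- setNames(vapply(labels, function(l) {
    paste(vapply(pieces, `[[`, character(1), l), collapse = "")
  }, character(1)), labels)
  structure(list(labels = labels, alignment = alignment,
                 positions = positions, partition = partition),
            class = "supermatrix")
}

records_to_gene_blocks <- function(records) {
  genes <- PCG_ORDER
  blocks <- setNames(vector("list", length(genes)), genes)
  for (g in genes) {
    seqs <- vapply(records, function(r) {
      f <- r$features[r$features$name == g, , drop = FALSE]
      if (nrow(f) == 0) return(NA_character_)
      s <- extract_feature_seq(r, f)
      # drop a trailing partial codon (incomplete stop) to stay in frame
      substr(s, 1, 3L * (nchar(s) %/% 3L))
    }, character(1))
    names(seqs) <- vapply(records, `[[`, character(1), "id")
    blocks[[g]] <- seqs[!is.na(seqs)]
  }
  blocks[lengths(blocks) > 0]
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, positions {%s}, %d gene(s)\n",
              length(x$labels), nchar(x$alignment[[1]]),
              paste(x$positions, collapse = ","), nrow(x$partition)))
  invisible(x)
}

#' Write a supermatrix as relaxed PHYLIP
#' @param sm a `supermatrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(sm, path) {
  lines <- c(sprintf("%d %d", length(sm$labels), nchar(sm$alignment[[1]])),
             sprintf("%s  %s", sm$labels, sm$alignment))
  writeLines(lines, path)
  invisible(path)
}

#' Write a RAxML-style partition file for a supermatrix
#' @inheritParams write_phylip
#' @export
write_partitions <- function(sm, path) {
  writeLines(sprintf("DNA, %s = %d-%d",
                     sm$partition$gene, sm$partition$start, sm$partition$end),
             path)
  invisible(path)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in Q are
#' broken deterministically by label order (smallest pair first). A
#' negative branch length arising at a join is clamped to zero and its
#' deficit moved to the sibling branch, preserving the pair's summed
#' length.
#'
#' @param m a `gendist` with at least 3 labels and no undefined entries.
#' @return an unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(m) {
  stopifnot(inherits(m, "gendist"))
  if (any(is.na(m$d))) stop("undefined distances in matrix", call. = FALSE)
  n0 <- length(m$labels)
  if (n0 < 3) stop("need at least 3 taxa", call. = FALSE)
  d <- m$d
  # node representations as newick fragments, in current label order
  reps <- m$labels
  repeat {
    n <- nrow(d)
    if (n == 3) break
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # deterministic tie-break: smallest (i, j) in the current ordering
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[[1]]; j <- best[[2]]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_rep <- sprintf("(%s:%.12g,%s:%.12g)", reps[i], bi, reps[j], bj)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    du <- pmax(du[-c(i, j)], 0)
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, du), c(du, 0))
    reps <- c(reps[-c(i, j)], new_rep)
  }
  # resolve the final three nodes with the three-point formulae
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  newick <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                    reps[1], b[1], reps[2], b[2], reps[3], b[3])
  ape::read.tree(text = newick)
}

#' Is a label set a clade on some rooting of the tree?
#'
#' TRUE iff the group forms one side of an edge bipartition of the unrooted
#' tree (so singletons and the full label set are trivially clades).
#'
#' @param tree a `phylo`.
#' @param group character vector of tip labels.
#' @return logical flag.
#' @export
clade_check <- function(tree, group) {
  tips <- tree$tip.label
  unknown <- setdiff(group, tips)
  if (length(unknown) > 0) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  group <- unique(group)
  # trivial splits: singletons, the full set, and complements of a tip
  # (every tip edge induces the bipartition {tip} | rest)
  if (length(group) %in% c(1L, length(tips) - 1L, length(tips))) return(TRUE)
  splits <- tree_bipartitions(tree)
  target <- sort(group)
  other <- sort(setdiff(tips, group))
  any(vapply(splits, function(s) identical(s, target) || identical(s, other),
             logical(1)))
}

tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- unique(tree$edge[, 2][tree$edge[, 2] > ntip])
  lapply(internal, function(node) {
    sort(tree$tip.label[descendant_tips(tree, node)])
  })
}

descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    cur <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}
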