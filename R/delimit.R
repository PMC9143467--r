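# Threshold-based species delimitation: single-linkage clusters at a
# conspecific threshold t_intra, i.e. the connected components of the graph
# whose edges join pairs with d < t_intra. A pair split across clusters is
# a cryptic candidate only when the two records share a morphospecies label
# (cryptic = morphologically identical + genetically divergent); without
# morphology metadata, cross-cluster pairs are just "distinct".

#' Single-linkage species delimitation at a distance threshold
#'
#' @param m a `gendist` distance matrix.
#' @param t_intra conspecific threshold on the proportion scale, in (0, 1).
#'   The default 0.07 is the upper bound of the 1-7% intraspecific band
#'   typically reported for insect mitogenomes.
#' @param morphospecies optional morphology-based species assignment: a
#'   named character vector (names = labels) or a data.frame with columns
#'   `label` and `morphospecies`.
#' @return a `delimitation` object: `clusters` (list of label vectors, in
#'   order of first appearance), `membership` (named integer vector),
#'   `flags` (data.frame of all pairs with `a`, `b`, `distance`, `flag` in
#'   {conspecific, cryptic_candidate, distinct}), `t_intra`, and `evidence`
#'   (`within`: per-cluster maximum within-distance; `between`: per
#'   cluster-pair minimum between-distance).
#' @export
#' @examples
#' m <- vietnamella_distances()
#' delimit(m, 0.07, morphospecies = vietnamella_metadata())
delimit <- function(m, t_intra = 0.07, morphospecies = NULL) {
  stopifnot(inherits(m, "gendist"))
  if (!(t_intra > 0 && t_intra < 1)) stop("t_intra must be in (0, 1)", call. = FALSE)
  if (any(is.na(m$d))) {
    idx <- which(is.na(m$d) & upper.tri(m$d), arr.ind = TRUE)
    stop("undefined distances for pair(s): ",
         paste(sprintf("%s-%s", m$labels[idx[, 1]], m$labels[idx[, 2]]),
               collapse = ", "), call. = FALSE)
  }
  n <- length(m$labels)
  # union-find over edges d < t_intra
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (m$d[i, j] < t_intra) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cluster_ids <- match(roots, unique(roots))
  membership <- setNames(cluster_ids, m$labels)
  clusters <- split(m$labels, cluster_ids)
  names(clusters) <- paste0("C", seq_along(clusters))

  sp <- normalize_morphospecies(morphospecies, m$labels)
  fl <- pairs_of(m)
  same_cluster <- membership[fl$a] == membership[fl$b]
  same_morpho <- !is.na(sp[fl$a]) & !is.na(sp[fl$b]) & sp[fl$a] == sp[fl$b]
  fl$flag <- ifelse(same_cluster, "conspecific",
                    ifelse(same_morpho, "cryptic_candidate", "distinct"))

  within <- data.frame(cluster = names(clusters),
                       size = lengths(clusters),
                       max_within = vapply(clusters, function(cl) {
                         if (length(cl) < 2) return(NA_real_)
                         max(m$d[cl, cl])
                       }, numeric(1)),
                       row.names = NULL, stringsAsFactors = FALSE)
  between <- NULL
  if (length(clusters) > 1) {
    cmb <- utils::combn(names(clusters), 2)
    between <- data.frame(
      cluster_a = cmb[1, ], cluster_b = cmb[2, ],
      min_between = apply(cmb, 2, function(p) {
        min(m$d[clusters[[p[1]]], clusters[[p[2]]]])
      }),
      stringsAsFactors = FALSE)
  }
  structure(list(clusters = clusters, membership = membership, flags = fl,
                 t_intra = t_intra, morphospecies = sp,
                 evidence = list(within = within, between = between)),
            class = "delimitation")
}

normalize_morphospecies <- function(morphospecies, labels) {
  if (is.null(morphospecies)) {
    return(setNames(rep(NA_character_, length(labels)), labels))
  }
  if (is.data.frame(morphospecies)) {
    morphospecies <- setNames(morphospecies$morphospecies, morphospecies$label)
  }
  out <- setNames(rep(NA_character_, length(labels)), labels)
  hit <- intersect(labels, names(morphospecies))
  out[hit] <- morphospecies[hit]
  out
}

#' @export
print.delimitation <- function(x, ...) {
  cat(sprintf("<delimitation> t_intra = %g, %d cluster(s)\n",
              x$t_intra, length(x$clusters)))
  for (nm in names(x$clusters)) {
    cat(sprintf("  %s: %s\n", nm, paste(x$clusters[[nm]], collapse = ", ")))
  }
  cc <- x$flags[x$flags$flag == "cryptic_candidate", , drop = FALSE]
  if (nrow(cc) > 0) {
    cat("cryptic candidate pair(s):\n")
    for (i in seq_len(nrow(cc))) {
      cat(sprintf("  %s - %s (d = %.3f)\n", cc$a[i], cc$b[i], cc$distance[i]))
    }
  }
  invisible(x)
}

#' The cluster of a delimitation result containing a given label
#' @param res a `delimitation`.
#' @param label a record label.
#' @return character vector of cluster members.
#' @export
cluster_containing <- function(res, label) {
  if (!label %in% names(res$membership)) {
    stop("unknown label: ", label, call. = FALSE)
  }
  res$clusters[[res$membership[[label]]]]
}

#' One-line verdict per morphospecies group
#'
#' A morphospecies whose records fall into more than one cluster contains
#' cryptic-species candidates; the verdict names the outlier cluster(s) and
#' the minimum distance separating them from the largest cluster.
#'
#' @param res a `delimitation` with morphospecies metadata.
#' @param m the `gendist` the result was computed from.
#' @return data.frame with columns `morphospecies`, `n_records`,
#'   `n_clusters`, `verdict`.
#' @export
delimit_verdicts <- function(res, m) {
  sp <- res$morphospecies
  sp <- sp[!is.na(sp)]
  if (length(sp) == 0) {
    return(data.frame(morphospecies = character(), n_records = integer(),
                      n_clusters = integer(), verdict = character()))
  }
  do.call(rbind, lapply(split(names(sp), sp), function(labs) {
    cl <- unique(res$membership[labs])
    verdict <- if (length(cl) == 1) {
      "single cluster: conspecific at t_intra"
    } else {
      sizes <- table(res$membership[labs])
      main <- names(sizes)[which.max(sizes)]
      main_labs <- intersect(labs, names(res$membership)[res$membership == as.integer(main)])
      outliers <- setdiff(labs, main_labs)
      dmin <- min(m$d[outliers, main_labs, drop = FALSE])
      sprintf("cryptic candidate(s) %s: min distance %.3f to main cluster {%s}",
              paste(outliers, collapse = ","), dmin,
              paste(main_labs, collapse = ","))
    }
    data.frame(morphospecies = sp[[labs[1]]], n_records = length(labs),
               n_clusters = length(cl), verdict = verdict,
               stringsAsFactors = FALSE)
  }))
}

#' Write a delimitation result as JSON
#'
#' @param res a `delimitation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_delimitation_json <- function(res, path) {
  payload <- list(
    t_intra = res$t_intra,
    clusters = res$clusters,
    flags = res$flags,
    evidence = list(within = res$evidence$within,
                    between = res$evidence$between))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the pair flags of a delimitation result as TSV
#' @inheritParams write_delimitation_json
#' @export
write_delimitation_tsv <- function(res, path) {
  write.table(res$flags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
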