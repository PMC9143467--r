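# Pairwise genetic distances on aligned sequences. Default model is the
# uncorrected proportion of differing sites (p-distance) with pairwise
# deletion: a site enters the comparison only when both sequences carry an
# unambiguous base (A/C/G/T); gaps and N are deleted per pair. K2P is
# provided as a sensitivity model.

UNAMBIG <- c("A", "C", "G", "T")
TRANSITIONS <- c("AG", "GA", "CT", "TC")

site_classes <- function(a, b) {
  ca <- seq_chars(toupper(a))
  cb <- seq_chars(toupper(b))
  if (length(ca) != length(cb)) {
    stop("aligned sequences differ in length", call. = FALSE)
  }
  ok <- ca %in% UNAMBIG & cb %in% UNAMBIG
  list(a = ca[ok], b = cb[ok], n = sum(ok))
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among sites where both sequences have an
#' unambiguous base (pairwise deletion of gaps and N).
#'
#' @param a,b aligned DNA strings of equal length (`-` and `N` allowed).
#' @return proportion in `[0, 1]`; `NA` when no comparable sites remain.
#' @export
#' @examples
#' p_distance("AA-A", "AATA")   # 1/3: three comparable sites, one differs
p_distance <- function(a, b) {
  s <- site_classes(a, b)
  if (s$n == 0) return(NA_real_)
  sum(s$a != s$b) / s$n
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' With P the transition and Q the transversion fraction over comparable
#' sites, `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`. Returns `NA` when
#' a log argument is non-positive (saturation) or no sites are comparable.
#'
#' @inheritParams p_distance
#' @return distance in substitutions/site; `NA` on saturation.
#' @export
k2p_distance <- function(a, b) {
  s <- site_classes(a, b)
  if (s$n == 0) return(NA_real_)
  diff <- s$a != s$b
  ts <- sum(diff & paste0(s$a, s$b) %in% TRANSITIONS)
  P <- ts / s$n
  Q <- (sum(diff) - ts) / s$n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1 * sqrt(arg2))
}

#' Pairwise distance matrix over a labelled alignment
#'
#' @param alignment named character vector of aligned sequences (equal
#'   lengths), e.g. from [read_fasta()].
#' @param model `"p"` (default) or `"k2p"`.
#' @return a `gendist` object: `labels`, symmetric matrix `d` with zero
#'   diagonal, and `model`.
#' @export
distance_matrix <- function(alignment, model = c("p", "k2p")) {
  model <- match.arg(model)
  labels <- names(alignment)
  if (is.null(labels) || any(labels == "")) {
    stop("alignment sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(alignment) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (length(unique(nchar(alignment))) != 1) {
    stop("aligned sequences differ in length", call. = FALSE)
  }
  fn <- if (model == "p") p_distance else k2p_distance
  n <- length(alignment)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- fn(alignment[[i]], alignment[[j]])
    }
  }
  gendist(labels, d, model)
}

#' Construct a `gendist` distance-matrix object
#'
#' @param labels ordered record ids.
#' @param d symmetric numeric matrix (proportion scale for model `"p"`).
#' @param model `"p"` or `"k2p"`.
#' @return a `gendist` object.
#' @export
gendist <- function(labels, d, model = "p") {
  stopifnot(nrow(d) == length(labels), ncol(d) == length(labels))
  dimnames(d) <- list(labels, labels)
  if (any(!is.na(d) & d < 0)) stop("negative distances", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-12, na.rm = TRUE)) {
    stop("distance matrix not symmetric", call. = FALSE)
  }
  structure(list(labels = labels, d = d, model = model), class = "gendist")
}

#' @export
as.matrix.gendist <- function(x, ...) x$d

#' @export
print.gendist <- function(x, ...) {
  cat(sprintf("<gendist> %d taxa, model %s\n", length(x$labels), x$model))
  print(round(x$d, 4))
  invisible(x)
}

#' Summary statistics of the off-diagonal distances
#'
#' @param object a `gendist`.
#' @param ... unused.
#' @return list with `n_pairs`, `min`, `max`, `mean` over the unique
#'   unordered pairs.
#' @export
summary.gendist <- function(object, ...) {
  v <- object$d[lower.tri(object$d)]
  list(n_pairs = length(v), min = min(v), max = max(v), mean = mean(v))
}

pairs_of <- function(m) {
  idx <- which(lower.tri(m$d), arr.ind = TRUE)
  data.frame(a = m$labels[idx[, 2]], b = m$labels[idx[, 1]],
             distance = m$d[idx], stringsAsFactors = FALSE)
}

#' Write a distance matrix as a square TSV
#' @param m a `gendist`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(m, path) {
  df <- data.frame(label = m$labels, m$d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix as lower-triangle text
#'
#' MEGA-style layout: a header line with the taxon count and model, then one
#' row per taxon with its label and the distances to the preceding taxa.
#'
#' @inheritParams write_distance_tsv
#' @param digits decimals printed (default 3, the resolution of published
#'   whole-mitogenome distance tables).
#' @export
write_distance_lower <- function(m, path, digits = 3) {
  n <- length(m$labels)
  lines <- c(sprintf("# %d taxa, model %s, lower triangle", n, m$model))
  for (i in seq_len(n)) {
    vals <- if (i == 1) "" else
      paste(formatC(m$d[i, seq_len(i - 1)], digits = digits, format = "f"),
            collapse = "\t")
    lines <- c(lines, paste(m$labels[i], vals, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a lower-triangle distance file written by [write_distance_lower()]
#'
#' @param path input file.
#' @param model model tag to attach (default read from the header when
#'   present, else `"p"`).
#' @return a `gendist`.
#' @export
read_distance_lower <- function(path, model = NULL) {
  lines <- readLines(path, warn = FALSE)
  header <- grepl("^#", lines)
  if (is.null(model)) {
    h1 <- if (any(header)) lines[header][1] else ""
    m <- regmatches(h1, regexec("model ([^,[:space:]]+)", h1))[[1]]
    model <- if (length(m) == 2) m[2] else "p"
  }
  lines <- lines[!header & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  labels <- vapply(parts, `[`, character(1), 1)
  n <- length(labels)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    vals <- as.numeric(parts[[i]][-1])
    vals <- vals[!is.na(vals)]
    if (length(vals) != i - 1) {
      stop(sprintf("row '%s': expected %d distances, found %d",
                   labels[i], i - 1, length(vals)), call. = FALSE)
    }
    if (i > 1) d[i, seq_len(i - 1)] <- d[seq_len(i - 1), i] <- vals
  }
  gendist(labels, d, model)
}

#' The whole-mitogenome distance matrix of the six Vietnamellidae records
#'
#' The published pairwise distances (proportion scale) between the six
#' complete Vietnamellidae mitogenomes: *V. sinensis* HM067837, *V.* sp.
#' MT-2014 (KM244655), *V.* sp. JZ-2021 (MF352146), and the three
#' *V. sinensis* population genomes CN (OK265111), TL (OK265109) and QY
#' (OK265110). Shipped as a plain-text fixture so the delimitation pipeline
#' is exercisable without downloads.
#'
#' @return a `gendist` with 6 labels.
#' @export
vietnamella_distances <- function() {
  read_distance_lower(system.file("extdata", "vietnamellidae_mt_distances.txt",
                                  package = "mitodelim", mustWork = TRUE))
}

#' Morphospecies metadata for the six Vietnamellidae records
#'
#' @return data.frame with columns `label`, `accession`, `morphospecies`.
#'   The four records identified morphologically as *V. sinensis*
#'   (HM067837, CN, TL, QY) share one morphospecies label.
#' @export
vietnamella_metadata <- function() {
  read.delim(system.file("extdata", "vietnamellidae_metadata.tsv",
                         package = "mitodelim", mustWork = TRUE),
             stringsAsFactors = FALSE)
}
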