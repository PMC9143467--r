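# The record model shared by all stages: a MitoRecord is a list with
#   id        accession or label
#   sequence  upper-case DNA string over {A,C,G,T,N} (the published strand)
#   circular  logical
#   features  data.frame: name, kind, start, end, strand, anticodon,
#             segment, incomplete_stop
# Coordinates are GenBank-style 1-based inclusive on the published strand.
# A feature wrapping the circular origin is stored as two rows sharing a
# name, with segment = 1, 2 in reading order on the written strand.

FEATURE_KINDS <- c("PCG", "tRNA", "rRNA", "control_region")

#' Construct a gene-feature table
#'
#' @param name gene labels (canonical vocabulary preferred, see
#'   [normalize_gene_name()]).
#' @param kind one of `"PCG"`, `"tRNA"`, `"rRNA"`, `"control_region"`.
#' @param start,end 1-based inclusive positions on the published strand.
#' @param strand `"H"` (feature read off the record sequence as written) or
#'   `"L"` (reverse complement).
#' @param anticodon optional 3-mer for tRNAs.
#' @param segment segment index for features wrapping the circular origin
#'   (1 for ordinary features).
#' @param incomplete_stop logical; TRUE for PCGs annotated with a truncated
#'   (T/TA) stop codon, which makes a length not divisible by 3 legal.
#' @return data.frame with one row per feature.
#' @export
gene_features <- function(name, kind, start, end, strand,
                          anticodon = NA_character_, segment = 1L,
                          incomplete_stop = FALSE) {
  stopifnot(all(kind %in% FEATURE_KINDS), all(strand %in% c("H", "L")))
  data.frame(name = as.character(name), kind = as.character(kind),
             start = as.integer(start), end = as.integer(end),
             strand = as.character(strand),
             anticodon = as.character(anticodon),
             segment = as.integer(segment),
             incomplete_stop = as.logical(incomplete_stop),
             stringsAsFactors = FALSE)
}

empty_features <- function() {
  gene_features(character(), character(), integer(), integer(),
                character(), character(), integer(), logical())
}

#' Construct an annotated mitogenome record
#'
#' @param id accession or label.
#' @param sequence DNA string over `{A,C,G,T,N}`; lower case is folded up.
#' @param features feature table from [gene_features()]; may be empty, in
#'   which case the record is valid for whole-genome statistics only.
#' @param circular logical flag (default TRUE).
#' @return object of class `mito_record`.
#' @export
mito_record <- function(id, sequence, features = empty_features(),
                        circular = TRUE) {
  sequence <- toupper(sequence)
  check_dna(sequence, sprintf("record '%s'", id))
  rec <- structure(list(id = id, sequence = sequence,
                        circular = isTRUE(circular), features = features),
                   class = "mito_record")
  validate_mito_record(rec)
  rec
}

#' Validate a mitogenome record's invariants
#'
#' Checks coordinate sanity, the mod-3 rule for protein-coding genes (a
#' remainder is only legal for incomplete-stop annotations) and, when
#' `complete = TRUE`, the canonical 13 PCG / 22 tRNA / 2 rRNA / <=1 control
#' region census with unique names.
#'
#' @param record a `mito_record`.
#' @param complete also require the canonical full-genome census.
#' @return the record, invisibly; errors describe the offending feature.
#' @export
validate_mito_record <- function(record, complete = FALSE) {
  f <- record$features
  n <- nchar(record$sequence)
  if (nrow(f) > 0) {
    if (any(f$start < 1L) || any(f$end > n)) {
      bad <- f$name[f$start < 1L | f$end > n]
      stop(sprintf("record '%s': feature(s) outside sequence [1, %d]: %s",
                   record$id, n, paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (any(f$end < f$start)) {
      stop(sprintf("record '%s': end < start for %s (wrap-around must be two segments)",
                   record$id, paste(f$name[f$end < f$start], collapse = ", ")),
           call. = FALSE)
    }
    pcg <- f[f$kind == "PCG", , drop = FALSE]
    if (nrow(pcg) > 0) {
      len <- vapply(split(pcg, pcg$name),
                    function(g) sum(g$end - g$start + 1L), integer(1))
      inc <- vapply(split(pcg, pcg$name),
                    function(g) any(g$incomplete_stop), logical(1))
      off <- len %% 3L != 0L & !inc
      if (any(off)) {
        stop(sprintf("record '%s': PCG length not divisible by 3 without incomplete-stop flag: %s",
                     record$id, paste(names(len)[off], collapse = ", ")),
             call. = FALSE)
      }
    }
  }
  if (complete) {
    census <- table(factor(unique(f[, c("name", "kind")])$kind,
                           levels = FEATURE_KINDS))
    want <- c(PCG = 13L, tRNA = 22L, rRNA = 2L)
    for (k in names(want)) {
      if (census[[k]] != want[[k]]) {
        stop(sprintf("record '%s': expected %d %s features, found %d",
                     record$id, want[[k]], k, census[[k]]), call. = FALSE)
      }
    }
    if (census[["control_region"]] > 1L) {
      stop(sprintf("record '%s': more than one control region", record$id),
           call. = FALSE)
    }
    dup <- duplicated(f$name) & !(f$segment > 1L)
    if (any(dup)) {
      stop(sprintf("record '%s': duplicate feature name(s): %s",
                   record$id, paste(unique(f$name[dup]), collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(record)
}

#' @export
print.mito_record <- function(x, ...) {
  cat(sprintf("<mito_record> %s: %d bp, %s, %d feature row(s)\n",
              x$id, nchar(x$sequence),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  if (nrow(x$features) > 0) {
    print(table(x$features$kind[x$features$segment == 1L]))
  }
  invisible(x)
}

#' Extract the gene-oriented (sense) sequence of a feature
#'
#' Returns the sub-sequence as written for strand-H features and the reverse
#' complement for strand-L features, so the result always reads 5'->3' in the
#' gene's own orientation. Features wrapping the circular origin (stored as
#' two segments) are concatenated in segment order before orientation.
#'
#' @param record a `mito_record`.
#' @param feature a gene name present in `record$features`, or a one-or-more
#'   row subset of the feature table (all rows one gene).
#' @return DNA string.
#' @export
#' @examples
#' r <- mito_record("x", "AAACCC",
#'                  gene_features("g", "tRNA", 1, 3, "L"))
#' extract_feature_seq(r, "g")   # "TTT"
extract_feature_seq <- function(record, feature) {
  f <- if (is.character(feature)) {
    record$features[record$features$name == feature, , drop = FALSE]
  } else {
    feature
  }
  if (nrow(f) == 0) {
    stop(sprintf("record '%s': no feature named '%s'", record$id,
                 if (is.character(feature)) feature else "<table>"),
         call. = FALSE)
  }
  if (length(unique(f$name)) > 1L) {
    stop("extract_feature_seq() expects the rows of a single gene", call. = FALSE)
  }
  n <- nchar(record$sequence)
  if (any(f$start < 1L) || any(f$end > n)) {
    stop(sprintf("record '%s': feature '%s' outside sequence", record$id,
                 f$name[1]), call. = FALSE)
  }
  f <- f[order(f$segment), , drop = FALSE]
  parts <- substring(record$sequence, f$start, f$end)
  s <- paste(parts, collapse = "")
  if (f$strand[1] == "L") revcomp(s) else s
}

#' Intergenic nucleotides between consecutive features
#'
#' Lengths of the unannotated gaps between consecutive features in genome
#' order (negative values indicate overlapping annotations, which real
#' mitogenomes do contain). For a circular record the gap between the last
#' feature and the first (across the origin) is included.
#'
#' @param record a `mito_record` with at least 2 features.
#' @return data.frame with columns `after`, `before`, `ign` (bp).
#' @export
intergenic_lengths <- function(record) {
  f <- record$features[record$features$segment == 1L, , drop = FALSE]
  if (nrow(f) < 2) {
    stop(sprintf("record '%s': need >= 2 features", record$id), call. = FALSE)
  }
  # use the full extent of multi-segment genes
  ext <- do.call(rbind, lapply(split(record$features, record$features$name),
                               function(g) data.frame(name = g$name[1],
                                                      start = min(g$start),
                                                      end = max(g$end))))
  ext <- ext[order(ext$start), ]
  n <- nrow(ext)
  gaps <- data.frame(
    after = ext$name[-n], before = ext$name[-1],
    ign = ext$start[-1] - ext$end[-n] - 1L, stringsAsFactors = FALSE)
  if (record$circular) {
    wrap <- nchar(record$sequence) - ext$end[n] + ext$start[1] - 1L
    gaps <- rbind(gaps, data.frame(after = ext$name[n], before = ext$name[1],
                                   ign = wrap))
  }
  rownames(gaps) <- NULL
  gaps
}

#' All gene-oriented sequences of a record, by kind
#' @noRd
feature_seqs <- function(record, kind = NULL, strand = NULL) {
  f <- record$features
  if (!is.null(kind)) f <- f[f$kind %in% kind, , drop = FALSE]
  if (!is.null(strand)) f <- f[f$strand %in% strand, , drop = FALSE]
  if (nrow(f) == 0) return(setNames(character(0), character(0)))
  # keep genome order of first segments; multi-segment genes pulled whole
  ord <- f[f$segment == 1L, , drop = FALSE]
  ord <- ord[order(ord$start), , drop = FALSE]
  setNames(vapply(ord$name, function(nm) {
    extract_feature_seq(record, f[f$name == nm, , drop = FALSE])
  }, character(1)), ord$name)
}
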