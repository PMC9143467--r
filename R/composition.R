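# Per-region nucleotide composition and strand-skew statistics.
#
# Strand-class regions (PCG +, PCG -, tRNA +, tRNA -, rRNA) are computed on
# gene-oriented (sense) sequences: minus-strand genes are reverse
# complemented before counting. This is the convention under which
# minus-strand protein-coding genes show positive GC skew while
# plus-strand ones are negative, the sign structure seen in insect
# mitogenome tables. The whole genome is counted as written.

REGIONS <- c("whole_genome", "PCG", "tRNA", "rRNA", "control_region")

#' Count A, T, G, C in a DNA string
#'
#' `N` (and any gap characters) are excluded from the tallies, so downstream
#' fractions and skews stay well defined; length bookkeeping is left to the
#' caller.
#'
#' @param seq DNA string.
#' @return named integer vector `c(A=, T=, G=, C=)`.
#' @export
#' @examples
#' base_counts("ATGC")
base_counts <- function(seq) {
  if (nchar(seq) == 0) return(c(A = 0L, T = 0L, G = 0L, C = 0L))
  ch <- seq_chars(seq)
  tab <- table(factor(ch, levels = c("A", "T", "G", "C")))
  c(A = unname(tab[["A"]]), T = unname(tab[["T"]]),
    G = unname(tab[["G"]]), C = unname(tab[["C"]]))
}

#' AT skew, (A - T) / (A + T)
#'
#' @param counts named vector with `A` and `T` entries, as from
#'   [base_counts()].
#' @return numeric; `NA` when A + T = 0 (undefined, not an error).
#' @export
at_skew <- function(counts) {
  den <- counts[["A"]] + counts[["T"]]
  if (den == 0) return(NA_real_)
  (counts[["A"]] - counts[["T"]]) / den
}

#' GC skew, (G - C) / (G + C)
#'
#' @param counts named vector with `G` and `C` entries.
#' @return numeric; `NA` when G + C = 0.
#' @export
gc_skew <- function(counts) {
  den <- counts[["G"]] + counts[["C"]]
  if (den == 0) return(NA_real_)
  (counts[["G"]] - counts[["C"]]) / den
}

#' A+T content as a percentage
#' @param counts named vector with A, T, G, C entries.
#' @return numeric percentage; `NA` on an all-N sequence.
#' @export
at_percent <- function(counts) {
  tot <- sum(counts[c("A", "T", "G", "C")])
  if (tot == 0) return(NA_real_)
  100 * (counts[["A"]] + counts[["T"]]) / tot
}

#' Composition statistics for one region / strand class of a record
#'
#' @param record a `mito_record`.
#' @param region one of `"whole_genome"`, `"PCG"`, `"tRNA"`, `"rRNA"`,
#'   `"control_region"`.
#' @param strand_class `"+"`, `"-"` or `"both"`; ignored for
#'   `whole_genome` (counted on the written strand as-is).
#' @return a `region_stats` list: region, strand_class, length, counts,
#'   at_percent, at_skew, gc_skew (all full precision; see
#'   [composition_report()] for table-style rounding).
#' @export
region_stats <- function(record, region = "whole_genome",
                         strand_class = "both") {
  region <- match.arg(region, REGIONS)
  stopifnot(strand_class %in% c("+", "-", "both"))
  if (region == "whole_genome") {
    s <- record$sequence
    len <- nchar(s)
  } else {
    strand <- switch(strand_class, "+" = "H", "-" = "L", "both" = c("H", "L"))
    seqs <- feature_seqs(record, kind = region, strand = strand)
    if (length(seqs) == 0) {
      stop(sprintf("record '%s': no %s feature on strand class '%s'",
                   record$id, region, strand_class), call. = FALSE)
    }
    s <- paste(seqs, collapse = "")
    len <- nchar(s)
  }
  counts <- base_counts(s)
  structure(list(region = region, strand_class = strand_class,
                 length = len, counts = counts,
                 at_percent = at_percent(counts),
                 at_skew = at_skew(counts), gc_skew = gc_skew(counts)),
            class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf("%s (%s): %d bp, AT%% %.1f, AT skew %.3f, GC skew %.3f\n",
              x$region, x$strand_class, x$length, x$at_percent,
              x$at_skew, x$gc_skew))
  invisible(x)
}

#' Composition report over the standard region rows
#'
#' One row per (record, region, strand class) in the fixed order used by
#' mitogenome composition tables: whole genome, PCG +/-, tRNA +/-, rRNA
#' rows for strands present, and optionally the control region. Percentages
#' are rounded to 1 decimal and skews to 3 decimals, as conventionally
#' printed; use [region_stats()] for full precision.
#'
#' @param records a `mito_record` or list of them.
#' @param include_cr add a control-region row when the record has one.
#' @return data.frame with columns record, region, strand, length_bp,
#'   AT_pct, AT_skew, GC_skew.
#' @export
composition_report <- function(records, include_cr = FALSE) {
  if (inherits(records, "mito_record")) records <- list(records)
  rows <- list()
  for (rec in records) {
    specs <- list(c("whole_genome", "both"))
    for (region in c("PCG", "tRNA", "rRNA")) {
      for (sc in c("+", "-")) {
        f <- rec$features
        strand <- if (sc == "+") "H" else "L"
        if (any(f$kind == region & f$strand == strand)) {
          specs[[length(specs) + 1L]] <- c(region, sc)
        }
      }
    }
    if (include_cr && any(rec$features$kind == "control_region")) {
      specs[[length(specs) + 1L]] <- c("control_region", "both")
    }
    for (sp in specs) {
      st <- region_stats(rec, sp[1], sp[2])
      rows[[length(rows) + 1L]] <- data.frame(
        record = rec$id, region = sp[1], strand = sp[2],
        length_bp = st$length,
        AT_pct = round_half_up(st$at_percent, 1),
        AT_skew = round_half_up(st$at_skew, 3),
        GC_skew = round_half_up(st$gc_skew, 3),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Printed base composition of the Vietnamellidae population genomes
#'
#' The published whole-genome base percentages of the two *V. sinensis*
#' composition profiles (CN/TL and QY), shipped as a plain-text fixture.
#' Because [at_percent()] normalizes by the A+T+G+C total, percentages can
#' be fed to it directly in place of counts.
#'
#' @return data.frame with columns record, A, T, G, C (percent).
#' @export
vietnamella_base_composition <- function() {
  read.delim(system.file("extdata", "vietnamella_base_composition.tsv",
                         package = "mitodelim", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Write a composition report as TSV
#'
#' @param report data.frame from [composition_report()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
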