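# Codon counting, RSCU and translation under the invertebrate mitochondrial
# genetic code (NCBI transl_table 5: AGA/AGG = Ser, ATA = Met, TGA = Trp;
# stops TAA and TAG only). Synonymous families are grouped by amino acid
# under this code, which makes Leu a 6-codon and Ser an 8-codon family.

ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                    paste0), c("T", "C", "A", "G"), paste0))

#' The invertebrate mitochondrial genetic code
#'
#' @return named character vector mapping the 64 DNA codons to one-letter
#'   amino acids, with `*` for the stops (TAA, TAG).
#' @export
invert_mito_code <- function() {
  aa <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "M", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "W", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "S", AGG = "S",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  aa[ALL_CODONS]
}

MITO_STOPS <- c("TAA", "TAG")
CANONICAL_STARTS <- c("ATA", "ATT", "ATG", "ATC")

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Tally codons over a set of in-frame coding sequences
#'
#' Sequences are read in frame from position 1; a trailing partial codon
#' (1-2 bases, e.g. an incomplete stop) is dropped. Codons containing `N`
#' go to an `ambiguous` bucket rather than the 64-codon table.
#'
#' @param cds_seqs character vector (or list) of gene-oriented CDS strings.
#' @return named integer vector over the 64 codons, with attributes
#'   `ambiguous` (count of N-containing codons) and `stop_counts` (the
#'   TAA/TAG tallies, also present in the main table).
#' @export
#' @examples
#' codon_counts("ATGAAATAA")[c("ATG", "AAA", "TAA")]
codon_counts <- function(cds_seqs) {
  codons <- unlist(lapply(unlist(cds_seqs, use.names = FALSE), split_codons),
                   use.names = FALSE)
  ambiguous <- sum(grepl("N", codons, fixed = TRUE))
  codons <- codons[!grepl("N", codons, fixed = TRUE)]
  counts <- table(factor(codons, levels = ALL_CODONS))
  out <- setNames(as.integer(counts), ALL_CODONS)
  attr(out, "ambiguous") <- ambiguous
  attr(out, "stop_counts") <- out[MITO_STOPS]
  out
}

#' Relative synonymous codon usage
#'
#' For each sense codon c in synonymous family F (grouped by amino acid
#' under the invertebrate mitochondrial code),
#' `RSCU(c) = count(c) * |F| / sum(count(F))`: the observed count divided by
#' the family mean, so 1 means no bias within the family. Stop codons are
#' excluded; a family with zero observations gets `NA` throughout.
#'
#' @param counts codon tallies from [codon_counts()].
#' @return a `codon_usage_table` data.frame with columns `codon` (DNA),
#'   `codon_rna`, `amino_acid`, `count`, `rscu`, ordered by amino acid then
#'   codon.
#' @export
rscu <- function(counts) {
  code <- invert_mito_code()
  sense <- names(code)[code != "*"]
  df <- data.frame(codon = sense,
                   codon_rna = chartr("T", "U", sense),
                   amino_acid = unname(code[sense]),
                   count = as.integer(counts[sense]),
                   rscu = NA_real_,
                   stringsAsFactors = FALSE)
  for (aa in unique(df$amino_acid)) {
    idx <- df$amino_acid == aa
    fam_total <- sum(df$count[idx])
    if (fam_total > 0) {
      df$rscu[idx] <- df$count[idx] * sum(idx) / fam_total
    }
  }
  df <- df[order(df$amino_acid, df$codon), ]
  rownames(df) <- NULL
  class(df) <- c("codon_usage_table", "data.frame")
  df
}

#' Classify the start and stop codon of a coding sequence
#'
#' The start is the first 3 bases, flagged canonical when it matches the
#' mitochondrial ATN pattern (ATA/ATT/ATG/ATC). The stop is the last
#' complete codon when the length is divisible by 3 and it is TAA/TAG;
#' otherwise a trailing `T` or `TA` is reported as an incomplete stop
#' (completed to TAA by polyadenylation in vivo); anything else is
#' `non-canonical`.
#'
#' @param cds gene-oriented CDS string, length >= 6.
#' @param gene optional gene name carried into the result.
#' @return list with `gene`, `start_codon`, `start_canonical`,
#'   `stop_codon`, `stop_type` (`"complete"`, `"incomplete"`,
#'   `"non-canonical"`).
#' @export
#' @examples
#' classify_start_stop("ATGAAATAA")
classify_start_stop <- function(cds, gene = NA_character_) {
  if (nchar(cds) < 6) stop("CDS shorter than 6 bases", call. = FALSE)
  start <- substr(cds, 1, 3)
  rem <- nchar(cds) %% 3L
  if (rem == 0L) {
    last <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (last %in% MITO_STOPS) {
      stop_codon <- last; stop_type <- "complete"
    } else {
      stop_codon <- last; stop_type <- "non-canonical"
    }
  } else {
    tail_bases <- substr(cds, nchar(cds) - rem + 1L, nchar(cds))
    if (tail_bases %in% c("T", "TA")) {
      stop_codon <- tail_bases; stop_type <- "incomplete"
    } else {
      stop_codon <- tail_bases; stop_type <- "non-canonical"
    }
  }
  list(gene = gene, start_codon = start,
       start_canonical = start %in% CANONICAL_STARTS,
       stop_codon = stop_codon, stop_type = stop_type)
}

#' Start/stop classification for every protein-coding gene of a record
#'
#' @param record a `mito_record`.
#' @return data.frame with one row per PCG.
#' @export
codon_signatures <- function(record) {
  seqs <- feature_seqs(record, kind = "PCG")
  do.call(rbind, lapply(names(seqs), function(g) {
    s <- classify_start_stop(seqs[[g]], gene = g)
    data.frame(gene = g, start_codon = s$start_codon,
               start_canonical = s$start_canonical,
               stop_codon = s$stop_codon, stop_type = s$stop_type,
               stringsAsFactors = FALSE)
  }))
}

#' Translate a CDS under the invertebrate mitochondrial code
#'
#' An incomplete trailing codon is dropped; codons containing `N` translate
#' to `X`; a terminal complete stop is rendered `*`. Internal stop codons
#' raise a warning listing their codon positions, since they usually signal
#' a frame or annotation error.
#'
#' @param cds in-frame, gene-oriented CDS string.
#' @return protein string.
#' @export
#' @examples
#' translate_mito("ATGTGA")   # "MW"
translate_mito <- function(cds) {
  codons <- split_codons(toupper(cds))
  if (length(codons) == 0) return("")
  code <- invert_mito_code()
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  internal_stop <- which(aa == "*" & seq_along(aa) < length(aa))
  if (length(internal_stop) > 0) {
    warning("internal stop codon(s) at codon position(s): ",
            paste(internal_stop, collapse = ", "), call. = FALSE)
  }
  paste(aa, collapse = "")
}

#' Pooled RSCU table for the 13 protein-coding genes of records
#'
#' Counts are pooled across all PCGs per record (the per-genome convention
#' of published RSCU figures); set `per_gene = TRUE` for a long-format
#' per-gene table instead.
#'
#' @param records a `mito_record` or list of them.
#' @param per_gene return per-gene rows instead of pooled-per-record.
#' @return data.frame with a `record` (and optionally `gene`) column
#'   prepended to the [rscu()] columns.
#' @export
rscu_report <- function(records, per_gene = FALSE) {
  if (inherits(records, "mito_record")) records <- list(records)
  rows <- list()
  for (rec in records) {
    seqs <- feature_seqs(rec, kind = "PCG")
    if (length(seqs) == 0) {
      stop(sprintf("record '%s': no protein-coding features", rec$id),
           call. = FALSE)
    }
    if (per_gene) {
      for (g in names(seqs)) {
        tab <- rscu(codon_counts(seqs[[g]]))
        rows[[length(rows) + 1L]] <- cbind(record = rec$id, gene = g, tab)
      }
    } else {
      tab <- rscu(codon_counts(seqs))
      rows[[length(rows) + 1L]] <- cbind(record = rec$id, tab)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
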