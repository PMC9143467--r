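# Canonical 37-gene vocabulary for the insect mitogenome, in the ancestral
# (Drosophila-like) gene order starting at trnI, plus the control region.
# Strand is the published/written strand: "H" genes read off the record
# sequence as-is, "L" genes are reverse-complemented to get the sense strand.
# ref_len holds typical insect lengths used by the simulator to hit a
# ~15.6 kb genome; PCG ref_len counts complete codons including the stop.

canonical_gene_table <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
name  kind strand ref_len anticodon
trnI  tRNA H 65 GAT
trnQ  tRNA L 68 TTG
trnM  tRNA H 68 CAT
ND2   PCG  H 1023 NA
trnW  tRNA H 67 TCA
trnC  tRNA L 61 GCA
trnY  tRNA L 70 GTA
COI   PCG  H 1539 NA
trnL2 tRNA H 66 TAA
COII  PCG  H 688 NA
trnK  tRNA H 70 CTT
trnD  tRNA H 66 GTC
ATP8  PCG  H 162 NA
ATP6  PCG  H 678 NA
COIII PCG  H 789 NA
trnG  tRNA H 64 TCC
ND3   PCG  H 354 NA
trnA  tRNA H 64 TGC
trnR  tRNA H 64 TCG
trnN  tRNA H 65 GTT
trnS1 tRNA H 66 GCT
trnE  tRNA H 65 TTC
trnF  tRNA L 66 GAA
ND5   PCG  L 1735 NA
trnH  tRNA L 64 GTG
ND4   PCG  L 1341 NA
ND4L  PCG  L 297 NA
trnT  tRNA H 64 TGT
trnP  tRNA L 64 TGG
ND6   PCG  H 525 NA
CytB  PCG  H 1138 NA
trnS2 tRNA H 68 TGA
ND1   PCG  L 942 NA
trnL1 tRNA L 65 TAG
16S   rRNA L 1223 NA
trnV  tRNA L 72 TAC
12S   rRNA L 792 NA
CR    control_region H 960 NA
")
  df$anticodon[df$anticodon == "NA"] <- NA_character_
  df
}

# PCGs in genome order; also the canonical concatenation order of
# supermatrix blocks.
PCG_ORDER <- c("ND2", "COI", "COII", "ATP8", "ATP6", "COIII",
               "ND3", "ND5", "ND4", "ND4L", "ND6", "CytB", "ND1")

#' Gene-name normalization map
#'
#' GenBank dialects label mitochondrial genes inconsistently (COX1 vs COI vs
#' CO1, CYTB vs COB vs Cyt b, rrnL vs 16S ...). This map folds the common
#' spellings onto the canonical vocabulary used throughout the package.
#' Users can extend it via the `extra` argument of [normalize_gene_name()].
#'
#' @return named character vector: raw (upper-cased) label -> canonical name.
#' @export
gene_name_map <- function() {
  c(
    "COX1" = "COI", "COX2" = "COII", "COX3" = "COIII",
    "CO1" = "COI", "CO2" = "COII", "CO3" = "COIII",
    "COXI" = "COI", "COXII" = "COII", "COXIII" = "COIII",
    "COI" = "COI", "COII" = "COII", "COIII" = "COIII",
    "CYTB" = "CytB", "COB" = "CytB", "CYT B" = "CytB", "CYTOCHROME B" = "CytB",
    "NAD1" = "ND1", "NAD2" = "ND2", "NAD3" = "ND3", "NAD4" = "ND4",
    "NAD4L" = "ND4L", "NAD5" = "ND5", "NAD6" = "ND6",
    "ND1" = "ND1", "ND2" = "ND2", "ND3" = "ND3", "ND4" = "ND4",
    "ND4L" = "ND4L", "ND5" = "ND5", "ND6" = "ND6",
    "NADH1" = "ND1", "NADH2" = "ND2", "NADH3" = "ND3", "NADH4" = "ND4",
    "NADH4L" = "ND4L", "NADH5" = "ND5", "NADH6" = "ND6",
    "ATP6" = "ATP6", "ATP8" = "ATP8", "ATPASE6" = "ATP6", "ATPASE8" = "ATP8",
    "ATPASE 6" = "ATP6", "ATPASE 8" = "ATP8",
    "L-RRNA" = "16S", "RRNL" = "16S", "16S" = "16S", "16S RRNA" = "16S",
    "16S RIBOSOMAL RNA" = "16S", "LARGE SUBUNIT RIBOSOMAL RNA" = "16S",
    "S-RRNA" = "12S", "RRNS" = "12S", "12S" = "12S", "12S RRNA" = "12S",
    "12S RIBOSOMAL RNA" = "12S", "SMALL SUBUNIT RIBOSOMAL RNA" = "12S",
    "D-LOOP" = "CR", "CONTROL REGION" = "CR", "A+T-RICH REGION" = "CR",
    "AT-RICH REGION" = "CR", "A+T RICH REGION" = "CR", "CR" = "CR",
    "TRNL(UUR)" = "trnL2", "TRNL(CUN)" = "trnL1",
    "TRNL1" = "trnL1", "TRNL2" = "trnL2",
    "TRNS(AGN)" = "trnS1", "TRNS(UCN)" = "trnS2",
    "TRNS1" = "trnS1", "TRNS2" = "trnS2",
    "TRNA-LEU(UUR)" = "trnL2", "TRNA-LEU(CUN)" = "trnL1",
    "TRNA-SER(AGN)" = "trnS1", "TRNA-SER(UCN)" = "trnS2",
    setNames(
      paste0("trn", c("I", "Q", "M", "W", "C", "Y", "K", "D", "G", "A", "R",
                      "N", "E", "F", "H", "T", "P", "V")),
      paste0("TRN", c("I", "Q", "M", "W", "C", "Y", "K", "D", "G", "A", "R",
                      "N", "E", "F", "H", "T", "P", "V"))),
    setNames(
      paste0("trn", c("I", "Q", "M", "W", "C", "Y", "K", "D", "G", "A", "R",
                      "N", "E", "F", "H", "T", "P", "V")),
      paste0("TRNA-", c("ILE", "GLN", "MET", "TRP", "CYS", "TYR", "LYS",
                        "ASP", "GLY", "ALA", "ARG", "ASN", "GLU", "PHE",
                        "HIS", "THR", "PRO", "VAL")))
  )
}

#' Normalize a gene label to the canonical vocabulary
#'
#' Unknown labels are returned unchanged with a warning, so records carrying
#' unusual annotations are kept rather than rejected.
#'
#' @param name character vector of raw gene labels.
#' @param extra optional named character vector of additional raw -> canonical
#'   mappings, taking precedence over the built-in map.
#' @param warn warn on labels that cannot be normalized (default TRUE).
#' @return character vector of canonical (or raw, if unknown) names.
#' @export
#' @examples
#' normalize_gene_name(c("COX1", "cytb", "l-rRNA"))
normalize_gene_name <- function(name, extra = NULL, warn = TRUE) {
  map <- c(extra, gene_name_map())
  key <- toupper(trimws(name))
  hit <- map[key]
  unknown <- is.na(hit)
  if (any(unknown) && warn) {
    warning("unknown gene label(s) kept as-is: ",
            paste(unique(name[unknown]), collapse = ", "), call. = FALSE)
  }
  hit[unknown] <- name[unknown]
  unname(hit)
}
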