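#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames runif
#' @importFrom utils read.delim write.table head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' Vectorised over its input. `N` maps to `N`, `-` (alignment gap) maps to
#' `-`, so aligned sequences survive the round trip.
#'
#' @param x character vector of DNA strings (A/C/G/T/N/-).
#' @return character vector of reverse-complemented strings.
#' @export
#' @examples
#' revcomp("AAACCC")   # "GGGTTT"
revcomp <- function(x) {
  flipped <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Split a DNA string into single characters
#' @noRd
seq_chars <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1]]
}

#' Validate a DNA sequence over {A,C,G,T,N}
#' @noRd
check_dna <- function(seq, what = "sequence") {
  bad <- setdiff(unique(seq_chars(seq)), DNA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("%s contains letters outside {A,C,G,T,N}: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Round half away from zero, the convention used in the printed tables
#' @noRd
round_half_up <- function(x, digits = 0) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}
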