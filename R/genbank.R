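# Minimal GenBank flat-file reader/writer covering the feature subset that
# matters for mitogenomes: CDS, tRNA, rRNA, D-loop and misc_feature
# (A+T-rich region). Locations understood: n..m, complement(...),
# join(a..b,c..d) and partial markers (<, >). Everything else in the header
# is carried through untouched or ignored.

#' Read annotated mitogenome records from a GenBank flat file
#'
#' One `mito_record` is returned per LOCUS. GenBank feature keys are mapped
#' to the record model (`CDS` -> PCG, `tRNA` -> tRNA, `rRNA` -> rRNA,
#' `D-loop` / `misc_feature` A+T-rich region -> control_region); `gene` and
#' `source` keys are skipped as redundant. Gene labels are taken from
#' `/gene=` (falling back to `/product=`) and normalized to the canonical
#' vocabulary; unknown labels are kept raw with a warning. A CDS whose
#' length is not divisible by 3 is flagged incomplete-stop.
#'
#' @param path GenBank flat file (possibly multi-record).
#' @param normalize normalize gene names (default TRUE).
#' @return list of `mito_record`.
#' @export
read_genbank <- function(path, normalize = TRUE) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//\\s*$", lines)
  if (length(ends) == 0) stop("not a GenBank flat file (no // terminator): ", path,
                              call. = FALSE)
  starts <- c(1L, head(ends, -1) + 1L)
  records <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    chunk <- lines[starts[i]:ends[i]]
    records[[i]] <- parse_genbank_record(chunk, normalize = normalize)
  }
  records
}

parse_genbank_record <- function(lines, normalize = TRUE) {
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus_line) != 1) {
    stop("malformed GenBank record: expected exactly one LOCUS line", call. = FALSE)
  }
  toks <- strsplit(trimws(locus_line), "\\s+")[[1]]
  id <- if (length(toks) >= 2) toks[2] else stop("malformed LOCUS line", call. = FALSE)
  circular <- any(grepl("circular", locus_line, ignore.case = TRUE))

  ftop <- grep("^FEATURES", lines)
  otop <- grep("^ORIGIN", lines)
  if (length(otop) != 1) {
    stop(sprintf("malformed GenBank record '%s': missing ORIGIN", id), call. = FALSE)
  }
  seq_lines <- lines[(otop + 1):(length(lines) - 1)]
  sequence <- toupper(gsub("[0-9 /]", "", paste(seq_lines, collapse = "")))
  check_dna(sequence, sprintf("GenBank record '%s'", id))

  feats <- empty_features()
  if (length(ftop) == 1 && ftop + 1 <= otop - 1) {
    fl <- lines[(ftop + 1):(otop - 1)]
    feats <- parse_genbank_features(fl, id, normalize = normalize)
  }
  mito_record(id, sequence, feats, circular = circular)
}

parse_genbank_features <- function(flines, id, normalize = TRUE) {
  # a new feature starts with a key in column 6; qualifiers are indented to 22
  key_idx <- grep("^ {4,5}\\S", flines)
  out <- list()
  for (k in seq_along(key_idx)) {
    from <- key_idx[k]
    to <- if (k < length(key_idx)) key_idx[k + 1] - 1L else length(flines)
    block <- flines[from:to]
    key <- sub("^\\s+", "", substr(block[1], 1, 21))
    key <- trimws(key)
    body <- paste(trimws(c(substring(block[1], 22), block[-1])), collapse = "\n")
    # location may continue over lines before the first qualifier
    pieces <- strsplit(body, "\n", fixed = TRUE)[[1]]
    qual_at <- grep("^/", pieces)
    loc_str <- paste(pieces[seq_len(if (length(qual_at)) qual_at[1] - 1 else length(pieces))],
                     collapse = "")
    quals <- parse_genbank_qualifiers(pieces[qual_at])
    kind <- switch(key,
                   "CDS" = "PCG", "tRNA" = "tRNA", "rRNA" = "rRNA",
                   "D-loop" = "control_region",
                   "misc_feature" = {
                     note <- tolower(paste(quals[["note"]] %||% "",
                                           quals[["product"]] %||% ""))
                     if (grepl("a\\+t|at-rich|control region|d-loop", note))
                       "control_region" else NA_character_
                   },
                   NA_character_)
    if (is.na(kind)) next
    loc <- parse_genbank_location(loc_str, id, key)
    raw_name <- quals[["gene"]] %||% quals[["product"]] %||%
      if (kind == "control_region") "CR" else NA_character_
    if (is.na(raw_name)) {
      warning(sprintf("record '%s': %s feature without /gene or /product dropped",
                      id, key), call. = FALSE)
      next
    }
    name <- if (normalize) normalize_gene_name(raw_name) else raw_name
    anticodon <- NA_character_
    note <- quals[["note"]] %||% ""
    ac <- regmatches(note, regexec("anticodon:([ACGTUacgtu]{3})", note))[[1]]
    if (length(ac) == 2) anticodon <- toupper(ac[2])
    len <- sum(loc$end - loc$start + 1L)
    out[[length(out) + 1L]] <- gene_features(
      name = name, kind = kind, start = loc$start, end = loc$end,
      strand = if (loc$complement) "L" else "H",
      anticodon = anticodon,
      segment = seq_along(loc$start),
      incomplete_stop = kind == "PCG" && len %% 3L != 0L)
  }
  if (length(out) == 0) empty_features() else do.call(rbind, out)
}

parse_genbank_qualifiers <- function(qlines) {
  if (length(qlines) == 0) return(list())
  # re-join continuation lines (qualifiers start with "/")
  joined <- character(0)
  for (l in qlines) {
    if (grepl("^/", l) || length(joined) == 0) joined <- c(joined, l)
    else joined[length(joined)] <- paste(joined[length(joined)], l)
  }
  out <- list()
  for (l in joined) {
    m <- regmatches(l, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', l))[[1]]
    if (length(m) == 3) out[[m[2]]] <- m[3]
  }
  out
}

parse_genbank_location <- function(loc, id, key) {
  raw <- gsub("[<> ]", "", loc)
  complement <- grepl("^complement\\(", raw)
  inner <- sub("^complement\\((.*)\\)$", "\\1", raw)
  inner <- sub("^join\\((.*)\\)$", "\\1", inner)
  parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)\\.\\.([0-9]+)$", parts))
  ok <- vapply(m, length, integer(1)) == 3
  single <- regmatches(parts, regexec("^([0-9]+)$", parts))
  for (i in which(!ok)) {
    if (length(single[[i]]) == 2) {
      m[[i]] <- c(parts[i], single[[i]][2], single[[i]][2])
      ok[i] <- TRUE
    }
  }
  if (!all(ok)) {
    stop(sprintf("record '%s': cannot parse %s location '%s'", id, key, loc),
         call. = FALSE)
  }
  list(start = as.integer(vapply(m, `[`, character(1), 2)),
       end = as.integer(vapply(m, `[`, character(1), 3)),
       complement = complement)
}

#' Write mitogenome records as a GenBank flat file
#'
#' Inverse of [read_genbank()] on the record model: reading the written file
#' back yields identical records (id, sequence, circular flag, features).
#'
#' @param records a `mito_record` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "mito_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(format_genbank_record(rec), con)
  }
  invisible(path)
}

format_genbank_record <- function(rec) {
  n <- nchar(rec$sequence)
  topo <- if (rec$circular) "circular" else "linear"
  out <- c(
    sprintf("LOCUS       %-16s %6d bp    DNA     %s INV 01-JAN-2026",
            rec$id, n, topo),
    sprintf("DEFINITION  %s mitochondrion.", rec$id),
    sprintf("ACCESSION   %s", rec$id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n))
  f <- rec$features
  if (nrow(f) > 0) {
    first <- f[f$segment == 1L, , drop = FALSE]
    first <- first[order(first$start), , drop = FALSE]
    for (i in seq_len(nrow(first))) {
      g <- f[f$name == first$name[i], , drop = FALSE]
      g <- g[order(g$segment), , drop = FALSE]
      spans <- sprintf("%d..%d", g$start, g$end)
      loc <- if (length(spans) > 1) sprintf("join(%s)", paste(spans, collapse = ",")) else spans
      if (g$strand[1] == "L") loc <- sprintf("complement(%s)", loc)
      key <- switch(g$kind[1], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                    control_region = "D-loop")
      out <- c(out, sprintf("     %-15s %s", key, loc),
               sprintf("                     /gene=\"%s\"", g$name[1]))
      if (!is.na(g$anticodon[1])) {
        out <- c(out, sprintf("                     /note=\"anticodon:%s\"",
                              g$anticodon[1]))
      }
      if (isTRUE(g$incomplete_stop[1])) {
        out <- c(out, "                     /note=\"incomplete stop codon\"")
      }
    }
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    starts <- seq(p, min(p + 59L, n), by = 10L)
    chunk <- substring(rec$sequence, starts, pmin(starts + 9L, n))
    out <- c(out, sprintf("%9d %s", p, tolower(paste(chunk, collapse = " "))))
  }
  c(out, "//")
}

#' Read a FASTA file as plain named DNA strings
#'
#' Thin wrapper over Biostrings; gaps (`-`) are preserved so the same reader
#' serves aligned and unaligned input.
#'
#' @param path FASTA file.
#' @return named character vector of upper-cased sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write named DNA strings as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTA + feature-table pair as mitogenome records
#'
#' The sidecar is a TSV with columns `record` (optional when the FASTA holds
#' one sequence), `gene`, `kind`, `start`, `end`, `strand` and optionally
#' `anticodon`, `segment`, `incomplete_stop`.
#'
#' @param fasta FASTA file of genome sequences.
#' @param table TSV feature table; NULL for sequence-only records.
#' @param circular circular flag applied to all records.
#' @return list of `mito_record`.
#' @export
read_fasta_records <- function(fasta, table = NULL, circular = TRUE) {
  seqs <- read_fasta(fasta)
  tab <- if (is.null(table)) NULL else
    read.delim(table, stringsAsFactors = FALSE)
  lapply(names(seqs), function(id) {
    feats <- empty_features()
    if (!is.null(tab)) {
      sub <- if ("record" %in% names(tab)) tab[tab$record == id, , drop = FALSE] else tab
      if (nrow(sub) > 0) {
        feats <- gene_features(
          name = sub$gene, kind = sub$kind, start = sub$start, end = sub$end,
          strand = sub$strand,
          anticodon = sub$anticodon %||% NA_character_,
          segment = sub$segment %||% 1L,
          incomplete_stop = sub$incomplete_stop %||% FALSE)
      }
    }
    mito_record(id, seqs[[id]], feats, circular = circular)
  })
}

#' Write the feature table of records as TSV
#'
#' @param records a `mito_record` or list of them.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, path) {
  if (inherits(records, "mito_record")) records <- list(records)
  rows <- do.call(rbind, lapply(records, function(r) {
    if (nrow(r$features) == 0) return(NULL)
    cbind(record = r$id,
          stats::setNames(r$features,
                          c("gene", "kind", "start", "end", "strand",
                            "anticodon", "segment", "incomplete_stop")))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
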