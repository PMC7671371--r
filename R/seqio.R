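## Sequence input and peptide output. FASTA/FASTQ parsing is delegated to
## Biostrings; records are normalized to lowercase and validated against the
## 22-letter alphabet on ingestion.

#' Read protein records from a FASTA or FASTQ file
#'
#' The format is auto-detected from the first non-blank character (`>` for
#' FASTA, `@` for FASTQ); FASTQ quality strings are parsed and discarded.
#' Sequences are lowercased and every residue checked against the 22-letter
#' amino-acid alphabet; stop codons (`*`), gaps and ambiguity codes are
#' rejected with the offending record named.
#'
#' @param path Input file.
#' @param format `"auto"` (default), `"fasta"` or `"fastq"`.
#' @return A data frame with columns `id` (first header token),
#'   `description` (header remainder, possibly empty) and `sequence`
#'   (normalized lowercase).
#' @export
read_records <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    pc_stop_usage(sprintf("input file '%s' does not exist", path))
  }
  if (format == "auto") {
    head <- readLines(path, n = 50L, warn = FALSE)
    head <- head[nzchar(trimws(head))]
    if (!length(head)) pc_stop_usage(sprintf("input file '%s' is empty", path))
    first <- substr(head[1L], 1L, 1L)
    format <- switch(first,
      ">" = "fasta",
      "@" = "fastq",
      pc_stop_data(sprintf(
        "cannot detect format of '%s': first record starts with '%s', expected '>' (fasta) or '@' (fastq)",
        path, first
      ))
    )
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) {
      pc_stop_data(sprintf("malformed %s file '%s': %s",
                           format, path, conditionMessage(e)))
    }
  )
  if (!length(set)) {
    pc_stop_usage(sprintf("input file '%s' contains no records", path))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(set)
  seqs <- vapply(seq_along(seqs), function(i) {
    normalize_sequence(seqs[i], what = sprintf("record '%s'", ids[i]))
  }, character(1L))
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

format_peptides <- function(peptides) {
  data.frame(
    parent_id = peptides$parent_id,
    enzyme = peptides$enzyme,
    ordinal = peptides$ordinal,
    cleavage_position = peptides$cleavage_position,
    length = peptides$length,
    mass = sprintf("%.4f", peptides$mass),
    pi = sprintf("%.2f", peptides$pi),
    sequence = toupper(peptides$sequence),
    stringsAsFactors = FALSE
  )
}

#' Write a peptide table to FASTA, CSV or TSV
#'
#' FASTA output uses the header layout
#' `>parent_ordinal_enzyme_position_length_mass_pI`; CSV/TSV output has one
#' row per peptide with a header line and columns `parent_id`, `enzyme`,
#' `ordinal`, `cleavage_position`, `length`, `mass` (4 decimals), `pi`
#' (2 decimals), `sequence`. The three formats carry identical peptide
#' multisets.
#'
#' @param peptides Peptide data frame from [digest()] / [digest_one()].
#' @param path Output file (or `""` for standard output).
#' @param format `"fasta"`, `"csv"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_results <- function(peptides, path, format = c("fasta", "csv", "tsv")) {
  if (!is.character(format) || !format[1L] %in% c("fasta", "csv", "tsv")) {
    pc_stop_usage(sprintf("unknown output format '%s'",
                          paste(format[1L], collapse = "")))
  }
  format <- format[1L]
  fp <- format_peptides(peptides)
  if (format == "fasta") {
    headers <- with(fp, paste(parent_id, ordinal, enzyme, cleavage_position,
                              length, mass, pi, sep = "_"))
    if (nrow(fp)) {
      set <- Biostrings::BStringSet(stats::setNames(fp$sequence, headers))
      Biostrings::writeXStringSet(set, filepath = path)
    } else {
      writeLines(character(0), path)
    }
  } else {
    utils::write.table(fp, file = path,
                       sep = if (format == "csv") "," else "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}
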