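#' @keywords internal
"_PACKAGE"

## Residue alphabet: 20 standard amino acids plus pyrrolysine (O) and
## selenocysteine (U). Lowercase is the canonical internal form.
RESIDUE_ALPHABET <- c(
  "a", "c", "d", "e", "f", "g", "h", "i", "k", "l", "m",
  "n", "o", "p", "q", "r", "s", "t", "u", "v", "w", "y"
)

pc_error <- function(msg, class, call = NULL) {
  stop(structure(
    class = c(class, "protcleave_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

pc_stop_usage <- function(msg) pc_error(msg, "protcleave_usage_error")
pc_stop_data <- function(msg) pc_error(msg, "protcleave_data_error")
pc_stop_parse <- function(msg) {
  pc_error(msg, c("protcleave_parse_error", "protcleave_data_error"))
}
pc_stop_alphabet <- function(msg) {
  pc_error(msg, c("protcleave_alphabet_error", "protcleave_data_error"))
}

#' Normalize and validate a protein sequence
#'
#' Lowercases a sequence and checks every residue against the 22-letter
#' amino-acid alphabet (20 standard residues plus pyrrolysine `o` and
#' selenocysteine `u`). Stop codons (`*`), gaps and ambiguity codes
#' (`b`, `j`, `x`, `z`) are rejected.
#'
#' @param sequence Character scalar, amino-acid sequence (case-insensitive).
#' @param what Label used in error messages (e.g. a record id).
#' @return The normalized lowercase sequence.
#' @examples
#' normalize_sequence("AeRt")
#' @export
normalize_sequence <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    pc_stop_data(sprintf("%s must be a single character string", what))
  }
  seq <- tolower(sequence)
  if (!nzchar(seq)) {
    pc_stop_data(sprintf("%s is empty", what))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% RESIDUE_ALPHABET)
  if (length(bad)) {
    pc_stop_alphabet(sprintf(
      "%s: illegal residue '%s' at position %d (allowed: %s)",
      what, chars[bad[1L]], bad[1L], paste(RESIDUE_ALPHABET, collapse = "")
    ))
  }
  seq
}

## Internal: sequence string -> validated lowercase character vector.
seq_chars <- function(sequence, what = "sequence") {
  strsplit(normalize_sequence(sequence, what), "", fixed = TRUE)[[1L]]
}
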