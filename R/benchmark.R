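## Reference benchmark on human Titin (UniProtKB A0A0A0MTS7, 35 991 aa):
## per-enzyme sequential peptide counts and the three-enzyme concurrent
## digestion. The sequence is not shipped with the package; fetch it with
## scripts/fetch_titin.R (network required).

#' Per-enzyme peptide counts on a reference protein
#'
#' Digests one protein (intended: human Titin, UniProtKB A0A0A0MTS7) with a
#' panel of catalog enzymes in sequential mode and with the
#' Arg-C / Lys-N / BNPS-Skatole trio in concurrent mode, reporting the
#' number of generated peptides for each digestion. Mass/pI annotation is
#' skipped; only counts are produced.
#'
#' @param fasta_path FASTA file holding the reference protein (first record
#'   is used).
#' @param enzymes Character vector of catalog enzyme names to run
#'   sequentially.
#' @param concurrent_trio Enzyme names digested together in concurrent
#'   mode, reported under the dash-joined name.
#' @return Named integer vector of peptide counts.
#' @export
titin_benchmark <- function(fasta_path,
                            enzymes = c("trypsin", "hydroxylamine", "asp-n",
                                        "asp-n-pepc", "caspase-1",
                                        "proteinase-k", "arg-c", "lys-c",
                                        "lys-n", "bnps-skatole", "glutamyl",
                                        "staphylococcal-peptidase-i",
                                        "cnbr", "ntcb", "chymotrypsin-high"),
                            concurrent_trio = c("arg-c", "lys-n",
                                                "bnps-skatole")) {
  rec <- read_records(fasta_path)
  seq <- rec$sequence[1L]
  counts <- vapply(enzymes, function(nm) {
    nrow(digest_one(seq, nm, parent_id = rec$id[1L], annotate = FALSE))
  }, integer(1L))
  names(counts) <- enzymes
  if (length(concurrent_trio)) {
    conc <- digest_concurrent(seq, as.list(concurrent_trio),
                              parent_id = rec$id[1L], annotate = FALSE)
    counts[[paste(concurrent_trio, collapse = "-")]] <- nrow(conc)
  }
  counts
}
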