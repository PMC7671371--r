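## Synthetic protein fixtures: random sequences with planted cleavage
## motifs and a sidecar manifest of where each motif sits, so expected site
## counts are computable without external data. The background alphabet
## excludes every letter occurring in a planted motif, so the manifest is
## exhaustive: no accidental motif copies and no accidental extension of a
## planted motif can arise.

#' Generate random protein records with planted cleavage motifs
#'
#' @param n_records Number of records.
#' @param length_range Integer pair: minimum/maximum record length.
#' @param motifs Character vector of motifs to plant (e.g. `"ng"` for
#'   hydroxylamine sites, `"wkp"` / `"kp"` for trypsin contexts,
#'   `"lvprgs"` for sequencing-grade thrombin).
#' @param motifs_per_record Integer pair: each record carries a uniform
#'   number of planted motifs in this range (subject to fitting).
#' @param seed Optional integer seed; fixed seeds give byte-identical
#'   output.
#' @return A list with `records` (data frame `id`, `sequence`) and
#'   `manifest` (data frame `id`, `motif`, `start` -- 1-based start of each
#'   planted motif).
#' @examples
#' fx <- generate_fixtures(3, c(40, 60), motifs = "ng", seed = 1)
#' fx$manifest
#' @export
generate_fixtures <- function(n_records = 10,
                              length_range = c(50, 200),
                              motifs = c("lvprgs", "wkp", "ng"),
                              motifs_per_record = c(1, 3),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  motifs <- tolower(motifs)
  motif_letters <- unique(unlist(strsplit(motifs, "", fixed = TRUE)))
  background <- setdiff(setdiff(RESIDUE_ALPHABET, c("o", "u")),
                        motif_letters)
  if (length(background) < 4L) {
    pc_stop_usage("motif set leaves too few background residues")
  }
  ids <- sprintf("synth%03d", seq_len(n_records))
  seqs <- character(n_records)
  man <- list()
  for (i in seq_len(n_records)) {
    len <- sample(length_range[1L]:length_range[2L], 1L)
    chars <- sample(background, len, replace = TRUE)
    n_plant <- sample(motifs_per_record[1L]:motifs_per_record[2L], 1L)
    occupied <- rep(FALSE, len)
    for (k in seq_len(n_plant)) {
      motif <- sample(motifs, 1L)
      w <- nchar(motif)
      ## candidate starts whose window is free and strictly inside the
      ## record (sites at the extreme ends would be suppressed as bonds)
      cand <- which(vapply(seq_len(len - w + 1L), function(s) {
        !any(occupied[s:(s + w - 1L)])
      }, logical(1L)))
      cand <- setdiff(cand, c(1L, len - w + 1L))
      if (!length(cand)) next
      s <- if (length(cand) == 1L) cand else sample(cand, 1L)
      chars[s:(s + w - 1L)] <- strsplit(motif, "", fixed = TRUE)[[1L]]
      occupied[s:(s + w - 1L)] <- TRUE
      man[[length(man) + 1L]] <-
        data.frame(id = ids[i], motif = motif, start = s,
                   stringsAsFactors = FALSE)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  manifest <- if (length(man)) {
    do.call(rbind, man)
  } else {
    data.frame(id = character(0), motif = character(0), start = integer(0),
               stringsAsFactors = FALSE)
  }
  list(
    records = data.frame(id = ids, sequence = seqs,
                         stringsAsFactors = FALSE),
    manifest = manifest
  )
}

#' Write fixture records to a FASTA file
#'
#' @param fixtures Result of [generate_fixtures()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_fixture_fasta <- function(fixtures, path) {
  set <- Biostrings::BStringSet(stats::setNames(
    fixtures$records$sequence, fixtures$records$id
  ))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
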