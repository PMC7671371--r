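## Digestion orchestration: splitting sequences at cleavage sites, missed
## cleavage sampling, sequential and concurrent multi-protease modes, and
## the peptide table every mode produces.

## Assemble the peptide table for one parent sequence given kept bond
## indices (sorted, in parent coordinates). `bonds` excludes the sequence
## end. cleavage_position is the 1-based position of the residue on the
## N-terminal side of each bond (PeptideCutter convention); the final
## peptide, which ends at the sequence end rather than at a cleavage,
## reports 0.
assemble_peptides <- function(sequence, bonds, parent_id, enzyme_name,
                              pka = "ipc_peptide", annotate = TRUE) {
  n <- nchar(sequence)
  ends <- c(bonds, n)
  starts <- c(1L, bonds + 1L)
  seqs <- substring(sequence, starts, ends)
  out <- data.frame(
    parent_id = parent_id,
    enzyme = enzyme_name,
    ordinal = seq_along(seqs),
    cleavage_position = c(bonds, 0L),
    sequence = seqs,
    length = nchar(seqs),
    stringsAsFactors = FALSE
  )
  if (annotate) {
    out$mass <- vapply(seqs, peptide_mass, numeric(1L), USE.NAMES = FALSE)
    out$pi <- vapply(seqs, isoelectric_point, numeric(1L), pka = pka,
                     USE.NAMES = FALSE)
  }
  out
}

empty_peptides <- function(annotate = TRUE) {
  out <- data.frame(
    parent_id = character(0), enzyme = character(0), ordinal = integer(0),
    cleavage_position = integer(0), sequence = character(0),
    length = integer(0), stringsAsFactors = FALSE
  )
  if (annotate) {
    out$mass <- numeric(0)
    out$pi <- numeric(0)
  }
  out
}

## Bernoulli missed-cleavage filter: one uniform draw in [0, 100) per site,
## left to right; a site is kept iff its draw is >= the miscleavage
## percentage. With pct = 0 no draws are consumed.
apply_miscleavage <- function(sites, pct) {
  if (pct < 0 || pct > 100) {
    pc_stop_usage("miscleavage percentage must be in [0, 100]")
  }
  if (!length(sites) || pct == 0) {
    return(sites)
  }
  u <- stats::runif(length(sites)) * 100
  sites[u >= pct]
}

#' Digest one sequence with one enzyme
#'
#' Finds all cleavage sites on the full sequence (context is never
#' truncated: a site's surrounding residues are read from the intact
#' parent), applies the missed-cleavage filter to each site left to right,
#' splits at the kept sites and annotates each resulting peptide with its
#' length, average mass and isoelectric point.
#'
#' @param sequence Amino-acid sequence (case-insensitive).
#' @param enzyme A `protease` or the name of a catalog enzyme.
#' @param miscleavage Missed-cleavage probability in percent (`[0, 100]`).
#'   At 100, every site is suppressed and the whole sequence is returned as
#'   one peptide. Draws come from R's RNG; call `set.seed()` (or use the
#'   `seed` argument of [digest()]) for reproducibility.
#' @param parent_id Identifier recorded in the `parent_id` column.
#' @param pka pKa set name or object, see [pka_set()].
#' @param annotate Logical; set `FALSE` to skip mass/pI computation (used by
#'   large resampling experiments).
#' @return A data frame with one row per peptide and columns `parent_id`,
#'   `enzyme`, `ordinal`, `cleavage_position`, `sequence`, `length` and
#'   (when annotated) `mass`, `pi`. Concatenating `sequence` in `ordinal`
#'   order reconstructs the parent.
#' @examples
#' digest_one("aeert", "staphylococcal-peptidase-i")$sequence # "ae" "ert"
#' @export
digest_one <- function(sequence, enzyme, miscleavage = 0,
                       parent_id = "seq", pka = "ipc_peptide",
                       annotate = TRUE) {
  enzyme <- resolve_enzyme(enzyme)
  seq <- tryCatch(
    normalize_sequence(sequence, what = sprintf("record '%s'", parent_id)),
    protcleave_alphabet_error = function(e) pc_stop_alphabet(conditionMessage(e))
  )
  sites <- find_sites(seq, enzyme)
  kept <- apply_miscleavage(sites, miscleavage)
  assemble_peptides(seq, kept, parent_id, enzyme$name, pka, annotate)
}

## Accept a protease object, a catalog name, or a list of either.
resolve_enzyme <- function(enzyme) {
  if (inherits(enzyme, "protease")) {
    return(enzyme)
  }
  if (is.character(enzyme) && length(enzyme) == 1L) {
    return(load_enzyme(enzyme))
  }
  pc_stop_usage("enzyme must be a protease object or a catalog enzyme name")
}

resolve_enzymes <- function(enzymes) {
  if (inherits(enzymes, "protease") ||
      (is.character(enzymes) && length(enzymes) == 1L)) {
    enzymes <- list(enzymes)
  }
  if (is.character(enzymes)) enzymes <- as.list(enzymes)
  lapply(enzymes, resolve_enzyme)
}

## Normalize record input to data.frame(id, sequence): accepts the output of
## read_records(), a data frame with id/sequence, or a (named) character
## vector.
as_records <- function(records) {
  if (is.data.frame(records)) {
    if (!all(c("id", "sequence") %in% names(records))) {
      pc_stop_usage("record data frame needs columns 'id' and 'sequence'")
    }
    df <- records[, c("id", "sequence")]
  } else if (is.character(records)) {
    if (!length(records)) pc_stop_usage("no sequence records supplied")
    ids <- names(records)
    if (is.null(ids)) ids <- paste0("seq", seq_along(records))
    df <- data.frame(id = ids, sequence = unname(records),
                     stringsAsFactors = FALSE)
  } else {
    pc_stop_usage("records must be a data frame or a character vector")
  }
  if (!nrow(df)) pc_stop_usage("no sequence records supplied")
  df
}

## Per-enzyme miscleavage vector for a job: `miscleavage` may be a single
## percentage or a named vector; enzymes not named fall back to their
## default (normally 0).
miscleavage_for <- function(enzymes, miscleavage) {
  pct <- vapply(enzymes, function(e) e$default_miscleavage, numeric(1L))
  names(pct) <- vapply(enzymes, `[[`, character(1L), "name")
  if (is.null(miscleavage)) {
    return(pct)
  }
  if (is.null(names(miscleavage))) {
    if (length(miscleavage) != 1L) {
      pc_stop_usage("unnamed miscleavage must be a single percentage")
    }
    pct[] <- miscleavage
  } else {
    unknown <- setdiff(names(miscleavage), names(pct))
    if (length(unknown)) {
      pc_stop_usage(sprintf("miscleavage given for unknown enzyme '%s'",
                            unknown[1L]))
    }
    pct[names(miscleavage)] <- miscleavage
  }
  if (any(pct < 0 | pct > 100)) {
    pc_stop_usage("miscleavage percentages must be in [0, 100]")
  }
  pct
}

#' Digest sequences with one or more proteases
#'
#' The top-level digestion entry point. In `sequential` mode every enzyme
#' digests every intact record independently (identical to running one
#' digestion per enzyme); output is record-major, then in enzyme order. In
#' `concurrent` mode all enzymes act together until no fragment offers a
#' site: cleavage by one enzyme can expose sites of another that the intact
#' protein hides (and, conversely, destroy context a rule needs), see
#' [digest_concurrent()].
#'
#' @param records Sequence records: a data frame with columns `id` and
#'   `sequence` (e.g. from [read_records()]) or a (named) character vector.
#' @param enzymes A `protease`, a catalog enzyme name, or a list/vector of
#'   them (order is preserved).
#' @param mode `"sequential"` (default) or `"concurrent"`.
#' @param miscleavage Single percentage applied to all enzymes, or a named
#'   vector `c(trypsin = 10, ...)`; enzymes not named use their default (0).
#' @param seed Optional integer seed for the missed-cleavage RNG stream.
#' @param pka pKa set name or object, see [pka_set()].
#' @return Peptide data frame as in [digest_one()].
#' @examples
#' digest(c(p1 = "aeert"), "staphylococcal-peptidase-i")
#' @export
digest <- function(records, enzymes, mode = c("sequential", "concurrent"),
                   miscleavage = NULL, seed = NULL, pka = "ipc_peptide") {
  mode <- match.arg(mode)
  records <- as_records(records)
  enzymes <- resolve_enzymes(enzymes)
  if (!length(enzymes)) pc_stop_usage("no enzymes supplied")
  pct <- miscleavage_for(enzymes, miscleavage)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (mode == "sequential") {
    out <- lapply(seq_len(nrow(records)), function(i) {
      per_enz <- lapply(enzymes, function(e) {
        digest_one(records$sequence[i], e, pct[[e$name]],
                   parent_id = records$id[i], pka = pka)
      })
      do.call(rbind, per_enz)
    })
  } else {
    out <- lapply(seq_len(nrow(records)), function(i) {
      digest_concurrent(records$sequence[i], enzymes, pct,
                        parent_id = records$id[i], pka = pka)
    })
  }
  do.call(rbind, out)
}

#' Concurrent digestion of one sequence to fixpoint
#'
#' Simulates all enzymes digesting together for an unlimited time. A FIFO
#' worklist holds sequence fragments (initially the whole sequence, tracked
#' in parent coordinates). For each fragment the union of all enzymes'
#' sites is computed *on the fragment*, so context beyond a fragment
#' boundary is invisible -- an out-of-fragment residue can neither satisfy
#' nor block a rule. Fragments are split at all kept sites and the pieces
#' re-enqueued; a fragment yielding no kept site is final. With 0%
#' miscleavage every split strictly shortens fragments, so the iteration
#' terminates. With miscleavage, sampling is per proposed site per
#' fragment; a site whose draws fail (for every proposing enzyme) is not
#' re-proposed for that fragment, which preserves termination -- it may be
#' proposed again only on a later, shorter fragment.
#'
#' @inheritParams digest_one
#' @param enzymes List of `protease` objects or catalog names.
#' @param miscleavage Named per-enzyme percentage vector or single value.
#' @return Peptide data frame; peptides are reported sorted by their start
#'   position in the parent, the `enzyme` column is the dash-joined list of
#'   enzyme names, and `cleavage_position` is the parent coordinate of each
#'   peptide's C-terminal bond (0 for the final peptide).
#' @examples
#' blocked <- compile_enzyme("pro-blocker", "(,p)", exceptions = "(,p)(k)")
#' res <- digest_concurrent("aapkaa", list(blocked, load_enzyme("lys-n")))
#' res$sequence # "aa" "p" "kaa"
#' @export
digest_concurrent <- function(sequence, enzymes, miscleavage = 0,
                              parent_id = "seq", pka = "ipc_peptide",
                              annotate = TRUE) {
  enzymes <- resolve_enzymes(enzymes)
  pct <- miscleavage_for(enzymes, miscleavage)
  seq <- normalize_sequence(sequence,
                            what = sprintf("record '%s'", parent_id))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  queue <- list(c(1L, n))
  final <- list()
  while (length(queue)) {
    frag <- queue[[1L]]
    queue <- queue[-1L]
    fchars <- chars[frag[1L]:frag[2L]]
    ## union of per-enzyme sites on the fragment, each filtered by its
    ## enzyme's miscleavage; sites are local bond indices
    kept <- integer(0)
    for (e in enzymes) {
      s <- find_sites_chars(fchars, e)
      s <- apply_miscleavage(s, pct[[e$name]])
      kept <- union(kept, s)
    }
    kept <- sort(kept)
    if (!length(kept)) {
      final[[length(final) + 1L]] <- frag
    } else {
      bounds <- c(0L, kept, length(fchars))
      for (j in seq_len(length(bounds) - 1L)) {
        queue[[length(queue) + 1L]] <-
          c(frag[1L] + bounds[j], frag[1L] + bounds[j + 1L] - 1L)
      }
    }
  }
  starts <- vapply(final, `[`, integer(1L), 1L)
  ord <- order(starts)
  ends <- vapply(final, `[`, integer(1L), 2L)[ord]
  bonds <- ends[-length(ends)]
  assemble_peptides(seq, bonds,
                    parent_id,
                    paste(vapply(enzymes, `[[`, character(1L), "name"),
                          collapse = "-"),
                    pka, annotate)
}

#' Summarize peptides falling in a mass range
#'
#' Counts peptides whose average mass lies inside the (inclusive) range and
#' the residues they contain; useful for judging a protease set against the
#' optimal tandem-MS peptide size window of 600-5000 Da.
#'
#' @param peptides Peptide data frame with `mass` and `length` columns.
#' @param lo_da,hi_da Inclusive mass bounds in Dalton.
#' @return A list with `count`, `fraction`, `residues` and
#'   `residue_fraction` (fractions of the totals in `peptides`; 0 for an
#'   empty table).
#' @examples
#' pep <- digest(c(p = "wkrlvprgsaeakkdeeff"), "trypsin")
#' size_range_summary(pep, 600, 5000)
#' @export
size_range_summary <- function(peptides, lo_da = 600, hi_da = 5000) {
  if (lo_da > hi_da) pc_stop_usage("lower mass bound exceeds upper bound")
  if (!nrow(peptides)) {
    return(list(count = 0L, fraction = 0, residues = 0L,
                residue_fraction = 0))
  }
  sel <- peptides$mass >= lo_da & peptides$mass <= hi_da
  list(
    count = sum(sel),
    fraction = sum(sel) / nrow(peptides),
    residues = sum(peptides$length[sel]),
    residue_fraction = sum(peptides$length[sel]) / sum(peptides$length)
  )
}
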