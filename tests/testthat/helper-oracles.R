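## Independent cleavage-site oracles, written directly from each protease's
## prose specificity (not from the rule trees), used to cross-check the
## engine by exhaustive enumeration on small alphabets.

## Enumerate all sequences of length 1..max_len over an alphabet.
enumerate_sequences <- function(alphabet, max_len) {
  unlist(lapply(seq_len(max_len), function(len) {
    grid <- do.call(expand.grid, c(rep(list(alphabet), len),
                                   list(stringsAsFactors = FALSE,
                                        KEEP.OUT.ATTRS = FALSE)))
    do.call(paste0, grid)
  }))
}

## Oracle helpers operate on a character vector `s`; they return sorted
## bond indices in [1, length(s) - 1].

oracle_staph_peptidase <- function(s) {
  n <- length(s)
  sites <- which(vapply(seq_len(n), function(i) {
    s[i] == "e" && (i == 1L || s[i - 1L] != "e")
  }, logical(1L)))
  sites[sites >= 1L & sites <= n - 1L]
}

oracle_hydroxylamine <- function(s) {
  n <- length(s)
  sites <- which(vapply(seq_len(n), function(i) {
    s[i] == "n" && i < n && s[i + 1L] == "g"
  }, logical(1L)))
  sites[sites >= 1L & sites <= n - 1L]
}

oracle_thrombin_sg <- function(s) {
  n <- length(s)
  sites <- which(vapply(seq_len(n), function(i) {
    i >= 4L && i + 2L <= n &&
      identical(s[(i - 3L):(i + 2L)], c("l", "v", "p", "r", "g", "s"))
  }, logical(1L)))
  sites[sites >= 1L & sites <= n - 1L]
}

oracle_bromelain <- function(s) {
  n <- length(s)
  sites <- which(s %in% c("k", "a", "y"))
  sites[sites >= 1L & sites <= n - 1L]
}

## Trypsin, transcribed from its prose description: cleaves after k/r;
## p in P1' blocks, except for w-k-p and m-r-p; d/c in P2 with d/h/y in
## P1', and r/c in P2 with h/r/k in P1', considerably block.
oracle_trypsin <- function(s) {
  n <- length(s)
  at <- function(i) if (i >= 1L && i <= n) s[i] else ""
  cleaves <- function(i) {
    res <- s[i]
    if (!res %in% c("k", "r")) {
      return(FALSE)
    }
    nxt <- at(i + 1L)
    prv <- at(i - 1L)
    if (nxt == "p") {
      return((res == "k" && prv == "w") || (res == "r" && prv == "m"))
    }
    if (res == "k") {
      blocked <- (prv == "d" && nxt == "d") ||
        (prv == "c" && nxt %in% c("d", "h", "y"))
    } else {
      blocked <- (prv == "r" && nxt %in% c("h", "r")) ||
        (prv == "c" && nxt == "k")
    }
    !blocked
  }
  sites <- which(vapply(seq_len(n), cleaves, logical(1L)))
  sites[sites >= 1L & sites <= n - 1L]
}

expect_engine_matches_oracle <- function(enzyme, oracle, alphabet, max_len) {
  seqs <- enumerate_sequences(alphabet, max_len)
  for (sq in seqs) {
    chars <- strsplit(sq, "", fixed = TRUE)[[1L]]
    got <- find_sites(sq, enzyme)
    want <- as.integer(oracle(chars))
    if (!identical(got, want)) {
      fail(sprintf("site sets differ on '%s': engine {%s}, oracle {%s}",
                   sq, paste(got, collapse = ","),
                   paste(want, collapse = ",")))
      return(invisible(FALSE))
    }
  }
  succeed()
  invisible(TRUE)
}

## The expanded trypsin definition (one rule/exception per residue pair).
trypsin_expanded <- function() {
  compile_enzyme("trypsin-expanded",
    rules = c("(k,)", "(r,)", "(w)(k,)(p)", "(m)(r,)(p)"),
    exceptions = c("(k,)(p)", "(r,)(p)", "(d)(k,)(d)", "(c)(k,)(d)",
                   "(c)(k,)(h)", "(c)(k,)(y)", "(r)(r,)(h)", "(c)(r,)(k)",
                   "(r)(r,)(r)"))
}

## Random peptide over the 20 standard residues.
random_peptide <- function(len) {
  paste(sample(setdiff(protcleave:::RESIDUE_ALPHABET, c("o", "u")),
               len, replace = TRUE), collapse = "")
}

## Independent grid-search pI oracle: dense pH grid, own charge formula
## written from the rearranged Henderson-Hasselbalch equations and the
## published pKa table (not calling the package's net_charge).
grid_pi_oracle_factory <- function(set_name = "ipc_peptide",
                                   step = 0.001) {
  tabs <- list(
    ipc_peptide = list(
      pos = c(n_term = 9.564, h = 6.018, k = 10.517, r = 12.503),
      neg = c(c_term = 2.383, c = 8.297, d = 3.887, e = 4.317, y = 10.071)
    ),
    typical = list(
      pos = c(n_term = 8.0, h = 6.0, k = 10.8, r = 12.5),
      neg = c(c_term = 3.1, c = 8.3, d = 4.1, e = 4.1, y = 10.9)
    )
  )
  tab <- tabs[[set_name]]
  ph <- seq(0, 14, by = step)
  ## unit-charge curves per group, one column per ionizable group
  pos_curves <- vapply(tab$pos, function(pk) 1 / (1 + 10^(ph - pk)),
                       numeric(length(ph)))
  neg_curves <- vapply(tab$neg, function(pk) -1 / (1 + 10^(pk - ph)),
                       numeric(length(ph)))
  function(sequence) {
    s <- strsplit(tolower(sequence), "", fixed = TRUE)[[1L]]
    pos_n <- c(n_term = 1, h = sum(s == "h"), k = sum(s == "k"),
               r = sum(s == "r"))
    neg_n <- c(c_term = 1, c = sum(s == "c"), d = sum(s == "d"),
               e = sum(s == "e"), y = sum(s == "y"))
    q <- as.numeric(pos_curves %*% pos_n + neg_curves %*% neg_n)
    ph[which.min(abs(q))]
  }
}
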