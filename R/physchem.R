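## Peptide physicochemistry: average molecular mass, net charge at a given
## pH from rearranged Henderson-Hasselbalch equations, and isoelectric point
## by binary search.

## Average residue masses (Da), ExPASy values; 22 residues including
## pyrrolysine (o) and selenocysteine (u).
RESIDUE_MASSES <- c(
  a = 71.0788,  c = 103.1388, d = 115.0886, e = 129.1155, f = 147.1766,
  g = 57.0519,  h = 137.1411, i = 113.1594, k = 128.1741, l = 113.1594,
  m = 131.1926, n = 114.1038, o = 237.3018, p = 97.1167,  q = 128.1307,
  r = 156.1875, s = 87.0782,  t = 101.1051, u = 150.0388, v = 99.1326,
  w = 186.2132, y = 163.1760
)

## Average mass of one water molecule (Da), added once per peptide:
## proteolysis puts H on the new N-terminus and OH on the new C-terminus.
WATER_MASS <- 18.01528

## pKa tables. Signs: +1 for the N-terminus and the basic side chains
## (H, K, R); -1 for the C-terminus and the acidic side chains (C, D, E, Y).
PKA_SETS <- list(
  ipc_peptide = list(
    positive = c(n_term = 9.564, h = 6.018, k = 10.517, r = 12.503),
    negative = c(c_term = 2.383, c = 8.297, d = 3.887, e = 4.317, y = 10.071)
  ),
  typical = list(
    positive = c(n_term = 8.0, h = 6.0, k = 10.8, r = 12.5),
    negative = c(c_term = 3.1, c = 8.3, d = 4.1, e = 4.1, y = 10.9)
  )
)

#' pKa sets for charge and isoelectric-point estimation
#'
#' Two built-in tables of acid dissociation constants for the ionizable
#' groups of a peptide (N-terminus, C-terminus and the C, D, E, H, K, R, Y
#' side chains): `"ipc_peptide"` (the peptide-calibrated IPC values, the
#' default throughout the package) and `"typical"` (textbook values).
#'
#' @param name `"ipc_peptide"` or `"typical"`.
#' @return A list with named numeric vectors `positive` and `negative`.
#' @examples
#' pka_set("ipc_peptide")$positive
#' @export
pka_set <- function(name = c("ipc_peptide", "typical")) {
  name <- match.arg(name)
  PKA_SETS[[name]]
}

#' Average molecular mass of a peptide
#'
#' Sums the average isotopic residue masses and adds the average mass of one
#' water molecule (18.01528 Da) for the peptide's termini. Masses are
#' reported downstream to four decimals; this function returns the full
#' floating-point value.
#'
#' @param sequence Amino-acid sequence (case-insensitive, 22-letter
#'   alphabet; ambiguity codes such as B/Z/X are rejected).
#' @return Mass in Dalton.
#' @examples
#' round(peptide_mass("ae"), 4) # 218.2096
#' round(peptide_mass("g"), 4)  # 75.0672
#' @export
peptide_mass <- function(sequence) {
  chars <- seq_chars(sequence)
  sum(RESIDUE_MASSES[chars]) + WATER_MASS
}

## Charge contributions from a residue composition at pH values `ph`
## (vectorized over ph). counts: named counts of ionizable side chains.
charge_from_groups <- function(ph, pos_pka, neg_pka, pos_n, neg_n) {
  pos <- vapply(ph, function(p) {
    sum(pos_n / (1 + 10^(p - pos_pka)))
  }, numeric(1L))
  neg <- vapply(ph, function(p) {
    sum(-neg_n / (1 + 10^(neg_pka - p)))
  }, numeric(1L))
  pos + neg
}

ionizable_counts <- function(chars, set) {
  pos_groups <- names(set$positive)
  neg_groups <- names(set$negative)
  pos_n <- vapply(pos_groups, function(g) {
    if (g == "n_term") 1 else sum(chars == g)
  }, numeric(1L))
  neg_n <- vapply(neg_groups, function(g) {
    if (g == "c_term") 1 else sum(chars == g)
  }, numeric(1L))
  list(pos_pka = set$positive, neg_pka = set$negative,
       pos_n = pos_n, neg_n = neg_n)
}

#' Net charge of a peptide at a given pH
#'
#' Rearranged Henderson-Hasselbalch model: each positively ionizable group
#' (N-terminus, H, K, R) contributes `1 / (1 + 10^(pH - pKa))`, each
#' negatively ionizable group (C-terminus, C, D, E, Y) contributes
#' `-1 / (1 + 10^(pKa - pH))`; other residues contribute nothing. The model
#' is compositional: residue order does not matter.
#'
#' @inheritParams peptide_mass
#' @param ph Numeric vector of pH values in `[0, 14]`.
#' @param pka "ipc_peptide" (default) or "typical", or a list as returned by
#'   [pka_set()].
#' @return Numeric vector of net charges, one per element of `ph`.
#' @examples
#' net_charge("g", 7)            # slightly negative: pI of glycine is 5.97
#' net_charge("kk", c(4, 7, 11)) # strictly decreasing in pH
#' @export
net_charge <- function(sequence, ph, pka = "ipc_peptide") {
  set <- if (is.character(pka)) pka_set(pka) else pka
  if (any(ph < 0 | ph > 14)) pc_stop_data("pH must lie in [0, 14]")
  cnt <- ionizable_counts(seq_chars(sequence), set)
  charge_from_groups(ph, cnt$pos_pka, cnt$neg_pka, cnt$pos_n, cnt$neg_n)
}

#' Isoelectric point of a peptide
#'
#' Binary search for the pH of zero net charge: starting from the interval
#' `[0, 14]` (first evaluation at pH 7), the net charge at the interval
#' midpoint decides which half to keep; the search stops when the interval
#' is narrower than `accuracy` and returns its midpoint. Every peptide has
#' both termini, so a unique root always exists inside (0, 14) for both
#' built-in pKa sets.
#'
#' @inheritParams net_charge
#' @param accuracy Width of the final search interval (pH units).
#' @return Estimated pI (pH units).
#' @examples
#' isoelectric_point("g")                   # 5.97 +/- 0.01
#' isoelectric_point("g", pka = "typical")  # 5.55 +/- 0.01
#' @export
isoelectric_point <- function(sequence, pka = "ipc_peptide",
                              accuracy = 0.01) {
  set <- if (is.character(pka)) pka_set(pka) else pka
  cnt <- ionizable_counts(seq_chars(sequence), set)
  lo <- 0
  hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    if ((hi - lo) < accuracy) {
      return(mid)
    }
    q <- charge_from_groups(mid, cnt$pos_pka, cnt$neg_pka,
                            cnt$pos_n, cnt$neg_n)
    if (q < 0) hi <- mid else lo <- mid
  }
}
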