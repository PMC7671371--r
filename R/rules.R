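## Recursive cleavage-rule model.
##
## A protease is a list of rule trees. Each node names a residue set at a
## signed offset from the anchor (the P1 residue for C-side cutters, the P1'
## residue for N-side cutters), carries a cleave/do-not-cleave flag and an
## ordered list of sub-rules refining it. Offset 0 is the anchor, -1 one
## residue N-terminal (P2 for an `after` rule), +1 one residue C-terminal.

#' Construct a cleavage-rule node
#'
#' Low-level constructor for one node of a protease's recursive rule tree.
#' Most users should write grammar definitions and call
#' [compile_enzyme()] instead.
#'
#' @param residues Character vector of single-letter residue codes this node
#'   matches, or `NULL` for a wildcard that matches any residue (the matched
#'   position must still lie inside the sequence).
#' @param index Signed integer offset relative to the anchor position.
#' @param cleave Logical; the decision this node contributes when it is the
#'   deepest matching node on its branch.
#' @param side `"after"` or `"before"`: which side of the anchor the scissile
#'   bond lies on. Only meaningful on root nodes (`index == 0`); sub-rules
#'   inherit the root's side and the argument is ignored for them.
#' @param sub_rules List of child `cleavage_rule` nodes (exceptions and
#'   refinements).
#' @return A `cleavage_rule` object.
#' @examples
#' # staphylococcal peptidase I: cleave after e, unless preceded by e
#' cleavage_rule("e", 0, TRUE, "after",
#'   list(cleavage_rule("e", -1, FALSE))
#' )
#' @export
cleavage_rule <- function(residues, index = 0L, cleave = TRUE,
                          side = c("after", "before"), sub_rules = list()) {
  side <- match.arg(side)
  if (!is.null(residues)) {
    residues <- sort(unique(tolower(residues)))
    bad <- setdiff(residues, RESIDUE_ALPHABET)
    if (length(bad)) {
      pc_stop_data(sprintf("unknown residue code '%s' in rule", bad[1L]))
    }
  }
  structure(
    list(
      residues = residues,
      index = as.integer(index),
      cleave = isTRUE(cleave),
      side = side,
      sub_rules = sub_rules
    ),
    class = "cleavage_rule"
  )
}

#' Construct a protease from rule trees
#'
#' @param name Nonempty identifier string.
#' @param rules List of root `cleavage_rule` nodes (each with `index == 0`).
#' @param expressions Optional list of parsed grammar expressions retained for
#'   pretty-printing (filled by [compile_enzyme()]).
#' @param default_miscleavage Missed-cleavage probability in percent, `[0, 100]`.
#' @return A `protease` object.
#' @seealso [compile_enzyme()], [load_enzyme()]
#' @export
protease <- function(name, rules, expressions = list(),
                     default_miscleavage = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    pc_stop_data("protease name must be a nonempty string")
  }
  if (!length(rules)) {
    pc_stop_data(sprintf("protease '%s' has no rules", name))
  }
  for (r in rules) {
    if (!inherits(r, "cleavage_rule") || r$index != 0L) {
      pc_stop_data(sprintf(
        "protease '%s': every root rule must be a cleavage_rule with index 0",
        name
      ))
    }
  }
  if (default_miscleavage < 0 || default_miscleavage > 100) {
    pc_stop_data("default_miscleavage must be in [0, 100]")
  }
  structure(
    list(
      name = name,
      rules = rules,
      expressions = expressions,
      default_miscleavage = default_miscleavage
    ),
    class = "protease"
  )
}

#' @export
print.protease <- function(x, ...) {
  cat(format_enzyme(x), sep = "\n")
  invisible(x)
}

## Does `node` match around anchor position `pos` (1-based)?
## Out-of-bounds offsets never match: a context residue beyond a fragment
## end cannot satisfy (or block) a rule.
node_matches <- function(node, chars, pos) {
  p <- pos + node$index
  if (p < 1L || p > length(chars)) {
    return(FALSE)
  }
  is.null(node$residues) || chars[p] %in% node$residues
}

## Effective cleave decision of a matched node: if no sub-rule matches, the
## node's own flag stands; otherwise the decision is the conjunction of the
## decisions of all matching sub-branches (a blocking exception dominates a
## permissive sibling; rules that re-enable cleavage inside an exception's
## context are nested *under* that exception node by the compiler).
resolve_rule <- function(node, chars, pos) {
  decision <- NA
  for (child in node$sub_rules) {
    if (node_matches(child, chars, pos)) {
      d <- resolve_rule(child, chars, pos)
      decision <- if (is.na(decision)) d else decision && d
      if (!decision) {
        return(FALSE)
      }
    }
  }
  if (is.na(decision)) node$cleave else decision
}

#' Decide whether an enzyme cleaves at one position
#'
#' Applies every root rule of `enzyme` anchored at residue `pos` of
#' `sequence` and returns the scissile-bond index if any root's resolved
#' decision is to cleave. Bond `b` lies between residues `b` and `b + 1`
#' (1-based); bonds at 0 or at the sequence end are suppressed so that no
#' empty peptide can be produced.
#'
#' @param sequence Amino-acid sequence (case-insensitive).
#' @param pos 1-based residue position to anchor the rules at.
#' @param enzyme A `protease` object.
#' @return Integer bond index in `[1, nchar(sequence) - 1]`, or
#'   `integer(0)` if no cleavage occurs at `pos`.
#' @examples
#' sp1 <- load_enzyme("staphylococcal-peptidase-i")
#' evaluate_position("aeert", 2, sp1) # bond 2: ae | ert
#' evaluate_position("aeert", 3, sp1) # no cleavage (e preceded by e)
#' @export
evaluate_position <- function(sequence, pos, enzyme) {
  chars <- seq_chars(sequence)
  if (pos < 1L || pos > length(chars)) {
    pc_stop_data(sprintf("position %d outside sequence of length %d",
                         pos, length(chars)))
  }
  evaluate_position_chars(chars, as.integer(pos), enzyme)
}

evaluate_position_chars <- function(chars, pos, enzyme) {
  n <- length(chars)
  res <- chars[pos]
  for (root in enzyme$rules) {
    if (!(res %in% root$residues) && !is.null(root$residues)) next
    if (resolve_rule(root, chars, pos)) {
      bond <- if (root$side == "after") pos else pos - 1L
      if (bond >= 1L && bond <= n - 1L) {
        return(bond)
      }
    }
  }
  integer(0)
}

#' Find all cleavage sites of an enzyme on a sequence
#'
#' Scans the sequence residue by residue, applies [evaluate_position()] at
#' each and returns the sorted, duplicate-free set of scissile-bond indices.
#'
#' @inheritParams evaluate_position
#' @return Sorted integer vector of bond indices (possibly empty); every
#'   value lies strictly between 0 and `nchar(sequence)`.
#' @examples
#' find_sites("aeert", load_enzyme("staphylococcal-peptidase-i")) # 2
#' find_sites("kkkk", load_enzyme("trypsin")) # 1 2 3
#' @export
find_sites <- function(sequence, enzyme) {
  find_sites_chars(seq_chars(sequence), enzyme)
}

find_sites_chars <- function(chars, enzyme) {
  anchors <- unlist(lapply(enzyme$rules, `[[`, "residues"))
  wildcard_anchor <- any(vapply(enzyme$rules,
                                function(r) is.null(r$residues), logical(1L)))
  cand <- if (wildcard_anchor) seq_along(chars) else which(chars %in% anchors)
  if (!length(cand)) {
    return(integer(0))
  }
  sites <- integer(0)
  for (pos in cand) {
    b <- evaluate_position_chars(chars, pos, enzyme)
    if (length(b)) sites <- c(sites, b)
  }
  sort(unique(sites))
}

## Widest context window (max |offset|) referenced by an enzyme's rules;
## used by locality checks and tests.
rule_window <- function(enzyme) {
  walk <- function(node) {
    w <- abs(node$index)
    for (child in node$sub_rules) w <- max(w, walk(child))
    w
  }
  max(vapply(enzyme$rules, walk, numeric(1L)))
}
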