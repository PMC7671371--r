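## Protease-definition grammar.
##
## A definition line describes one cleavage rule in Schechter-Berger
## coordinates. Each parenthesis system is one position (P2)(P1,)(P1');
## a comma marks the scissile bond, `or` builds residue alternatives inside
## a system, and `()` is a wildcard position. Examples:
##   (n,)(g)                      cleave between n (P1) and g (P1')
##   (k or a or y,)               cleave after k, a or y
##   (,f or l or w or y,)         cleave before AND after f/l/w/y (two rules)
##   (e)()()(y)()(q,)(g or s)     TEV: full seven-position context
## The bare form (no parentheses, e.g. `n,g`) is allowed only when every
## position holds a single residue; any `or` requires full parenthesization.

#' Tokenize a protease-definition line
#'
#' Splits one grammar line into tokens: residue letters, parentheses, commas
#' and the keyword `or`. Uppercase letters are lowercased, whitespace is
#' insignificant. A letter run that is not `or` is split into individual
#' residue tokens, so `ac` tokenizes as residues `a`, `c`.
#'
#' @param text Character scalar, one rule per line.
#' @return A data frame with columns `type` (`res`, `lparen`, `rparen`,
#'   `comma`, `or`), `value` and `col` (1-based source column).
#' @examples
#' tokenize_rule("(n,)(g)")
#' @export
tokenize_rule <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    pc_stop_parse("rule text must be a single character string")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  type <- character(0)
  value <- character(0)
  col <- integer(0)
  push <- function(t, v, cc) {
    type <<- c(type, t)
    value <<- c(value, v)
    col <<- c(col, cc)
  }
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch == "(") {
      push("lparen", ch, i); i <- i + 1L
    } else if (ch == ")") {
      push("rparen", ch, i); i <- i + 1L
    } else if (ch == ",") {
      push("comma", ch, i); i <- i + 1L
    } else if (grepl("^[A-Za-z]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z]$", chars[j])) j <- j + 1L
      word <- tolower(paste(chars[i:(j - 1L)], collapse = ""))
      if (word == "or") {
        push("or", word, i)
      } else {
        letters_ <- strsplit(word, "", fixed = TRUE)[[1L]]
        for (k in seq_along(letters_)) {
          if (!letters_[k] %in% RESIDUE_ALPHABET) {
            pc_stop_parse(sprintf(
              "syntax error at column %d: illegal character '%s'",
              i + k - 1L, letters_[k]
            ))
          }
          push("res", letters_[k], i + k - 1L)
        }
      }
      i <- j
    } else {
      pc_stop_parse(sprintf(
        "syntax error at column %d: illegal character '%s'", i, ch
      ))
    }
  }
  data.frame(type = type, value = value, col = col,
             stringsAsFactors = FALSE)
}

## A parsed rule expression: one cleavage site in one rule.
new_rule_expression <- function(systems, anchor, side, is_exception) {
  structure(
    list(systems = systems, anchor = anchor, side = side,
         is_exception = is_exception),
    class = "rule_expression"
  )
}

#' @export
print.rule_expression <- function(x, ...) {
  cat(format_rule_expression(x), "\n")
  invisible(x)
}

#' Render a parsed rule expression back in grammar form
#'
#' @param expr A `rule_expression` as returned by [parse_rule()].
#' @return Character scalar in fully parenthesized grammar notation.
#' @export
format_rule_expression <- function(expr) {
  out <- vapply(seq_along(expr$systems), function(j) {
    sys <- expr$systems[[j]]
    inner <- if (is.null(sys)) "" else paste(sys, collapse = " or ")
    if (j == expr$anchor) {
      inner <- if (expr$side == "after") paste0(inner, ",")
               else paste0(",", inner)
    }
    paste0("(", inner, ")")
  }, character(1L))
  paste(out, collapse = "")
}

#' Parse a protease-definition line
#'
#' Parses one grammar line into one or two rule expressions. A line holds an
#' ordered series of position systems; exactly one system carries the comma
#' marking the scissile bond. The two-comma form `(,x,)` (cleave before and
#' after `x`) expands into two expressions. The bare, parenthesis-free form
#' (`n,g`) is accepted only when every position is a single residue; any use
#' of `or` must be fully parenthesized, because e.g. `ac, or d,` could mean
#' either "after c or d with a in P2" or "after c (with a in P2) or after d".
#'
#' @param text Character scalar, one rule.
#' @param is_exception Logical; marks the expression as an exception (a
#'   blocker attached to already-defined main rules by [compile_enzyme()]).
#' @return List of `rule_expression` objects (length 1, or 2 for `(,x,)`).
#' @examples
#' parse_rule("(n,)(g)")
#' parse_rule("(,f or l or w or y,)") # expands to two expressions
#' @export
parse_rule <- function(text, is_exception = FALSE) {
  toks <- tokenize_rule(text)
  if (!nrow(toks)) pc_stop_parse("empty rule")
  has_paren <- any(toks$type == "lparen")

  ## systems: list of (residues | NULL); commas: data.frame(system, side)
  systems <- list()
  commas <- list()

  if (!has_paren) {
    if (any(toks$type == "or")) {
      pc_stop_parse(paste0(
        "ambiguous rule '", text, "': 'or' requires every position to be ",
        "parenthesized (a parenthesis system denotes one position)"
      ))
    }
    if (any(toks$type == "rparen")) {
      pc_stop_parse(sprintf("unbalanced parentheses in '%s'", text))
    }
    pending_before <- FALSE
    for (i in seq_len(nrow(toks))) {
      t <- toks$type[i]
      if (t == "res") {
        systems[[length(systems) + 1L]] <- toks$value[i]
        if (pending_before) {
          commas[[length(commas) + 1L]] <-
            list(system = length(systems), side = "before")
          pending_before <- FALSE
        }
      } else if (t == "comma") {
        ## a comma between two residues marks the bond after the residue it
        ## follows; a leading comma attaches before the next residue
        if (length(systems) && !pending_before) {
          commas[[length(commas) + 1L]] <-
            list(system = length(systems), side = "after")
        } else {
          pending_before <- TRUE
        }
      }
    }
    if (pending_before) {
      pc_stop_parse(sprintf("dangling comma in '%s'", text))
    }
  } else {
    i <- 1L
    n <- nrow(toks)
    while (i <= n) {
      if (toks$type[i] != "lparen") {
        pc_stop_parse(sprintf(
          "column %d: expected '(' (every position must be parenthesized)",
          toks$col[i]
        ))
      }
      i <- i + 1L
      lead_comma <- FALSE
      trail_comma <- FALSE
      residues <- character(0)
      if (i <= n && toks$type[i] == "comma") {
        lead_comma <- TRUE
        i <- i + 1L
      }
      expect_res <- TRUE
      while (i <= n && toks$type[i] %in% c("res", "or")) {
        if (toks$type[i] == "res") {
          if (!expect_res) {
            pc_stop_parse(sprintf(
              "column %d: residues inside a position must be separated by 'or'",
              toks$col[i]
            ))
          }
          residues <- c(residues, toks$value[i])
          expect_res <- FALSE
        } else {
          if (expect_res) {
            pc_stop_parse(sprintf("column %d: misplaced 'or'", toks$col[i]))
          }
          expect_res <- TRUE
        }
        i <- i + 1L
      }
      if (expect_res && length(residues)) {
        pc_stop_parse("rule ends with a dangling 'or'")
      }
      if (i <= n && toks$type[i] == "comma") {
        trail_comma <- TRUE
        i <- i + 1L
      }
      if (i > n || toks$type[i] != "rparen") {
        pc_stop_parse(sprintf("unbalanced or malformed parentheses in '%s'",
                              text))
      }
      i <- i + 1L
      ## note: `[<- list(...)` keeps a NULL wildcard as a real element
      systems[length(systems) + 1L] <-
        list(if (length(residues)) sort(unique(residues)) else NULL)
      if (lead_comma) {
        commas[[length(commas) + 1L]] <-
          list(system = length(systems), side = "before")
      }
      if (trail_comma) {
        commas[[length(commas) + 1L]] <-
          list(system = length(systems), side = "after")
      }
      if ((lead_comma || trail_comma) && !length(residues)) {
        pc_stop_parse(sprintf(
          "the cleavage position in '%s' cannot be a wildcard '()'", text
        ))
      }
    }
  }

  if (!length(systems)) pc_stop_parse(sprintf("no positions in '%s'", text))
  n_commas <- length(commas)
  if (n_commas == 0L) {
    pc_stop_parse(sprintf(
      "rule '%s' has no comma: the cleavage site must be marked", text
    ))
  }
  if (n_commas > 2L) {
    pc_stop_parse(sprintf("rule '%s' has more than two commas", text))
  }
  if (n_commas == 2L) {
    if (commas[[1L]]$system != commas[[2L]]$system ||
        commas[[1L]]$side == commas[[2L]]$side) {
      pc_stop_parse(sprintf(
        "rule '%s': two commas are only allowed before and after the same position",
        text
      ))
    }
  }
  lapply(commas, function(cm) {
    new_rule_expression(systems, cm$system, cm$side, isTRUE(is_exception))
  })
}

## Context specs of an expression: offsets and residue sets of every
## non-anchor system, ordered by |offset| ascending, C-side (positive)
## first on ties. The ordering fixes where rule chains and exception chains
## share nodes.
context_specs <- function(expr) {
  idx <- setdiff(seq_along(expr$systems), expr$anchor)
  if (!length(idx)) {
    return(list())
  }
  off <- idx - expr$anchor
  ord <- order(abs(off), off < 0L)
  lapply(ord, function(k) {
    list(residues = expr$systems[[idx[k]]], index = off[k])
  })
}

same_residue_set <- function(a, b) {
  (is.null(a) && is.null(b)) ||
    (!is.null(a) && !is.null(b) && identical(sort(a), sort(b)))
}

## Insert a context chain into a sub-rule list, sharing an existing node when
## residue set, offset and flag coincide (so a re-enabling rule like
## (w)(k,)(p) nests its refinement under the shared (k,)(p) exception node).
insert_chain <- function(subs, specs, leaf_flag, mid_flag) {
  spec <- specs[[1L]]
  flag <- if (length(specs) == 1L) leaf_flag else mid_flag
  hit <- 0L
  for (j in seq_along(subs)) {
    nd <- subs[[j]]
    if (nd$index == spec$index && nd$cleave == flag &&
        same_residue_set(nd$residues, spec$residues)) {
      hit <- j
      break
    }
  }
  if (hit) {
    node <- subs[[hit]]
  } else {
    node <- cleavage_rule(spec$residues, spec$index, flag)
  }
  if (length(specs) > 1L) {
    node$sub_rules <- insert_chain(node$sub_rules, specs[-1L],
                                   leaf_flag, mid_flag)
  }
  if (hit) subs[[hit]] <- node else subs <- c(subs, list(node))
  subs
}

#' Compile grammar definitions into a protease
#'
#' Turns an ordered list of grammar lines into the recursive rule trees of a
#' [protease()]. Each main rule creates one root per residue of its
#' comma-marked position (alternatives produced by `or` share their context
#' sub-trees); context positions become chained sub-rules at their signed
#' offsets, with the deepest required node carrying the cleave decision. An
#' exception attaches, as a blocking sub-tree, to every already-defined root
#' whose anchor residue and cleavage side it names -- so exceptions must
#' follow the main rules they modify.
#'
#' @param name Enzyme name.
#' @param rules Character vector of main-rule lines.
#' @param exceptions Character vector of exception lines.
#' @param default_miscleavage Missed-cleavage percentage in `[0, 100]`.
#' @return A `protease` object.
#' @examples
#' hx <- compile_enzyme("hydroxylamine", "(n,)(g)")
#' find_sites("angq", hx) # bond 2: an | gq
#' sp1 <- compile_enzyme("sp1", "(e,)", exceptions = "(e)(e,)")
#' find_sites("aeert", sp1) # bond 2 only
#' @export
compile_enzyme <- function(name, rules, exceptions = character(0),
                           default_miscleavage = 0) {
  lines <- c(
    lapply(rules, function(tx) list(text = tx, is_exception = FALSE)),
    lapply(exceptions, function(tx) list(text = tx, is_exception = TRUE))
  )
  compile_enzyme_lines(name, lines, default_miscleavage)
}

## lines: list of list(text=, is_exception=) in declaration order.
compile_enzyme_lines <- function(name, lines, default_miscleavage = 0) {
  roots <- list()
  expressions <- list()
  for (ln in lines) {
    exprs <- parse_rule(ln$text, is_exception = ln$is_exception)
    for (expr in exprs) {
      expressions[[length(expressions) + 1L]] <- expr
      specs <- context_specs(expr)
      anchor_set <- expr$systems[[expr$anchor]]
      if (!expr$is_exception) {
        for (r in anchor_set) {
          root <- cleavage_rule(r, 0L,
                                cleave = !length(specs), side = expr$side)
          if (length(specs)) {
            root$sub_rules <- insert_chain(list(), specs,
                                           leaf_flag = TRUE, mid_flag = FALSE)
          }
          roots[[length(roots) + 1L]] <- root
        }
      } else {
        matched <- FALSE
        for (j in seq_along(roots)) {
          root <- roots[[j]]
          if (root$side != expr$side || !root$residues %in% anchor_set) next
          matched <- TRUE
          if (!length(specs)) {
            root$cleave <- FALSE
          } else {
            root$sub_rules <- insert_chain(root$sub_rules, specs,
                                           leaf_flag = FALSE,
                                           mid_flag = root$cleave)
          }
          roots[[j]] <- root
        }
        if (!matched) {
          pc_stop_parse(sprintf(
            "enzyme '%s': exception '%s' has no matching main rule (every exception must be linked to a main rule)",
            name, ln$text
          ))
        }
      }
    }
  }
  protease(name, roots, expressions, default_miscleavage)
}

#' Render a protease definition in grammar form
#'
#' @param enzyme A `protease`.
#' @return Character vector of definition lines (`NAME:`, `RULE:`,
#'   `EXCEPTION:`), suitable for an enzyme-definition file.
#' @export
format_enzyme <- function(enzyme) {
  out <- sprintf("NAME: %s", enzyme$name)
  for (expr in enzyme$expressions) {
    tag <- if (expr$is_exception) "EXCEPTION" else "RULE"
    out <- c(out, sprintf("%s: %s", tag, format_rule_expression(expr)))
  }
  if (length(out) == 1L) {
    out <- c(out, "# (defined programmatically; no grammar source retained)")
  }
  out
}

#' Test behavioral equivalence of two proteases by exhaustive enumeration
#'
#' Enumerates every sequence up to `max_len` over `alphabet` and compares the
#' cleavage-site sets of the two enzymes. Intended for small alphabets and
#' lengths (at most ~7 residues over ~6 letters).
#'
#' @param enzyme_a,enzyme_b `protease` objects.
#' @param alphabet Character vector of residue letters to enumerate over.
#' @param max_len Maximum sequence length to enumerate.
#' @return `TRUE` if the site sets agree on every enumerated sequence,
#'   otherwise `FALSE` (invisibly carrying the first counterexample in
#'   attribute `"counterexample"`).
#' @examples
#' a <- compile_enzyme("a", "(a or b,)")
#' b <- compile_enzyme("b", c("(a,)", "(b,)"))
#' equivalent(a, b, c("a", "b", "c"), 4)
#' @export
equivalent <- function(enzyme_a, enzyme_b, alphabet, max_len) {
  alphabet <- tolower(alphabet)
  stopifnot(all(alphabet %in% RESIDUE_ALPHABET), max_len >= 1L)
  for (len in seq_len(max_len)) {
    grid <- as.matrix(do.call(expand.grid, c(
      rep(list(alphabet), len),
      list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    )))
    for (i in seq_len(nrow(grid))) {
      chars <- grid[i, ]
      sa <- find_sites_chars(chars, enzyme_a)
      sb <- find_sites_chars(chars, enzyme_b)
      if (!identical(sa, sb)) {
        res <- FALSE
        attr(res, "counterexample") <- paste(chars, collapse = "")
        return(res)
      }
    }
  }
  TRUE
}
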