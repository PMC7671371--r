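test_that("tokenizer splits rules into residues, parentheses, commas and 'or'", {
  toks <- tokenize_rule("(n,)(g)")
  expect_identical(toks$type,
                   c("lparen", "res", "comma", "rparen",
                     "lparen", "res", "rparen"))
  expect_identical(toks$value[c(2, 6)], c("n", "g"))

  toks <- tokenize_rule("(k or a or y,)")
  expect_identical(sum(toks$type == "or"), 2L)
  expect_identical(toks$value[toks$type == "res"], c("k", "a", "y"))

  # uppercase is folded, whitespace ignored
  expect_identical(tokenize_rule(" ( N , ) ( G ) ")$value[c(2, 6)],
                   c("n", "g"))
  # a letter run that is not 'or' is a residue sequence; it tokenizes fine
  # and only the parser rejects the ambiguous construct
  expect_silent(tokenize_rule("ac, or d,"))
  err <- tryCatch(tokenize_rule("(b?)"), condition = identity)
  expect_s3_class(err, "protcleave_parse_error")
  expect_match(conditionMessage(err), "column")
})

test_that("parser builds position systems with a single marked cleavage site", {
  ex <- parse_rule("(n,)(g)")
  expect_length(ex, 1)
  expect_identical(ex[[1]]$systems, list("n", "g"))
  expect_identical(ex[[1]]$anchor, 1L)
  expect_identical(ex[[1]]$side, "after")

  ex <- parse_rule("n,g") # bare form
  expect_identical(ex[[1]]$systems, list("n", "g"))
  expect_identical(ex[[1]]$anchor, 1L)

  ex <- parse_rule("(d or e)(d or e)(d or e)(d or e)(k,)")
  expect_length(ex[[1]]$systems, 5)
  expect_identical(ex[[1]]$anchor, 5L)

  # wildcard positions stay as explicit empty systems
  ex <- parse_rule("(e)()()(y)()(q,)(g or s)")
  expect_length(ex[[1]]$systems, 7)
  expect_null(ex[[1]]$systems[[2]])
  expect_identical(ex[[1]]$systems[[7]], c("g", "s"))
})

test_that("two commas in one system expand to a before- and an after-rule", {
  ex <- parse_rule("(,f or l or w or y,)")
  expect_length(ex, 2)
  sides <- vapply(ex, `[[`, character(1), "side")
  expect_setequal(sides, c("before", "after"))
  expect_identical(ex[[1]]$systems, ex[[2]]$systems)
})

test_that("malformed rules are rejected with located errors", {
  expect_error(parse_rule("(n)(g)"), "no comma",
               class = "protcleave_parse_error")
  expect_error(parse_rule("(a,)(b,)"), class = "protcleave_parse_error")
  expect_error(parse_rule("(,a)(b,)"), class = "protcleave_parse_error")
  expect_error(parse_rule("(a,)(g"), "parenthes",
               class = "protcleave_parse_error")
  expect_error(parse_rule("ac, or d,"), "ambiguous",
               class = "protcleave_parse_error")
  expect_error(parse_rule("(,)"), class = "protcleave_parse_error")
  expect_error(parse_rule("(a or ,)"), class = "protcleave_parse_error")
  expect_error(parse_rule(""), class = "protcleave_parse_error")
})

test_that("compiled rule trees carry the expected structure", {
  hx <- compile_enzyme("hx", "(n,)(g)")
  expect_length(hx$rules, 1)
  root <- hx$rules[[1]]
  expect_identical(root$residues, "n")
  expect_false(root$cleave) # context required: decision sits on the sub-rule
  expect_identical(root$side, "after")
  expect_length(root$sub_rules, 1)
  expect_identical(root$sub_rules[[1]]$residues, "g")
  expect_identical(root$sub_rules[[1]]$index, 1L)
  expect_true(root$sub_rules[[1]]$cleave)

  # three roots for chymotrypsin-high; all carry the p exception, only the
  # w root carries the m exception
  ch <- compile_enzyme("ch", "(f or y or w,)",
                       exceptions = c("(f or y or w,)(p)", "(w,)(m)"))
  expect_length(ch$rules, 3)
  n_subs <- vapply(ch$rules, function(r) length(r$sub_rules), integer(1))
  anchors <- vapply(ch$rules, `[[`, character(1), "residues")
  expect_identical(n_subs[anchors == "w"], 2L)
  expect_identical(unname(n_subs[anchors != "w"]), c(1L, 1L))
})

test_that("orphan exceptions and duplicate definitions are linkage errors", {
  expect_error(
    compile_enzyme("x", "(k,)", exceptions = "(r,)(p)"),
    "linked to a main rule", class = "protcleave_parse_error"
  )
  # side must match too: a before-exception cannot attach to an after-rule
  expect_error(
    compile_enzyme("x", "(k,)", exceptions = "(,k)(p)"),
    class = "protcleave_parse_error"
  )
})

test_that("'or' distributes over rules and two-comma rules over sides", {
  a <- compile_enzyme("a", "(a or g,)")
  b <- compile_enzyme("b", c("(a,)", "(g,)"))
  expect_true(equivalent(a, b, c("a", "g", "c"), 4))

  x <- compile_enzyme("x", "(,f,)")
  y <- compile_enzyme("y", c("(,f)", "(f,)"))
  expect_true(equivalent(x, y, c("f", "a", "g"), 4))

  expect_true(equivalent(a, a, c("a", "g"), 3)) # reflexivity
  expect_false(isTRUE(equivalent(load_enzyme("hydroxylamine"),
                                 load_enzyme("bromelain"),
                                 c("n", "g", "k"), 4)))
})

test_that("definitions round-trip: compile -> print -> re-parse -> equivalent", {
  for (nm in c("trypsin", "hydroxylamine", "staphylococcal-peptidase-i",
               "thrombin-sg", "chymotrypsin-high", "bromelain",
               "pepsin-simplified", "enterokinase", "tev", "asp-n",
               "lys-c", "lys-n", "caspase-1", "proline-endopeptidase")) {
    enz <- load_enzyme(nm)
    tmp <- tempfile(fileext = ".txt")
    writeLines(format_enzyme(enz), tmp)
    back <- read_enzyme_file(tmp)[[1]]
    resid <- unique(unlist(lapply(enz$expressions,
                                  function(e) unlist(e$systems))))
    alpha <- utils::head(unique(c(resid, "a", "g")), 5)
    expect_true(isTRUE(equivalent(enz, back, alpha, 4)),
                label = sprintf("round-trip equivalence for %s", nm))
    unlink(tmp)
  }
})
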