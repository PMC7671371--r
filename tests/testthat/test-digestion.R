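test_that("single digestions split at the predicted bonds", {
  pep <- digest_one("aeert", "staphylococcal-peptidase-i")
  expect_identical(pep$sequence, c("ae", "ert"))
  expect_identical(pep$cleavage_position, c(2L, 0L))
  expect_identical(pep$ordinal, 1:2)
  expect_identical(pep$length, c(2L, 3L))

  # 100% miscleavage suppresses every site
  whole <- digest_one("aeert", "staphylococcal-peptidase-i",
                      miscleavage = 100)
  expect_identical(whole$sequence, "aeert")

  # WKP cleaves, plain KP does not
  expect_identical(digest_one("wkpakpa", "trypsin")$sequence,
                   c("wk", "pakpa"))
})

test_that("peptides concatenate to the parent in every mode", {
  set.seed(5)
  enzymes <- c("trypsin", "pepsin-simplified", "proteinase-k", "tev")
  for (i in 1:10) {
    sq <- random_peptide(sample(30:120, 1))
    for (nm in enzymes) {
      expect_identical(paste(digest_one(sq, nm)$sequence, collapse = ""), sq)
    }
    conc <- digest_concurrent(sq, list("arg-c", "lys-n", "bnps-skatole"))
    expect_identical(paste(conc$sequence, collapse = ""), sq)
  }
})

test_that("mass is conserved up to one water per cleavage", {
  set.seed(13)
  for (i in 1:10) {
    sq <- random_peptide(sample(30:100, 1))
    pep <- digest_one(sq, "proteinase-k")
    k <- nrow(pep)
    expect_equal(sum(pep$mass), peptide_mass(sq) + (k - 1) * 18.01528,
                 tolerance = 1e-6)
  }
})

test_that("sequential mode equals independent per-enzyme digestions", {
  recs <- c(r1 = "wkrlvprgsaeak", r2 = "ddddkaengaa")
  both <- digest(recs, c("trypsin", "hydroxylamine"))
  # record-major, enzyme order preserved
  expect_identical(unique(both$parent_id), c("r1", "r2"))
  r1 <- both[both$parent_id == "r1", ]
  expect_identical(unique(r1$enzyme), c("trypsin", "hydroxylamine"))
  solo <- rbind(
    digest_one(recs[["r1"]], "trypsin", parent_id = "r1"),
    digest_one(recs[["r1"]], "hydroxylamine", parent_id = "r1")
  )
  expect_equal(r1, solo, ignore_attr = TRUE)
  # two records in one job == two single-record jobs
  one_by_one <- rbind(
    digest(recs["r1"], c("trypsin", "hydroxylamine")),
    digest(recs["r2"], c("trypsin", "hydroxylamine"))
  )
  expect_equal(both, one_by_one, ignore_attr = TRUE)
  expect_error(digest(character(0), "trypsin"),
               class = "protcleave_usage_error")
})

test_that("concurrent mode reaches the fragment fixpoint", {
  # one protease cleaving before p unless k follows in P2', plus lys-n:
  # lys-n opens the fragment and exposes the p site
  blocked <- compile_enzyme("pro-blocker", "(,p)", exceptions = "(,p)(k)")
  res <- digest_concurrent("aapkaa", list(blocked, load_enzyme("lys-n")))
  expect_identical(res$sequence, c("aa", "p", "kaa"))
  expect_identical(res$enzyme, rep("pro-blocker-lys-n", 3))
  expect_identical(res$cleavage_position, c(2L, 3L, 0L))

  # neither enzyme alone can produce that digest
  expect_identical(digest_one("aapkaa", blocked)$sequence, "aapkaa")
  expect_identical(digest_one("aapkaa", "lys-n")$sequence,
                   c("aap", "kaa"))
})

test_that("concurrent digestion is idempotent and refines sequential sites", {
  set.seed(17)
  trio <- list("arg-c", "lys-n", "bnps-skatole") # context-free enzymes
  for (i in 1:6) {
    sq <- random_peptide(sample(40:100, 1))
    conc <- digest_concurrent(sq, trio)
    # for context-free enzymes the concurrent bonds equal the union of the
    # per-enzyme site sets on the intact parent
    union_sites <- sort(Reduce(union, lapply(trio, function(e)
      find_sites(sq, load_enzyme(e)))))
    expect_identical(conc$cleavage_position[-nrow(conc)],
                     as.integer(union_sites))
    # re-digesting any product peptide yields it unchanged (fixpoint)
    for (p in conc$sequence) {
      expect_identical(digest_concurrent(p, trio)$sequence, p)
    }
  }
  # single context-free enzyme: concurrent == sequential
  sq <- random_peptide(60)
  expect_equal(digest_concurrent(sq, list("arg-c"))$sequence,
               digest_one(sq, "arg-c")$sequence)
  # single context-dependent enzyme: fragmentation may expose new sites
  # (the mechanism behind the concurrent mode); aeert -> ae|ert -> ae|e|rt
  conc <- digest_concurrent("aeert", list("staphylococcal-peptidase-i"))
  expect_identical(conc$sequence, c("ae", "e", "rt"))
})

test_that("miscleavage keeps each site with probability 1 - p/100", {
  sq <- strrep("aang", 50) # 50 hydroxylamine sites
  hx <- load_enzyme("hydroxylamine")
  sites <- find_sites(sq, hx)
  expect_length(sites, 50)
  set.seed(99)
  kept <- replicate(2000, length(protcleave:::apply_miscleavage(sites, 30)))
  expect_equal(mean(kept), 50 * 0.7, tolerance = 0.02)
  # the digestion row count reflects the kept sites
  set.seed(99)
  pep <- digest_one(sq, hx, miscleavage = 30, annotate = FALSE)
  expect_identical(nrow(pep), kept[1] + 1L)
})

test_that("a fixed seed reproduces a stochastic digestion exactly", {
  recs <- c(a = strrep("aang", 25), b = strrep("wkra", 25))
  d1 <- digest(recs, c("hydroxylamine", "trypsin"), miscleavage = 40,
               seed = 123)
  d2 <- digest(recs, c("hydroxylamine", "trypsin"), miscleavage = 40,
               seed = 123)
  expect_identical(d1, d2)
  d3 <- digest(recs, c("hydroxylamine", "trypsin"), miscleavage = 40,
               seed = 124)
  expect_false(identical(d1$sequence, d3$sequence))
})

test_that("size-range summaries use inclusive bounds and consistent fractions", {
  pep <- data.frame(mass = c(500, 600, 5000, 5001),
                    length = c(5, 6, 45, 46))
  s <- size_range_summary(pep, 600, 5000)
  expect_identical(s$count, 2L)
  expect_equal(s$fraction, 0.5)
  expect_identical(s$residues, 51)
  expect_equal(s$residue_fraction, 51 / 102)
  expect_identical(size_range_summary(pep[0, ], 600, 5000)$count, 0L)
  expect_error(size_range_summary(pep, 5000, 600),
               class = "protcleave_usage_error")
  # complement consistency on a digestion
  set.seed(3)
  d <- digest_one(random_peptide(300), "trypsin")
  a <- size_range_summary(d, 600, 5000)
  expect_equal(a$count + sum(d$mass < 600 | d$mass > 5000), nrow(d))
})
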