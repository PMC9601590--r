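test_that("ambiguity location finds all and only non-ACGT positions", {
  expect_equal(nrow(locate_ambiguities("ACGT")), 0L)
  expect_equal(locate_ambiguities("ACYT"),
               data.frame(position = 3L, code = "Y", stringsAsFactors = FALSE))

  set.seed(61)
  s <- strsplit(random_dna(5000), "")[[1]]
  s[c(2976, 4110) %% 5000] <- "Y"
  amb <- locate_ambiguities(paste(s, collapse = ""))
  expect_equal(amb$position, c(2976, 4110) %% 5000)
  expect_equal(amb$code, c("Y", "Y"))
})

test_that("a single defined alternate resolves a degenerate site", {
  set.seed(62)
  truth <- random_dna(400)
  substr(truth, 200, 200) <- "C"
  prim <- truth
  substr(prim, 200, 200) <- "Y"
  res <- resolve_ambiguities(mito_record("p", prim), list(truth), flank = 12)
  expect_identical(res$report$resolution, "C")
  expect_identical(res$report$rule, "single-source")
  expect_identical(res$record$residues, truth)
})

test_that("no ambiguities means identity with an empty report", {
  s <- random_dna(100)
  res <- resolve_ambiguities(s, list(random_dna(100)), flank = 10)
  expect_identical(res$record$residues, toupper(s))
  expect_equal(nrow(res$report), 0L)
})

test_that("two-voter configurations follow unanimity / strict majority / tie rules", {
  set.seed(63)
  truth <- random_dna(500)
  substr(truth, 250, 250) <- "C"
  prim <- truth; substr(prim, 250, 250) <- "Y"
  altC <- truth
  altT <- truth; substr(altT, 250, 250) <- "T"
  altG <- truth; substr(altG, 250, 250) <- "G"

  # enumerate all two-voter base configurations for a Y (C/T) site
  cases <- list(
    list(alts = list(altC, altC), res = "C", rule = "unanimous"),
    list(alts = list(altT, altT), res = "T", rule = "unanimous"),
    list(alts = list(altC, altT), res = "unresolved", rule = "tie"),
    # a G vote is outside the IUPAC expansion of Y: discarded, single voter left
    list(alts = list(altC, altG), res = "C", rule = "single-source"),
    list(alts = list(altG, altG), res = "unresolved", rule = "no votes")
  )
  for (cs in cases) {
    r <- resolve_ambiguities(prim, cs$alts, flank = 12)$report
    expect_identical(r$resolution, cs$res)
    expect_identical(r$rule, cs$rule)
  }

  # three voters: strict majority wins
  r3 <- resolve_ambiguities(prim, list(altC, altC, altT), flank = 12)$report
  expect_identical(r3$resolution, "C")
  expect_identical(r3$rule, "majority")
})

test_that("conflicting repeat placements abstain; agreeing ones count once", {
  set.seed(64)
  block <- random_dna(30)
  mid <- random_dna(120)
  # the flank context occurs twice with DIFFERENT middle bases: placement
  # ambiguity, so the alternate must abstain
  truth <- paste0(block, "C", block, mid, block, "T", block)
  prim <- truth
  pos <- nchar(block) + 1L
  substr(prim, pos, pos) <- "Y"
  res <- resolve_ambiguities(mito_record("p", prim), list(truth), flank = 12)
  expect_identical(res$report$resolution[1], "unresolved")
  expect_match(attr(res$report, "notes"), "conflicting", all = FALSE)

  # the same context twice with the SAME middle base is redundant
  # coverage and yields a single vote
  truth2 <- paste0(block, "C", block, mid, block, "C", block)
  prim2 <- truth2
  substr(prim2, pos, pos) <- "Y"
  res2 <- resolve_ambiguities(mito_record("p", prim2), list(truth2), flank = 12)
  expect_identical(res2$report$resolution[1], "C")
})

test_that("injected ambiguities are fully recovered from truth-derived alternates", {
  sim <- generate_mitogenome(seed = 17)
  for (frag in list(NULL, 300L)) {
    av <- make_assembly_variants(sim, n_ambiguities = 6L, n_alternates = 2L,
                                 fragment_length = frag, seed = 23)
    res <- resolve_ambiguities(av$primary, av$alternates,
                               flank = if (is.null(frag)) 12L else 20L)
    expect_identical(res$report$resolution, av$truth$true_base)
    expect_identical(res$record$residues, sim$genome$record$residues)
    # non-ambiguous positions never altered; substitutions within expansion
    expect_equal(nchar(res$record$residues), sim$genome$length)
  }
})

test_that("flank context that is itself ambiguous leaves the site unresolved", {
  set.seed(65)
  truth <- random_dna(200)
  prim <- truth
  substr(prim, 100, 100) <- "Y"
  substr(prim, 105, 105) <- "N"   # inside the right flank
  res <- resolve_ambiguities(mito_record("p", prim), list(truth), flank = 10)
  r <- res$report[res$report$position == 100, ]
  expect_identical(r$resolution, "unresolved")
  expect_match(r$rule, "ambiguous flank")
})
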