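code <- mito_code()

test_that("codon counting excludes stops and incomplete terminal codons", {
  counts <- codon_counts(c(toy = "CTACTGCTATAA"))
  expect_equal(unname(counts["CTA"]), 2L)
  expect_equal(unname(counts["CTG"]), 1L)
  expect_equal(sum(counts), 3L)
  expect_equal(unname(attr(counts, "stop_counts")["TAA"]), 1L)

  # 688-base CDS: floor(688/3) = 229 complete codons, 1-base remainder dropped
  set.seed(81)
  sense <- names(code$table)[code$table != "*"]
  cds <- paste0(paste(sample(sense, 229, replace = TRUE), collapse = ""), "T")
  expect_equal(nchar(cds), 688L)
  expect_equal(sum(codon_counts(cds)), 229L)

  expect_equal(sum(codon_counts(list())), 0L)
  expect_error(codon_counts(c(ND9 = "ATGTAAAAATAA")), "ND9.*codon index 2")
})

test_that("RSCU satisfies its defining identities", {
  sense <- names(code$table)[code$table != "*"]
  uniform <- setNames(rep(5L, length(sense)), sense)
  tab <- rscu(uniform, code)
  expect_true(all(tab$rscu == 1))

  # a 4-fold family used through one codon only: that codon's RSCU is 4
  counts <- setNames(rep(0L, length(sense)), sense)
  counts["GGA"] <- 7L  # Gly family GGN
  tab2 <- rscu(counts, code)
  expect_equal(tab2$rscu[tab2$codon == "GGA"], 4)
  expect_true(all(is.na(tab2$rscu[tab2$aa == "F"])))  # untouched family undefined

  # Leu is 6-fold under this code: {CTA:3, CTG:1} -> RSCU(CTA) = 3/(4/6)
  counts3 <- setNames(rep(0L, length(sense)), sense)
  counts3["CTA"] <- 3L; counts3["CTG"] <- 1L
  tab3 <- rscu(counts3, code)
  expect_equal(tab3$rscu[tab3$codon == "CTA"], 4.5)
  expect_identical(tab3$codon_rna[tab3$codon == "CTA"], "CUA")
})

test_that("RSCU family sums equal family sizes on random counts", {
  set.seed(82)
  sense <- names(code$table)[code$table != "*"]
  for (i in 1:10) {
    counts <- setNames(rpois(length(sense), 8) + 1L, sense)
    tab <- rscu(counts, code)
    sums <- tapply(tab$rscu, tab$aa, sum)
    sizes <- tapply(tab$family_size, tab$aa, unique)
    expect_equal(as.numeric(sums), as.numeric(sizes))
  }
})

test_that("potential sites match the enumeration oracle and conserve N + S = 3", {
  sense <- names(code$table)[code$table != "*"]
  tabs <- mitochar:::ng_tables(code)
  for (cd in sense) {
    expect_equal(unname(tabs$syn_sites[cd]), oracle_syn_sites(cd, code),
                 info = cd)
  }
  # conservation: every codon contributes 3 sites in total by construction
  p <- nei_gojobori_pair(paste(sense[1:20], collapse = ""),
                         paste(sense[21:40], collapse = ""))
  expect_equal(p$N + p$S, 3 * p$n_codons)
})

test_that("observed differences match the pathway oracle, including 2-hit codons", {
  # trivial and 1-difference cases
  p0 <- nei_gojobori_pair("ATGGCA", "ATGGCA")
  expect_equal(c(p0$Nd, p0$Sd, p0$ka, p0$ks), c(0, 0, 0, 0))
  p1 <- nei_gojobori_pair("GAA", "GAG")
  expect_equal(c(p1$Sd, p1$Nd), c(1, 0))

  # a 2-difference codon pair averages over both substitution orders
  set.seed(83)
  sense <- names(code$table)[code$table != "*"]
  pairs2 <- list(c("GAG", "AAA"), c("TTA", "CTC"), c("ATG", "ACA"), c("TGT", "AGA"))
  for (pr in pairs2) {
    if (any(!(pr %in% sense))) next
    want <- oracle_pathways(pr[1], pr[2], code)
    got <- nei_gojobori_pair(pr[1], pr[2])
    expect_equal(got$Sd, unname(want["Sd"]), info = paste(pr, collapse = "/"))
    expect_equal(got$Nd, unname(want["Nd"]), info = paste(pr, collapse = "/"))
  }
})

test_that("the pairwise statistic is exactly symmetric and flags saturation", {
  set.seed(84)
  sense <- names(code$table)[code$table != "*"]
  for (i in 1:10) {
    a <- paste(sample(sense, 40, replace = TRUE), collapse = "")
    b <- paste(sample(sense, 40, replace = TRUE), collapse = "")
    pab <- suppressWarnings(nei_gojobori_pair(a, b))
    pba <- suppressWarnings(nei_gojobori_pair(b, a))
    expect_identical(pab[c("N", "S", "Nd", "Sd", "pN", "pS")],
                     pba[c("N", "S", "Nd", "Sd", "pN", "pS")])
  }
  # a single fully synonymous difference on a 1-site gene sits on the 3/4
  # horizon: pS = 1, Jukes-Cantor undefined, reported as saturated
  sat <- nei_gojobori_pair("GGT", "GGA")
  expect_equal(c(sat$Sd, sat$S), c(1, 1))
  expect_true(is.na(sat$ks))
  expect_identical(sat$saturated, "ks")

  # ambiguous/gapped codons are deleted pairwise
  pg <- nei_gojobori_pair("GAANNNGAA", "GAGA-AGAA")
  expect_equal(pg$n_codons, 2L)
  expect_equal(pg$n_skipped, 1L)
})

test_that("gene-level aggregation equals the closed-form hand computation", {
  # 10-codon genes, three taxa: one synonymous difference (A/B), one
  # nonsynonymous (A/C), and a 2-hit codon (B/C) whose both pathways give
  # one synonymous plus one nonsynonymous step
  A <- strrep("GAA", 10)
  B <- paste0("GAG", strrep("GAA", 9))
  C <- paste0("AAA", strrep("GAA", 9))
  res <- gene_kaks(list(g = c(A = A, B = B, C = C)))

  # every codon here (GAA, GAG, AAA) has 1/3 synonymous sites
  S <- 10 / 3; N <- 30 - S
  ks1 <- -0.75 * log(1 - 4 * (1 / S) / 3)   # A-B
  ka1 <- 0
  ks2 <- 0                                   # A-C
  ka2 <- -0.75 * log(1 - 4 * (1 / N) / 3)
  ks3 <- -0.75 * log(1 - 4 * (1 / S) / 3)   # B-C: Sd = 1, Nd = 1
  ka3 <- -0.75 * log(1 - 4 * (1 / N) / 3)
  expect_equal(res$genes$mean_ka, mean(c(ka1, ka2, ka3)))
  expect_equal(res$genes$mean_ks, mean(c(ks1, ks2, ks3)))
  expect_equal(res$genes$kaks, mean(c(ka1, ka2, ka3)) / mean(c(ks1, ks2, ks3)))

  # identical taxa: 0/0 is undefined
  res0 <- gene_kaks(list(g = c(x = A, y = A)))
  expect_true(is.na(res0$genes$kaks))
})

test_that("purifying-selection simulations do not fake positive selection", {
  sim <- generate_mitogenome(seed = 6)
  div <- mutate_set(sim$genome, taxa = 4, dnds = 0.3, branch_length = 0.04, seed = 7)
  est <- gene_kaks(div$alignments)
  ok <- !is.na(est$genes$kaks)
  expect_true(any(ok))
  expect_true(all(est$genes$kaks[ok] < 1))
})
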