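test_that("skew formulas evaluate correctly on hand cases", {
  expect_equal(compute_skews(2, 2, 1, 1), data.frame(at_skew = 0, gc_skew = 0))
  # GGGC: GC-skew (3-1)/(3+1)
  bc <- base_composition("GGGC")
  expect_equal(bc$gc_skew, 0.5)
  bc2 <- base_composition("AATT")
  expect_equal(bc2$pct_A, 50); expect_equal(bc2$at_content, 100)
  expect_equal(bc2$at_skew, 0)
  bc3 <- base_composition("ACGT")
  expect_equal(unlist(bc3[c("pct_A", "pct_C", "pct_G", "pct_T")], use.names = FALSE),
               rep(25, 4))
  expect_equal(c(bc3$at_skew, bc3$gc_skew), c(0, 0))

  # whole-genome percentages of the two focal newts round to the reported skews
  expect_equal(round(compute_skews(33.6, 25.7, 14.5, 26.3)$at_skew, 2), 0.13)
  expect_equal(round(compute_skews(33.6, 25.6, 14.6, 26.3)$at_skew, 2), 0.14)
  expect_equal(round(compute_skews(33.6, 25.7, 14.5, 26.3)$gc_skew, 2), -0.29)

  # zero denominators are undefined, not infinite
  expect_true(is.na(compute_skews(0, 0, 1, 1)$at_skew))
  expect_true(is.na(base_composition("AATT")$gc_skew))
})

test_that("swapping A<->T and G<->C negates both skews", {
  set.seed(71)
  for (i in 1:20) {
    v <- runif(4)
    a <- compute_skews(v[1], v[2], v[3], v[4])
    b <- compute_skews(v[2], v[1], v[4], v[3])
    expect_equal(a$at_skew, -b$at_skew)
    expect_equal(a$gc_skew, -b$gc_skew)
  }
})

test_that("reported skews are recovered from reported percentages for 33 published genomes", {
  tab <- published_genome_compositions()
  expect_equal(nrow(tab), 33L)
  sk <- compute_skews(tab$pct_A, tab$pct_T, tab$pct_G, tab$pct_C)
  # double rounding (percentages to 1-2 decimals, skews to 2) allows +-0.01
  expect_true(all(abs(round(sk$at_skew, 2) - tab$at_skew) <= 0.01 + 1e-9))
  expect_true(all(abs(round(sk$gc_skew, 2) - tab$gc_skew) <= 0.01 + 1e-9))
})

test_that("regional summaries reproduce the architecture's region sizes", {
  sim <- generate_mitogenome(seed = 2)
  comp <- regional_summaries(sim$genome)
  size_of <- function(region) comp$size[comp$region == region]
  expect_equal(size_of("tRNAs"), 1537L)
  expect_equal(size_of("PCGs"), 11383L)
  expect_equal(size_of("Genome"), 16265L)
  expect_equal(size_of("D-loop"), 716L)
  expect_equal(size_of("12S-rRNA"), 928L)
  expect_equal(size_of("16S-rRNA"), 1563L)

  # per-gene reading frames: the four incomplete-stop genes each add an
  # extra first-position base (11,383 = 9 x 0 + 4 x 1 mod 3)
  expect_equal(comp$size[grepl("^PCGs-", comp$region)], c(3797L, 3793L, 3793L))

  # global triplet chopping of the concatenated PCGs, the convention of
  # some annotation suites, splits the same total 3795/3794/3794
  comp2 <- regional_summaries(sim$genome, position_assignment = "concatenated")
  expect_equal(comp2$size[grepl("^PCGs-", comp2$region)], c(3795L, 3794L, 3794L))
  expect_equal(sum(comp2$size[grepl("^PCGs-", comp2$region)]), 11383L)
})

test_that("a 6-base PCG contributes two bases to each codon position", {
  g <- tiny_genome(paste0("ATGTAA", random_dna(60)),
                   name = c("g1", "cr"), type = c("PCG", "CR"),
                   start = c(1, 7), end = c(6, 66), strand = "H")
  comp <- suppressWarnings(regional_summaries(g))
  expect_equal(comp$size[grepl("^PCGs-", comp$region)], c(2L, 2L, 2L))
})

test_that("whole-genome counts decompose into covered plus intergenic counts", {
  sim <- generate_mitogenome(seed = 5)
  chars <- strsplit(sim$genome$record$residues, "")[[1]]
  covered <- logical(sim$genome$length)
  ft <- sim$genome$features
  for (i in seq_len(nrow(ft))) covered[ft$start[i]:ft$end[i]] <- TRUE
  whole <- base_composition(sim$genome$record)
  inter <- base_composition(paste(chars[!covered], collapse = ""), "intergenic")
  feat <- base_composition(paste(chars[covered], collapse = ""), "features")
  for (b in c("A", "C", "G", "T")) {
    col <- paste0("count_", b)
    expect_equal(whole[[col]], inter[[col]] + feat[[col]])
  }
})

test_that("per-gene skews are computed on the coding strand", {
  # an L-strand gene whose coding sequence is G-rich must show positive
  # GC-skew even though its H-strand span is C-rich
  cds <- paste0("ATG", strrep("GGA", 20), "TAA")
  hspan <- revcomp(cds)
  g <- tiny_genome(paste0(hspan, random_dna(40)),
                   name = c("gL", "cr"), type = c("PCG", "CR"),
                   start = c(1, nchar(hspan) + 1), end = c(nchar(hspan), nchar(hspan) + 40),
                   strand = c("L", "H"))
  sk <- per_gene_skews(g)
  expect_gt(sk$gc_skew, 0)

  # a gene that is its own reverse complement has zero skews
  pal <- "ACGCGT"
  g2 <- tiny_genome(paste0(pal, random_dna(40)),
                    name = c("p", "cr"), type = c("PCG", "CR"),
                    start = c(1, 7), end = c(6, 46), strand = c("H", "H"))
  sk2 <- per_gene_skews(g2)
  expect_equal(sk2$at_skew, 0)
  expect_equal(sk2$gc_skew, 0)

  expect_error(per_gene_skews(tiny_genome(random_dna(50), name = "cr",
                                          type = "CR", start = 1, end = 50,
                                          strand = "H")),
               "no protein-coding")
})

test_that("ambiguous bases are excluded from percentages with a warning", {
  expect_warning(bc <- base_composition("AANNTT"), "ambiguous")
  expect_equal(bc$size, 6L)
  expect_equal(bc$n_ambiguous, 2L)
  expect_equal(bc$pct_A, 50)
  expect_error(suppressWarnings(base_composition("NNNN")), "no unambiguous")
})
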