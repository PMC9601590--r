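make_aln <- function(genes, taxa, lens, seed = 1) {
  set.seed(seed)
  setNames(lapply(lens, function(L) {
    setNames(vapply(taxa, function(t) random_dna(L), ""), taxa)
  }), genes)
}

test_that("supermatrix concatenation keeps coordinate bookkeeping straight", {
  taxa <- c("t1", "t2")
  aln <- make_aln(c("g1", "g2"), taxa, c(6, 9))
  sm <- concatenate_pcgs(aln)
  expect_equal(nchar(sm$alignment[["t1"]]), 15L)
  expect_equal(nrow(sm$partitions), 6L)
  p1 <- sm$partitions[sm$partitions$gene == "g1", ]
  expect_equal(p1$start, 1:3)
  expect_equal(unique(p1$end), 6L)
  # stride-3 site sets for a 6-column gene: {1,4}, {2,5}, {3,6}
  expect_equal(lapply(1:3, function(p) seq(p1$start[p], p1$end[p], by = 3)),
               list(c(1, 4), c(2, 5), c(3, 6)))
  p2 <- sm$partitions[sm$partitions$gene == "g2", ]
  expect_equal(p2$start, 6 + 1:3)

  # conservation: partition site counts sum to the supermatrix length
  sites <- sum(vapply(seq_len(nrow(sm$partitions)), function(i) {
    length(seq(sm$partitions$start[i], sm$partitions$end[i], by = 3))
  }, 0))
  expect_equal(sites, nchar(sm$alignment[["t1"]]))

  # 13 genes -> 39 partitions
  sm13 <- concatenate_pcgs(make_aln(sprintf("g%02d", 1:13), taxa, rep(30, 13)))
  expect_equal(nrow(sm13$partitions), 39L)
  expect_match(write_raxml_partitions(sm13)[1], "^DNA, g01_pos1 = 1-30\\\\3$")

  bad <- make_aln(c("g1", "g2"), taxa, c(6, 6))
  bad$g2 <- bad$g2[1]
  expect_error(concatenate_pcgs(bad), "taxon set mismatch")
  expect_error(concatenate_pcgs(make_aln("g", taxa, 7)), "divisible by 3")
})

test_that("supermatrix writers emit parseable PHYLIP/NEXUS/partition files", {
  sm <- concatenate_pcgs(make_aln(c("nd1", "cox1"), c("alpha", "beta", "gamma"),
                                  c(12, 9)))
  phy <- withr::local_tempfile(fileext = ".phy")
  nex <- withr::local_tempfile(fileext = ".nex")
  part <- withr::local_tempfile(fileext = ".txt")
  write_phylip(sm, phy)
  write_nexus(sm, nex)
  write_raxml_partitions(sm, part)
  expect_identical(readLines(phy)[1], "3 21")
  expect_length(readLines(part), 6L)
  expect_identical(readLines(nex)[1], "#NEXUS")
  # ape reads our PHYLIP back with identical content
  back <- ape::read.dna(phy, format = "sequential", as.character = TRUE)
  expect_identical(toupper(paste(back["alpha", ], collapse = "")),
                   sm$alignment[["alpha"]])
})

test_that("p-distances use pairwise deletion and match brute force and ape", {
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)

  set.seed(91)
  taxa <- sprintf("s%d", 1:5)
  L <- 60
  aln <- setNames(vapply(taxa, function(t) random_dna(L), ""), taxa)
  # punch gaps and ambiguities into some rows
  aln[2] <- paste0("--", substr(aln[2], 3, L))
  aln[3] <- paste0(substr(aln[3], 1, 10), "NNN", substr(aln[3], 14, L))
  d <- p_distance_matrix(aln)
  expect_true(isSymmetric(unname(d)))

  # brute-force column scan oracle
  mat <- do.call(rbind, strsplit(unname(aln), ""))
  for (i in 1:4) for (j in (i + 1):5) {
    ok <- mat[i, ] %in% c("A", "C", "G", "T") & mat[j, ] %in% c("A", "C", "G", "T")
    expect_equal(d[i, j], sum(mat[i, ok] != mat[j, ok]) / sum(ok))
  }

  # independent cross-check against ape's raw pairwise-deletion distance
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(unname(aln)), "")))
  rownames(bin) <- taxa
  dape <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(unname(d), unname(dape), tolerance = 1e-12)

  expect_error(p_distance_matrix(c(a = "NNNN", b = "AAAA")), "no comparable")
})

test_that("three-taxon NJ solves the three-point formulas exactly", {
  dm <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  tip_edge <- function(t, lab) t$edge.length[t$edge[, 2] == which(t$tip.label == lab)]
  expect_equal(tip_edge(tr, "a"), (2 + 4 - 6) / 2)
  expect_equal(tip_edge(tr, "b"), (2 + 6 - 4) / 2)
  expect_equal(tip_edge(tr, "c"), (4 + 6 - 2) / 2)
})

test_that("NJ exactly recovers additive distance matrices", {
  set.seed(92)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    tr0 <- ape::rtree(n, rooted = FALSE)
    tr0$edge.length <- runif(length(tr0$edge.length), 0.05, 1)
    dm <- cophenetic(tr0)
    tr <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr0), tr), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    # branch lengths recovered too (additivity)
    expect_equal(sum(tr$edge.length), sum(tr0$edge.length), tolerance = 1e-8)
  }
})

test_that("identical taxa become zero-branch siblings and validation rejects bad input", {
  aln <- c(a = "ACGTACGTAA", b = "ACGTACGTAA", c = "ACGTACGTCC", d = "AGGTTCGTCG")
  tr <- nj_tree(p_distance_matrix(aln))
  pair <- ape::mrca(tr)["a", "b"]
  desc <- tr$edge[, 2][tr$edge[, 1] == pair]
  expect_setequal(tr$tip.label[desc[desc <= 4]], c("a", "b"))
  ab_edges <- tr$edge.length[tr$edge[, 2] %in% which(tr$tip.label %in% c("a", "b"))]
  expect_equal(ab_edges, c(0, 0))

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(matrix(runif(9), 3, 3)), "symmetric|diagonal|non-negative")
})

test_that("Newick serialization round trips topology and branch lengths", {
  set.seed(93)
  tr0 <- ape::rtree(8, rooted = FALSE)
  nwk <- write_newick(tr0)
  back <- ape::read.tree(text = nwk)
  expect_equal(ape::dist.topo(tr0, back), structure(0, names = "PH85"),
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr0$edge.length), tolerance = 1e-9)

  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr0, path)
  expect_identical(readLines(path), nwk)
})
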