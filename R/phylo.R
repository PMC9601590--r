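# Supermatrix assembly with gene-by-codon-position partitions, p-distances
# with pairwise deletion, and neighbor-joining verification trees.

#' Concatenate per-gene codon alignments into a partitioned supermatrix
#'
#' Every gene alignment must cover the same taxon set (no automatic
#' gap-filling) and have length divisible by 3 (stop codons / incomplete
#' terminal codons trimmed beforehand). The partition scheme lists three
#' blocks per gene, one per codon position, each a stride-3 range within
#' the gene's coordinate range in the supermatrix.
#'
#' @param alignments named list (gene -> named character vector of aligned
#'   sequences, taxon names as names).
#' @return a list of class `pcg_supermatrix`: `alignment` (named character
#'   vector), `partitions` (data.frame `gene`, `position`, `start`, `end`,
#'   `stride`), `gene_lengths`.
#' @export
concatenate_pcgs <- function(alignments) {
  stopifnot(is.list(alignments), length(alignments) > 0L)
  if (is.null(names(alignments))) names(alignments) <- sprintf("gene%d", seq_along(alignments))
  alignments <- lapply(alignments, function(a) {
    if (inherits(a, "XStringSet")) setNames(as.character(a), names(a)) else a
  })
  taxa <- sort(names(alignments[[1L]]))
  if (is.null(taxa) || any(!nzchar(taxa))) stop("alignments must have taxon names", call. = FALSE)

  offset <- 0L
  parts <- list()
  pieces <- list()
  for (g in names(alignments)) {
    aln <- alignments[[g]]
    missing <- setdiff(taxa, names(aln))
    extra <- setdiff(names(aln), taxa)
    if (length(missing) || length(extra)) {
      stop(sprintf("%s: taxon set mismatch (missing: %s; extra: %s)", g,
                   paste(missing, collapse = ",") , paste(extra, collapse = ",")),
           call. = FALSE)
    }
    lens <- nchar(aln)
    if (length(unique(lens)) != 1L) stop(sprintf("%s: unequal sequence lengths", g), call. = FALSE)
    len <- lens[[1L]]
    if (len %% 3L != 0L) {
      stop(sprintf("%s: length %d not divisible by 3 (trim incomplete terminal codon first)",
                   g, len), call. = FALSE)
    }
    parts[[g]] <- data.frame(gene = g, position = 1:3,
                             start = offset + 1:3, end = offset + len,
                             stride = 3L, stringsAsFactors = FALSE)
    pieces[[g]] <- toupper(aln[taxa])
    offset <- offset + len
  }
  supermatrix <- vapply(taxa, function(tx) {
    paste(vapply(pieces, function(p) p[[tx]], ""), collapse = "")
  }, "")
  structure(list(alignment = supermatrix,
                 partitions = do.call(rbind, c(parts, list(make.row.names = FALSE))),
                 gene_lengths = vapply(alignments, function(a) nchar(a[[1L]]), 0L)),
            class = "pcg_supermatrix")
}

#' @export
print.pcg_supermatrix <- function(x, ...) {
  cat(sprintf("<pcg_supermatrix> %d taxa x %s sites; %d genes, %d partitions\n",
              length(x$alignment), format(nchar(x$alignment[[1L]]), big.mark = ","),
              length(x$gene_lengths), nrow(x$partitions)))
  invisible(x)
}

#' RAxML-style partition lines for a supermatrix
#'
#' One line per gene-by-codon-position block, e.g.
#' `DNA, ND1_pos1 = 1-969\3`.
#'
#' @param x a `pcg_supermatrix`.
#' @param path optional output path; when `NULL` the lines are returned.
#' @return the lines, invisibly when written to `path`.
#' @export
write_raxml_partitions <- function(x, path = NULL) {
  stopifnot(inherits(x, "pcg_supermatrix"))
  p <- x$partitions
  lines <- sprintf("DNA, %s_pos%d = %d-%d\\3", p$gene, p$position, p$start, p$end)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Write an alignment in relaxed PHYLIP format
#'
#' @param alignment named character vector (or a `pcg_supermatrix`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(alignment, path) {
  if (inherits(alignment, "pcg_supermatrix")) alignment <- alignment$alignment
  writeLines(c(sprintf("%d %d", length(alignment), nchar(alignment[[1L]])),
               sprintf("%s  %s", names(alignment), unname(alignment))), path)
  invisible(path)
}

#' Write an alignment as a simple NEXUS DATA block
#'
#' @param alignment named character vector (or a `pcg_supermatrix`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(alignment, path) {
  if (inherits(alignment, "pcg_supermatrix")) alignment <- alignment$alignment
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(alignment),
                     nchar(alignment[[1L]])),
             "  FORMAT DATATYPE=DNA MISSING=N GAP=-;",
             "  MATRIX",
             sprintf("    %s  %s", names(alignment), unname(alignment)),
             "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Pairwise p-distance matrix with pairwise deletion
#'
#' For each taxon pair, the proportion of mismatching sites among the
#' columns where both sequences carry an unambiguous base (gap and
#' ambiguity columns are deleted pairwise, not alignment-wide). A pair
#' with no comparable site is an error.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences (>= 2 taxa).
#' @return a symmetric numeric matrix with zero diagonal and taxon
#'   dimnames.
#' @export
p_distance_matrix <- function(alignment) {
  if (inherits(alignment, "XStringSet")) alignment <- setNames(as.character(alignment), names(alignment))
  m <- length(alignment)
  if (m < 2L) stop("need at least two taxa", call. = FALSE)
  if (length(unique(nchar(alignment))) != 1L) stop("sequences must be aligned (equal length)", call. = FALSE)
  chars <- lapply(alignment, function(s) seq_chars(toupper(s)))
  good <- lapply(chars, function(ch) ch %in% .BASES)
  taxa <- names(alignment)
  d <- matrix(0, m, m, dimnames = list(taxa, taxa))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      ok <- good[[i]] & good[[j]]
      if (!any(ok)) {
        stop(sprintf("no comparable sites between %s and %s", taxa[i], taxa[j]),
             call. = FALSE)
      }
      d[i, j] <- d[j, i] <- mean(chars[[i]][ok] != chars[[j]][ok])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]) on a validated symmetric,
#' non-negative distance matrix; negative branch lengths, which NJ can
#' produce on non-additive input, are clamped to zero with a message.
#'
#' @param dm symmetric distance matrix with zero diagonal, >= 3 taxa.
#' @return an unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("need at least three taxa", call. = FALSE)
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("distance matrix must be symmetric", call. = FALSE)
  if (any(dm < 0)) stop("distances must be non-negative", call. = FALSE)
  if (any(abs(diag(dm)) > 1e-12)) stop("diagonal must be zero", call. = FALSE)
  tr <- ape::nj(dm)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sprintf("%d negative NJ branch length(s) clamped to 0 (min %.3g)",
                    sum(neg), min(tr$edge.length)))
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param path optional output path; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
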