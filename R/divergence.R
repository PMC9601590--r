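# Codon-aware divergence of a mitogenome into a set of taxa with
# controlled per-gene dN/dS, and assembly variants with injected
# IUPAC ambiguities for exercising the consensus stage.

#' Diverge the protein-coding genes of a genome into a taxon set
#'
#' Evolves each PCG's coding sequence (start codon retained, terminal
#' stop / incomplete remainder removed) along a star topology -- or along
#' a supplied tree -- by proposal/acceptance: point mutations are proposed
#' at rate `branch_length` per nucleotide site with a transition:
#' transversion bias, proposals creating stop codons are rejected,
#' synonymous changes are always accepted and nonsynonymous changes are
#' accepted with probability equal to the gene's dN/dS target. There are
#' no indels, so the per-gene outputs are aligned by construction.
#'
#' @param genome a [mito_genome] (or `mito_sim`) with annotated PCGs.
#' @param taxa number of taxa for the star topology (ignored when `tree`
#'   is given).
#' @param dnds dN/dS target(s) in (0, Inf): a scalar, or a vector named by
#'   PCG.
#' @param branch_length expected proposed substitutions per nucleotide
#'   site per branch.
#' @param tstv transition:transversion proposal bias (default 4,
#'   a typical mitochondrial value).
#' @param tree optional `phylo` tree with edge lengths; tips become taxa.
#' @param seed integer seed.
#' @param code a [mito_code()] specification.
#' @return a list of class `mito_divergence`: `alignments` (gene -> named
#'   character vector of CDS strings), `truth` (`dnds` targets, realized
#'   accepted `events` per gene, `branch_length`, `tstv`, `seed`).
#' @export
mutate_set <- function(genome, taxa = 12L, dnds = 0.2, branch_length = 0.05,
                       tstv = 4, tree = NULL, seed = 1L, code = mito_code()) {
  if (inherits(genome, "mito_sim")) genome <- genome$genome
  stopifnot(inherits(genome, "mito_genome"))
  set.seed(seed)
  pcg <- genome$features[genome$features$type == "PCG", , drop = FALSE]
  if (!nrow(pcg)) stop("genome has no protein-coding genes", call. = FALSE)

  if (is.null(names(dnds))) {
    dnds <- setNames(rep_len(dnds, nrow(pcg)), pcg$name)
  } else if (!all(pcg$name %in% names(dnds))) {
    stop("dnds must be named for every PCG", call. = FALSE)
  }
  if (any(dnds <= 0)) stop("dN/dS targets must be > 0", call. = FALSE)

  labels <- if (is.null(tree)) sprintf("t%02d", seq_len(taxa)) else tree$tip.label
  alignments <- list()
  events <- list()

  for (i in seq_len(nrow(pcg))) {
    g <- pcg$name[i]
    cds <- extract_feature_sequence(genome, pcg[i, ])
    rem <- nchar(cds) %% 3L
    if (rem > 0L) cds <- substr(cds, 1L, nchar(cds) - rem)
    codons <- codon_split(cds)
    k <- length(codons)
    if (k && codons[k] %in% code$stops) codons <- codons[-k]
    omega <- dnds[[g]]

    if (is.null(tree)) {
      tips <- lapply(seq_len(taxa), function(tx) {
        evolve_branch(codons, branch_length, omega, tstv, code)
      })
    } else {
      tips <- evolve_tree(codons, tree, omega, tstv, code)
    }
    alignments[[g]] <- setNames(
      vapply(tips, function(tp) paste(tp$codons, collapse = ""), ""), labels)
    events[[g]] <- data.frame(
      gene = g, taxon = labels,
      syn = vapply(tips, function(tp) tp$syn, 0L),
      nonsyn = vapply(tips, function(tp) tp$nonsyn, 0L),
      stringsAsFactors = FALSE)
  }

  structure(list(alignments = alignments,
                 truth = list(dnds = dnds,
                              events = do.call(rbind, c(events, list(make.row.names = FALSE))),
                              branch_length = branch_length, tstv = tstv,
                              seed = seed)),
            class = "mito_divergence")
}

#' @export
print.mito_divergence <- function(x, ...) {
  cat(sprintf("<mito_divergence> %d gene(s) x %d taxa; dN/dS targets %.3g-%.3g\n",
              length(x$alignments), length(x$alignments[[1L]]),
              min(x$truth$dnds), max(x$truth$dnds)))
  invisible(x)
}

evolve_branch <- function(codons, b, omega, tstv, code) {
  n_sites <- 3L * length(codons)
  n_events <- rpois(1L, b * n_sites)
  syn <- 0L; nonsyn <- 0L
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tab <- code$table
  if (n_events > 0L) for (e in seq_len(n_events)) {
    site <- sample.int(n_sites, 1L)
    ci <- (site - 1L) %/% 3L + 1L
    p <- (site - 1L) %% 3L + 1L
    cod <- seq_chars(codons[ci])
    cur <- cod[p]
    new <- if (runif(1L) < tstv / (tstv + 2)) ts_map[[cur]] else {
      sample(setdiff(.BASES, c(cur, ts_map[[cur]])), 1L)
    }
    cod[p] <- new
    nstr <- paste(cod, collapse = "")
    if (nstr %in% code$stops) next
    if (tab[[nstr]] == tab[[codons[ci]]]) {
      codons[ci] <- nstr
      syn <- syn + 1L
    } else if (runif(1L) < omega) {
      codons[ci] <- nstr
      nonsyn <- nonsyn + 1L
    }
  }
  list(codons = codons, syn = syn, nonsyn = nonsyn)
}

evolve_tree <- function(codons, tree, omega, tstv, code) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  acc <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- codons
  acc[[root]] <- c(syn = 0L, nonsyn = 0L)
  edges <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(edges$edge))) {
    from <- edges$edge[e, 1L]; to <- edges$edge[e, 2L]
    res <- evolve_branch(seqs[[from]], edges$edge.length[e], omega, tstv, code)
    seqs[[to]] <- res$codons
    acc[[to]] <- acc[[from]] + c(syn = res$syn, nonsyn = res$nonsyn)
  }
  lapply(seq_len(ntip), function(i) {
    list(codons = seqs[[i]], syn = acc[[i]][["syn"]], nonsyn = acc[[i]][["nonsyn"]])
  })
}

#' Derive assembly variants with injected ambiguities
#'
#' Emulates the multi-assembler correction scenario: the "primary"
#' assembly is the genome with `n_ambiguities` positions replaced by
#' two-base IUPAC codes compatible with the true base; the alternates are
#' unambiguous copies of the truth, optionally fragmented into
#' overlapping (and randomly reverse-complemented) pieces.
#'
#' @param genome a [mito_genome] or `mito_sim`.
#' @param n_ambiguities number of degenerate positions to inject.
#' @param n_alternates number of alternate assemblies.
#' @param fragment_length when not `NULL`, alternates are split into
#'   fragments of about this many bp, overlapping by `2 * flank_guard` so
#'   every site keeps full flank context in some fragment.
#' @param flank_guard minimum spacing kept between injected sites and
#'   fragment overlap width (default 40).
#' @param seed integer seed.
#' @return a list of class `assembly_variants`: `primary` (record with
#'   ambiguities), `alternates` (list of record lists), `truth`
#'   (data.frame `position`, `true_base`, `code`), `seed`.
#' @export
make_assembly_variants <- function(genome, n_ambiguities = 2L, n_alternates = 2L,
                                   fragment_length = NULL, flank_guard = 40L,
                                   seed = 1L) {
  if (inherits(genome, "mito_sim")) genome <- genome$genome
  stopifnot(inherits(genome, "mito_genome"), n_ambiguities >= 0L)
  set.seed(seed)
  chars <- seq_chars(genome$record$residues)
  L <- length(chars)

  positions <- integer(0)
  guard <- 2L * flank_guard
  tries <- 0L
  while (length(positions) < n_ambiguities) {
    cand <- sample.int(L, 1L)
    dist <- pmin(abs(cand - positions) %% L, (L - abs(cand - positions)) %% L)
    if (!length(positions) || all(dist > guard)) positions <- c(positions, cand)
    tries <- tries + 1L
    if (tries > 1000L * max(1L, n_ambiguities)) {
      stop("could not place ambiguities with the requested spacing", call. = FALSE)
    }
  }
  positions <- sort(positions)
  true_base <- chars[positions]
  code <- vapply(true_base, function(b) {
    other <- sample(setdiff(.BASES, b), 1L)
    .IUPAC_PAIR_CODE[[paste(sort(c(b, other)), collapse = "")]]
  }, "")

  prim_chars <- chars
  prim_chars[positions] <- code
  primary <- mito_record(sprintf("%s|primary|seed=%d", genome$record$id, seed),
                         paste(prim_chars, collapse = ""), circular = TRUE)

  truth_seq <- genome$record$residues
  alternates <- lapply(seq_len(n_alternates), function(a) {
    if (is.null(fragment_length)) {
      list(mito_record(sprintf("alt%d|seed=%d", a, seed), truth_seq, circular = TRUE))
    } else {
      step <- max(fragment_length - 2L * flank_guard, 1L)
      starts <- seq.int(1L, L, by = step)
      lapply(seq_along(starts), function(fi) {
        pos <- wrap_pos(starts[fi]:(starts[fi] + fragment_length - 1L), L)
        s <- paste(chars[pos], collapse = "")
        if (runif(1L) < 0.5) s <- revcomp(s)
        mito_record(sprintf("alt%d-frag%d|seed=%d", a, fi, seed), s)
      })
    }
  })

  structure(list(primary = primary, alternates = alternates,
                 truth = data.frame(position = positions, true_base = true_base,
                                    code = unname(code), stringsAsFactors = FALSE),
                 seed = seed),
            class = "assembly_variants")
}

#' Random circular gene layouts for geometry testing
#'
#' Generates an annotated genome with arbitrary (biologically
#' unconstrained) feature geometry: random feature lengths, random signed
#' gaps including overlaps, a random rotation so that one feature may span
#' the origin, and a uniform random sequence. Intended as a fuzzer for the
#' organization accounting, where only the coordinate arithmetic matters.
#'
#' @param n_features number of features (default drawn in 5..40).
#' @param seed integer seed.
#' @return a [mito_genome].
#' @export
random_genome_layout <- function(n_features = NULL, seed = 1L) {
  set.seed(seed)
  n <- n_features %||% sample(5:40, 1L)
  lens <- sample(60:1500, n, replace = TRUE)
  gaps <- integer(n)
  for (i in seq_len(n - 1L)) {
    max_ov <- min(lens[i], lens[i + 1L]) - 1L
    gaps[i] <- sample(seq.int(-min(15L, max_ov), 120L), 1L)
  }
  gaps[n] <- sample(0:120, 1L)  # closure gap back to the first feature
  starts <- cumsum(c(1L, (lens + gaps)[-n]))
  ends <- starts + lens - 1L
  L <- ends[n] + gaps[n]

  off <- sample.int(L, 1L) - 1L
  starts <- wrap_pos(starts + off, L)
  ends <- wrap_pos(ends + off, L)

  types <- sample(c("tRNA", "rRNA", "OL"), n, replace = TRUE)
  rec <- mito_record(sprintf("layout|seed=%d", seed),
                     paste(sample(.BASES, L, replace = TRUE), collapse = ""),
                     circular = TRUE)
  mito_genome(rec, mito_features(sprintf("f%02d", seq_len(n)), types,
                                 starts, ends,
                                 sample(c("H", "L"), n, replace = TRUE)))
}
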