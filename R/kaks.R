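# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Potential synonymous sites per codon: at each codon position the fraction
# of the three possible single-base changes that are synonymous, computed
# among changes that do not create a stop codon (nonsense changes are
# ignored, the classic convention); the nonsynonymous site count is the
# complement, so every codon contributes N + S = 3 sites. Observed
# differences between codons differing at k > 1 positions are apportioned
# by averaging over all k! substitution orderings, discarding orderings
# that pass through a stop codon (if every ordering does, all orderings
# are used as a documented fallback). Both per-codon tables are
# precomputed once per genetic code and cached.

.ng_cache <- new.env(parent = emptyenv())

ng_tables <- function(code) {
  key <- code$id
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  sense <- sense_codons(code)
  tab <- code$table
  stops <- code$stops

  syn_sites <- setNames(numeric(length(sense)), sense)
  for (cd in sense) {
    ch <- seq_chars(cd)
    s <- 0
    for (p in 1:3) {
      muts <- vapply(setdiff(.BASES, ch[p]), function(b) {
        m <- ch; m[p] <- b; paste(m, collapse = "")
      }, "")
      keep <- !(muts %in% stops)
      if (any(keep)) s <- s + sum(tab[muts[keep]] == tab[cd]) / sum(keep)
    }
    syn_sites[cd] <- s
  }

  n <- length(sense)
  Sd <- Nd <- matrix(0, n, n, dimnames = list(sense, sense))
  perms <- list(`1` = matrix(1L, 1, 1),
                `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                            c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(n)) {
    ci <- seq_chars(sense[i])
    for (j in seq_len(n)) {
      if (i >= j) next
      cj <- seq_chars(sense[j])
      diffpos <- which(ci != cj)
      k <- length(diffpos)
      if (k == 0L) next
      pm <- perms[[as.character(k)]]
      path_s <- path_n <- numeric(0)
      all_s <- all_n <- numeric(0)
      for (r in seq_len(nrow(pm))) {
        cur <- ci; s <- 0; ns <- 0; valid <- TRUE
        for (p in diffpos[pm[r, ]]) {
          nxt <- cur; nxt[p] <- cj[p]
          cs <- paste(cur, collapse = ""); nstr <- paste(nxt, collapse = "")
          if (nstr %in% stops) valid <- FALSE
          if (identical(tab[[cs]], tab[[nstr]]) && !(nstr %in% stops) && !(cs %in% stops)) {
            s <- s + 1
          } else ns <- ns + 1
          cur <- nxt
        }
        all_s <- c(all_s, s); all_n <- c(all_n, ns)
        if (valid) { path_s <- c(path_s, s); path_n <- c(path_n, ns) }
      }
      if (length(path_s)) {
        Sd[i, j] <- Sd[j, i] <- mean(path_s)
        Nd[i, j] <- Nd[j, i] <- mean(path_n)
      } else {
        Sd[i, j] <- Sd[j, i] <- mean(all_s)
        Nd[i, j] <- Nd[j, i] <- mean(all_n)
      }
    }
  }
  .ng_cache[[key]] <- list(syn_sites = syn_sites, Sd = Sd, Nd = Nd)
  .ng_cache[[key]]
}

jc_correct <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise Ka/Ks by the Nei-Gojobori method
#'
#' Sequences must be codon-aligned and of equal length; a trailing
#' incomplete codon is trimmed. Codon pairs in which either codon contains
#' a gap or ambiguity code are skipped; codon pairs involving a stop codon
#' are skipped with a warning (an aligned terminal stop is skipped
#' silently). Proportions `pN = Nd/N` and `pS = Sd/S` are Jukes-Cantor
#' corrected, `d = -(3/4) ln(1 - (4/3) p)`; a proportion at or beyond the
#' correction's 3/4 horizon is reported as saturated (`NA`). The statistic
#' is exactly symmetric in its two arguments.
#'
#' @param cds1,cds2 coding-strand, codon-aligned DNA strings.
#' @param code a [mito_code()] specification.
#' @return a list of class `kaks_pair`: `n_codons`, `N`, `S`, `Nd`, `Sd`,
#'   `pN`, `pS`, `ka`, `ks`, `kaks`, `saturated`, `n_skipped`.
#' @export
nei_gojobori_pair <- function(cds1, cds2, code = mito_code()) {
  s1 <- toupper(if (inherits(cds1, "mito_record")) cds1$residues else cds1)
  s2 <- toupper(if (inherits(cds2, "mito_record")) cds2$residues else cds2)
  if (nchar(s1) != nchar(s2)) stop("sequences must be codon-aligned and equal length", call. = FALSE)
  nc <- nchar(s1) %/% 3L
  if (nc == 0L) stop("alignment shorter than one codon", call. = FALSE)
  c1 <- codon_split(s1)[seq_len(nc)]
  c2 <- codon_split(s2)[seq_len(nc)]

  sense <- sense_codons(code)
  clean <- c1 %in% sense & c2 %in% sense
  has_stop <- (c1 %in% code$stops) | (c2 %in% code$stops)
  if (any(has_stop & seq_len(nc) < nc)) {
    warning(sprintf("%d non-terminal codon pair(s) involve stop codons; skipped",
                    sum(has_stop & seq_len(nc) < nc)))
  }
  n_skipped <- sum(!clean)
  c1 <- c1[clean]; c2 <- c2[clean]
  if (!length(c1)) stop("no comparable sense codon pairs", call. = FALSE)

  tabs <- ng_tables(code)
  S <- (sum(tabs$syn_sites[c1]) + sum(tabs$syn_sites[c2])) / 2
  N <- 3 * length(c1) - S
  idx <- cbind(match(c1, sense), match(c2, sense))
  Sd <- sum(tabs$Sd[idx])
  Nd <- sum(tabs$Nd[idx])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  ks <- jc_correct(pS)
  ka <- jc_correct(pN)
  saturated <- c(if (!is.na(pS) && pS >= 0.75) "ks", if (!is.na(pN) && pN >= 0.75) "ka")
  kaks <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_

  structure(list(n_codons = length(c1), N = N, S = S, Nd = Nd, Sd = Sd,
                 pN = pN, pS = pS, ka = ka, ks = ks, kaks = kaks,
                 saturated = saturated, n_skipped = n_skipped),
            class = "kaks_pair")
}

#' @export
print.kaks_pair <- function(x, ...) {
  cat(sprintf("<kaks_pair> %d codons: Ka %.4f (Nd %.2f / N %.1f), Ks %.4f (Sd %.2f / S %.1f), Ka/Ks %s\n",
              x$n_codons, x$ka, x$Nd, x$N, x$ks, x$Sd, x$S,
              ifelse(is.na(x$kaks), "undefined", sprintf("%.3f", x$kaks))))
  invisible(x)
}

#' Gene-level Ka/Ks across a set of taxa
#'
#' Computes all pairwise [nei_gojobori_pair()] values per gene and
#' aggregates each gene as `mean(Ka) / mean(Ks)` over the pairs with
#' defined (unsaturated) values -- the ratio of means is robust to
#' near-zero per-pair Ks; the full per-pair table is returned alongside.
#' A gene in which two taxa are identical contributes a 0/0 pair; a gene
#' whose mean Ks is 0 (or with no usable pair) is reported as undefined.
#'
#' @param alignments a named list (one element per gene) of named
#'   character vectors: taxon -> aligned coding sequence.
#' @param code a [mito_code()] specification.
#' @return a list of class `kaks_table` with `genes` (gene, `n_pairs`,
#'   `mean_ka`, `mean_ks`, `kaks`) and `pairs` (per-pair rows).
#' @export
gene_kaks <- function(alignments, code = mito_code()) {
  stopifnot(is.list(alignments), length(alignments) > 0L)
  if (is.null(names(alignments))) names(alignments) <- sprintf("gene%d", seq_along(alignments))
  pair_rows <- list()
  gene_rows <- list()
  for (g in names(alignments)) {
    aln <- alignments[[g]]
    taxa <- names(aln)
    if (length(aln) < 2L) stop(sprintf("%s: need at least two taxa", g), call. = FALSE)
    cmb <- combn(length(aln), 2L)
    rows <- lapply(seq_len(ncol(cmb)), function(k) {
      i <- cmb[1L, k]; j <- cmb[2L, k]
      p <- nei_gojobori_pair(aln[[i]], aln[[j]], code)
      data.frame(gene = g, taxon1 = taxa[i], taxon2 = taxa[j],
                 n_codons = p$n_codons, ka = p$ka, ks = p$ks, kaks = p$kaks,
                 saturated = length(p$saturated) > 0L, stringsAsFactors = FALSE)
    })
    pr <- do.call(rbind, rows)
    pair_rows[[g]] <- pr
    ok <- !is.na(pr$ka) & !is.na(pr$ks)
    mean_ka <- if (any(ok)) mean(pr$ka[ok]) else NA_real_
    mean_ks <- if (any(ok)) mean(pr$ks[ok]) else NA_real_
    ratio <- if (any(ok) && mean_ks > 0) mean_ka / mean_ks else NA_real_
    gene_rows[[g]] <- data.frame(gene = g, n_pairs = sum(ok),
                                 mean_ka = mean_ka, mean_ks = mean_ks,
                                 kaks = ratio, stringsAsFactors = FALSE)
  }
  out <- list(genes = do.call(rbind, c(gene_rows, list(make.row.names = FALSE))),
              pairs = do.call(rbind, c(pair_rows, list(make.row.names = FALSE))))
  class(out) <- "kaks_table"
  out
}

#' @export
print.kaks_table <- function(x, ...) {
  g <- x$genes
  cat(sprintf("<kaks_table> %d gene(s), %d pairwise comparisons\n", nrow(g), nrow(x$pairs)))
  ord <- order(-ifelse(is.na(g$kaks), -Inf, g$kaks))
  print.data.frame(g[ord, ], row.names = FALSE, digits = 4)
  invisible(x)
}
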