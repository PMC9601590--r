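# Base composition, A+T content, and strand-asymmetry (AT/GC skew)
# statistics per region and per protein-coding codon position.

#' AT and GC skew
#'
#' `AT-skew = (A - T) / (A + T)`, `GC-skew = (G - C) / (G + C)`. Inputs may
#' be counts, fractions or percentages (the ratios are scale-invariant).
#' A zero denominator yields `NA` (undefined).
#'
#' @param a,t,g,c base amounts (vectors recycle).
#' @return a `data.frame` with columns `at_skew` and `gc_skew`, unrounded;
#'   the reporting layer rounds to 2 decimals.
#' @export
compute_skews <- function(a, t, g, c) {
  if (any(c(a, t, g, c) < 0)) stop("base amounts must be non-negative", call. = FALSE)
  at <- ifelse(a + t > 0, (a - t) / (a + t), NA_real_)
  gc <- ifelse(g + c > 0, (g - c) / (g + c), NA_real_)
  data.frame(at_skew = at, gc_skew = gc)
}

#' Base composition of a sequence
#'
#' Counts and percentages of A, C, G, T, the A+T content and both skews.
#' Percentages are relative to the unambiguous total; ambiguous bases are
#' counted separately (`n_ambiguous`) and excluded from numerators and
#' denominators, with a warning.
#'
#' @param seq a [mito_record] or DNA string.
#' @param region label for the output row.
#' @return a one-row `data.frame` of class `composition_summary` holding
#'   unrounded values; see [format_composition()] for table-style rounding.
#' @export
base_composition <- function(seq, region = "sequence") {
  rec <- as_record(seq)
  chars <- seq_chars(rec$residues)
  composition_row(chars, region)
}

composition_row <- function(chars, region) {
  n_amb <- sum(is_ambiguous(chars))
  counts <- vapply(.BASES, function(b) sum(chars == b), 0L)
  total <- sum(counts)
  if (total == 0L) stop(sprintf("region '%s': no unambiguous bases", region), call. = FALSE)
  if (n_amb > 0L) {
    warning(sprintf("region '%s': %d ambiguous base(s) excluded from percentages",
                    region, n_amb))
  }
  pct <- 100 * counts / total
  sk <- compute_skews(counts["A"], counts["T"], counts["G"], counts["C"])
  out <- data.frame(
    region = region, size = length(chars),
    count_A = counts[["A"]], count_C = counts[["C"]],
    count_G = counts[["G"]], count_T = counts[["T"]],
    pct_A = pct[["A"]], pct_C = pct[["C"]], pct_G = pct[["G"]], pct_T = pct[["T"]],
    at_content = pct[["A"]] + pct[["T"]],
    at_skew = sk$at_skew, gc_skew = sk$gc_skew,
    n_ambiguous = n_amb, stringsAsFactors = FALSE)
  class(out) <- c("composition_summary", "data.frame")
  out
}

#' Round a composition summary for table-style reporting
#'
#' Percentages to 1 decimal, skews to 2 decimals; unrounded values are
#' retained in the input object.
#'
#' @param x a `composition_summary` (any number of rows).
#' @return a plain `data.frame` with the rounded reporting columns.
#' @export
format_composition <- function(x) {
  data.frame(region = x$region, size = x$size,
             pct_A = round(x$pct_A, 1), pct_T = round(x$pct_T, 1),
             pct_C = round(x$pct_C, 1), pct_G = round(x$pct_G, 1),
             at_content = round(x$at_content, 1),
             at_skew = round(x$at_skew, 2), gc_skew = round(x$gc_skew, 2),
             stringsAsFactors = FALSE)
}

#' Regional composition summaries of an annotated mitogenome
#'
#' One [base_composition()] row each for the whole genome, the control
#' region (labelled `D-loop`), each rRNA, the pooled tRNAs, the pooled
#' protein-coding genes (concatenated in annotation order after
#' light-strand orientation), and the three PCG codon positions. Region
#' classes absent from the annotation are omitted with a warning.
#'
#' Codon positions are assigned per gene from that gene's own reading
#' frame, so a gene whose length is not a multiple of 3 (incomplete stop
#' codon) contributes only the positions its partial terminal codon
#' actually has. `position_assignment = "concatenated"` instead chops the
#' pooled PCG sequence into global triplets, which is what some annotation
#' suites report; the two conventions give slightly different position
#' sizes whenever incomplete stop codons are present.
#'
#' @param genome a [mito_genome].
#' @param position_assignment `"per_gene"` (default) or `"concatenated"`.
#' @return a multi-row `composition_summary` data.frame.
#' @export
regional_summaries <- function(genome,
                               position_assignment = c("per_gene", "concatenated")) {
  stopifnot(inherits(genome, "mito_genome"))
  position_assignment <- match.arg(position_assignment)
  ft <- genome$features
  rows <- list()

  cr <- which(ft$type == "CR")
  if (length(cr)) {
    rows <- c(rows, lapply(cr, function(i) {
      composition_row(seq_chars(extract_feature_sequence(genome, ft[i, ])), "D-loop")
    }))
  } else warning("no control-region (CR) feature annotated; D-loop row omitted")

  rr <- which(ft$type == "rRNA")
  if (length(rr)) {
    rows <- c(rows, lapply(rr, function(i) {
      composition_row(seq_chars(extract_feature_sequence(genome, ft[i, ])), ft$name[i])
    }))
  } else warning("no rRNA features annotated; rRNA rows omitted")

  tr <- which(ft$type == "tRNA")
  if (length(tr)) {
    chars <- unlist(lapply(tr, function(i) {
      seq_chars(extract_feature_sequence(genome, ft[i, ]))
    }))
    rows <- c(rows, list(composition_row(chars, "tRNAs")))
  } else warning("no tRNA features annotated; tRNA row omitted")

  pc <- which(ft$type == "PCG")
  if (length(pc)) {
    per_gene <- lapply(pc, function(i) {
      seq_chars(extract_feature_sequence(genome, ft[i, ]))
    })
    pooled <- unlist(per_gene)
    pos <- switch(position_assignment,
      per_gene = unlist(lapply(per_gene, function(ch) rep_len(1:3, length(ch)))),
      concatenated = rep_len(1:3, length(pooled)))
    for (p in 1:3) {
      rows <- c(rows, list(composition_row(pooled[pos == p], sprintf("PCGs-%s", c("1st", "2nd", "3rd")[p]))))
    }
    rows <- c(rows, list(composition_row(pooled, "PCGs")))
  } else warning("no PCG features annotated; PCG rows omitted")

  rows <- c(rows, list(composition_row(seq_chars(genome$record$residues), "Genome")))
  out <- do.call(rbind, rows)
  class(out) <- c("composition_summary", "data.frame")
  rownames(out) <- NULL
  out
}

#' Per-gene AT and GC skews of the protein-coding genes
#'
#' Skews are computed on the coding-strand-oriented sequence of each PCG,
#' so a light-strand gene (typically ND6) is reverse-complemented first.
#'
#' @param genome a [mito_genome] with at least one PCG.
#' @return a `data.frame` with columns `gene`, `at_content`, `at_skew`,
#'   `gc_skew`.
#' @export
per_gene_skews <- function(genome) {
  stopifnot(inherits(genome, "mito_genome"))
  pc <- which(genome$features$type == "PCG")
  if (!length(pc)) stop("no protein-coding genes annotated", call. = FALSE)
  rows <- lapply(pc, function(i) {
    cc <- composition_row(
      seq_chars(extract_feature_sequence(genome, genome$features[i, ])),
      genome$features$name[i])
    data.frame(gene = cc$region, at_content = cc$at_content,
               at_skew = cc$at_skew, gc_skew = cc$gc_skew,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
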