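# Gene organization analytics: per-feature lengths, start/stop codons,
# signed inter-feature gaps on the circle, and overlap / intergenic
# summaries.

#' Build the gene organization table
#'
#' One row per annotated feature, in circle order. Protein-coding rows
#' carry the observed first codon and the classified stop codon from
#' [translate_mito()] (incomplete stops rendered `T(AA)` / `TA(A)`). The
#' `ign` column is the signed intergenic gap FOLLOWING the feature on the
#' circle: `start(next) - end(this) - 1`, computed modularly, with
#' negative values marking overlaps; the last row gaps back to the first.
#' Non-coding features (control region, OL) participate in the adjacency
#' chain as first-class rows.
#'
#' @param genome a [mito_genome] with at least one feature.
#' @param code a [mito_code()] specification; a PCG whose first codon is
#'   not in the permitted start set triggers a warning but the codon is
#'   still reported.
#' @return a `data.frame` of class `mito_org_table` with columns `gene`,
#'   `type`, `strand`, `start`, `end`, `length`, `start_codon`,
#'   `stop_codon`, `ign`, and the genome length as an attribute.
#' @export
build_gene_table <- function(genome, code = mito_code()) {
  stopifnot(inherits(genome, "mito_genome"))
  ft <- genome$features
  if (nrow(ft) == 0L) stop("annotated genome has no features", call. = FALSE)
  L <- genome$length

  lens <- mapply(span_length, ft$start, ft$end, MoreArgs = list(len = L))
  nxt <- c(seq_len(nrow(ft))[-1L], 1L)
  gap <- (ft$start[nxt] - ft$end - 1L) %% L
  gap <- ifelse(gap > L / 2, gap - L, gap)

  start_codon <- rep(NA_character_, nrow(ft))
  stop_codon <- rep(NA_character_, nrow(ft))
  for (i in which(ft$type == "PCG")) {
    cds <- extract_feature_sequence(genome, ft[i, ])
    tr <- translate_mito(cds, code)
    start_codon[i] <- tr$start_codon
    stop_codon[i] <- tr$stop_display
    if (!tr$start_ok) {
      warning(sprintf("%s: first codon %s is not a permitted start codon",
                      ft$name[i], tr$start_codon))
    }
  }

  out <- data.frame(gene = ft$name, type = ft$type, strand = ft$strand,
                    start = ft$start, end = ft$end, length = as.integer(lens),
                    start_codon = start_codon, stop_codon = stop_codon,
                    ign = as.integer(gap), stringsAsFactors = FALSE)
  class(out) <- c("mito_org_table", "data.frame")
  attr(out, "genome_length") <- L
  out
}

#' @export
print.mito_org_table <- function(x, ...) {
  cat(sprintf("<mito_org_table> %d features on a %s bp circle (ign = gap following each feature)\n",
              nrow(x), format(attr(x, "genome_length"), big.mark = ",")))
  print.data.frame(x)
  invisible(x)
}

#' Summarise overlaps and intergenic spacers
#'
#' Totals, counts and extremes of the signed gaps in a gene organization
#' table: strictly negative gaps are overlaps between neighbouring
#' features, strictly positive gaps are intergenic nucleotides (IGN).
#'
#' @param rows a `mito_org_table` from [build_gene_table()].
#' @return a list of class `spacer_summary`: `overlap_total`,
#'   `overlap_pairs`, `longest_overlap`, `longest_overlap_pair`,
#'   `ign_total`, `ign_locations`, `longest_gap`, `longest_gap_pair`.
#' @export
spacer_summary <- function(rows) {
  stopifnot(inherits(rows, "mito_org_table"))
  nxt <- c(rows$gene[-1L], rows$gene[1L])
  pair <- paste(rows$gene, nxt, sep = "/")
  neg <- rows$ign < 0L
  pos <- rows$ign > 0L

  longest_overlap <- if (any(neg)) max(-rows$ign[neg]) else 0L
  longest_gap <- if (any(pos)) max(rows$ign[pos]) else 0L
  structure(list(
    overlap_total = sum(-rows$ign[neg]),
    overlap_pairs = sum(neg),
    longest_overlap = longest_overlap,
    longest_overlap_pair = if (any(neg)) pair[neg][which.max(-rows$ign[neg])] else NA_character_,
    ign_total = sum(rows$ign[pos]),
    ign_locations = sum(pos),
    longest_gap = longest_gap,
    longest_gap_pair = if (any(pos)) pair[pos][which.max(rows$ign[pos])] else NA_character_
  ), class = "spacer_summary")
}

#' @export
print.spacer_summary <- function(x, ...) {
  cat(sprintf(
    "<spacer_summary>\n  overlaps:   %d bp in %d neighbouring pairs (longest %d bp, %s)\n  intergenic: %d bp in %d locations (longest %d bp, %s)\n",
    x$overlap_total, x$overlap_pairs, x$longest_overlap,
    x$longest_overlap_pair %||% "-",
    x$ign_total, x$ign_locations, x$longest_gap, x$longest_gap_pair %||% "-"))
  invisible(x)
}
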