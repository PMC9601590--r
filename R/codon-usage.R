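# Codon counting and relative synonymous codon usage (RSCU).

#' Count codon usage over a set of coding sequences
#'
#' Walks each CDS in-frame (sequences must already be oriented to the
#' coding strand). Complete sense codons are counted; a terminal stop
#' codon is tallied separately; an incomplete terminal codon (trailing 1-2
#' bases) is dropped; codons containing gaps or ambiguity codes are
#' skipped and logged. An internal in-frame stop is an error naming the
#' gene and codon index.
#'
#' @param cds a character vector of coding sequences (optionally named by
#'   gene), a single string, or a list of strings.
#' @param code a [mito_code()] specification.
#' @return a named integer vector over the sense codons of the code, with
#'   attributes `stop_counts` (named tally of terminal stops) and
#'   `n_skipped` (ambiguous codons dropped).
#' @export
codon_counts <- function(cds, code = mito_code()) {
  cds <- unlist(cds, use.names = TRUE)
  if (is.null(names(cds)) && length(cds)) names(cds) <- sprintf("cds%d", seq_along(cds))
  sense <- sense_codons(code)
  counts <- setNames(integer(length(sense)), sense)
  stop_counts <- setNames(integer(length(code$stops)), code$stops)
  n_skipped <- 0L

  for (g in names(cds)) {
    s <- toupper(cds[[g]])
    codons <- codon_split(s)
    k <- length(codons)
    if (!k) next
    ambig <- vapply(codons, function(cc) any(!(seq_chars(cc) %in% .BASES)), TRUE)
    is_stop <- !ambig & codons %in% code$stops
    if (any(is_stop)) {
      internal <- which(is_stop & seq_len(k) < k)
      if (length(internal)) {
        stop(sprintf("%s: internal stop codon %s at codon index %s", g,
                     paste(codons[internal], collapse = ", "),
                     paste(internal, collapse = ", ")), call. = FALSE)
      }
      stop_counts[codons[k]] <- stop_counts[codons[k]] + 1L
    }
    keep <- codons[!ambig & !is_stop]
    n_skipped <- n_skipped + sum(ambig)
    tb <- table(keep)
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
  }
  structure(counts, stop_counts = stop_counts, n_skipped = n_skipped)
}

#' Relative synonymous codon usage
#'
#' For a codon with observed count `x` in a synonymous family of size `n`
#' totalling `X` uses, `RSCU = x / (X / n)`: the observed count divided by
#' the mean count of its family. Families are the synonymous codon sets of
#' the vertebrate mitochondrial code (no single-codon families exist under
#' this code). A family with zero total has undefined RSCU (`NA`).
#'
#' Codons are reported in the RNA alphabet (e.g. `CUA`), the convention of
#' codon-usage bar charts; the DNA spelling is kept alongside.
#'
#' @param counts codon counts from [codon_counts()].
#' @param code a [mito_code()] specification.
#' @return a `data.frame` of class `rscu_table` with columns `codon`
#'   (DNA), `codon_rna`, `aa`, `count`, `family_size`, `rscu`. RSCU values
#'   within each family sum to the family size.
#' @export
rscu <- function(counts, code = mito_code()) {
  sense <- sense_codons(code)
  if (!all(sense %in% names(counts))) stop("counts must cover all sense codons", call. = FALSE)
  counts <- counts[sense]
  aa <- unname(code$table[sense])
  fam_size <- ave(rep(1L, length(sense)), aa, FUN = sum)
  fam_total <- ave(as.numeric(counts), aa, FUN = sum)
  val <- ifelse(fam_total > 0, counts / (fam_total / fam_size), NA_real_)
  out <- data.frame(codon = sense, codon_rna = chartr("T", "U", sense), aa = aa,
                    count = as.integer(counts), family_size = as.integer(fam_size),
                    rscu = val, stringsAsFactors = FALSE)
  out <- out[order(out$aa, out$codon), ]
  rownames(out) <- NULL
  class(out) <- c("rscu_table", "data.frame")
  out
}

#' @export
print.rscu_table <- function(x, ...) {
  cat(sprintf("<rscu_table> %d sense codons, %d amino-acid families, %d codons counted\n",
              nrow(x), length(unique(x$aa)), sum(x$count)))
  top <- x[order(-ifelse(is.na(x$rscu), -Inf, x$rscu)), ]
  cat("most over-represented:",
      paste(sprintf("%s (%s, %.2f)", head(top$codon_rna, 4), head(top$aa, 4),
                    head(top$rscu, 4)), collapse = ", "), "\n")
  invisible(x)
}
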