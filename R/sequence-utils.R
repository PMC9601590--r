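# IUPAC nucleotide alphabet and low-level string utilities.
# Sequences are stored as uppercase character scalars; coordinates are
# 1-based inclusive throughout, with circular wrap expressed as start > end.

.IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
.DNA_LETTERS <- names(.IUPAC_EXPAND)
.BASES <- c("A", "C", "G", "T")
.COMP_FROM <- "ACGTRYSWKMBDHVN"
.COMP_TO   <- "TGCAYRSWMKVHDBN"
.COMP_MAP <- setNames(strsplit(.COMP_TO, "")[[1]], strsplit(.COMP_FROM, "")[[1]])

# two-base ambiguity code for an unordered base pair, e.g. C+T -> Y
.IUPAC_PAIR_CODE <- local({
  two <- Filter(function(x) length(x) == 2L, .IUPAC_EXPAND)
  setNames(names(two), vapply(two, function(b) paste(sort(b), collapse = ""), ""))
})

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of a DNA string
#'
#' Handles the full IUPAC alphabet (e.g. `Y` complements to `R`).
#'
#' @param x a DNA string (character scalar) or character vector of single
#'   bases.
#' @return an object of the same shape as `x`.
#' @examples
#' revcomp("AAAC")  # "GTTT"
#' @export
revcomp <- function(x) {
  if (length(x) == 1L && nchar(x) != 1L) {
    comp <- chartr(.COMP_FROM, .COMP_TO, toupper(x))
    paste(rev(seq_chars(comp)), collapse = "")
  } else {
    unname(rev(.COMP_MAP[toupper(x)]))
  }
}

complement_bases <- function(x) unname(.COMP_MAP[x])

validate_residues <- function(chars, id = "sequence") {
  bad <- which(!(chars %in% .DNA_LETTERS))
  if (length(bad)) {
    stop(sprintf(
      "record '%s': invalid residue(s) %s at position(s) %s",
      id,
      paste(unique(chars[head(bad, 5L)]), collapse = ", "),
      paste(head(bad, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

is_ambiguous <- function(chars) !(chars %in% .BASES)

# circular index arithmetic: map arbitrary integer positions onto 1..len
wrap_pos <- function(pos, len) ((pos - 1L) %% len) + 1L

# positions covered by a feature interval; start > end means wrap over the
# origin
span_positions <- function(start, end, len) {
  if (start <= end) seq.int(start, end) else c(seq.int(start, len), seq.int(1L, end))
}

span_length <- function(start, end, len) {
  if (start <= end) end - start + 1L else len - start + 1L + end
}
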