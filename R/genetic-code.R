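# Vertebrate mitochondrial genetic code and CDS translation with
# incomplete-stop classification.

#' Vertebrate mitochondrial genetic code specification
#'
#' Wraps the NCBI translation table 2 (vertebrate mitochondrial: `TGA` is
#' Trp, `ATA` is Met, and `AGA`/`AGG` are stops) together with the set of
#' permitted initiation codons. `ATG` and `GTG` are the defaults; other
#' vertebrates also use `ATA`/`ATT`, which can be supplied here.
#'
#' @param starts character vector of permitted start codons.
#' @return an object of class `genetic_code` with elements `id`, `table`
#'   (named character vector codon -> amino acid, `*` for stop), `starts`
#'   and `stops`.
#' @export
mito_code <- function(starts = c("ATG", "GTG")) {
  tab <- Biostrings::getGeneticCode("2")
  stops <- names(tab)[tab == "*"]
  starts <- toupper(starts)
  if (any(starts %in% stops)) stop("start and stop codon sets must be disjoint", call. = FALSE)
  if (!all(starts %in% names(tab))) stop("invalid start codon(s)", call. = FALSE)
  structure(list(id = "2", name = "vertebrate mitochondrial",
                 table = tab, starts = starts, stops = stops),
            class = "genetic_code")
}

sense_codons <- function(code) names(code$table)[code$table != "*"]

codon_split <- function(x) {
  n <- nchar(x) %/% 3L
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a mitochondrial CDS and classify its stop codon
#'
#' Translates under the vertebrate mitochondrial code. A trailing remainder
#' of one (`T`) or two (`TA`) bases is classified as an incomplete stop
#' codon, completed to `TAA` by mRNA polyadenylation and rendered `T(AA)` /
#' `TA(A)`; a terminal `TAA`, `TAG`, `AGA` or `AGG` is a complete stop.
#' An in-frame stop anywhere else is an error. Codons containing IUPAC
#' ambiguity codes translate to `X` with a warning.
#'
#' @param cds coding sequence, already oriented to the coding strand.
#' @param code a [mito_code()] specification.
#' @return an object of class `mito_translation`: a list with `protein`,
#'   `n_codons`, `start_codon`, `start_ok`, `stop_type` (`"complete"`,
#'   `"incomplete"` or `"none"`), `stop_codon` and `stop_display`.
#' @export
translate_mito <- function(cds, code = mito_code()) {
  cds <- toupper(if (inherits(cds, "mito_record")) cds$residues else cds)
  n <- nchar(cds)
  if (n < 3L) stop("CDS shorter than one codon", call. = FALSE)
  validate_residues(seq_chars(cds), "cds")
  rem <- n %% 3L
  codons <- codon_split(cds)
  k <- length(codons)

  if (rem == 0L && codons[k] %in% code$stops) {
    stop_type <- "complete"
    stop_codon <- codons[k]
    stop_display <- stop_codon
    coding <- codons[-k]
  } else if (rem > 0L) {
    tail_bases <- substr(cds, n - rem + 1L, n)
    stop_type <- "incomplete"
    stop_codon <- tail_bases
    completion <- substr("TAA", rem + 1L, 3L)
    stop_display <- paste0(tail_bases, "(", completion, ")")
    if (tail_bases != substr("TAA", 1L, rem)) {
      warning(sprintf("trailing remainder '%s' cannot be polyadenylated to TAA", tail_bases))
    }
    coding <- codons
  } else {
    stop_type <- "none"
    stop_codon <- NA_character_
    stop_display <- NA_character_
    coding <- codons
    warning("CDS does not end in a stop codon (complete or incomplete)")
  }

  ambig <- vapply(coding, function(cc) any(is_ambiguous(seq_chars(cc))), TRUE)
  if (any(ambig)) {
    warning(sprintf("%d codon(s) contain ambiguity codes; translated as X", sum(ambig)))
  }
  aa <- ifelse(ambig, "X", unname(code$table[coding]))
  internal_stop <- which(!ambig & aa == "*")
  if (length(internal_stop)) {
    stop(sprintf("internal in-frame stop codon(s) %s at codon index %s",
                 paste(coding[internal_stop], collapse = ", "),
                 paste(internal_stop, collapse = ", ")), call. = FALSE)
  }

  structure(list(
    protein = paste(aa, collapse = ""),
    n_codons = length(coding),
    start_codon = codons[1L],
    start_ok = codons[1L] %in% code$starts,
    stop_type = stop_type,
    stop_codon = stop_codon,
    stop_display = stop_display
  ), class = "mito_translation")
}

#' @export
print.mito_translation <- function(x, ...) {
  cat(sprintf("<mito_translation> %d aa, start %s%s, stop %s (%s)\n",
              x$n_codons, x$start_codon, if (x$start_ok) "" else " (non-canonical)",
              x$stop_display, x$stop_type))
  invisible(x)
}
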