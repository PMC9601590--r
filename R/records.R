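# SequenceRecord container and FASTA input/output.

#' Create a sequence record
#'
#' A light container for a DNA sequence: an identifier, the residues
#' (uppercase, IUPAC alphabet) and a circularity flag. Mitogenomes are
#' circular; assembly fragments are linear.
#'
#' @param id character label.
#' @param residues DNA string over `A,C,G,T` plus IUPAC ambiguity codes
#'   (case-insensitive; stored uppercase).
#' @param circular logical; is the molecule circular?
#' @return an object of class `mito_record`.
#' @export
mito_record <- function(id, residues, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) stop(sprintf("record '%s': empty sequence", id), call. = FALSE)
  validate_residues(seq_chars(residues), id)
  structure(list(id = id, residues = residues, circular = isTRUE(circular)),
            class = "mito_record")
}

#' @export
print.mito_record <- function(x, ...) {
  cat(sprintf("<mito_record> %s: %s bp, %s\n", x$id,
              format(nchar(x$residues), big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

as_record <- function(x, id = "sequence", circular = FALSE) {
  if (inherits(x, "mito_record")) x else mito_record(id, x, circular)
}

#' Read a FASTA file
#'
#' Parses a (multi-)FASTA file and validates each record against the IUPAC
#' nucleotide alphabet; an invalid character is reported with its record
#' name and position.
#'
#' @param path path to a FASTA file.
#' @param circular logical flag stored on every returned record.
#' @return a list of [mito_record] objects.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("FASTA file is empty: %s", path), call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    mito_record(ids[i], as.character(set[[i]]), circular = circular)
  })
}

#' Write records to a FASTA file
#'
#' @param records a [mito_record] or list of them.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "mito_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$residues, "")
  ids <- vapply(records, function(r) r$id, "")
  set <- Biostrings::BStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
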