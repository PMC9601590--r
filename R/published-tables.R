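# Bundled published summary tables (GenBank-derived), used to validate the
# skew arithmetic against independently reported values.

read_bundled_tsv <- function(file) {
  path <- system.file("extdata", file, package = "mitochar", mustWork = TRUE)
  df <- read.delim(path, header = FALSE, comment.char = "", skip = 1L,
                   stringsAsFactors = FALSE)
  header <- sub("^#", "", readLines(path, n = 1L))
  names(df) <- strsplit(header, "\t", fixed = TRUE)[[1]]
  df
}

#' Published whole-genome composition of 33 salamandrid mitogenomes
#'
#' Reported base percentages, A+T content and skews (2 decimals) for 33
#' salamander mitogenomes, with GenBank accessions. Useful as an
#' independent fixture: re-deriving the skews from the reported
#' percentages with [compute_skews()] must reproduce the reported skews
#' within double-rounding tolerance.
#'
#' @return a `data.frame` with columns `species`, `total_length`, `pct_T`,
#'   `pct_C`, `pct_A`, `pct_G`, `at_content`, `at_skew`, `gc_skew`,
#'   `accession`.
#' @export
published_genome_compositions <- function() {
  read_bundled_tsv("salamandrid_genome_composition.tsv")
}

#' Published per-region composition of two crocodile newt mitogenomes
#'
#' Reported region sizes, base percentages and skews for the mitogenomes
#' of *Tylototriton broadoridgus* (OP598114) and *T. gaowangjienensis*
#' (ON764431): control region, rRNAs, pooled tRNAs, pooled protein-coding
#' genes and their codon positions, and the whole genome.
#'
#' @return a `data.frame` with columns `species`, `region`, `size`,
#'   `pct_A`, `pct_T`, `pct_C`, `pct_G`, `at_content`, `at_skew`,
#'   `gc_skew`.
#' @export
published_region_compositions <- function() {
  read_bundled_tsv("tylototriton_region_composition.tsv")
}
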