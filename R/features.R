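# Feature annotations, the annotated-genome container, the five-column
# feature-table dialect, and feature sequence extraction.

.FEATURE_TYPES <- c("PCG", "tRNA", "rRNA", "CR", "OL")

#' Build a feature annotation table
#'
#' Features are stored with canonical `start <= end` plus a strand flag;
#' orientation is applied only at extraction. `start > end` is reserved for
#' origin-wrapping features (on either strand the stored coordinates still
#' ascend along the heavy strand).
#'
#' @param name gene labels (duplicated names are conventionally
#'   disambiguated with a suffix, e.g. `tRNA-Leu1` / `tRNA-Leu2`).
#' @param type one of `PCG`, `tRNA`, `rRNA`, `CR`, `OL` per feature.
#' @param start,end 1-based inclusive coordinates on the circle.
#' @param strand `"H"` (heavy) or `"L"` (light) per feature.
#' @param anticodon optional tRNA anticodon (3-mer), `NA` otherwise.
#' @return a `data.frame` with one row per feature.
#' @export
mito_features <- function(name, type, start, end, strand, anticodon = NA_character_) {
  type <- as.character(type)
  strand <- as.character(strand)
  if (!all(type %in% .FEATURE_TYPES)) {
    stop(sprintf("unknown feature type(s): %s",
                 paste(setdiff(unique(type), .FEATURE_TYPES), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(strand %in% c("H", "L"))) stop("strand must be 'H' or 'L'", call. = FALSE)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(end < 1L)) stop("coordinates must be >= 1", call. = FALSE)
  data.frame(name = as.character(name), type = type, start = start, end = end,
             strand = strand,
             anticodon = rep_len(as.character(anticodon), length(name)),
             stringsAsFactors = FALSE)
}

#' Assemble an annotated mitogenome
#'
#' Couples a circular sequence record with its ordered feature annotation.
#' Features are sorted into circle order by start coordinate; coordinates
#' are validated against the sequence length.
#'
#' @param record a circular [mito_record].
#' @param features a feature table from [mito_features()] or
#'   [read_feature_table()].
#' @return an object of class `mito_genome` with elements `record`,
#'   `features` and `length`.
#' @export
mito_genome <- function(record, features) {
  record <- as_record(record, circular = TRUE)
  if (!record$circular) stop("mitogenome record must be circular", call. = FALSE)
  len <- nchar(record$residues)
  if (any(features$start > len) || any(features$end > len)) {
    stop(sprintf("feature coordinates exceed genome length %d", len), call. = FALSE)
  }
  if (sum(features$type == "CR") > 1L) {
    warning("more than one control-region (CR) feature annotated")
  }
  dup <- features$name[duplicated(features$name)]
  if (length(dup)) {
    warning(sprintf("duplicated feature name(s): %s", paste(unique(dup), collapse = ", ")))
  }
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(record = record, features = features, length = len),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  tb <- table(factor(x$features$type, levels = .FEATURE_TYPES))
  cat(sprintf("<mito_genome> %s: %s bp circular; %d features (%s)\n",
              x$record$id, format(x$length, big.mark = ","), nrow(x$features),
              paste(sprintf("%s %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Read a five-column feature table
#'
#' Tab-separated dialect with columns `gene`, `type`, `from`, `to`,
#' `anticodon` (last column optional/empty); lines starting with `#` are
#' ignored. A light-strand feature is encoded by reversed coordinate order
#' (`from > to`) and is stored canonically with `start < end` and
#' `strand = "L"`. The dialect cannot express origin-wrapping features.
#'
#' @param path input path.
#' @param genome_length circle length used for coordinate validation.
#' @return a feature `data.frame` in genome order (see [mito_features()]).
#' @export
read_feature_table <- function(path, genome_length) {
  if (!file.exists(path)) stop(sprintf("feature table not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop(sprintf("feature table is empty: %s", path), call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 4L) stop(sprintf("line %d: expected 5 tab-separated columns", i), call. = FALSE)
    from <- suppressWarnings(as.integer(p[3L])); to <- suppressWarnings(as.integer(p[4L]))
    if (is.na(from) || is.na(to)) stop(sprintf("line %d: non-numeric coordinates", i), call. = FALSE)
    if (from < 1L || to < 1L || from > genome_length || to > genome_length) {
      stop(sprintf("line %d (%s): coordinate outside [1, %d]", i, p[1L], genome_length),
           call. = FALSE)
    }
    anticodon <- if (length(p) >= 5L && nzchar(p[5L])) p[5L] else NA_character_
    data.frame(name = p[1L], type = p[2L],
               start = min(from, to), end = max(from, to),
               strand = if (from <= to) "H" else "L",
               anticodon = anticodon, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # validates types via the constructor
  out <- mito_features(out$name, out$type, out$start, out$end, out$strand, out$anticodon)
  out[order(out$start), , drop = FALSE]
}

#' Write a five-column feature table
#'
#' Inverse of [read_feature_table()]: light-strand rows are written with
#' reversed coordinates. Origin-wrapping features (stored `start > end`)
#' cannot be represented in this dialect and raise an error.
#'
#' @param features feature `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (any(features$start > features$end)) {
    stop("origin-wrapping features cannot be written in the five-column dialect",
         call. = FALSE)
  }
  from <- ifelse(features$strand == "L", features$end, features$start)
  to <- ifelse(features$strand == "L", features$start, features$end)
  lines <- c("#gene\ttype\tfrom\tto\tanticodon",
             sprintf("%s\t%s\t%d\t%d\t%s", features$name, features$type, from, to,
                     ifelse(is.na(features$anticodon), "", features$anticodon)))
  writeLines(lines, path)
  invisible(path)
}

#' Extract the (oriented) sequence of an annotated feature
#'
#' Heavy-strand features return the substring `[start..end]`; light-strand
#' features return its reverse complement; origin-wrapping features
#' (`start > end`) concatenate tail and head of the circle before
#' orientation.
#'
#' @param genome a [mito_genome].
#' @param feature a feature name, a row index into `genome$features`, or a
#'   single-row feature data.frame.
#' @return the coding-strand DNA string of the feature.
#' @export
extract_feature_sequence <- function(genome, feature) {
  stopifnot(inherits(genome, "mito_genome"))
  f <- resolve_feature(genome, feature)
  pos <- span_positions(f$start, f$end, genome$length)
  chars <- seq_chars(genome$record$residues)[pos]
  s <- paste(chars, collapse = "")
  if (f$strand == "L") revcomp(s) else s
}

resolve_feature <- function(genome, feature) {
  ft <- genome$features
  if (is.character(feature)) {
    i <- which(ft$name == feature)
    if (length(i) != 1L) {
      stop(sprintf("feature '%s' matches %d annotation rows", feature, length(i)),
           call. = FALSE)
    }
    ft[i, ]
  } else if (is.numeric(feature)) {
    if (feature < 1L || feature > nrow(ft)) stop("feature index out of range", call. = FALSE)
    ft[feature, ]
  } else if (is.data.frame(feature) && nrow(feature) == 1L) {
    if (feature$start > genome$length || feature$end > genome$length) {
      stop("feature outside genome", call. = FALSE)
    }
    feature
  } else {
    stop("feature must be a name, an index, or a one-row data.frame", call. = FALSE)
  }
}
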