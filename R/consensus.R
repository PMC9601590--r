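# Undefined-site correction: resolve IUPAC-ambiguous positions in a primary
# assembly by flank-anchored voting against alternate assemblies.
#
# Rationale for flank-anchored exact matching instead of whole-genome
# alignment: alternate assemblies are often fragmented contigs, and
# mitochondrial genomes essentially never repeat 40-mers, so an exact
# left/right flank pair places a site uniquely. An alternate whose flank
# pair matches at several locations showing different bases abstains at
# that site (placement ambiguity must not create a false vote); agreeing
# multi-matches are redundant coverage from overlapping fragments and
# count as one vote. Ties between voters are left unresolved.

#' Locate IUPAC-ambiguous positions in a sequence
#'
#' @param seq a [mito_record] or DNA string.
#' @return a `data.frame` with columns `position` (1-based, ascending) and
#'   `code`; zero rows when the sequence is fully defined.
#' @export
locate_ambiguities <- function(seq) {
  rec <- as_record(seq)
  chars <- seq_chars(rec$residues)
  idx <- which(is_ambiguous(chars))
  data.frame(position = idx, code = chars[idx], stringsAsFactors = FALSE)
}

#' Resolve ambiguous sites against alternate assemblies
#'
#' For every ambiguous position in `primary`, the exact `flank`-length
#' context on each side is searched in every alternate assembly (both
#' orientations; circularly when an alternate is flagged circular). An
#' alternate whose matches all show the same base votes that base; an
#' alternate whose matches conflict abstains; a vote outside the IUPAC expansion of
#' the primary's code is discarded and logged. Votes are combined as:
#' unanimous base, else strict majority, else unresolved.
#'
#' @param primary a [mito_record] (or DNA string) with possible ambiguity
#'   codes.
#' @param alternates list of alternate assemblies; each may be a
#'   [mito_record], a list of records (fragments), or a character vector of
#'   fragment sequences.
#' @param flank exact-match context length on each side (>= 8; default 20).
#' @return a list with `record` (the corrected [mito_record]) and `report`
#'   (a `consensus_report` data.frame: `position`, `primary_code`, one
#'   vote column per alternate, `resolution`, `rule`).
#' @export
resolve_ambiguities <- function(primary, alternates = list(), flank = 20L) {
  if (flank < 8L) stop("flank must be >= 8", call. = FALSE)
  primary <- as_record(primary, id = "primary")
  alts <- lapply(alternates, normalize_assembly)
  if (is.null(names(alts)) || any(!nzchar(names(alts)))) {
    names(alts) <- sprintf("alt%d", seq_along(alts))
  }

  amb <- locate_ambiguities(primary)
  report <- amb
  names(report)[2L] <- "primary_code"
  for (a in names(alts)) report[[paste0("vote_", a)]] <- character(nrow(amb))
  report$resolution <- character(nrow(amb))
  report$rule <- character(nrow(amb))
  notes <- character(0)

  chars <- seq_chars(primary$residues)
  len <- length(chars)

  for (i in seq_len(nrow(amb))) {
    p <- amb$position[i]
    code <- amb$code[i]
    fl <- flank_context(chars, p, flank, primary$circular)
    if (is.null(fl)) {
      report$resolution[i] <- "unresolved"
      report$rule[i] <- "flank outside linear sequence"
      for (a in names(alts)) report[[paste0("vote_", a)]][i] <- "."
      next
    }
    if (any(is_ambiguous(seq_chars(paste0(fl$left, fl$right))))) {
      report$resolution[i] <- "unresolved"
      report$rule[i] <- "ambiguous flank context"
      for (a in names(alts)) report[[paste0("vote_", a)]][i] <- "."
      next
    }

    votes <- character(0)
    for (a in names(alts)) {
      v <- assembly_vote(alts[[a]], fl$left, fl$right, flank)
      report[[paste0("vote_", a)]][i] <- v$display
      if (!is.na(v$note)) notes <- c(notes, sprintf("pos %d, %s: %s", p, a, v$note))
      if (!is.na(v$base)) {
        if (v$base %in% .IUPAC_EXPAND[[code]]) {
          votes <- c(votes, v$base)
        } else {
          notes <- c(notes, sprintf(
            "pos %d, %s: vote %s outside IUPAC expansion of %s; discarded",
            p, a, v$base, code))
        }
      }
    }

    if (length(votes) == 0L) {
      report$resolution[i] <- "unresolved"
      report$rule[i] <- "no votes"
    } else if (length(unique(votes)) == 1L) {
      report$resolution[i] <- votes[1L]
      report$rule[i] <- if (length(votes) == 1L) "single-source" else "unanimous"
    } else {
      tab <- sort(table(votes), decreasing = TRUE)
      if (tab[1L] * 2L > length(votes)) {
        report$resolution[i] <- names(tab)[1L]
        report$rule[i] <- "majority"
      } else {
        report$resolution[i] <- "unresolved"
        report$rule[i] <- "tie"
      }
    }
  }

  resolved <- report$resolution %in% .BASES
  chars[report$position[resolved]] <- report$resolution[resolved]
  out <- mito_record(primary$id, paste(chars, collapse = ""), primary$circular)
  class(report) <- c("consensus_report", "data.frame")
  attr(report, "flank") <- flank
  attr(report, "notes") <- notes
  list(record = out, report = report)
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("<consensus_report> %d ambiguous site(s), flank %d; %d resolved\n",
              nrow(x), attr(x, "flank"),
              sum(x$resolution %in% .BASES)))
  if (nrow(x)) print.data.frame(x)
  notes <- attr(x, "notes")
  if (length(notes)) cat("notes:\n", paste(" -", notes, collapse = "\n"), "\n")
  invisible(x)
}

normalize_assembly <- function(alt) {
  if (inherits(alt, "mito_record")) alt <- list(alt)
  if (is.character(alt)) alt <- lapply(seq_along(alt), function(i) {
    mito_record(sprintf("fragment%d", i), alt[i])
  })
  stopifnot(is.list(alt), all(vapply(alt, inherits, TRUE, "mito_record")))
  alt
}

flank_context <- function(chars, p, flank, circular) {
  len <- length(chars)
  lpos <- (p - flank):(p - 1L)
  rpos <- (p + 1L):(p + flank)
  if (!circular && (any(lpos < 1L) || any(rpos > len))) return(NULL)
  list(left = paste(chars[wrap_pos(lpos, len)], collapse = ""),
       right = paste(chars[wrap_pos(rpos, len)], collapse = ""))
}

# one alternate assembly's vote at one site: search every fragment in both
# orientations for left + <base> + right; exactly one match site => vote.
# Circular fragments are extended by one pattern length so origin-crossing
# sites are found; a match can never fit entirely inside the extension, so
# no site is double-counted.
assembly_vote <- function(fragments, left, right, flank) {
  pattern <- paste0(left, "([ACGTRYSWKMBDHVN])", right)
  hits <- character(0)
  for (frag in fragments) {
    s <- frag$residues
    n <- nchar(s)
    search_space <- if (frag$circular) paste0(s, substr(s, 1L, min(n, 2L * flank))) else s
    for (orient in c("fwd", "rc")) {
      subject <- if (orient == "fwd") search_space else revcomp(search_space)
      m <- gregexpr(pattern, subject, perl = TRUE)[[1]]
      if (m[1L] == -1L) next
      starts <- as.integer(m)
      # the pattern is written in primary-strand orientation, so the middle
      # base is already a primary-strand base in either search orientation
      mid <- vapply(starts, function(st) substr(subject, st + flank, st + flank), "")
      hits <- c(hits, paste0(frag$id, ":", orient, ":", starts, ":", mid))
    }
  }
  if (length(hits) == 0L) {
    return(list(base = NA_character_, display = ".", note = NA_character_))
  }
  bases <- sub("^.*:", "", hits)
  # several matches with agreeing bases are redundant coverage (overlapping
  # fragments); matches showing different bases are genuine placement
  # ambiguity and the assembly abstains
  if (length(unique(bases)) > 1L) {
    return(list(base = NA_character_, display = paste0("(", paste(bases, collapse = "|"), ")"),
                note = sprintf("flanks match at %d sites with conflicting bases; abstained",
                               length(hits))))
  }
  b <- bases[1L]
  if (is_ambiguous(b)) {
    return(list(base = NA_character_, display = b,
                note = sprintf("matched base %s itself ambiguous; abstained", b)))
  }
  list(base = b, display = b, note = NA_character_)
}
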