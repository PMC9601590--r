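# Seeded simulator: annotated circular mitogenomes with the canonical
# vertebrate architecture and known ground truth; diverged taxon sets with
# controlled dN/dS; assembly variants with injected ambiguities.

#' The default mitogenome architecture template
#'
#' The 39-feature architecture of the crocodile newt *Tylototriton
#' broadoridgus* mitogenome (GenBank OP598114): 13 protein-coding genes,
#' 22 tRNAs, 2 rRNAs, the light-strand replication origin (OL) and the
#' control region, with their published coordinates, strands, anticodons
#' and start/stop codons (including incomplete stops, marked `T(AA)`) on a
#' 16,265 bp circle. Using real coordinates means simulated genomes
#' reproduce the real overlap/spacer geometry exactly.
#'
#' @return a `data.frame` with columns `name`, `type`, `start`, `end`,
#'   `strand`, `anticodon`, `start_codon`, `stop_codon`.
#' @export
mitogenome_template <- function() {
  rows <- c(
    "tRNA-Phe|tRNA|1|68|H|GAA||",
    "12S-rRNA|rRNA|69|996|H|||",
    "tRNA-Val|tRNA|996|1065|H|TAC||",
    "16S-rRNA|rRNA|1068|2630|H|||",
    "tRNA-Leu2|tRNA|2632|2706|H|TAA||",
    "ND1|PCG|2707|3675|H||ATG|TAG",
    "tRNA-Ile|tRNA|3675|3745|H|GAT||",
    "tRNA-Gln|tRNA|3748|3818|L|CAT||",
    "tRNA-Met|tRNA|3821|3890|H|TCA||",
    "ND2|PCG|3891|4934|H||ATG|TAA",
    "tRNA-Trp|tRNA|4933|5001|H|GTC||",
    "tRNA-Ala|tRNA|5003|5071|L|TTT||",
    "tRNA-Asn|tRNA|5072|5144|L|TCC||",
    "OL|OL|5147|5179|H|||",
    "tRNA-Cys|tRNA|5179|5244|L|TCG||",
    "tRNA-Tyr|tRNA|5245|5311|L|GTG||",
    "COI|PCG|5313|6863|H||GTG|TAA",
    "tRNA-Ser2|tRNA|6864|6934|L|GCT||",
    "tRNA-Asp|tRNA|6936|7005|H|TAG||",
    "COII|PCG|7007|7694|H||ATG|T(AA)",
    "tRNA-Lys|tRNA|7695|7767|H|TGT||",
    "ATP8|PCG|7769|7936|H||ATG|TAA",
    "ATP6|PCG|7927|8610|H||GTG|TAA",
    "COIII|PCG|8610|9393|H||ATG|T(AA)",
    "tRNA-Gly|tRNA|9394|9463|H|TGG||",
    "ND3|PCG|9464|9811|H||ATG|TAA",
    "tRNA-Arg|tRNA|9810|9878|H|TTC||",
    "ND4L|PCG|9879|10175|H||ATG|TAA",
    "ND4|PCG|10169|11546|H||ATG|T(AA)",
    "tRNA-His|tRNA|11547|11614|H|TGA||",
    "tRNA-Ser1|tRNA|11615|11682|H|GTA||",
    "tRNA-Leu1|tRNA|11682|11753|H|GCA||",
    "ND5|PCG|11754|13565|H||ATG|TAA",
    "ND6|PCG|13551|14069|L||ATG|AGA",
    "tRNA-Glu|tRNA|14070|14137|L|GTT||",
    "CYTB|PCG|14140|15280|H||ATG|T(AA)",
    "tRNA-Thr|tRNA|15281|15348|H|TGC||",
    "tRNA-Pro|tRNA|15457|15527|L|TTG||",
    "D-loop|CR|15550|16265|H|||"
  )
  m <- do.call(rbind, lapply(strsplit(rows, "|", fixed = TRUE), function(p) {
    c(p, character(8L - length(p)))  # strsplit drops trailing empty fields
  }))
  out <- data.frame(name = m[, 1L], type = m[, 2L],
                    start = as.integer(m[, 3L]), end = as.integer(m[, 4L]),
                    strand = m[, 5L],
                    anticodon = ifelse(nzchar(m[, 6L]), m[, 6L], NA_character_),
                    start_codon = ifelse(nzchar(m[, 7L]), m[, 7L], NA_character_),
                    stop_codon = ifelse(nzchar(m[, 8L]), m[, 8L], NA_character_),
                    stringsAsFactors = FALSE)
  out
}

#' Per-region base-frequency defaults
#'
#' Frequencies (A, C, G, T) for each region class, set to the published
#' composition of the *T. broadoridgus* mitogenome regions so that
#' simulated genomes are compositionally realistic: control region,
#' rRNAs, tRNAs, protein-coding genes (coding strand), and the
#' genome-wide background used for intergenic stretches.
#'
#' @return a named list of frequency vectors, each summing to 1.
#' @export
default_region_freqs <- function() {
  norm <- function(x) x / sum(x)
  list(
    CR = norm(c(A = 0.286, C = 0.212, G = 0.152, T = 0.349)),
    rRNA = norm(c(A = 0.395, C = 0.215, G = 0.170, T = 0.220)),
    tRNA = norm(c(A = 0.323, C = 0.177, G = 0.198, T = 0.301)),
    OL = norm(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)),
    PCG = norm(c(A = 0.310, C = 0.270, G = 0.147, T = 0.273)),
    intergenic = norm(c(A = 0.336, C = 0.263, G = 0.145, T = 0.257))
  )
}

#' Specification for a simulated mitogenome
#'
#' @param template architecture template (default [mitogenome_template()]).
#' @param base_freq named list of per-region base frequencies (default
#'   [default_region_freqs()]); each vector is normalized to sum 1.
#' @param at_content optional overall A+T target in (0, 1); when given,
#'   every region's frequencies are rescaled to this A+T content while
#'   preserving the A:T and G:C proportions.
#' @param label identifier prefix for emitted records.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(template = mitogenome_template(),
                        base_freq = default_region_freqs(),
                        at_content = NULL,
                        label = "synthetic-mitogenome") {
  base_freq <- lapply(base_freq, function(f) {
    stopifnot(all(c("A", "C", "G", "T") %in% names(f)), all(f >= 0), sum(f) > 0)
    f[c("A", "C", "G", "T")] / sum(f)
  })
  if (!is.null(at_content)) {
    stopifnot(at_content > 0, at_content < 1)
    base_freq <- lapply(base_freq, function(f) {
      at <- f[["A"]] + f[["T"]]; gc <- f[["C"]] + f[["G"]]
      c(A = f[["A"]] / at * at_content, C = f[["C"]] / gc * (1 - at_content),
        G = f[["G"]] / gc * (1 - at_content), T = f[["T"]] / at * at_content)
    })
  }
  validate_template(template)
  structure(list(template = template, base_freq = base_freq, label = label),
            class = "genome_spec")
}

validate_template <- function(tmpl) {
  needed <- c("name", "type", "start", "end", "strand")
  if (!all(needed %in% names(tmpl))) stop("template lacks required columns", call. = FALSE)
  pcg <- tmpl[tmpl$type == "PCG", ]
  if (nrow(pcg)) {
    if (any(is.na(pcg$start_codon)) || any(is.na(pcg$stop_codon))) {
      stop("every template PCG needs start_codon and stop_codon", call. = FALSE)
    }
    len <- pcg$end - pcg$start + 1L
    rem <- len %% 3L
    incomplete <- grepl("(", pcg$stop_codon, fixed = TRUE)
    bad <- (incomplete & rem == 0L) | (!incomplete & rem != 0L)
    if (any(bad)) {
      stop(sprintf("template PCG length inconsistent with stop codon class: %s",
                   paste(pcg$name[bad], collapse = ", ")), call. = FALSE)
    }
    # an overlap longer than either partner is unsatisfiable
    for (i in seq_len(nrow(pcg))) for (j in seq_len(nrow(pcg))) {
      if (i >= j) next
      ov <- min(pcg$end[i], pcg$end[j]) - max(pcg$start[i], pcg$start[j]) + 1L
      if (ov >= min(len[i], len[j])) {
        stop(sprintf("template overlap between %s and %s swallows a whole gene",
                     pcg$name[i], pcg$name[j]), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# iterative proportional fitting: per-position base weights q such that the
# sense-codon distribution proportional to q[b1]q[b2]q[b3] has per-base
# marginal equal to the target frequencies (stop-codon exclusion would
# otherwise bias realized composition away from the target)
sense_codon_probs <- function(freq, code) {
  sense <- sense_codons(code)
  mat <- do.call(rbind, strsplit(sense, ""))
  q <- freq
  for (it in 1:80) {
    w <- q[mat[, 1L]] * q[mat[, 2L]] * q[mat[, 3L]]
    w <- w / sum(w)
    marg <- vapply(.BASES, function(b) sum(w * rowSums(mat == b)) / 3, 0)
    if (max(abs(marg - freq)) < 1e-10) break
    q <- q * freq / pmax(marg, 1e-12)
    q <- q / sum(q)
  }
  list(codon_probs = setNames(w, sense), q = q, codon_mat = mat)
}

#' Generate an annotated mitogenome with known ground truth
#'
#' Realizes a random circular genome on the template's geometry:
#' non-coding regions are drawn from their per-region base frequencies;
#' protein-coding genes are built codon-wise from the sense codons of the
#' vertebrate mitochondrial code so that every PCG begins with its
#' template start codon, contains no internal in-frame stop, and ends with
#' the complete or incomplete stop its template row dictates. Bases shared
#' by two overlapping PCGs are sampled jointly under both genes' frame
#' constraints. Deterministic for a fixed seed; the seed is embedded in
#' the record header.
#'
#' @param spec a [genome_spec()].
#' @param seed integer seed for all randomness.
#' @return a list of class `mito_sim` with `genome` (a [mito_genome]) and
#'   `truth` (template-derived organization rows, per-region base-frequency
#'   targets, seed).
#' @export
generate_mitogenome <- function(spec = genome_spec(), seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(seed)
  code <- mito_code()
  tmpl <- spec$template
  fr <- spec$base_freq
  L <- max(tmpl$end)

  bases <- sample(.BASES, L, replace = TRUE, prob = fr$intergenic[.BASES])

  # non-coding features: fill with class frequencies (coding-side for L strand)
  for (i in which(tmpl$type != "PCG")) {
    f <- fr[[tmpl$type[i]]] %||% fr$intergenic
    n <- tmpl$end[i] - tmpl$start[i] + 1L
    s <- sample(.BASES, n, replace = TRUE, prob = f[.BASES])
    if (tmpl$strand[i] == "L") s <- rev(complement_bases(s))
    bases[tmpl$start[i]:tmpl$end[i]] <- s
  }

  pcg <- tmpl[tmpl$type == "PCG", , drop = FALSE]
  fix <- character(L)  # immutable start/stop bases, H-strand alphabet

  set_fixed <- function(gpos, coding_chars, strand) {
    hchars <- if (strand == "H") coding_chars else complement_bases(coding_chars)
    for (k in seq_along(gpos)) {
      p <- gpos[k]
      if (nzchar(fix[p]) && fix[p] != hchars[k]) {
        stop(sprintf("template start/stop codons conflict at position %d", p), call. = FALSE)
      }
      fix[p] <<- hchars[k]
    }
  }

  pcg_info <- lapply(seq_len(nrow(pcg)), function(i) {
    len <- pcg$end[i] - pcg$start[i] + 1L
    gpos <- if (pcg$strand[i] == "H") pcg$start[i]:pcg$end[i] else pcg$end[i]:pcg$start[i]
    stop_txt <- pcg$stop_codon[i]
    incomplete <- grepl("(", stop_txt, fixed = TRUE)
    stop_chars <- seq_chars(sub("\\(.*$", "", stop_txt))
    list(name = pcg$name[i], strand = pcg$strand[i], len = len, gpos = gpos,
         start_chars = seq_chars(pcg$start_codon[i]),
         stop_chars = stop_chars, incomplete = incomplete)
  })
  for (gi in pcg_info) {
    set_fixed(gi$gpos[1:3], gi$start_chars, gi$strand)
    ns <- length(gi$stop_chars)
    set_fixed(gi$gpos[(gi$len - ns + 1L):gi$len], gi$stop_chars, gi$strand)
  }
  bases[nzchar(fix)] <- fix[nzchar(fix)]

  # jointly sample bases shared by two PCGs under both frame constraints
  locked <- nzchar(fix)
  cw <- sense_codon_probs(fr$PCG[.BASES], code)
  if (nrow(pcg) > 1L) {
    for (i in seq_len(nrow(pcg) - 1L)) for (j in (i + 1L):nrow(pcg)) {
      ov_lo <- max(pcg$start[i], pcg$start[j]); ov_hi <- min(pcg$end[i], pcg$end[j])
      if (ov_lo > ov_hi) next
      ov <- ov_lo:ov_hi
      free <- ov[!nzchar(fix[ov])]
      det <- locked; det[ov] <- TRUE
      ok <- FALSE
      for (it in 1:10000) {
        if (length(free)) {
          bases[free] <- sample(.BASES, length(free), replace = TRUE, prob = fr$PCG[.BASES])
        }
        if (cluster_valid(bases, det, pcg_info[c(i, j)], ov, code)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not satisfy overlapping reading frames in template", call. = FALSE)
      locked[ov] <- TRUE
    }
  }

  # realize each PCG codon-by-codon around the locked positions
  for (gi in pcg_info) {
    bases <- realize_pcg(bases, gi, locked, cw, code)
    locked[gi$gpos] <- TRUE
  }

  record <- mito_record(sprintf("%s|seed=%d|length=%d", spec$label, seed, L),
                        paste(bases, collapse = ""), circular = TRUE)
  features <- mito_features(tmpl$name, tmpl$type, tmpl$start, tmpl$end,
                            tmpl$strand, tmpl$anticodon)
  genome <- mito_genome(record, features)

  truth <- list(
    org = template_org_truth(tmpl, L),
    base_freq = fr, seed = seed, length = L, template = tmpl)
  structure(list(genome = genome, truth = truth), class = "mito_sim")
}

#' @export
print.mito_sim <- function(x, ...) {
  cat("<mito_sim> seed", x$truth$seed, "\n")
  print(x$genome)
  invisible(x)
}

# expected organization rows straight from template arithmetic (the
# generator's ground truth; deliberately simple, no shared code with
# build_gene_table beyond the length/gap definitions)
template_org_truth <- function(tmpl, L) {
  ord <- order(tmpl$start)
  tmpl <- tmpl[ord, ]
  nxt <- c(seq_len(nrow(tmpl))[-1L], 1L)
  gap <- tmpl$start[nxt] - tmpl$end - 1L
  gap[length(gap)] <- tmpl$start[1L] + L - tmpl$end[nrow(tmpl)] - 1L
  data.frame(gene = tmpl$name, length = tmpl$end - tmpl$start + 1L,
             strand = tmpl$strand, ign = as.integer(gap),
             start_codon = tmpl$start_codon, stop_codon = tmpl$stop_codon,
             stringsAsFactors = FALSE)
}

# are all fully-determined internal codons of the given genes stop-free?
cluster_valid <- function(bases, det, gene_infos, ov, code) {
  for (gi in gene_infos) {
    cds_idx <- match(ov, gi$gpos)
    cds_idx <- cds_idx[!is.na(cds_idx)]
    if (!length(cds_idx)) next
    k_range <- unique((cds_idx - 1L) %/% 3L + 1L)
    n_complete <- gi$len %/% 3L
    last_internal <- if (gi$incomplete) n_complete else n_complete - 1L
    for (k in k_range) {
      if (k <= 1L || k > last_internal) next
      idx <- (3L * k - 2L):(3L * k)
      gp <- gi$gpos[idx]
      if (!all(det[gp])) next
      cod <- bases[gp]
      if (gi$strand == "L") cod <- complement_bases(cod)
      if (paste(cod, collapse = "") %in% code$stops) return(FALSE)
    }
  }
  TRUE
}

realize_pcg <- function(bases, gi, locked, cw, code) {
  n_complete <- gi$len %/% 3L
  rem <- gi$len %% 3L
  last_internal <- if (gi$incomplete) n_complete else n_complete - 1L
  cds <- character(gi$len)
  cds[1:3] <- gi$start_chars
  if (gi$incomplete) {
    cds[(gi$len - rem + 1L):gi$len] <- gi$stop_chars
  } else {
    cds[(gi$len - 2L):gi$len] <- gi$stop_chars
  }

  # coding-strand values of already-locked genome positions
  lk <- locked[gi$gpos]
  lk_val <- bases[gi$gpos]
  if (gi$strand == "L") lk_val <- complement_bases(lk_val)

  sense <- names(cw$codon_probs)
  internal <- setdiff(seq_len(last_internal), 1L)
  has_constraint <- vapply(internal, function(k) any(lk[(3L * k - 2L):(3L * k)]), TRUE)

  free_ks <- internal[!has_constraint]
  if (length(free_ks)) {
    draws <- sample(sense, length(free_ks), replace = TRUE, prob = cw$codon_probs)
    for (z in seq_along(free_ks)) {
      k <- free_ks[z]
      cds[(3L * k - 2L):(3L * k)] <- seq_chars(draws[z])
    }
  }
  for (k in internal[has_constraint]) {
    idx <- (3L * k - 2L):(3L * k)
    fixed <- lk[idx]
    pattern <- ifelse(fixed, lk_val[idx], NA_character_)
    cand <- sense
    for (p in 1:3) if (!is.na(pattern[p])) cand <- cand[cw$codon_mat[match(cand, sense), p] == pattern[p]]
    if (!length(cand)) {
      stop(sprintf("%s: no sense codon satisfies locked bases at codon %d", gi$name, k),
           call. = FALSE)
    }
    draw <- if (length(cand) == 1L) cand else {
      sample(cand, 1L, prob = cw$codon_probs[cand])
    }
    cds[idx] <- seq_chars(draw)
  }

  # fully locked positions keep their genome values (joint sampling already
  # vetted them); unlocked positions take the freshly drawn values
  out_val <- ifelse(lk, lk_val, cds)
  hchars <- if (gi$strand == "H") out_val else complement_bases(out_val)
  bases[gi$gpos] <- hchars
  bases
}
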