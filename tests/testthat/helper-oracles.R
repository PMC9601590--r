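# Shared fixtures and independent oracles for the test suite.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# independent single-codon site oracle: fraction of synonymous changes per
# position among changes not creating stops, via direct enumeration
oracle_syn_sites <- function(codon, code) {
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    syn <- 0; considered <- 0
    for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
      m <- ch; m[p] <- b
      ms <- paste(m, collapse = "")
      if (code$table[[ms]] == "*") next
      considered <- considered + 1
      if (code$table[[ms]] == code$table[[codon]]) syn <- syn + 1
    }
    if (considered > 0) s <- s + syn / considered
  }
  s
}

# independent pathway oracle: recursively enumerate all substitution
# orderings between two codons, drop orderings passing through stops,
# average the per-step synonymous/nonsynonymous tallies
oracle_pathways <- function(c1, c2, code) {
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  walk <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(s = 0, n = 0, valid = 1)))
    out <- list()
    for (p in remaining) {
      nxt <- cur; nxt[p] <- ch2[p]
      ns <- paste(nxt, collapse = "")
      step_valid <- code$table[[ns]] != "*"
      step_syn <- step_valid && code$table[[paste(cur, collapse = "")]] == code$table[[ns]]
      for (tail in walk(nxt, setdiff(remaining, p))) {
        out[[length(out) + 1L]] <- c(
          s = unname(tail["s"]) + as.numeric(step_syn),
          n = unname(tail["n"]) + as.numeric(!step_syn),
          valid = unname(tail["valid"]) * as.numeric(step_valid))
      }
    }
    out
  }
  paths <- do.call(rbind, walk(ch1, which(ch1 != ch2)))
  valid <- paths[paths[, "valid"] == 1, , drop = FALSE]
  use <- if (nrow(valid)) valid else paths
  c(Sd = mean(use[, "s"]), Nd = mean(use[, "n"]))
}

# a tiny annotated genome with explicitly chosen sequence and features
tiny_genome <- function(seq, ...) {
  mito_genome(mito_record("tiny", seq, circular = TRUE), mito_features(...))
}
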