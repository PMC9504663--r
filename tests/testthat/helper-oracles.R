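# Shared helpers: sequence fixtures built in code, plus independent oracles
# (brute-force enumeration and Biostrings dynamic programming) used to check
# the package's own alignment and order-concordance implementations.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) tyrfish:::mutate_dna(seq, rate)

# --- alignment oracles (Biostrings DP, independent of src/align.cpp) -------

unit_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

nw_oracle <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = unit_matrix(),
    gapOpening = 0, gapExtension = 2)
  list(score = Biostrings::score(pa),
       identity = 100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa))
}

sw_oracle <- function(query, subject) {
  pa <- Biostrings::pairwiseAlignment(
    query, subject, type = "local", substitutionMatrix = unit_matrix(),
    gapOpening = 0, gapExtension = 2)
  list(score = Biostrings::score(pa),
       matches = Biostrings::nmatch(pa),
       aln_length = Biostrings::nchar(pa),
       identity = 100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa))
}

# --- brute-force minimal-removal oracle ------------------------------------
# Smallest number of elements to delete from permutation p so the remainder
# is strictly increasing, by enumerating kept subsets in decreasing size.
# Independent of the patience-sorting LIS in the package.

subsets_by_size_desc <- function(n) {
  out <- list()
  for (k in n:1) {
    cmb <- utils::combn(n, k)
    for (ci in seq_len(ncol(cmb))) out[[length(out) + 1]] <- cmb[, ci]
  }
  out[[length(out) + 1]] <- integer(0)
  out
}

bf_min_removal <- function(p, subsets = subsets_by_size_desc(length(p))) {
  for (s in subsets) {
    if (length(s) == 0 || !is.unsorted(p[s], strictly = TRUE)) {
      return(length(p) - length(s))
    }
  }
  length(p)
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  unlist(lapply(seq_along(v), function(i) {
    lapply(all_permutations(v[-i]), function(p) c(v[i], p))
  }), recursive = FALSE)
}

# --- toy genome with planted probe copies ----------------------------------
# Background random sequence with the probe inserted at its target locus and
# diverged copies planted at known, well-separated positions. Returns the
# genome plus the truth needed by the exhaustive specificity oracle.

plant_copies <- function(probe_len = 800, genome_len = 20000,
                         divergences = c(0.05, 0.30)) {
  probe <- rand_dna(probe_len)
  n_ins <- 1 + length(divergences)
  gap <- (genome_len - n_ins * probe_len) %/% (n_ins + 1)
  stopifnot(gap > 200)
  pieces <- character(0)
  starts <- integer(0)
  pos <- 0
  inserts <- c(list(probe), lapply(divergences, function(d) {
    mutate_seq(probe, d)
  }))
  for (i in seq_len(n_ins)) {
    pieces <- c(pieces, rand_dna(gap), inserts[[i]])
    pos <- pos + gap
    starts <- c(starts, pos)
    pos <- pos + probe_len
  }
  pieces <- c(pieces, rand_dna(genome_len - pos))
  list(genome = seq_tbl("toy", paste(pieces, collapse = "")),
       probe = probe,
       target = list(seq_id = "toy", start = starts[1],
                     end = starts[1] + probe_len),
       copy_starts = starts[-1], copy_divergences = divergences,
       probe_len = probe_len)
}

# Exhaustive specificity oracle for a planted-copy instance: align the probe
# against each planted window with Biostrings local DP and classify with the
# same strict thresholds; background regions of a random toy genome cannot
# reach 100 aligned columns above 80 % identity.
oracle_dangerous_copies <- function(inst, identity_gt = 80,
                                    length_gt = 100) {
  g <- inst$genome$seq[1]
  vapply(seq_along(inst$copy_starts), function(i) {
    s <- inst$copy_starts[i]
    win <- substr(g, max(1, s - 100), s + inst$probe_len + 100)
    o <- sw_oracle(inst$probe, win)
    o$identity > identity_gt && o$aln_length > length_gt
  }, TRUE)
}
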