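#' Sequence tables
#'
#' Sequences travel through the pipeline as plain tibbles with an `id` and a
#' `seq` column, so they pipe like every other table. Residue case is
#' meaningful: lowercase bases are soft-masked (annotated repeats), `N`/`n`
#' are hard-masked (assembly gaps or removed repeats). No other characters
#' are accepted.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param seq Character vector of residues over `A,C,G,T,N,a,c,g,t,n`.
#' @return A tibble with columns `id`, `seq`.
#' @export
#' @examples
#' seq_tbl("g1", "ACGTacgtNN")
seq_tbl <- function(id, seq) {
  stopifnot(length(id) == length(seq))
  out <- tibble(id = as.character(id), seq = as.character(seq))
  validate_seq_tbl(out)
}

validate_seq_tbl <- function(x) {
  if (!all(c("id", "seq") %in% names(x))) {
    abort("sequence table needs `id` and `seq` columns")
  }
  if (anyDuplicated(x$id)) {
    dup <- unique(x$id[duplicated(x$id)])
    abort(paste0("duplicate sequence id(s): ", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(x$seq))) {
    abort(paste0("empty sequence for id(s): ",
                 paste(x$id[!nzchar(x$seq)], collapse = ", ")))
  }
  bad <- stringr::str_detect(x$seq, "[^ACGTNacgtn]")
  if (any(bad)) {
    abort(paste0("illegal residue characters in record(s): ",
                 paste(x$id[bad], collapse = ", ")))
  }
  as_tibble(x)
}

#' Read and write FASTA files
#'
#' Residues are preserved byte-for-byte (including soft-mask case), record
#' order is kept, and duplicate ids or illegal residues are errors naming the
#' offending record.
#'
#' @param path File path.
#' @param seqs A sequence tibble (see [seq_tbl()]).
#' @param width Line-wrap width for output.
#' @return `read_fasta()` returns a sequence tibble; `write_fasta()` returns
#'   `path` invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                       seqonly = FALSE),
    error = function(e) abort(paste0("cannot parse FASTA ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(recs) == 0) abort(paste0("empty FASTA file: ", path))
  seq_tbl(names(recs), vapply(recs, function(s) as.character(s)[1], ""))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, width = 60) {
  seqs <- validate_seq_tbl(seqs)
  seqinr::write.fasta(as.list(seqs$seq), names = seqs$id, file.out = path,
                      nbchar = width, as.string = TRUE)
  invisible(path)
}

#' Masking statistics of sequence records
#'
#' @param seqs A sequence tibble.
#' @return A tibble with per-record `length`, `n_soft_masked` (lowercase
#'   bases) and `n_hard_masked` (`N`/`n` bases).
#' @export
mask_stats <- function(seqs) {
  seqs <- validate_seq_tbl(seqs)
  tibble(
    id = seqs$id,
    length = nchar(seqs$seq),
    n_soft_masked = stringr::str_count(seqs$seq, "[acgt]"),
    n_hard_masked = stringr::str_count(seqs$seq, "[Nn]")
  )
}

#' Reverse complement
#'
#' Case-preserving: soft-masked bases stay lowercase in the complement.
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Genomic interval tables
#'
#' Intervals are 0-based half-open (`start` inclusive, `end` exclusive) on a
#' named sequence, with strand `+` or `-` — the BED convention, used
#' everywhere internally. 1-based fully-closed coordinates appear only in
#' human-readable reports.
#'
#' @param seq_id,start,end,strand Parallel vectors defining the intervals.
#' @return A tibble with columns `seq_id`, `start`, `end`, `strand`.
#' @export
interval_tbl <- function(seq_id, start, end, strand = "+") {
  out <- tibble(seq_id = as.character(seq_id),
                start = as.integer(start), end = as.integer(end),
                strand = rep_len(as.character(strand), length(seq_id)))
  bad <- out$start < 0 | out$start >= out$end
  if (any(bad)) abort("intervals must satisfy 0 <= start < end")
  if (!all(out$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  out
}

#' Extract the sequence of a genomic interval
#'
#' Minus-strand requests return the reverse complement of the spanned
#' segment.
#'
#' @param assembly A sequence tibble holding the assembly.
#' @param seq_id,start,end,strand The interval (0-based half-open).
#' @param id Identifier for the extracted record; default
#'   `"<seq_id>:<start>-<end>(<strand>)"`.
#' @return A one-row sequence tibble of length `end - start`.
#' @export
#' @examples
#' asm <- seq_tbl("s", "AACCGGTT")
#' extract_interval(asm, "s", 2, 6)$seq  # "CCGG"
extract_interval <- function(assembly, seq_id, start, end, strand = "+",
                             id = NULL) {
  assembly <- validate_seq_tbl(assembly)
  i <- match(seq_id, assembly$id)
  if (is.na(i)) abort(paste0("unknown seq_id: ", seq_id))
  L <- nchar(assembly$seq[i])
  if (start < 0 || start >= end || end > L) {
    abort(sprintf("interval [%d,%d) out of range for %s (length %d)",
                  start, end, seq_id, L))
  }
  s <- substr(assembly$seq[i], start + 1, end)
  if (strand == "-") s <- revcomp(s)
  seq_tbl(id %||% sprintf("%s:%d-%d(%s)", seq_id, start, end, strand), s)
}

#' Write intervals as BED6
#'
#' @param intervals An interval tibble; optional `name` and `score` columns
#'   are used when present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  nm <- if ("name" %in% names(intervals)) intervals$name else {
    sprintf("%s_%d", intervals$seq_id, intervals$start)
  }
  sc <- if ("score" %in% names(intervals)) intervals$score else {
    rep(0, nrow(intervals))
  }
  bed <- tibble(intervals$seq_id, intervals$start, intervals$end, nm, sc,
                intervals$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Percent identity of two sequences
#'
#' Global (end-to-end) alignment with unit match/mismatch and a linear gap
#' cost; identity is `100 * matches / aligned columns`, gap columns
#' included. Symmetric in its arguments.
#'
#' @param a,b Sequences: strings or one-row sequence tibbles.
#' @param match,mismatch,gap Alignment scores (defaults +1/-1/-2).
#' @return Identity in percent.
#' @export
#' @examples
#' percent_identity("ACGT", "ACGT")  # 100
percent_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- as_seq_string(a)
  b <- as_seq_string(b)
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  r <- nw_align_cpp(a, b, match, mismatch, gap)
  100 * r$matches / r$aln_length
}

as_seq_string <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- x$seq
  }
  as.character(x)[1]
}
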