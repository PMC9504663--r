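#' Genome-wide off-target scan of a probe
#'
#' Internal seed-and-extend local aligner: exact k-mer seeds between the
#' probe and each genome sequence (both strands) are clustered by position,
#' each cluster's window (the seeded span plus enough margin to hold the
#' whole probe) is aligned with a full Smith–Waterman extension (unit
#' match/mismatch, linear gap), and every alignment of at least
#' `min_report_len` columns is reported with its identity
#' (`100 * matches / aligned columns`) and aligned length. The probe's own
#' locus, when supplied, is reported too and flagged `is_target_locus`
#' (>= 1 bp overlap with the product interval).
#'
#' This replaces an external search engine: the downstream dangerous-hit
#' rule only consumes identity and aligned length, so explicit reporting
#' floors stand in for E-values. Externally produced tabular hits can be fed
#' straight to [classify_dangerous()] instead.
#'
#' @param probe A one-row sequence tibble or string.
#' @param genome A sequence tibble.
#' @param k Seed size.
#' @param match,mismatch,gap Extension scores.
#' @param min_report_len Minimum aligned columns to report.
#' @param target Optional target interval: list or one-row data frame with
#'   `seq_id`, `start`, `end` (0-based half-open).
#' @param cluster_gap Seed clusters farther apart than this (bp) are
#'   extended separately.
#' @param window_margin Extra bp of genomic context aligned on each side of
#'   a cluster's seed span. Alignments worth reporting contain exact seeds
#'   at short intervals (at 80 % identity an intact 13-mer occurs every few
#'   tens of bp in expectation), so a 200 bp margin loses nothing while
#'   keeping extension windows small.
#' @param probe_id Id used in the output when `probe` is a bare string.
#' @param genome_index Optional precomputed k-mer index from
#'   [index_genome()] (reused across probes by [screen_probes()]).
#' @return A tibble of hits: `probe_id`, `subject_seq`, `start`, `end`,
#'   `strand`, `score`, `identity`, `aln_length`, `is_target_locus`. Empty
#'   when no seeds match.
#' @export
scan_genome <- function(probe, genome, k = 13, match = 1, mismatch = -1,
                        gap = -2, min_report_len = 50, target = NULL,
                        cluster_gap = 400, window_margin = 200,
                        probe_id = NULL, genome_index = NULL) {
  if (is.data.frame(probe)) {
    probe_id <- probe$id[1]
    pseq <- probe$seq[1]
  } else {
    pseq <- as.character(probe)
    probe_id <- probe_id %||% "probe"
  }
  genome <- validate_seq_tbl(genome)
  if (nchar(pseq) < k) abort("probe shorter than seed size k")
  q <- toupper(pseq)
  plen <- nchar(q)
  hits <- list()
  for (i in seq_len(nrow(genome))) {
    subject <- toupper(genome$seq[i])
    slen <- nchar(subject)
    sk <- if (!is.null(genome_index)) genome_index[[genome$id[i]]] else {
      subject_kmers(subject, k)
    }
    for (strand in c("+", "-")) {
      query <- if (strand == "+") q else revcomp(q)
      seeds <- seed_matches(query, subject, k, sk = sk)
      if (nrow(seeds) == 0) next
      for (cl in cluster_seeds(seeds, k, cluster_gap)) {
        win_start <- max(0, min(cl$gpos) - window_margin)
        win_end <- min(slen, max(cl$gpos) + k + window_margin)
        aln <- sw_align_cpp(query,
                            substr(subject, win_start + 1, win_end),
                            match, mismatch, gap)
        if (aln$aln_length < min_report_len) next
        hits[[length(hits) + 1]] <- tibble(
          probe_id = probe_id, subject_seq = genome$id[i],
          start = win_start + aln$sstart, end = win_start + aln$send,
          strand = strand, score = aln$score,
          identity = 100 * aln$matches / aln$aln_length,
          aln_length = as.integer(aln$aln_length)
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble(probe_id = character(), subject_seq = character(),
                  start = integer(), end = integer(), strand = character(),
                  score = double(), identity = double(),
                  aln_length = integer(), is_target_locus = logical()))
  }
  out <- purrr::list_rbind(hits) |>
    # both-strand scans can rediscover the same locus; keep the best per span
    dplyr::distinct(.data$subject_seq, .data$start, .data$end,
                    .keep_all = TRUE)
  out$is_target_locus <- if (is.null(target)) FALSE else {
    out$subject_seq == target$seq_id[1] &
      out$start < target$end[1] & out$end > target$start[1]
  }
  arrange(out, .data$subject_seq, .data$start)
}

#' Precompute the k-mer index of a genome
#'
#' @param genome A sequence tibble.
#' @param k Seed size.
#' @return A named list (one character vector of k-mers per sequence) to
#'   pass as `genome_index` to [scan_genome()].
#' @export
index_genome <- function(genome, k = 13) {
  genome <- validate_seq_tbl(genome)
  stats::setNames(
    purrr::map(genome$seq, function(s) subject_kmers(toupper(s), k)),
    genome$id)
}

# Split seeds (sorted by genomic position) into clusters separated by more
# than cluster_gap bp.
cluster_seeds <- function(seeds, k, cluster_gap) {
  seeds <- arrange(seeds, .data$gpos)
  brk <- cumsum(c(0, diff(seeds$gpos) > cluster_gap))
  unname(split(seeds, brk))
}

#' Classify off-target hits as dangerous
#'
#' A hit is "dangerous" — predicted to cause non-specific hybridization
#' signal — when it lies outside the target locus and exceeds both
#' thresholds strictly: identity above `identity_gt` percent AND aligned
#' length above `length_gt` bp. A hit at exactly a threshold is not
#' dangerous.
#'
#' @param hits A hit tibble (needs `identity`, `aln_length`,
#'   `is_target_locus`), e.g. from [scan_genome()] or an external search
#'   tool.
#' @param identity_gt,length_gt Strict thresholds (defaults 80 % and
#'   100 bp, matching a hybridization/washing stringency of 80 %).
#' @return `hits` with a logical `is_dangerous` column.
#' @export
classify_dangerous <- function(hits, identity_gt = 80, length_gt = 100) {
  mutate(hits, is_dangerous = !.data$is_target_locus &
           .data$identity > identity_gt & .data$aln_length > length_gt)
}

#' Map hybridization stringency to the dangerous-hit identity threshold
#'
#' The washing stringency (percentage of paired nucleotides needed to keep
#' the probe-target duplex stable) is used directly as the identity
#' threshold above which an off-target alignment can produce signal: a
#' pass-through mapping, documented as such.
#'
#' @param stringency_pct Stringency in percent, in (0, 100].
#' @return The identity threshold (= `stringency_pct`).
#' @export
stringency_identity_threshold <- function(stringency_pct) {
  if (!is.numeric(stringency_pct) || stringency_pct <= 0 ||
      stringency_pct > 100) {
    abort("stringency_pct must be in (0, 100]")
  }
  stringency_pct
}

#' Screen probe candidates genome-wide and select the least-hit probe
#'
#' `screen_probes()` scans every live candidate against the genome and
#' summarises each into a specificity verdict (its dangerous-hit count and
#' total off-target aligned bases). `rank_candidates()` orders verdicts
#' within each gene ascending by (dangerous count, off-target aligned bases,
#' primer penalty) and marks rank 1 as selected — the probe with none or the
#' least dangerous hits wins; the further keys only break ties.
#'
#' @param candidates Candidate tibble from [extract_candidates()] (rows with
#'   `status == "candidate"` are screened).
#' @param genome A sequence tibble.
#' @param identity_gt,length_gt Dangerous-hit thresholds.
#' @param ... Passed to [scan_genome()].
#' @return `screen_probes()`: list with `hits` (all hits, classified) and
#'   `verdicts` (per probe: `gene_id`, `probe_id`, `dangerous_count`,
#'   `offtarget_aligned_bases`, `penalty`).
#' @export
screen_probes <- function(candidates, genome, identity_gt = 80,
                          length_gt = 100, k = 13, ...) {
  live <- filter(candidates, .data$status == "candidate")
  idx <- index_genome(genome, k)
  res <- purrr::map(seq_len(nrow(live)), function(i) {
    row <- live[i, ]
    target <- if ("chrom" %in% names(row) && !is.na(row$chrom)) {
      list(seq_id = row$chrom, start = row$start, end = row$end)
    }
    scan_genome(row$seq, genome, k = k, target = target,
                probe_id = row$probe_id, genome_index = idx, ...) |>
      classify_dangerous(identity_gt, length_gt)
  })
  hits <- purrr::list_rbind(res)
  verdicts <- purrr::map(seq_len(nrow(live)), function(i) {
    h <- res[[i]]
    off <- filter(h, !.data$is_target_locus)
    tibble(gene_id = live$gene_id[i], probe_id = live$probe_id[i],
           dangerous_count = sum(h$is_dangerous),
           offtarget_aligned_bases = sum(off$aln_length),
           penalty = live$penalty[i])
  }) |> purrr::list_rbind()
  list(hits = hits, verdicts = verdicts)
}

#' @rdname screen_probes
#' @param verdicts Verdict tibble from `screen_probes()`.
#' @return `rank_candidates()`: the verdicts with `rank` and `selected`
#'   columns (a permutation of the input rows); a gene whose only candidate
#'   still has dangerous hits carries `warning_dangerous = TRUE`.
#' @export
rank_candidates <- function(verdicts) {
  out <- verdicts |>
    group_by(.data$gene_id) |>
    arrange(.data$dangerous_count, .data$offtarget_aligned_bases,
            .data$penalty, .by_group = TRUE) |>
    mutate(rank = row_number(), selected = .data$rank == 1L,
           warning_dangerous = .data$selected & .data$dangerous_count > 0) |>
    ungroup()
  if (any(out$warning_dangerous)) {
    warn(paste0("selected probe(s) with dangerous hits: ",
                paste(out$probe_id[out$warning_dangerous], collapse = ", ")))
  }
  out
}
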