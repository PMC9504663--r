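#' Place a transcript on a genome by chained exact seeds
#'
#' A spliced-alignment stand-in adequate for modest genomes: exact k-mer
#' seed matches between the transcript and each genome sequence (both
#' strands) are chained colinearly, allowing genomic gaps up to `max_intron`
#' between consecutive seeds (intron tolerance). The chain score is the
#' seed length times the number of chained seeds. The best-scoring chain
#' defines the locus; the best chain on any other locus (other sequence,
#' other strand, or a non-overlapping region of the same sequence) gives
#' `second_best_score`, and the placement is flagged ambiguous when
#' `second_best_score >= ambiguity_ratio * chain_score`.
#'
#' @param transcript A one-row sequence tibble (or a string; then supply
#'   `transcript_id`).
#' @param genome A sequence tibble.
#' @param k Seed k-mer size.
#' @param max_intron Maximum genomic gap between chained seeds (bp).
#' @param ambiguity_ratio Second-best/best score ratio at or above which the
#'   placement is called ambiguous.
#' @param transcript_id Id when `transcript` is a bare string.
#' @return A one-row tibble: `transcript_id`, `placed`, `seq_id`, `start`,
#'   `end`, `strand` (0-based half-open locus), `chain_score`,
#'   `second_best_score`, `ambiguous`. A transcript with no seed hits
#'   anywhere returns `placed = FALSE`, not an error.
#' @export
place_transcript <- function(transcript, genome, k = 13, max_intron = 5000,
                             ambiguity_ratio = 0.95, transcript_id = NULL) {
  if (is.data.frame(transcript)) {
    transcript_id <- transcript$id[1]
    tseq <- transcript$seq[1]
  } else {
    tseq <- as.character(transcript)
    transcript_id <- transcript_id %||% "transcript"
  }
  genome <- validate_seq_tbl(genome)
  if (nchar(tseq) < k) abort("transcript shorter than seed size k")
  q <- toupper(tseq)
  chains <- list()
  for (i in seq_len(nrow(genome))) {
    subject <- toupper(genome$seq[i])
    sk <- subject_kmers(subject, k)
    for (strand in c("+", "-")) {
      query <- if (strand == "+") q else revcomp(q)
      seeds <- seed_matches(query, subject, k, stride = k, sk = sk)
      if (nrow(seeds) == 0) next
      for (chain in peel_chains(seeds, k, max_intron, n_chains = 2,
                                qlen = nchar(query),
                                slen = nchar(subject))) {
        chains[[length(chains) + 1]] <- tibble(
          seq_id = genome$id[i], strand = strand,
          start = chain$gstart, end = chain$gend, score = chain$score
        )
      }
    }
  }
  if (length(chains) == 0) {
    return(tibble(transcript_id = transcript_id, placed = FALSE,
                  seq_id = NA_character_, start = NA_integer_,
                  end = NA_integer_, strand = NA_character_,
                  chain_score = 0, second_best_score = 0, ambiguous = FALSE))
  }
  chains <- purrr::list_rbind(chains) |> arrange(desc(.data$score))
  best <- chains[1, ]
  second <- if (nrow(chains) > 1) chains$score[2] else 0
  tibble(
    transcript_id = transcript_id, placed = TRUE,
    seq_id = best$seq_id, start = as.integer(best$start),
    end = as.integer(best$end), strand = best$strand,
    chain_score = best$score, second_best_score = second,
    ambiguous = second >= ambiguity_ratio * best$score
  )
}

#' @rdname place_transcript
#' @param transcripts A sequence tibble of transcripts.
#' @param ... Passed to `place_transcript()`.
#' @export
place_transcripts <- function(transcripts, genome, ...) {
  transcripts <- validate_seq_tbl(transcripts)
  purrr::map(seq_len(nrow(transcripts)), function(i) {
    place_transcript(transcripts[i, ], genome, ...)
  }) |> purrr::list_rbind()
}

# k-mers of an (uppercase) sequence at every position; k-mers containing N
# are blanked so they never match (N is not a real base).
subject_kmers <- function(subject, k) {
  ns <- nchar(subject) - k + 1
  if (ns < 1) return(character())
  sk <- substring(subject, 1:ns, k:(ns + k - 1))
  sk[stringr::str_detect(sk, "N")] <- ""
  sk
}

# Exact k-mer matches of query within subject (both uppercase).
# Returns 0-based qpos/gpos. `stride` thins the query-side seed positions
# (stride = k gives non-overlapping seeds, enough for placement chaining);
# `sk` may be precomputed with subject_kmers().
seed_matches <- function(query, subject, k, stride = 1, sk = NULL) {
  nq <- nchar(query) - k + 1
  if (is.null(sk)) sk <- subject_kmers(subject, k)
  if (nq < 1 || length(sk) < 1) {
    return(tibble(qpos = integer(), gpos = integer()))
  }
  qpos0 <- seq(0, nq - 1, by = stride)
  qk <- substring(query, qpos0 + 1, qpos0 + k)
  ok <- !stringr::str_detect(qk, "N")
  qtab <- split(qpos0[ok], qk[ok])
  hit <- sk %in% names(qtab)
  if (!any(hit)) return(tibble(qpos = integer(), gpos = integer()))
  gpos <- which(hit) - 1L
  qpos_list <- qtab[sk[hit]]
  tibble(qpos = as.integer(unlist(qpos_list, use.names = FALSE)),
         gpos = rep(gpos, lengths(qpos_list)))
}

# Best colinear chain of seeds by quadratic DP; then peel (drop seeds
# overlapping the best chain's genomic span) and re-chain for the runner-up
# locus on the same sequence/strand.
peel_chains <- function(seeds, k, max_intron, n_chains = 2, qlen, slen) {
  out <- list()
  for (rep in seq_len(n_chains)) {
    if (nrow(seeds) == 0) break
    ch <- best_chain(seeds, k, max_intron, qlen = qlen, slen = slen)
    out[[rep]] <- ch
    keep <- seeds$gpos + k <= ch$gstart | seeds$gpos >= ch$gend
    seeds <- seeds[keep, ]
  }
  out
}

best_chain <- function(seeds, k, max_intron, max_query_gap = 50, qlen,
                       slen) {
  seeds <- arrange(seeds, .data$gpos, .data$qpos)
  n <- nrow(seeds)
  score <- rep(1L, n)
  prev <- rep(0L, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1)) {
      dq <- seeds$qpos[j] - seeds$qpos[i]
      dg <- seeds$gpos[j] - seeds$gpos[i]
      if (dq <= 0 || dg <= 0) next
      if (dg - dq > max_intron) next        # intron-sized genomic insertion
      if (dq - dg > max_query_gap) next     # small query-side slack only
      if (score[i] + 1L > score[j]) {
        score[j] <- score[i] + 1L
        prev[j] <- i
      }
    }
  }
  jbest <- which.max(score)
  idx <- jbest
  while (prev[idx[1]] > 0) idx <- c(prev[idx[1]], idx)
  # snap the locus to the full query footprint: extend past the outermost
  # seeds by the uncovered query length on each side (clamped to the
  # subject), so the locus covers the whole placed transcript
  qfirst <- seeds$qpos[idx[1]]
  qlast <- seeds$qpos[idx[length(idx)]]
  list(gstart = max(0, min(seeds$gpos[idx]) - qfirst),
       gend = min(slen, max(seeds$gpos[idx]) + (qlen - qlast)),
       score = k * score[jbest])
}

#' Partition markers by the probe-design exclusion filters
#'
#' A marker is retained when its transcript has a protein annotation, places
#' unambiguously on the genome, and its best placement lies on the expected
#' chromosome's sequences. Every marker lands in exactly one partition with
#' a machine-readable reason.
#'
#' @param markers Tibble: `marker_id`, `transcript_id`, `linkage_group`,
#'   `cM`, `has_protein_annotation`.
#' @param placements Output of [place_transcripts()] covering every
#'   referenced transcript.
#' @param expected_seq_ids Character vector of genome sequence ids belonging
#'   to the expected chromosome.
#' @return `markers` joined with placements plus `status`
#'   (`retained`/`excluded`) and `reason` (`retained`,
#'   `no_protein_annotation`, `unplaced`, `ambiguous`, `wrong_chromosome`).
#' @export
filter_markers <- function(markers, placements, expected_seq_ids) {
  if (anyDuplicated(markers$marker_id)) abort("duplicate marker ids")
  missing <- setdiff(markers$transcript_id, placements$transcript_id)
  if (length(missing)) {
    abort(paste0("markers reference unknown transcript(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- left_join(markers, placements, by = "transcript_id") |>
    mutate(
      reason = dplyr::case_when(
        !.data$has_protein_annotation ~ "no_protein_annotation",
        !.data$placed ~ "unplaced",
        .data$ambiguous ~ "ambiguous",
        !(.data$seq_id %in% expected_seq_ids) ~ "wrong_chromosome",
        TRUE ~ "retained"
      ),
      status = ifelse(.data$reason == "retained", "retained", "excluded")
    )
  out
}

#' Hard-mask screen for a gene sequence
#'
#' Genomic sequences containing a long run of `N` (a hard-masked repeat or
#' an assembly gap) are unusable as probe templates and are discarded.
#' Isolated ambiguities below the run threshold are tolerated.
#'
#' @param seq Character vector of sequences.
#' @param max_N_run Minimum `N`-run length that triggers discarding.
#' @return Logical: `TRUE` = keep. Vectorised.
#' @export
discard_hard_masked <- function(seq, max_N_run = 10) {
  !stringr::str_detect(seq, paste0("[Nn]{", max_N_run, ",}"))
}

#' Primer melting temperature and GC content
#'
#' Wallace-style long-oligo rule: `Tm = 64.9 + 41 * (GC_count - 16.4) / L`.
#'
#' @param seq Character vector of primer sequences.
#' @return Temperature in degrees Celsius / GC percent. Vectorised.
#' @export
#' @examples
#' primer_tm(strrep("GC", 5) |> paste0(strrep("AT", 5)))  # 20-mer, 10 G/C
primer_tm <- function(seq) {
  gc <- stringr::str_count(toupper(seq), "[GC]")
  64.9 + 41 * (gc - 16.4) / nchar(seq)
}

#' @rdname primer_tm
#' @export
primer_gc <- function(seq) {
  100 * stringr::str_count(toupper(seq), "[GC]") / nchar(seq)
}

#' Propose primer pairs for a gene sequence
#'
#' A transparent, dependency-free primer model standing behind the same
#' contract as an external primer-design backend: candidate primers of
#' length 18–27 nt are evaluated on a position grid, must contain no masked
#' base and keep GC within bounds, and are scored by absolute deviation from
#' the optima (length 20, GC 50 %, Tm 60 °C); a pair's penalty adds the
#' deviation of its product length from the window midpoint. The best
#' `n_pairs` pairs with distinct product windows are returned, ascending by
#' penalty.
#'
#' @param gene_seq A one-row sequence tibble or a string.
#' @param min_product,max_product Product length bounds (bp).
#' @param n_pairs Maximum number of pairs to return.
#' @param primer_len Primer length range.
#' @param opt_len,opt_gc,opt_tm Primer optima.
#' @param gc_bounds Hard GC bounds (percent).
#' @param opt_product Product-length optimum (bp).
#' @param step Anchor grid step (bp); the grid keeps the pair search
#'   tractable and the output deterministic.
#' @return A tibble of pairs: `left_seq`, `right_seq`, `left_start`,
#'   `right_end` (0-based half-open on the gene), `product_length`,
#'   `tm_left`, `tm_right`, `gc_left`, `gc_right`, `penalty`. Empty (with
#'   attribute `reason`) when the gene is shorter than `min_product` or no
#'   primer site qualifies.
#' @export
propose_primer_pairs <- function(gene_seq, min_product = 1000,
                                 max_product = 4000, n_pairs = 5,
                                 primer_len = c(18, 27), opt_len = 20,
                                 gc_bounds = c(40, 60), opt_gc = 50,
                                 opt_tm = 60, opt_product = 2500,
                                 step = 25) {
  s <- as_seq_string(gene_seq)
  L <- nchar(s)
  empty <- tibble(left_seq = character(), right_seq = character(),
                  left_start = integer(), right_end = integer(),
                  product_length = integer(), tm_left = double(),
                  tm_right = double(), gc_left = double(),
                  gc_right = double(), penalty = double())
  if (L < min_product) {
    attr(empty, "reason") <- "gene_shorter_than_min_product"
    return(empty)
  }
  lefts <- best_primer_at(s, anchors = seq(0, L - min_product, by = step),
                          side = "left", primer_len, gc_bounds, opt_len,
                          opt_gc, opt_tm)
  rights <- best_primer_at(s, anchors = seq(min_product, L, by = step),
                           side = "right", primer_len, gc_bounds, opt_len,
                           opt_gc, opt_tm)
  if (nrow(lefts) == 0 || nrow(rights) == 0) {
    attr(empty, "reason") <- "no_valid_primer_site"
    return(empty)
  }
  pairs <- tidyr::crossing(dplyr::rename_with(lefts, ~ paste0("l_", .x)),
                           dplyr::rename_with(rights, ~ paste0("r_", .x))) |>
    mutate(product_length = .data$r_anchor - .data$l_anchor) |>
    filter(.data$product_length >= min_product,
           .data$product_length <= max_product) |>
    mutate(penalty = .data$l_penalty + .data$r_penalty +
             abs(.data$product_length - opt_product) / 500) |>
    arrange(.data$penalty, .data$l_anchor, .data$r_anchor) |>
    dplyr::distinct(.data$l_anchor, .keep_all = TRUE) |>
    dplyr::distinct(.data$r_anchor, .keep_all = TRUE) |>
    dplyr::slice_head(n = n_pairs)
  tibble(
    left_seq = pairs$l_seq, right_seq = pairs$r_seq,
    left_start = as.integer(pairs$l_anchor),
    right_end = as.integer(pairs$r_anchor),
    product_length = as.integer(pairs$product_length),
    tm_left = pairs$l_tm, tm_right = pairs$r_tm,
    gc_left = pairs$l_gc, gc_right = pairs$r_gc,
    penalty = pairs$penalty
  )
}

# Best primer (by single-primer penalty) anchored at each grid position.
# A left primer starts at its anchor; a right primer ends at its anchor and
# is reported as the reverse complement (the synthesised strand).
best_primer_at <- function(s, anchors, side, primer_len, gc_bounds,
                           opt_len, opt_gc, opt_tm) {
  L <- nchar(s)
  purrr::map(anchors, function(a) {
    cand <- purrr::map(primer_len[1]:primer_len[2], function(len) {
      if (side == "left") {
        if (a + len > L) return(NULL)
        p <- substr(s, a + 1, a + len)
      } else {
        if (a - len < 0) return(NULL)
        p <- substr(s, a - len + 1, a)
      }
      if (stringr::str_detect(p, "[acgtNn]")) return(NULL)  # masked base
      gc <- primer_gc(p)
      if (gc < gc_bounds[1] || gc > gc_bounds[2]) return(NULL)
      tm <- primer_tm(p)
      tibble(anchor = a,
             seq = if (side == "left") p else revcomp(p),
             tm = tm, gc = gc,
             penalty = abs(tm - opt_tm) + 0.5 * abs(gc - opt_gc) +
               abs(len - opt_len))
    }) |> purrr::list_rbind()
    if (nrow(cand) == 0) NULL else cand[which.min(cand$penalty), ]
  }) |> purrr::list_rbind()
}

#' Extract primer-delimited probe candidates
#'
#' One candidate per primer pair: the product sequence is cut from the gene
#' sequence; candidates containing any masked base (soft-masked lowercase or
#' hard-masked `N`) are flagged `discarded_masked` — a masked base anywhere
#' in the probe risks repeat-driven background signal. When a placement is
#' supplied, the product interval is lifted to genome coordinates through
#' the gene's locus.
#'
#' @param gene_id Gene identifier.
#' @param gene_seq A one-row sequence tibble or string (the genomic gene
#'   sequence the pairs were designed on).
#' @param pairs Output of [propose_primer_pairs()] on the same sequence.
#' @param placement Optional one-row placement (from [place_transcript()])
#'   lifting gene coordinates to the genome.
#' @return A tibble: `gene_id`, `probe_id`, pair columns, `seq`,
#'   `masked_bases`, `status` (`candidate`/`discarded_masked`), and genome
#'   coordinates (`chrom`, `start`, `end`, `strand`) when a placement is
#'   given.
#' @export
extract_candidates <- function(gene_id, gene_seq, pairs, placement = NULL) {
  s <- as_seq_string(gene_seq)
  if (nrow(pairs) == 0) {
    return(tibble(gene_id = character(), probe_id = character()))
  }
  out <- pairs |>
    mutate(
      gene_id = gene_id,
      probe_id = sprintf("%s_p%d", gene_id, row_number()),
      seq = substring(s, .data$left_start + 1, .data$right_end),
      masked_bases = stringr::str_count(.data$seq, "[acgtNn]"),
      status = ifelse(.data$masked_bases > 0, "discarded_masked",
                      "candidate")
    )
  if (!is.null(placement) && isTRUE(placement$placed[1])) {
    out <- out |>
      mutate(
        chrom = placement$seq_id[1],
        start = if (placement$strand[1] == "+") {
          placement$start[1] + .data$left_start
        } else {
          placement$end[1] - .data$right_end
        },
        end = if (placement$strand[1] == "+") {
          placement$start[1] + .data$right_end
        } else {
          placement$end[1] - .data$left_start
        },
        strand = placement$strand[1]
      )
  }
  select(out, "gene_id", "probe_id", dplyr::everything())
}
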