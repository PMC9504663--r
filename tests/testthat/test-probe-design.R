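test_that("a transcript copied from a unique locus places there unambiguously", {
  set.seed(11)
  bg <- rand_dna(3000)
  tr <- rand_dna(600)
  genome <- seq_tbl(c("chrA", "chrB"),
                    c(paste0(bg, tr, rand_dna(1000)), rand_dna(2000)))
  pl <- place_transcript(seq_tbl("t1", tr), genome)
  expect_true(pl$placed)
  expect_equal(pl$seq_id, "chrA")
  expect_equal(pl$start, 3000)
  expect_equal(pl$end, 3600)
  expect_equal(pl$strand, "+")
  expect_false(pl$ambiguous)
})

test_that("an identical paralog elsewhere makes the placement ambiguous", {
  set.seed(12)
  tr <- rand_dna(500)
  genome <- seq_tbl(c("chrA", "chrB"),
                    c(paste0(rand_dna(1000), tr, rand_dna(1000)),
                      paste0(rand_dna(500), tr, rand_dna(500))))
  pl <- place_transcript(seq_tbl("t1", tr), genome)
  expect_true(pl$ambiguous)
  expect_equal(pl$chain_score, pl$second_best_score)
})

test_that("a transcript split by an intron is chained across it", {
  set.seed(13)
  ex1 <- rand_dna(600); ex2 <- rand_dna(700); intron <- rand_dna(500)
  genome <- seq_tbl("chrA",
                    paste0(rand_dna(1000), ex1, intron, ex2, rand_dna(800)))
  pl <- place_transcript(seq_tbl("t1", paste0(ex1, ex2)), genome,
                         max_intron = 600)
  expect_equal(pl$start, 1000)
  expect_equal(pl$end, 1000 + 600 + 500 + 700)
  # with the intron tolerance below the intron size, only one exon chains
  pl2 <- place_transcript(seq_tbl("t1", paste0(ex1, ex2)), genome,
                          max_intron = 100)
  expect_lt(pl2$end - pl2$start, 1500)
})

test_that("chain score equals exhaustive enumeration over seed subsets on a toy", {
  # seeds are enumerable on a small instance: check the DP chain score
  # against the best colinear subset found by brute force
  set.seed(14)
  for (trial in 1:5) {
    ex1 <- rand_dna(40); ex2 <- rand_dna(39); intron <- rand_dna(120)
    genome_str <- paste0(rand_dna(300), ex1, intron, ex2, rand_dna(200))
    tr <- paste0(ex1, ex2)
    k <- 13
    sk <- tyrfish:::subject_kmers(toupper(genome_str), k)
    seeds <- tyrfish:::seed_matches(toupper(tr), toupper(genome_str), k,
                                    stride = k, sk = sk)
    n <- nrow(seeds)
    skip_if(n == 0 || n > 12)
    best_bf <- 0
    for (mask in 1:(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
      idx <- idx[order(seeds$gpos[idx], seeds$qpos[idx])]
      ok <- TRUE
      if (length(idx) > 1) {
        for (j in 2:length(idx)) {
          dq <- seeds$qpos[idx[j]] - seeds$qpos[idx[j - 1]]
          dg <- seeds$gpos[idx[j]] - seeds$gpos[idx[j - 1]]
          if (dq <= 0 || dg <= 0 || dg - dq > 5000 || dq - dg > 50) {
            ok <- FALSE; break
          }
        }
      }
      if (ok) best_bf <- max(best_bf, k * length(idx))
    }
    pl <- place_transcript(seq_tbl("t", tr), seq_tbl("g", genome_str), k = k)
    expect_equal(pl$chain_score, best_bf)
  }
})

test_that("marker filtering partitions every input with a reason", {
  placements <- tibble::tibble(
    transcript_id = sprintf("t%d", 1:10),
    placed = c(rep(TRUE, 9), FALSE),
    seq_id = c(rep("chr2", 8), "chrU", NA),
    start = 0L, end = 100L, strand = "+",
    chain_score = 100, second_best_score = c(rep(0, 5), 99, rep(0, 4)),
    ambiguous = c(rep(FALSE, 5), TRUE, rep(FALSE, 4))
  )
  markers <- tibble::tibble(
    marker_id = sprintf("m%d", 1:10), transcript_id = sprintf("t%d", 1:10),
    linkage_group = "LG2", cM = 1:10,
    has_protein_annotation = c(FALSE, rep(TRUE, 9))
  )
  out <- filter_markers(markers, placements, expected_seq_ids = "chr2")
  expect_equal(nrow(out), 10)
  expect_equal(out$reason[out$marker_id == "m1"], "no_protein_annotation")
  expect_equal(out$reason[out$marker_id == "m6"], "ambiguous")
  expect_equal(out$reason[out$marker_id == "m9"], "wrong_chromosome")
  expect_equal(out$reason[out$marker_id == "m10"], "unplaced")
  expect_equal(sum(out$status == "retained"), 6)
  expect_equal(sum(out$status == "retained") + sum(out$status == "excluded"),
               nrow(markers))
  expect_error(
    filter_markers(dplyr::mutate(markers, transcript_id = "missing"),
                   placements, "chr2"),
    "unknown transcript")
})

test_that("hard-mask screening discards long N runs only", {
  set.seed(15)
  base <- rand_dna(2000)
  with_run <- paste0(substr(base, 1, 1000), strrep("N", 50),
                     substr(base, 1051, 2000))
  with_single <- paste0(substr(base, 1, 1000), "N", substr(base, 1002, 2000))
  expect_false(discard_hard_masked(with_run, max_N_run = 10))
  expect_true(discard_hard_masked(with_single, max_N_run = 10))
  expect_true(discard_hard_masked(base))
})

test_that("primer Tm follows the long-oligo rule", {
  p <- paste0(strrep("GC", 5), strrep("AT", 5))  # 20-mer, 10 G/C
  expect_equal(primer_tm(p), 64.9 + 41 * (10 - 16.4) / 20)
  expect_equal(primer_tm(p), 51.78)
  expect_equal(primer_gc(p), 50)
})

test_that("primer pairs respect the product window and are penalty-sorted", {
  set.seed(16)
  gene <- rand_dna(5000)
  pp <- propose_primer_pairs(gene)
  expect_gte(nrow(pp), 1)
  expect_lte(nrow(pp), 5)
  expect_true(all(pp$product_length >= 1000 & pp$product_length <= 4000))
  expect_true(all(pp$product_length == pp$right_end - pp$left_start))
  expect_false(is.unsorted(pp$penalty))
  expect_true(all(nchar(pp$left_seq) >= 18 & nchar(pp$left_seq) <= 27))
  # deterministic for fixed input
  expect_identical(pp, propose_primer_pairs(gene))
})

test_that("a gene shorter than the minimum product yields no pairs", {
  set.seed(17)
  pp <- propose_primer_pairs(rand_dna(800))
  expect_equal(nrow(pp), 0)
  expect_equal(attr(pp, "reason"), "gene_shorter_than_min_product")
})

test_that("primers never sit on masked bases", {
  set.seed(18)
  left <- rand_dna(1500)
  gene <- paste0(tolower(rand_dna(40)), left, tolower(rand_dna(30)),
                 rand_dna(1000))
  pp <- propose_primer_pairs(gene, min_product = 1000, max_product = 2400)
  for (i in seq_len(nrow(pp))) {
    expect_false(grepl("[acgtn]",
                       substring(gene, pp$left_start[i] + 1,
                                 pp$left_start[i] + nchar(pp$left_seq[i]))))
  }
})

test_that("candidates spanning masked islands are discarded, clean ones kept", {
  set.seed(19)
  clean <- rand_dna(2400)
  pp <- propose_primer_pairs(clean, min_product = 1000, max_product = 2400)
  expect_gt(nrow(pp), 0)
  cand <- extract_candidates("g1", clean, pp)
  expect_true(all(cand$status == "candidate"))
  expect_true(all(cand$masked_bases == 0))
  expect_true(all(nchar(cand$seq) == cand$product_length))

  # soft-masked island in the middle of every feasible product
  masked <- paste0(substr(clean, 1, 1190),
                   tolower(substr(clean, 1191, 1210)),
                   substr(clean, 1211, 2400))
  ppm <- propose_primer_pairs(masked, min_product = 2000,
                              max_product = 2400)
  candm <- extract_candidates("g1", masked, ppm)
  expect_true(all(candm$status == "discarded_masked"))
  expect_true(all(candm$masked_bases > 0))
})

test_that("candidate intervals lift to genome coordinates through the placement", {
  set.seed(20)
  gene <- rand_dna(2400)
  pp <- propose_primer_pairs(gene, min_product = 1000, max_product = 2400,
                             n_pairs = 2)
  plus <- tibble::tibble(placed = TRUE, seq_id = "chr1", start = 5000L,
                         end = 7400L, strand = "+")
  c_plus <- extract_candidates("g1", gene, pp, placement = plus)
  expect_equal(c_plus$start, 5000 + pp$left_start)
  expect_equal(c_plus$end, 5000 + pp$right_end)
  minus <- dplyr::mutate(plus, strand = "-")
  c_minus <- extract_candidates("g1", gene, pp, placement = minus)
  expect_equal(c_minus$start, 7400 - pp$right_end)
  expect_equal(c_minus$end, 7400 - pp$left_start)
  expect_true(all(c_minus$end - c_minus$start == pp$product_length))
})
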