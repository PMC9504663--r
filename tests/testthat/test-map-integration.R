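test_that("physical ordering walks the short arm down and the long arm up", {
  pos <- tibble::tibble(probe_id = c("far", "near"), rphc_mean = c(80, 20),
                        arm = "short")
  expect_equal(physical_order(pos, 0.4)$probe_id, c("far", "near"))
  lone <- tibble::tibble(probe_id = "x", rphc_mean = 10, arm = "long")
  expect_equal(nrow(physical_order(lone, 0.4)), 1)
  dup <- tibble::tibble(probe_id = c("x", "x"), rphc_mean = c(1, 2),
                        arm = "long")
  expect_error(physical_order(dup, 0.4), "duplicate")
  tied <- tibble::tibble(probe_id = c("b", "a"), rphc_mean = c(50, 50),
                         arm = "long")
  expect_warning(po <- physical_order(tied, 0.4), "tie")
  expect_equal(po$probe_id, c("a", "b"))
})

test_that("orientation detection recognises concordant, reversed and thin maps", {
  phys <- tibble::tibble(marker_id = letters[1:6], fl = 1:6 * 10)
  gen <- tibble::tibble(marker_id = letters[1:6], cM = c(1, 3, 8, 9, 15, 20))
  expect_equal(detect_orientation(gen, phys), "as_is")
  flipped <- dplyr::mutate(gen, cM = rev(cM))
  expect_equal(detect_orientation(flipped, phys), "flipped")
  expect_warning(
    o <- detect_orientation(gen[1:2, ], phys[1:2, ]), "undetermined")
  expect_equal(o, "undetermined")
})

test_that("reversing the genetic map flips the orientation verdict", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(4:15, 1)
    phys <- tibble::tibble(marker_id = paste0("m", 1:n),
                           fl = sort(runif(n, 0, 100)))
    gen <- tibble::tibble(marker_id = sample(phys$marker_id),
                          cM = sort(runif(n, 0, 120)))
    o1 <- detect_orientation(gen, phys)
    o2 <- detect_orientation(dplyr::mutate(gen, cM = max(cM) - cM), phys)
    if (o1 != "undetermined" && o2 != "undetermined") {
      expect_true(o1 != o2)
    }
  }
})

test_that("rank mismatch counts markers whose ordinal position differs", {
  expect_equal(rank_mismatch_count(c("A", "B", "C"), c("A", "B", "C")), 0)
  expect_equal(rank_mismatch_count(c("B", "A", "C"), c("A", "B", "C")), 2)
  expect_error(rank_mismatch_count(c("A", "B"), c("A", "C")), "only in")
})

test_that("minimal removal equals n minus the longest increasing subsequence", {
  expect_equal(min_removal_count(letters[1:5], letters[1:5]), 0)
  # the rank sequence 2 1 3 9 4 6 5 8 7 10 11 needs 4 removals (LIS 7)
  a <- paste0("m", 1:11)
  b <- a[order(c(2, 1, 3, 9, 4, 6, 5, 8, 7, 10, 11))]
  expect_equal(lis_length(c(2, 1, 3, 9, 4, 6, 5, 8, 7, 10, 11)), 7)
  expect_equal(min_removal_count(a, b), 4)
})

test_that("minimal removal matches brute-force enumeration on small cases", {
  subs6 <- subsets_by_size_desc(6)
  for (p in all_permutations(1:6)[seq(1, 720, by = 7)]) {
    ids <- paste0("m", 1:6)
    expect_equal(min_removal_count(ids, ids[order(p)]),
                 bf_min_removal(p, subs6))
  }
  set.seed(42)
  for (i in 1:25) {
    n <- sample(7:10, 1)
    p <- sample(n)
    ids <- paste0("m", 1:n)
    expect_equal(min_removal_count(ids, ids[order(p)]), bf_min_removal(p))
  }
})

test_that("removal never exceeds rank mismatch, and both metrics are invariant", {
  set.seed(43)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    a <- paste0("m", sample(1000, n))
    b <- sample(a)
    rm_ct <- rank_mismatch_count(a, b)
    mr_ct <- min_removal_count(a, b)
    expect_lte(mr_ct, rm_ct)
    # simultaneous reversal of both orders
    expect_equal(rank_mismatch_count(rev(a), rev(b)), rm_ct)
    expect_equal(min_removal_count(rev(a), rev(b)), mr_ct)
    # relabeling of markers
    relab <- stats::setNames(paste0("x", seq_len(n)), a)
    expect_equal(min_removal_count(unname(relab[a]), unname(relab[b])),
                 mr_ct)
    # both zero iff identical
    expect_equal(rm_ct == 0, identical(a, b))
    expect_equal(mr_ct == 0, identical(a, b))
  }
})

test_that("per-marker discordance flags track both metrics", {
  cmp <- compare_orders(c("a", "b", "c", "d"), c("b", "a", "c", "d"))
  expect_equal(cmp$rank_mismatch_count, 2)
  expect_equal(cmp$min_removal_count, 1)
  expect_setequal(cmp$rank_mismatch_markers, c("a", "b"))
  expect_true(all(cmp$min_removal_markers %in% c("a", "b")))
  expect_length(cmp$min_removal_markers, 1)
})

test_that("the packaged chromosome-2 maps reproduce the published discordance", {
  entries <- fixture_map_entries(2)
  report <- build_report(entries)
  pairs <- tidy(report)
  gp <- pairs[pairs$map_pair == "genetic_vs_physical", ]
  expect_equal(gp$n_shared, 12)  # mlh1 absent from the genetic map
  expect_false(gp$orientation_flipped)
  expect_equal(gp$rank_mismatch_count, 3)
  expect_equal(gp$rank_mismatch_pct, 25.0)
  pp <- pairs[pairs$map_pair == "pseudo_vs_physical", ]
  expect_equal(pp$n_shared, 13)  # mlh1 included
  expect_equal(pp$rank_mismatch_count, 3)
  expect_equal(pp$rank_mismatch_pct, 23.1)
  # the genetic and pseudochromosome orders coincide on this chromosome
  gps <- pairs[pairs$map_pair == "genetic_vs_pseudo", ]
  expect_equal(gps$rank_mismatch_count, 0)
  expect_equal(gps$min_removal_count, 0)
})

test_that("the packaged chromosome-6 maps flip and reproduce the removals", {
  report <- build_report(fixture_map_entries(6))
  pairs <- tidy(report)
  gp <- pairs[pairs$map_pair == "genetic_vs_physical", ]
  expect_true(gp$orientation_flipped)
  expect_equal(gp$n_shared, 11)
  expect_equal(gp$min_removal_count, 4)
  expect_equal(gp$min_removal_pct, 36.4)
  pp <- pairs[pairs$map_pair == "pseudo_vs_physical", ]
  expect_equal(pp$min_removal_count, 3)
  expect_equal(pp$min_removal_pct, 27.3)
})

test_that("map pairs sharing too few markers are reported as not comparable", {
  entries <- tibble::tibble(
    marker_id = c("a", "b", "c"),
    genetic_cM = c(1, 2, NA),
    physical_fl = c(10, 20, 30),
    pseudo_mbp = c(NA, NA, 5)
  )
  expect_warning(report <- build_report(entries), "undetermined")
  pairs <- tidy(report)
  expect_false(pairs$comparable[pairs$map_pair == "genetic_vs_pseudo"])
  expect_true(pairs$comparable[pairs$map_pair == "genetic_vs_physical"])
})

test_that("report accessors expose tidy, glance, flags and a plot", {
  report <- build_report(fixture_map_entries(6))
  expect_s3_class(tidy(report), "tbl_df")
  g <- glance(report)
  expect_equal(g$n_markers, 11)
  expect_true(g$any_flipped)
  dm <- discordant_markers(report)
  expect_true(all(c("map_pair", "marker_id", "rank_mismatch",
                    "in_removal_set") %in% names(dm)))
  p <- autoplot(report)
  expect_s3_class(p, "ggplot")
  expect_output(print(report), "concordance")
})
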