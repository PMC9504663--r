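#' Order markers along the physical chromosome
#'
#' Converts per-arm RPHC positions to whole-chromosome FL and sorts by
#' ascending FL: short-arm markers by descending RPHC (telomere first), then
#' long-arm markers by ascending RPHC. Ties are broken by marker id with a
#' warning.
#'
#' @param positions Tibble with columns `probe_id`, `rphc_mean`, `arm`
#'   (short/long, any case).
#' @param short_arm_fraction Short-arm fraction of the chromosome.
#' @return `positions` with an `fl` column, sorted by ascending FL.
#' @export
physical_order <- function(positions, short_arm_fraction) {
  if (anyDuplicated(positions$probe_id)) {
    abort("duplicate marker ids in positions table")
  }
  out <- positions |>
    mutate(arm = tolower(.data$arm),
           fl = rphc_to_fl(.data$rphc_mean, .data$arm, short_arm_fraction)) |>
    arrange(.data$fl, .data$probe_id)
  if (anyDuplicated(out$fl)) {
    warn("tied FL positions; ties broken by marker id")
  }
  out
}

#' Detect the orientation of a linkage group against a physical map
#'
#' Linkage groups are drawn by convention with the short arm at the top, but
#' the published orientation of a linkage group can be upended relative to
#' the physical chromosome. The orientation with the higher Kendall rank
#' correlation between the two coordinate sets wins: `"as_is"` when
#' positions increase together, `"flipped"` when the genetic coordinate
#' decreases along the physical chromosome.
#'
#' @param genetic Tibble with columns `marker_id` and a genetic coordinate
#'   (`cM`, or the second column).
#' @param physical Tibble with columns `marker_id` and a physical coordinate
#'   (`fl`, or the second column).
#' @return `"as_is"`, `"flipped"`, or `"undetermined"` (fewer than 3 shared
#'   markers).
#' @export
detect_orientation <- function(genetic, physical) {
  g <- coord_vector(genetic, c("cM", "genetic_cM"))
  p <- coord_vector(physical, c("fl", "physical_fl"))
  shared <- intersect(names(g), names(p))
  if (length(shared) < 3) {
    warn("fewer than 3 shared markers; orientation undetermined")
    return("undetermined")
  }
  tau <- suppressWarnings(
    stats::cor(g[shared], p[shared], method = "kendall")
  )
  if (is.na(tau)) return("undetermined")
  if (tau < 0) "flipped" else "as_is"
}

coord_vector <- function(x, preferred) {
  stopifnot(is.data.frame(x), "marker_id" %in% names(x))
  col <- intersect(preferred, names(x))[1]
  if (is.na(col)) col <- setdiff(names(x), "marker_id")[1]
  stats::setNames(x[[col]], x$marker_id)
}

#' Marker-order discordance metrics
#'
#' Two ways of counting markers "placed in the wrong position" between two
#' orderings of the same marker set:
#'
#' * `rank_mismatch_count()` — the number of markers whose ordinal rank
#'   differs between the two orders.
#' * `min_removal_count()` — the minimum number of markers whose removal
#'   makes the remaining orders identical; computed as `n` minus the length
#'   of the longest increasing subsequence (LIS) of one order's ranks taken
#'   in the other order's sequence.
#'
#' `min_removal_count(a, b) <= rank_mismatch_count(a, b)` always: removing
#' every rank-mismatched marker leaves an identical order.
#'
#' @param order_a,order_b Character vectors: the same markers in two orders.
#' @return An integer count.
#' @export
#' @examples
#' rank_mismatch_count(c("B", "A", "C"), c("A", "B", "C"))  # 2
#' min_removal_count(c("B", "A", "C"), c("A", "B", "C"))    # 1
rank_mismatch_count <- function(order_a, order_b) {
  check_same_set(order_a, order_b)
  sum(order_a != order_b)
}

#' @rdname rank_mismatch_count
#' @export
min_removal_count <- function(order_a, order_b) {
  check_same_set(order_a, order_b)
  length(order_a) - lis_length(match(order_b, order_a))
}

#' Longest strictly increasing subsequence
#'
#' @param x An integer/numeric vector without ties.
#' @return Length of the longest strictly increasing subsequence.
#' @export
lis_length <- function(x) {
  lis_length_cpp(as.integer(x))
}

# One LIS realisation (indices into x), via patience sorting with parents;
# used to flag a minimal removal set. Minimal sets are not unique.
lis_members <- function(x) {
  n <- length(x)
  if (n == 0) return(integer())
  tails_idx <- integer(0)
  parent <- integer(n)
  for (i in seq_len(n)) {
    vals <- x[tails_idx]
    pos <- findInterval(x[i] - 1L, vals) + 1L
    parent[i] <- if (pos > 1) tails_idx[pos - 1] else 0L
    tails_idx[pos] <- i
  }
  out <- integer(0)
  i <- tails_idx[length(tails_idx)]
  while (i > 0) {
    out <- c(i, out)
    i <- parent[i]
  }
  out
}

check_same_set <- function(a, b) {
  if (length(a) != length(b) || !setequal(a, b) ||
      anyDuplicated(a) || anyDuplicated(b)) {
    only_a <- setdiff(a, b)
    only_b <- setdiff(b, a)
    abort(paste0(
      "orders are not permutations of the same marker set",
      if (length(only_a)) paste0("; only in first: ",
                                 paste(only_a, collapse = ", ")) else "",
      if (length(only_b)) paste0("; only in second: ",
                                 paste(only_b, collapse = ", ")) else ""
    ))
  }
  invisible(TRUE)
}

#' Compare two marker orders in detail
#'
#' @param order_a,order_b Character vectors over the same marker set
#'   (`order_a` is the reference, e.g. the physical order).
#' @return A list: both counts and percentages, plus per-marker discordance
#'   flags (`rank_mismatch`, and `in_removal_set` for one minimal removal
#'   set).
#' @export
compare_orders <- function(order_a, order_b) {
  check_same_set(order_a, order_b)
  n <- length(order_a)
  ranks_in_a <- match(order_b, order_a)
  keep <- lis_members(match(order_b, order_a))
  removed <- order_b[setdiff(seq_len(n), keep)]
  mism <- order_a[order_a != order_b]
  list(
    n_shared = n,
    rank_mismatch_count = length(mism),
    rank_mismatch_pct = round(100 * length(mism) / n, 1),
    min_removal_count = n - length(keep),
    min_removal_pct = round(100 * (n - length(keep)) / n, 1),
    rank_mismatch_markers = mism,
    min_removal_markers = removed
  )
}

#' Build the integrated map-concordance report
#'
#' Takes one marker table holding up to three coordinates per marker —
#' genetic (`genetic_cM`), physical (`physical_fl`, from [physical_order()])
#' and pseudochromosome (`pseudo_mbp`, 1-Mbp bins) — and compares every map
#' pair. For each pair, markers missing either coordinate are excluded from
#' that pair only (and listed); the non-physical order is flipped when
#' [detect_orientation()] says the published orientation is upended; both
#' discordance metrics are reported, because neither is canonical.
#'
#' Markers sharing a pseudochromosome bin keep their input order and are
#' flagged as ties.
#'
#' @param entries Tibble with columns `marker_id` and at least two of
#'   `genetic_cM`, `physical_fl`, `pseudo_mbp` (NA = absent from that map).
#' @return A `tyr_concordance` object: list with `pairs` (one row per map
#'   pair), `entries`, and per-pair detail in `comparisons`. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
build_report <- function(entries) {
  stopifnot("marker_id" %in% names(entries))
  coords <- c(genetic = "genetic_cM", physical = "physical_fl",
              pseudo = "pseudo_mbp")
  coords <- coords[coords %in% names(entries)]
  if (length(coords) < 2) abort("need at least two map coordinates")
  pairs <- utils::combn(names(coords), 2, simplify = FALSE)
  # compare physical-containing pairs with physical as reference
  pairs <- purrr::map(pairs, function(p) {
    if ("physical" %in% p) c("physical", setdiff(p, "physical")) else rev(p)
  })
  comparisons <- purrr::map(pairs, function(p) {
    ref_col <- coords[[p[1]]]
    oth_col <- coords[[p[2]]]
    sub <- entries |> filter(!is.na(.data[[ref_col]]), !is.na(.data[[oth_col]]))
    excluded <- setdiff(entries$marker_id, sub$marker_id)
    pair_name <- paste0(p[2], "_vs_", p[1])
    if (nrow(sub) < 2) {
      return(list(map_pair = pair_name, comparable = FALSE,
                  excluded_markers = excluded))
    }
    if (anyDuplicated(sub[[oth_col]]) || anyDuplicated(sub[[ref_col]])) {
      warn(paste0(pair_name, ": tied coordinates; input order kept for ties"))
    }
    ref_order <- sub$marker_id[order(sub[[ref_col]])]
    oth_order <- sub$marker_id[order(sub[[oth_col]])]
    orientation <- detect_orientation(
      stats::setNames(sub[c("marker_id", oth_col)], c("marker_id", "cM")),
      stats::setNames(sub[c("marker_id", ref_col)], c("marker_id", "fl"))
    )
    if (identical(orientation, "flipped")) oth_order <- rev(oth_order)
    c(list(map_pair = pair_name, comparable = TRUE,
           orientation_flipped = identical(orientation, "flipped"),
           excluded_markers = excluded),
      compare_orders(ref_order, oth_order))
  })
  pair_rows <- purrr::map(comparisons, function(cm) {
    if (!cm$comparable) {
      return(tibble(map_pair = cm$map_pair, comparable = FALSE,
                    n_shared = NA_integer_, orientation_flipped = NA,
                    rank_mismatch_count = NA_integer_,
                    rank_mismatch_pct = NA_real_,
                    min_removal_count = NA_integer_,
                    min_removal_pct = NA_real_))
    }
    tibble(map_pair = cm$map_pair, comparable = TRUE,
           n_shared = cm$n_shared,
           orientation_flipped = cm$orientation_flipped,
           rank_mismatch_count = cm$rank_mismatch_count,
           rank_mismatch_pct = cm$rank_mismatch_pct,
           min_removal_count = cm$min_removal_count,
           min_removal_pct = cm$min_removal_pct)
  }) |> purrr::list_rbind()
  structure(list(pairs = pair_rows, comparisons = comparisons,
                 entries = as_tibble(entries)),
            class = "tyr_concordance")
}

#' Assemble the marker map entries for a packaged chromosome
#'
#' Convenience wrapper joining the packaged position, map-order and
#' karyotype tables into the entry table consumed by [build_report()].
#'
#' @param chromosome 2 or 6.
#' @return A tibble: `marker_id`, `genetic_cM`, `physical_fl`,
#'   `physical_arm`, `rphc_mean`, `pseudo_mbp`, in physical order.
#' @export
fixture_map_entries <- function(chromosome) {
  stopifnot(chromosome %in% c(2, 6))
  positions <- load_paper_fixture(
    if (chromosome == 2) "positions_chr2" else "positions_chr6")
  orders <- load_paper_fixture("marker_orders") |>
    filter(.data$chromosome == !!chromosome)
  kary <- load_paper_fixture("karyotype")
  f_s <- kary$short_arm_fraction[kary$chromosome == chromosome]
  phys <- physical_order(positions, f_s)
  phys |>
    select(marker_id = "probe_id", physical_fl = "fl",
           physical_arm = "arm", "rphc_mean") |>
    left_join(select(orders, "marker_id", "genetic_cM", "pseudo_mbp"),
              by = "marker_id")
}

#' @export
print.tyr_concordance <- function(x, ...) {
  cat("Map-order concordance report (", nrow(x$entries), " markers)\n\n",
      sep = "")
  print(x$pairs, ...)
  invisible(x)
}

#' @describeIn build_report One row per map pair: counts, percentages,
#'   orientation.
#' @param x A `tyr_concordance` object.
#' @param ... Unused.
#' @export
tidy.tyr_concordance <- function(x, ...) {
  x$pairs
}

#' @describeIn build_report One-row summary: marker count and the worst
#'   discordance across pairs.
#' @export
glance.tyr_concordance <- function(x, ...) {
  p <- filter(x$pairs, .data$comparable)
  tibble(
    n_markers = nrow(x$entries),
    n_pairs = nrow(x$pairs),
    any_flipped = any(p$orientation_flipped),
    max_rank_mismatch_pct = max(p$rank_mismatch_pct),
    max_min_removal_pct = max(p$min_removal_pct)
  )
}

#' Per-marker discordance flags of a concordance report
#'
#' @param report A `tyr_concordance` object.
#' @return Tibble: `map_pair`, `marker_id`, `rank_mismatch`,
#'   `in_removal_set`.
#' @export
discordant_markers <- function(report) {
  stopifnot(inherits(report, "tyr_concordance"))
  purrr::map(report$comparisons, function(cm) {
    if (!cm$comparable) return(NULL)
    shared <- setdiff(report$entries$marker_id, cm$excluded_markers)
    tibble(map_pair = cm$map_pair, marker_id = shared,
           rank_mismatch = shared %in% cm$rank_mismatch_markers,
           in_removal_set = shared %in% cm$min_removal_markers)
  }) |> purrr::list_rbind()
}
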