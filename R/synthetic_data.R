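#' Specification for a synthetic toy genome
#'
#' The generator emulates the features the probe pipeline must cope with in
#' a real plant genome, at toy scale: gene loci with introns (so transcript
#' placement must chain across genomic gaps), soft-masked repeat families
#' (tandem arrays and dispersed copies, lowercase in the FASTA), and
#' diverged paralogs (off-target traps for the specificity screen). The
#' default scale — 2 chromosomes x 200 kb, 20 genes, 2 repeat families — is
#' large enough to exercise seeding and masking while keeping runs at
#' seconds scale.
#'
#' @param n_chromosomes,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes Number of gene loci.
#' @param exon_length Range of per-exon lengths (bp).
#' @param n_exons Range of exon counts per gene.
#' @param intron_length Range of intron lengths (bp).
#' @param repeat_families List of families, each
#'   `list(unit, copies, mode)` with `mode` `"tandem"` or `"dispersed"`.
#' @param paralog_rate Probability that a gene has a diverged paralog copy
#'   planted elsewhere.
#' @param paralog_divergence Per-base substitution rate of paralog copies.
#' @param seed Integer seed; the whole genome is a deterministic function of
#'   the spec.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(n_chromosomes = 2, chrom_length = 200000,
                        n_genes = 20, exon_length = c(400, 1500),
                        n_exons = c(1, 3), intron_length = c(200, 800),
                        repeat_families = list(
                          list(unit = 300, copies = 30, mode = "dispersed"),
                          list(unit = 150, copies = 20, mode = "tandem")),
                        paralog_rate = 0.1, paralog_divergence = 0.05,
                        seed = 1) {
  structure(as.list(environment()), class = "genome_spec")
}

#' Generate a synthetic genome with truth tables
#'
#' Deterministic for a fixed spec (seed included). Repeats are written
#' soft-masked (lowercase) so masking filters are exercised; truth tables
#' exactly describe every planted feature, sufficient to score every
#' downstream module.
#'
#' @param spec A [genome_spec()].
#' @return A list: `genome` (sequence tibble), `genes` (gene loci with
#'   0-based half-open coordinates), `exons`, `transcripts` (spliced exon
#'   sequences), `repeats`, `paralogs` (planted diverged copies), `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, generate_genome_impl(spec))
}

generate_genome_impl <- function(spec) {
  chrom_ids <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  lens <- rep_len(spec$chrom_length, spec$n_chromosomes)
  chroms <- vapply(lens, random_dna, "")
  occupied <- stats::setNames(vector("list", length(chrom_ids)), chrom_ids)

  place_feature <- function(width) {
    for (try in 1:1000) {
      ci <- sample.int(length(chrom_ids), 1)
      if (lens[ci] < width + 2) next
      s <- sample.int(lens[ci] - width - 1, 1)
      iv <- c(s, s + width)
      clash <- any(vapply(occupied[[ci]],
                          function(o) iv[1] < o[2] && iv[2] > o[1], TRUE))
      if (!clash) {
        occupied[[ci]] <<- c(occupied[[ci]], list(iv))
        return(list(chrom = ci, start = iv[1], end = iv[2]))
      }
    }
    abort("infeasible packing: could not place feature without overlap")
  }

  genes <- list(); exons <- list(); transcripts <- list(); paralogs <- list()
  for (g in seq_len(spec$n_genes)) {
    gid <- sprintf("gene%02d", g)
    ne <- sample_range(spec$n_exons[1], spec$n_exons[2], 1)
    ex_len <- sample_range(spec$exon_length[1], spec$exon_length[2], ne)
    in_len <- if (ne > 1) {
      sample_range(spec$intron_length[1], spec$intron_length[2], ne - 1)
    } else integer()
    ex_seq <- vapply(ex_len, random_dna, "")
    in_seq <- vapply(in_len, random_dna, "")
    pieces <- character(2 * ne - 1)
    pieces[seq(1, 2 * ne - 1, by = 2)] <- ex_seq
    if (ne > 1) pieces[seq(2, 2 * ne - 2, by = 2)] <- in_seq
    body <- paste(pieces, collapse = "")
    loc <- place_feature(nchar(body))
    substr(chroms[loc$chrom], loc$start + 1, loc$end) <- body
    genes[[g]] <- tibble(gene_id = gid, seq_id = chrom_ids[loc$chrom],
                         start = loc$start, end = loc$end, strand = "+",
                         n_exons = ne)
    off <- loc$start + c(0, cumsum(ex_len[-ne] + in_len))
    exons[[g]] <- tibble(gene_id = gid, seq_id = chrom_ids[loc$chrom],
                         start = off, end = off + ex_len)
    transcripts[[g]] <- tibble(id = gid, seq = paste(ex_seq, collapse = ""))
    if (stats::runif(1) < spec$paralog_rate) {
      copy <- mutate_dna(body, spec$paralog_divergence)
      ploc <- place_feature(nchar(copy))
      substr(chroms[ploc$chrom], ploc$start + 1, ploc$end) <- copy
      paralogs[[length(paralogs) + 1]] <- tibble(
        gene_id = gid, seq_id = chrom_ids[ploc$chrom],
        start = ploc$start, end = ploc$end,
        divergence = spec$paralog_divergence)
    }
  }

  repeats <- list()
  for (fi in seq_along(spec$repeat_families)) {
    fam <- spec$repeat_families[[fi]]
    fam_id <- sprintf("repfam%d", fi)
    unit <- random_dna(fam$unit)
    if (identical(fam$mode, "tandem")) {
      arr <- tolower(strrep(unit, fam$copies))
      loc <- place_feature(nchar(arr))
      substr(chroms[loc$chrom], loc$start + 1, loc$end) <- arr
      repeats[[length(repeats) + 1]] <- tibble(
        family = fam_id, mode = "tandem", seq_id = chrom_ids[loc$chrom],
        start = loc$start, end = loc$end)
    } else {
      for (cp in seq_len(fam$copies)) {
        copy <- tolower(mutate_dna(unit, 0.02))
        loc <- place_feature(nchar(copy))
        substr(chroms[loc$chrom], loc$start + 1, loc$end) <- copy
        repeats[[length(repeats) + 1]] <- tibble(
          family = fam_id, mode = "dispersed",
          seq_id = chrom_ids[loc$chrom], start = loc$start, end = loc$end)
      }
    }
  }

  list(genome = seq_tbl(chrom_ids, chroms),
       genes = purrr::list_rbind(genes),
       exons = purrr::list_rbind(exons),
       transcripts = do.call(seq_tbl, purrr::list_rbind(transcripts)),
       repeats = purrr::list_rbind(repeats),
       paralogs = if (length(paralogs)) purrr::list_rbind(paralogs) else
         tibble(gene_id = character(), seq_id = character(),
                start = integer(), end = integer(), divergence = double()),
       spec = spec)
}

# uniform integer draw on [lo, hi] that is safe when lo == hi (base
# sample() would treat a scalar as 1:n)
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1, n, replace = TRUE) - 1L
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Point-mutate a sequence at the given per-base rate (substitutions only),
# preserving case.
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    repl <- vapply(ch[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), toupper(b)), 1)
    }, "")
    lower <- ch[hit] %in% c("a", "c", "g", "t")
    repl[lower] <- tolower(repl[lower])
    ch[hit] <- repl
  }
  paste(ch, collapse = "")
}

#' Specification for a synthetic genetic map
#'
#' Emulates a linkage map built over a chromosome with zones of suppressed
#' recombination (pericentromeric or subtelomeric heterochromatin): the cM
#' coordinate is the cumulative integral of a recombination-rate profile
#' along the physical (FL) axis, with the rate multiplied by a factor in
#' `[0, 1]` inside each suppressed zone (0 = full suppression), plus
#' Gaussian noise. Optionally the map is emitted flipped (long arm at top),
#' and marker pairs can be swapped to plant local order errors.
#'
#' @param suppressed_zones List of `list(fl_start, fl_end, factor)`.
#' @param noise_sd_cM SD of additive Gaussian noise on cM.
#' @param flip Emit the map upended.
#' @param swap_pairs List of length-2 character vectors (marker ids) whose
#'   cM values are exchanged, planting an inversion-like order error.
#' @param cM_per_fl Baseline recombination rate (cM per FL percent).
#' @param seed Integer seed.
#' @return A `map_spec` list.
#' @export
map_spec <- function(suppressed_zones = list(), noise_sd_cM = 0,
                     flip = FALSE, swap_pairs = NULL, cM_per_fl = 1,
                     seed = 1) {
  structure(as.list(environment()), class = "map_spec")
}

#' Generate a genetic map from true physical positions
#'
#' @param true_fl Tibble with `marker_id` and `fl` (true physical position,
#'   percent of chromosome length from the short-arm telomere).
#' @param spec A [map_spec()].
#' @param linkage_group Label for the emitted linkage group.
#' @return A tibble: `marker_id`, `linkage_group`, `cM`.
#' @export
generate_genetic_map <- function(true_fl, spec, linkage_group = "LG1") {
  stopifnot(inherits(spec, "map_spec"))
  if (any(true_fl$fl < 0 | true_fl$fl > 100)) abort("fl must be in [0, 100]")
  withr::with_seed(spec$seed, {
    cm <- vapply(true_fl$fl, rate_integral, 0,
                 zones = spec$suppressed_zones) * spec$cM_per_fl
    if (spec$noise_sd_cM > 0) {
      cm <- cm + stats::rnorm(length(cm), 0, spec$noise_sd_cM)
      cm <- pmax(cm, 0)
    }
    out <- tibble(marker_id = true_fl$marker_id,
                  linkage_group = linkage_group, cM = cm)
    for (sp in spec$swap_pairs %||% list()) {
      i <- match(sp, out$marker_id)
      if (anyNA(i)) abort("swap_pairs names a marker not in the map")
      out$cM[i] <- out$cM[rev(i)]
    }
    if (spec$flip) {
      out$cM <- max(out$cM) - out$cM
    }
    out
  })
}

# Integral of the recombination-rate profile from 0 to fl (baseline rate 1,
# multiplied by each zone's factor inside the zone).
rate_integral <- function(fl, zones) {
  total <- fl
  for (z in zones) {
    lo <- max(0, z$fl_start)
    hi <- min(fl, z$fl_end)
    if (hi > lo) total <- total - (hi - lo) * (1 - z$factor)
  }
  total
}

#' Simulate noisy per-metaphase hybridization signal measurements
#'
#' Emulates the measurement layer behind a FISH position table: in each
#' analyzed metaphase the probe is detected with probability `detection_p`;
#' a detected metaphase contributes one measurement per homolog (2 copies),
#' each the true RPHC plus Gaussian noise, clipped to `[0, 100]` (clip
#' events are counted). Deterministic per seed.
#'
#' @param true_positions Tibble: `probe_id`, `arm`, `rphc` (true values).
#' @param rphc_noise_sd Measurement noise SD (RPHC percent units).
#' @param detection_p Per-metaphase detection probability, in (0, 1].
#' @param n_metaphases Metaphases analyzed per probe.
#' @param arm_length_um Nominal arm length (measurement units).
#' @param seed Integer seed.
#' @return A list: `signals` (tibble `probe_id`, `metaphase_id`,
#'   `chromosome_copy`, `arm`, `d_centromere`, `arm_length`), `detection`
#'   (tibble `probe_id`, `n_analyzed`, `n_detected`), `n_clipped`.
#' @export
simulate_signals <- function(true_positions, rphc_noise_sd = 2.5,
                             detection_p = 0.5, n_metaphases = 30,
                             arm_length_um = 10, seed = 1) {
  if (detection_p <= 0 || detection_p > 1) {
    abort("detection_p must be in (0, 1]")
  }
  withr::with_seed(seed, {
    n_clipped <- 0L
    signals <- purrr::map(seq_len(nrow(true_positions)), function(i) {
      p <- true_positions[i, ]
      det <- stats::runif(n_metaphases) < detection_p
      if (!any(det)) return(NULL)
      grid <- tidyr::crossing(metaphase = which(det), copy = 1:2)
      meas <- p$rphc + stats::rnorm(nrow(grid), 0, rphc_noise_sd)
      n_clipped <<- n_clipped + sum(meas < 0 | meas > 100)
      meas <- pmin(pmax(meas, 0), 100)
      tibble(probe_id = p$probe_id,
             metaphase_id = sprintf("m%03d", grid$metaphase),
             chromosome_copy = sprintf("hom%d", grid$copy),
             arm = p$arm,
             d_centromere = meas / 100 * arm_length_um,
             arm_length = arm_length_um)
    }) |> purrr::list_rbind()
    detection <- purrr::map(seq_len(nrow(true_positions)), function(i) {
      p <- true_positions[i, ]
      n_det <- length(unique(
        signals$metaphase_id[signals$probe_id == p$probe_id]))
      tibble(probe_id = p$probe_id, n_analyzed = n_metaphases,
             n_detected = n_det)
    }) |> purrr::list_rbind()
    list(signals = signals, detection = detection, n_clipped = n_clipped)
  })
}
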