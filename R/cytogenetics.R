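#' Relative position of a hybridization site on a chromosome arm (RPHC)
#'
#' RPHC is the distance between the hybridization site and the centromere
#' divided by the length of the chromosome arm, in percent: 0 at the
#' centromere, 100 at the telomere.
#'
#' @param d_centromere Distance from the centromere to the signal (any
#'   consistent unit).
#' @param arm_length Length of the arm in the same unit (> 0).
#' @return RPHC in percent. Vectorised.
#' @export
#' @examples
#' compute_rphc(4, 5)  # 80
compute_rphc <- function(d_centromere, arm_length) {
  if (any(arm_length <= 0)) abort("arm_length must be > 0")
  if (any(d_centromere < 0 | d_centromere > arm_length)) {
    abort("measurement error: d_centromere must lie in [0, arm_length]")
  }
  100 * d_centromere / arm_length
}

#' Aggregate per-chromosome signal measurements into a probe position
#'
#' Produces one table row per probe in the style of a FISH position table:
#' sample mean and sample standard deviation (n - 1 denominator) of the
#' per-chromosome RPHC values, the arm, the number of measured chromosomes,
#' and the detection frequency.
#'
#' The detection-frequency denominator is configurable because published
#' frequencies are not always expressible as a fraction of analyzed
#' metaphases: `"metaphases"` (default) divides by `n_analyzed`,
#' `"chromosomes"` by `2 * n_analyzed` (two homologs per metaphase),
#' `"sites"` by `4 * n_analyzed` (two sister chromatids per homolog).
#'
#' @param signals Tibble of raw measurements for one probe with columns
#'   `probe_id`, `arm` (`short`/`long`, any case), `d_centromere`,
#'   `arm_length` (or a precomputed `rphc` column).
#' @param n_analyzed Number of metaphases analyzed.
#' @param n_detected Number of metaphases in which the signal was observed.
#' @param denominator Detection-frequency denominator convention.
#' @return A one-row tibble: `probe_id`, `rphc_mean`, `rphc_sd`, `arm`,
#'   `n_chromosomes`, `detection_frequency` (percent, 1 decimal),
#'   `n_metaphases`.
#' @export
#' @examples
#' sig <- tibble::tibble(probe_id = "p", arm = "short",
#'                       d_centromere = c(1, 2, 3), arm_length = 10)
#' aggregate_position(sig, n_analyzed = 15, n_detected = 13)
aggregate_position <- function(signals, n_analyzed, n_detected,
                               denominator = c("metaphases", "chromosomes",
                                               "sites")) {
  denominator <- match.arg(denominator)
  stopifnot(nrow(signals) >= 1, n_detected <= n_analyzed)
  probe <- unique(signals$probe_id)
  if (length(probe) != 1) abort("signals must belong to a single probe")
  arm <- unique(tolower(signals$arm))
  if (length(arm) != 1) {
    abort(paste0("signals on mixed arms for ", probe,
                 ": a probe maps to one arm"))
  }
  rphc <- if ("rphc" %in% names(signals)) signals$rphc else {
    compute_rphc(signals$d_centromere, signals$arm_length)
  }
  sd_val <- if (length(rphc) > 1) stats::sd(rphc) else {
    warn(paste0("single measurement for ", probe, "; SD reported as 0"))
    0
  }
  denom <- switch(denominator, metaphases = n_analyzed,
                  chromosomes = 2 * n_analyzed, sites = 4 * n_analyzed)
  tibble(
    probe_id = probe,
    rphc_mean = mean(rphc),
    rphc_sd = sd_val,
    arm = arm,
    n_chromosomes = length(rphc),
    detection_frequency = round(100 * n_detected / denom, 1),
    n_metaphases = as.integer(n_analyzed)
  )
}

#' Aggregate a full signal table, probe by probe
#'
#' @param signals Tibble with columns `probe_id`, `metaphase_id`, `arm`, and
#'   either `rphc` or `d_centromere` + `arm_length`.
#' @param detection Tibble with columns `probe_id`, `n_analyzed`,
#'   `n_detected`.
#' @inheritParams aggregate_position
#' @return A tibble with one row per probe (see [aggregate_position()]).
#' @export
aggregate_positions <- function(signals, detection,
                                denominator = "metaphases") {
  signals |>
    dplyr::group_split(.data$probe_id) |>
    purrr::map(function(g) {
      det <- detection[detection$probe_id == g$probe_id[1], ]
      if (nrow(det) != 1) {
        abort(paste0("detection counts missing for ", g$probe_id[1]))
      }
      aggregate_position(g, det$n_analyzed, det$n_detected,
                         denominator = denominator)
    }) |>
    purrr::list_rbind() |>
    arrange(.data$probe_id)
}

#' Convert between RPHC and fractional length (FL)
#'
#' FL is the distance from the telomere end of the short arm to the signal,
#' divided by the length of the entire chromosome, in percent — the
#' whole-chromosome coordinate used to align cytogenetic maps with genetic
#' and pseudochromosome maps (idiograms are drawn short arm up, so FL 0 is
#' the short-arm telomere). With short-arm fraction `f_s`:
#' short arm `FL = f_s * (100 - RPHC)`; long arm
#' `FL = 100 * f_s + (1 - f_s) * RPHC`.
#'
#' @param rphc RPHC in percent (0 centromere, 100 telomere).
#' @param arm `"short"` or `"long"` (any case).
#' @param short_arm_fraction Short-arm length / total chromosome length,
#'   in (0, 1).
#' @return `rphc_to_fl()`: FL in percent. `fl_to_rphc()`: a tibble with
#'   columns `arm`, `rphc` (the centromere, FL = 100 * f_s, maps to
#'   `arm = "centromere"`, `rphc = 0`).
#' @export
#' @examples
#' rphc_to_fl(60, "short", 0.335)  # 13.4
rphc_to_fl <- function(rphc, arm, short_arm_fraction) {
  check_fraction(short_arm_fraction)
  if (any(rphc < 0 | rphc > 100)) abort("rphc must lie in [0, 100]")
  arm <- tolower(arm)
  if (!all(arm %in% c("short", "long"))) abort("arm must be 'short' or 'long'")
  ifelse(arm == "short",
         short_arm_fraction * (100 - rphc),
         100 * short_arm_fraction + (1 - short_arm_fraction) * rphc)
}

#' @rdname rphc_to_fl
#' @param fl FL in percent.
#' @export
fl_to_rphc <- function(fl, short_arm_fraction) {
  check_fraction(short_arm_fraction)
  if (any(fl < 0 | fl > 100)) abort("fl must lie in [0, 100]")
  cen <- 100 * short_arm_fraction
  arm <- dplyr::case_when(fl < cen ~ "short", fl > cen ~ "long",
                          TRUE ~ "centromere")
  rphc <- dplyr::case_when(
    arm == "short" ~ 100 - fl / short_arm_fraction,
    arm == "long" ~ (fl - cen) / (1 - short_arm_fraction),
    TRUE ~ 0
  )
  tibble(arm = arm, rphc = rphc)
}

check_fraction <- function(f) {
  if (any(f <= 0 | f >= 1)) abort("short_arm_fraction must be in (0, 1)")
  invisible(f)
}
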