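#' Load a packaged reference table
#'
#' The package ships transcriptions of the published onion Tyr-FISH mapping
#' results as plain TSV files: the probe length/identity table
#' (`probe_table`), the chromosome 2 and 6 signal-position tables
#' (`positions_chr2`, `positions_chr6`), the genetic-map and
#' pseudochromosome coordinates of the mapped markers (`marker_orders`), and
#' the reconstructed arm fractions (`karyotype`). Cells not printed in the
#' study (most cM values and Mbp bins) are monotone interpolations that
#' preserve the stated marker orders; each such cell is flagged in a
#' `*_source` column.
#'
#' @param name One of `"probe_table"`, `"positions_chr2"`,
#'   `"positions_chr6"`, `"marker_orders"`, `"karyotype"`.
#' @return A tibble.
#' @export
#' @examples
#' load_paper_fixture("probe_table")
load_paper_fixture <- function(name) {
  known <- c("probe_table", "positions_chr2", "positions_chr6",
             "marker_orders", "karyotype")
  if (!is.character(name) || length(name) != 1 || !name %in% known) {
    abort(paste0("unknown fixture name; expected one of: ",
                 paste(known, collapse = ", ")))
  }
  path <- system.file("extdata", paste0(name, ".tsv"), package = "tyrfish",
                      mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
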