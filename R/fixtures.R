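#' Load a transcribed per-feature stability table
#'
#' The package ships two stability tables transcribed from the phantom
#' study that motivated this pipeline, at the precision each was printed:
#'
#' * `"table1"` — the 84 robust and reproducible features of the T2 map
#'   sequence, with CCC, DR, intra- and inter-observer ICC per feature
#'   (8 decimals).
#' * `"table2"` — the 8 features that are robust and reproducible across
#'   all five sequences, with the same four statistics for every
#'   (feature, sequence) combination (2 decimals; 40 rows).
#'
#' Neither table prints the bias-corrected CCC, so `ccc_corr` is carried
#' as `NA`.
#'
#' @param table_id `"table1"` or `"table2"`.
#' @return A tibble with columns `feature_name`, `sequence`, `ccc`, `dr`,
#'   `ccc_corr`, `icc_intra`, `icc_inter`.
#' @examples
#' t1 <- load_printed_fixture("table1")
#' nrow(t1)  # 84
#' @export
load_printed_fixture <- function(table_id = c("table1", "table2")) {
  table_id <- match.arg(table_id)
  file <- switch(table_id,
    table1 = "table1_t2map.csv",
    table2 = "table2_cross_sequence.csv"
  )
  path <- system.file("extdata", file, package = "radstab", mustWork = TRUE)
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      feature_name = readr::col_character(),
      sequence = readr::col_character(),
      .default = readr::col_double()
    )
  )
  x$ccc_corr <- NA_real_
  x[, c("feature_name", "sequence", "ccc", "dr", "ccc_corr",
        "icc_intra", "icc_inter")]
}
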