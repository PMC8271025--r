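# Observer reproducibility via intraclass correlation from a two-way
# (subject x rater) ANOVA. The intra-observer pair is reader 1's two
# sessions (R1S1, R1S2); the inter-observer pair is reader 1 vs reader 2
# (R1S1, R2). Subjects are the object x scan combinations, so both scans'
# segmentations enter each ICC.

#' Intraclass correlation coefficient of a complete ratings block
#'
#' Computes the single-measurement ICC from the two-way ANOVA mean squares
#' of a complete subjects-by-raters grid (Shrout-Fleiss forms). The
#' absolute-agreement form (ICC(2,1)) penalizes systematic rater shifts:
#' \deqn{\frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' The consistency form (ICC(3,1)) ignores them:
#' \deqn{\frac{MS_R - MS_E}{MS_R + (k-1) MS_E}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, rater and
#' residual mean squares, n subjects, k raters.
#'
#' @param values Numeric matrix, one row per subject, one column per
#'   rater; complete (no `NA`), at least 3 subjects and 2 raters.
#' @param variant `"absolute_agreement_single"` (default) or
#'   `"consistency_single"`.
#' @return A single number <= 1, or `NA` when the block is degenerate
#'   (all values identical, so between-subject mean square is 0).
#' @examples
#' icc(cbind(c(1, 3, 5), c(2, 4, 6)))                        # 8/9
#' icc(cbind(c(1, 3, 5), c(2, 4, 6)), "consistency_single")  # 1
#' @export
icc <- function(values,
                variant = c("absolute_agreement_single",
                            "consistency_single")) {
  variant <- match.arg(variant)
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  stopifnot(n >= 3L, k >= 2L)
  if (anyNA(values)) return(NA_real_)
  g <- mean(values)
  row_m <- rowMeans(values)
  col_m <- colMeans(values)
  ssr <- k * sum((row_m - g)^2)
  ssc <- n * sum((col_m - g)^2)
  sst <- sum((values - g)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- switch(variant,
    absolute_agreement_single =
      msr + (k - 1) * mse + k * (msc - mse) / n,
    consistency_single = msr + (k - 1) * mse
  )
  if (denom <= 0) return(NA_real_)
  (msr - mse) / denom
}

#' Intra- and inter-observer ICC per feature and sequence
#'
#' For every (feature, sequence), assembles the subjects-by-raters grids
#' of the two session pairs and computes the ICC of each:
#' intra-observer from sessions (R1S1, R1S2), inter-observer from
#' (R1S1, R2). Subjects are by default the object x scan combinations
#' (both scans' segmentations were repeated); `subjects = "object"`
#' averages the two scans per object first.
#'
#' @param x A long feature table.
#' @param variant ICC form, see [icc()].
#' @param subjects `"object_scan"` (default) or `"object"`.
#' @return A tibble with one row per (feature, sequence): `feature_name`,
#'   `sequence`, `icc_intra`, `icc_inter`. Rows with missing sessions or
#'   degenerate blocks carry `NA`.
#' @export
icc_tables <- function(x,
                       variant = c("absolute_agreement_single",
                                   "consistency_single"),
                       subjects = c("object_scan", "object")) {
  variant <- match.arg(variant)
  subjects <- match.arg(subjects)
  x <- validate_feature_table(x)

  wide <- x |>
    dplyr::select(dplyr::all_of(c("object_id", "sequence", "scan",
                                  "session", "feature_name", "value"))) |>
    tidyr::pivot_wider(names_from = "session", values_from = "value")
  for (s in setdiff(session_labels, names(wide))) wide[[s]] <- NA_real_
  if (subjects == "object") {
    wide <- wide |>
      dplyr::group_by(.data$object_id, .data$sequence,
                      .data$feature_name) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(session_labels), mean),
                       .groups = "drop")
  }
  wide |>
    dplyr::arrange(.data$sequence, .data$feature_name, .data$object_id) |>
    dplyr::group_by(.data$feature_name, .data$sequence) |>
    dplyr::summarise(
      icc_intra = .block_icc(.data$R1S1, .data$R1S2, variant),
      icc_inter = .block_icc(.data$R1S1, .data$R2, variant),
      .groups = "drop"
    )
}

.block_icc <- function(a, b, variant) {
  if (length(a) < 3L || anyNA(a) || anyNA(b)) return(NA_real_)
  icc(cbind(a, b), variant)
}

#' Full stability table: robustness plus reproducibility
#'
#' Joins the scan-rescan robustness statistics (CCC, DR; see
#' [robustness_table()]) with the observer ICCs (see [icc_tables()]) and
#' adds the bias-corrected CCC, `ccc_corr = ccc + (1 - icc_intra)`.
#'
#' @inheritParams robustness_table
#' @inheritParams icc_tables
#' @return A tibble with one row per (feature, sequence) and columns
#'   `feature_name`, `sequence`, `n_pairs`, `ccc`, `dr`, `ccc_corr`,
#'   `icc_intra`, `icc_inter`.
#' @export
stability_table <- function(x, session = "R1S1",
                            variant = c("absolute_agreement_single",
                                        "consistency_single"),
                            moments = c("population", "sample")) {
  variant <- match.arg(variant)
  moments <- match.arg(moments)
  robustness_table(x, session = session, moments = moments) |>
    dplyr::left_join(icc_tables(x, variant = variant),
                     by = c("feature_name", "sequence")) |>
    dplyr::mutate(ccc_corr = corrected_ccc(.data$ccc, .data$icc_intra)) |>
    dplyr::relocate("ccc_corr", .after = "dr")
}

#' Categorize an ICC value
#'
#' Reliability bands: excellent >= 0.75; good 0.60-0.74; moderate
#' 0.40-0.59; poor <= 0.39. The bands are two-decimal bands, so the value
#' is rounded half-up to 2 decimals before banding (0.745 -> 0.75 ->
#' excellent); otherwise values in (0.745, 0.75) would fall between bands.
#'
#' @param value Numeric vector of finite ICC values.
#' @return A factor with levels `poor < moderate < good < excellent`.
#' @examples
#' categorize_icc(c(0.75, 0.60, -0.2))
#' @export
categorize_icc <- function(value) {
  stopifnot(is.numeric(value))
  r <- floor(value * 100 + 0.5 + 1e-9) / 100  # half-up to 2 decimals
  cut(r, breaks = c(-Inf, 0.395, 0.595, 0.745, Inf),
      labels = c("poor", "moderate", "good", "excellent"),
      ordered_result = TRUE)
}

#' Select robust and reproducible features
#'
#' Applies the joint criterion `ccc >= ccc_cut & dr >= dr_cut &
#' icc_intra >= icc_cut & icc_inter >= icc_cut` (all inclusive) per
#' sequence, and intersects the per-sequence sets across all sequences
#' present. Rows with any undefined statistic are excluded from selection
#' and tallied.
#'
#' @param stability A stability table carrying `feature_name`, `sequence`,
#'   `ccc`, `dr`, `icc_intra`, `icc_inter` (e.g. [stability_table()] or
#'   [load_printed_fixture()]).
#' @param ccc_cut,dr_cut CCC and DR cutoffs, default 0.90.
#' @param icc_cut Cutoff applied to both intra- and inter-observer ICC,
#'   default 0.75.
#' @param gate_on `"ccc"` (default) gates on the raw CCC; `"ccc_corr"`
#'   gates on the bias-corrected CCC instead.
#' @return A list with `per_sequence` (named list of feature-name
#'   vectors), `intersection` (features selected in every sequence), and
#'   `n_undefined` (rows dropped for undefined statistics).
#' @examples
#' sel <- select_rrf(load_printed_fixture("table2"))
#' length(sel$intersection)  # 8
#' @export
select_rrf <- function(stability, ccc_cut = 0.90, dr_cut = 0.90,
                       icc_cut = 0.75, gate_on = c("ccc", "ccc_corr")) {
  gate_on <- match.arg(gate_on)
  ccc_col <- stability[[gate_on]]
  ok <- !(is.na(ccc_col) | is.na(stability$dr) |
            is.na(stability$icc_intra) | is.na(stability$icc_inter))
  pass <- ok & ccc_col >= ccc_cut & stability$dr >= dr_cut &
    stability$icc_intra >= icc_cut & stability$icc_inter >= icc_cut
  seqs <- unique(stability$sequence)
  per_sequence <- lapply(stats::setNames(seqs, seqs), function(s) {
    sort(stability$feature_name[pass & stability$sequence == s])
  })
  list(
    per_sequence = per_sequence,
    intersection = if (length(per_sequence) == 0L) character(0) else
      sort(Reduce(intersect, per_sequence)),
    n_undefined = sum(!ok)
  )
}
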