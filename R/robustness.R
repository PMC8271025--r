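# Scan-rescan robustness: Lin's concordance correlation coefficient (CCC)
# and the dynamic range (DR), computed per feature and sequence on paired
# samples x (scan 1) and y (scan 2) over the phantom objects.

#' Lin's concordance correlation coefficient
#'
#' Agreement between two paired samples, combining correlation with
#' location and scale shift:
#' \deqn{CCC = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' CCC ranges over \[-1, 1\]; 1 means perfect agreement (`x == y` with
#' nonzero variance) and -1 perfect anticorrelation (`x == -y`).
#'
#' @param x,y Numeric vectors of equal length (n >= 2), paired by object.
#' @param moments `"population"` (1/n, Lin's original definition; default)
#'   or `"sample"` (1/(n-1)) moment convention. The two agree except in
#'   the mean-difference term's relative weight.
#' @return A single number in \[-1, 1\], or `NA` when the denominator is
#'   zero (both samples constant with equal means).
#' @examples
#' concordance_cc(1:4, 2:5)  # 2.5/3.5
#' @export
concordance_cc <- function(x, y, moments = c("population", "sample")) {
  moments <- match.arg(moments)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 2L || anyNA(x) || anyNA(y)) return(NA_real_)
  mx <- mean(x); my <- mean(y)
  denom_n <- if (moments == "population") n else n - 1L
  sxy <- sum((x - mx) * (y - my)) / denom_n
  sx2 <- sum((x - mx)^2) / denom_n
  sy2 <- sum((y - my)^2) / denom_n
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom <= 0) return(NA_real_)
  2 * sxy / denom
}

#' Dynamic range of a paired sample
#'
#' One minus the mean absolute test-retest difference normalized by the
#' pooled value range:
#' \deqn{DR = 1 - \frac{\mathrm{mean}_i |x_i - y_i|}
#'                     {\max(x \cup y) - \min(x \cup y)}}
#' DR = 1 means optimal reproducibility (`x == y` with a nonzero data
#' range); DR = 0 is the lowest possible variability, two constant but
#' different samples.
#'
#' @inheritParams concordance_cc
#' @return A single number in \[0, 1\], or `NA` when the pooled range is
#'   zero (all values identical).
#' @examples
#' dynamic_range(c(0, 10), c(0, 8))  # 0.9
#' @export
dynamic_range <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 1L || anyNA(x) || anyNA(y)) return(NA_real_)
  pooled <- range(c(x, y))
  rng <- pooled[2] - pooled[1]
  if (rng <= 0) return(NA_real_)
  1 - mean(abs(x - y)) / rng
}

#' Bias-corrected CCC
#'
#' Corrects scan-rescan CCC for subtle intra-reader variance:
#' `CCC_corr = CCC + (1 - intra-observer ICC)`. The result is the exact
#' arithmetic of the formula and is deliberately not clipped to \[-1, 1\].
#'
#' @param ccc CCC value(s).
#' @param icc_intra Intra-observer ICC value(s).
#' @return `ccc + (1 - icc_intra)`.
#' @examples
#' corrected_ccc(0.88, 0.95)  # 0.93
#' @export
corrected_ccc <- function(ccc, icc_intra) {
  ccc + (1 - icc_intra)
}

#' Scan-rescan robustness per feature and sequence
#'
#' Builds, for every (feature, sequence), the paired sample of scan-1
#' versus scan-2 values across objects (one segmentation session, default
#' the reader-1 first session) and computes CCC and DR. Rows whose paired
#' statistics are undefined (degenerate denominators, or objects missing
#' a scan) carry `NA` and are tallied downstream rather than treated as
#' failures.
#'
#' @param x A long feature table (see [read_feature_table()]).
#' @param session Segmentation session entering the robustness arm,
#'   default `"R1S1"`.
#' @param moments Moment convention passed to [concordance_cc()].
#' @return A tibble with one row per (feature, sequence): `feature_name`,
#'   `sequence`, `n_pairs`, `ccc`, `dr`.
#' @export
robustness_table <- function(x, session = "R1S1",
                             moments = c("population", "sample")) {
  moments <- match.arg(moments)
  x <- validate_feature_table(x)
  if (!session %in% x$session) {
    stop("session '", session, "' not present in the feature table",
         call. = FALSE)
  }
  x |>
    dplyr::filter(.data$session == !!session) |>
    dplyr::select(dplyr::all_of(c("object_id", "sequence", "scan",
                                  "feature_name", "value"))) |>
    tidyr::pivot_wider(names_from = "scan", values_from = "value",
                       names_prefix = "scan") |>
    dplyr::arrange(.data$sequence, .data$feature_name, .data$object_id) |>
    dplyr::group_by(.data$feature_name, .data$sequence) |>
    dplyr::summarise(
      n_pairs = sum(!is.na(.data$scan1) & !is.na(.data$scan2)),
      ccc = if (any(is.na(.data$scan1)) || any(is.na(.data$scan2)))
        NA_real_ else concordance_cc(.data$scan1, .data$scan2, moments),
      dr = if (any(is.na(.data$scan1)) || any(is.na(.data$scan2)))
        NA_real_ else dynamic_range(.data$scan1, .data$scan2),
      .groups = "drop"
    )
}

#' Stratify robustness at nested cutoffs
#'
#' Flags each (feature, sequence) as robust at every cutoff c when
#' `ccc >= c & dr >= c` (inclusive), and summarizes the fraction of robust
#' features per sequence, per feature class within sequence, and per class
#' combined over sequences. Rows with undefined CCC or DR are excluded
#' from fractions and counted in `n_undefined`.
#'
#' @param stability A table carrying `feature_name`, `sequence`, `ccc`,
#'   `dr` (e.g. from [robustness_table()]).
#' @param cutoffs Robustness levels, default `c(0.85, 0.90, 0.95)`
#'   (relaxed / excellent / strict).
#' @param catalog Feature catalog used to attach class labels.
#' @param combined `"mean_of_fractions"` (default) averages the
#'   per-sequence fractions of a class; `"pooled"` pools (feature,
#'   sequence) rows of a class before taking the fraction.
#' @return A list with `flags` (per feature/sequence logicals `pass_<cut>`),
#'   `by_sequence`, `by_class_sequence`, and `by_class_combined` fraction
#'   tables (columns `cutoff`, `n_robust`, `n_defined`, `n_undefined`,
#'   `fraction`).
#' @export
stratify_robustness <- function(stability,
                                cutoffs = c(0.85, 0.90, 0.95),
                                catalog = build_feature_catalog(),
                                combined = c("mean_of_fractions",
                                             "pooled")) {
  combined <- match.arg(combined)
  stopifnot(all(is.finite(cutoffs)))
  cutoffs <- sort(cutoffs)
  flags <- stability |>
    dplyr::select(dplyr::all_of(c("feature_name", "sequence", "ccc",
                                  "dr"))) |>
    dplyr::left_join(catalog[, c("feature_name", "feature_class")],
                     by = "feature_name")
  for (cut in cutoffs) {
    flags[[.cut_col(cut)]] <- flags$ccc >= cut & flags$dr >= cut
  }
  flags$undefined <- is.na(flags$ccc) | is.na(flags$dr)

  long <- flags |>
    tidyr::pivot_longer(dplyr::all_of(.cut_col(cutoffs)),
                        names_to = "cutoff_label", values_to = "pass") |>
    dplyr::mutate(cutoff = as.numeric(sub("pass_", "",
                                          .data$cutoff_label)) / 100)

  summarise_frac <- function(d, ...) {
    d |>
      dplyr::group_by(..., .data$cutoff) |>
      dplyr::summarise(
        n_robust = sum(.data$pass & !.data$undefined, na.rm = TRUE),
        n_defined = sum(!.data$undefined),
        n_undefined = sum(.data$undefined),
        fraction = .data$n_robust / .data$n_defined,
        .groups = "drop"
      )
  }

  by_sequence <- summarise_frac(long, .data$sequence)
  by_class_sequence <- summarise_frac(long, .data$sequence,
                                      .data$feature_class)
  by_class_combined <- if (combined == "mean_of_fractions") {
    by_class_sequence |>
      dplyr::group_by(.data$feature_class, .data$cutoff) |>
      dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop")
  } else {
    summarise_frac(long, .data$feature_class)
  }

  list(flags = flags, by_sequence = by_sequence,
       by_class_sequence = by_class_sequence,
       by_class_combined = by_class_combined)
}

.cut_col <- function(cut) sprintf("pass_%02d", round(100 * cut))
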