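#' Bland-Altman limits of agreement
#'
#' Differences follow the `x - y` convention (scan 1 minus scan 2, or
#' reader 1 minus reader 2). The limits of agreement are
#' `mean_diff +/- 1.96 * sd_diff` with the n-1 standard deviation.
#'
#' @param x,y Paired numeric vectors, n >= 2.
#' @return A tibble with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `n`.
#' @examples
#' bland_altman(c(0, 2), c(1, 1))
#' @export
bland_altman <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 2L)
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(
    mean_diff = m, sd_diff = s,
    loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
    n = length(d)
  )
}

#' Distribution summary for box-whisker reporting
#'
#' Median, quartiles and the 5th/95th percentiles (linear interpolation
#' between closest ranks, `stats::quantile` type 7), plus the individual
#' values falling outside the 5-95 percentile band (the dots of a
#' box-whisker plot).
#'
#' @param values Nonempty numeric vector.
#' @return A list with `n`, `median`, `q1`, `q3`, `p5`, `p95`, and
#'   `outliers` (values strictly outside `[p5, p95]`).
#' @export
distribution_summary <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L, !anyNA(values))
  q <- stats::quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95),
                       names = FALSE, type = 7)
  list(
    n = length(values),
    median = q[3], q1 = q[2], q3 = q[4], p5 = q[1], p95 = q[5],
    outliers = values[values < q[1] | values > q[5]]
  )
}

#' Significance stars for p-values
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of markers.
#' @export
significance_marker <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}
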