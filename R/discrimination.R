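# Pairwise discriminative power: for every unordered object pair, feature
# and sequence, the six replicate values of each object (3 segmentation
# sessions x 2 scans) are compared with an exact Mann-Whitney U, rescaled
# to AUC = U / (n1 n2) and to the Gini score 2 AUC - 1. A "perfect" score
# is complete separation of the two replicate sets, in either direction;
# its exact null probability under random ranking is n1! n2! / (n1+n2)!.

#' Mann-Whitney U and AUC for two groups
#'
#' U is oriented as the number of pairs `(a_i, b_j)` with `b_j > a_i`,
#' ties counted 1/2 (midranks); `auc = u / (n1 * n2)` is the probability
#' that a random value of `b` exceeds a random value of `a`.
#'
#' @param a,b Nonempty numeric vectors (the two groups' replicate values).
#' @return A list with `u`, `auc`, `n1 = length(a)`, `n2 = length(b)`.
#' @examples
#' mann_whitney_auc(1:3, 4:6)  # u = 9, auc = 1
#' @export
mann_whitney_auc <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b),
            length(a) >= 1L, length(b) >= 1L)
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))  # midranks
  rb <- sum(r[(n1 + 1L):(n1 + n2)])
  u <- rb - n2 * (n2 + 1) / 2
  list(u = u, auc = u / (n1 * n2), n1 = n1, n2 = n2)
}

#' Gini score from an AUC
#'
#' `gini = 2 * auc - 1`. A Gini score of 1 means a correct decision can be
#' based on a single value of the feature; 0 means any prediction would be
#' random.
#'
#' @param auc AUC value(s) in \[0, 1\].
#' @return `2 * auc - 1`, in \[-1, 1\].
#' @export
gini_score <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1, na.rm = TRUE))
  2 * auc - 1
}

#' Exact Mann-Whitney Gini grid over all object pairs
#'
#' For every unordered pair of objects, feature and sequence, compares the
#' two objects' replicate values (all scans x sessions, 6 each in the
#' complete design) with [mann_whitney_auc()]. With 16 objects, 106
#' features and 5 sequences the grid has 120 x 106 x 5 = 63,600 entries.
#'
#' A pair is `perfect` when separation is complete in either direction
#' (`auc` is exactly 0 or 1); a tie straddling the two groups vetoes
#' perfection. Entries with incomplete replicate sets (`NA` values or
#' unbalanced replicate counts between the design and the data) are
#' flagged `incomplete` and carry `NA` statistics.
#'
#' @param x A long feature table covering all sessions and scans.
#' @return A tibble with columns `object_a`, `object_b` (ordered so
#'   `object_a < object_b`), `feature_name`, `sequence`, `n1`, `n2`, `u`,
#'   `auc`, `gini`, `perfect`, `incomplete`.
#' @export
pairwise_gini_grid <- function(x) {
  x <- validate_feature_table(x)
  groups <- x |>
    dplyr::group_by(.data$sequence, .data$feature_name)
  keys <- dplyr::group_keys(groups)
  idx <- dplyr::group_rows(groups)
  n_expected <- length(unique(paste(x$scan, x$session)))

  res <- vector("list", nrow(keys))
  for (g in seq_along(idx)) {
    sub <- x[idx[[g]], c("object_id", "value")]
    objs <- sort(unique(sub$object_id))
    vals <- split(sub$value, factor(sub$object_id, levels = objs))
    no <- length(objs)
    if (no < 2L) next
    pairs <- utils::combn(no, 2L)
    np <- ncol(pairs)
    u <- auc <- rep(NA_real_, np)
    n1 <- n2 <- integer(np)
    incomplete <- logical(np)
    for (p in seq_len(np)) {
      va <- vals[[pairs[1L, p]]]
      vb <- vals[[pairs[2L, p]]]
      n1[p] <- length(va); n2[p] <- length(vb)
      if (anyNA(va) || anyNA(vb) ||
          length(va) != n_expected || length(vb) != n_expected) {
        incomplete[p] <- TRUE
        next
      }
      mw <- mann_whitney_auc(va, vb)
      u[p] <- mw$u
      auc[p] <- mw$auc
    }
    res[[g]] <- tibble::tibble(
      object_a = objs[pairs[1L, ]],
      object_b = objs[pairs[2L, ]],
      feature_name = keys$feature_name[g],
      sequence = keys$sequence[g],
      n1 = n1, n2 = n2, u = u, auc = auc,
      gini = 2 * auc - 1,
      perfect = !is.na(auc) & (auc == 0 | auc == 1),
      incomplete = incomplete
    )
  }
  dplyr::bind_rows(res)
}

#' Success counts of feature groups over object pairs
#'
#' A group of features is successful for an object pair if at least one
#' feature in the group attains a perfect Gini score for that pair.
#' Counts successes per sequence, per feature class within sequence, or
#' per individual feature; the per-feature counting yields the
#' discriminative ranking (competition ranking: ties share a rank, the
#' next rank is skipped; ties are ordered alphabetically for
#' determinism).
#'
#' @param grid A Gini grid from [pairwise_gini_grid()].
#' @param group_by `"sequence"`, `"class_sequence"` or `"feature"`.
#' @param catalog Feature catalog supplying class labels.
#' @return A tibble with the grouping columns, `n_successes`,
#'   `n_pairs`, `success_rate`, and (for `"feature"`) `rank`.
#' @export
success_counts <- function(grid,
                           group_by = c("sequence", "class_sequence",
                                        "feature"),
                           catalog = build_feature_catalog()) {
  group_by <- match.arg(group_by)
  grid <- grid |>
    dplyr::filter(!.data$incomplete) |>
    dplyr::left_join(catalog[, c("feature_name", "feature_class")],
                     by = "feature_name")
  n_pairs_total <- dplyr::n_distinct(paste(grid$object_a, grid$object_b))
  grp <- switch(group_by,
    sequence = "sequence",
    class_sequence = c("sequence", "feature_class"),
    feature = c("sequence", "feature_name", "feature_class")
  )
  out <- grid |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp)),
                    .data$object_a, .data$object_b) |>
    dplyr::summarise(success = any(.data$perfect), .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_successes = sum(.data$success),
      n_pairs = dplyr::n(),
      success_rate = .data$n_successes / .data$n_pairs,
      .groups = "drop"
    )
  if (group_by == "feature") {
    out <- out |>
      dplyr::arrange(dplyr::desc(.data$n_successes), .data$feature_name,
                     .data$sequence) |>
      dplyr::mutate(rank = dplyr::min_rank(
        dplyr::desc(.data$n_successes)))
  }
  out
}

#' Exact null probability of perfect separation
#'
#' Under the null of exchangeable (randomly ranked, tie-free) values, the
#' probability that all `n2` values of one group exceed all `n1` of the
#' other in a fixed orientation is
#' \deqn{p = \frac{n_1!\, n_2!}{(n_1 + n_2)!} = 1 / \binom{n_1+n_2}{n_1}}
#' For the 6-vs-6 replicate design, p = 1/924.
#'
#' @param n1,n2 Group sizes (>= 1).
#' @param two_sided If `TRUE`, doubles the probability to cover complete
#'   separation in either direction. The default (`FALSE`) is the single
#'   fixed orientation.
#' @return The exact probability (computed in log space).
#' @examples
#' perfect_separation_pvalue(6, 6)  # 1/924
#' @export
perfect_separation_pvalue <- function(n1, n2, two_sided = FALSE) {
  stopifnot(n1 >= 1L, n2 >= 1L)
  p <- exp(lfactorial(n1) + lfactorial(n2) - lfactorial(n1 + n2))
  if (two_sided) p <- 2 * p
  p
}

#' False-discovery probability of a single success within a feature group
#'
#' Probability that at least one of `m` independent features attains a
#' perfect score by chance: `1 - (1 - p)^m`. With p = 1/924 and m = 106
#' features this is about 10.8%.
#'
#' @param p Per-feature perfect-separation probability.
#' @param m Number of features in the group (>= 1).
#' @return `1 - (1 - p)^m`.
#' @export
group_fdr <- function(p, m) {
  stopifnot(p >= 0, p <= 1, m >= 1)
  -expm1(m * log1p(-p))
}

#' Independence bound on all pairs succeeding by chance
#'
#' Upper bound, under independence across object pairs, on the
#' probability that every one of `n_pairs` pairs yields at least one
#' chance success: `fdr ^ n_pairs`. With fdr = 10.8% and 120 pairs the
#' bound is below 1e-58.
#'
#' @param fdr Per-pair success probability (e.g. from [group_fdr()]).
#' @param n_pairs Number of object pairs.
#' @return `fdr ^ n_pairs`.
#' @export
all_pairs_bound <- function(fdr, n_pairs) {
  stopifnot(fdr >= 0, fdr <= 1, n_pairs >= 1)
  exp(n_pairs * log(fdr))
}
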