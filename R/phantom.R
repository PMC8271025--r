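# Synthetic scan-rescan phantom: a Gaussian variance-components emulation
# of the multi-object (fruit) phantom study design. Each feature value is
#   value = base_level + T(type) + B(object) + O(session) + E(scan)
# with independent zero-mean Gaussian draws: T between-type spread,
# B between-object-within-type spread, E rescan noise redrawn per scan
# (shared by the sessions segmenting that scan), and O per-segmentation
# observer noise (none for the reference session R1S1, a small
# within-reader component for R1S2, and a systematic shift plus full
# observer noise for the second reader R2). The closed forms of the
# scan-rescan CCC and the observer ICCs under this model are exposed as
# oracles for parameter-recovery testing.

#' Configuration of the synthetic phantom generator
#'
#' Defaults emulate the study design: 4 object types x 4 replicates
#' (16 objects), the five MRI sequences, 2 scans and 3 segmentation
#' sessions. Variance components are free parameters of the emulation
#' (the phantom study reports no noise magnitudes); the defaults give
#' high but imperfect robustness and reproducibility, with shape-class
#' features more robust than texture classes via `shape_scan_factor`.
#'
#' @param n_types Number of object types (default 4).
#' @param n_objects_per_type Replicates per type (default 4).
#' @param sequences Sequence labels (default the five MRI sequences).
#' @param sigma_type Between-type spread (default 3).
#' @param sigma_obj Between-object-within-type spread (default 1).
#' @param sigma_scan Rescan noise, redrawn per scan (default 1).
#' @param sigma_obs Between-observer noise for the second reader
#'   (default 0.5).
#' @param obs_shift Systematic offset of the second reader (default 0.5).
#' @param eps_intra Within-reader noise for the repeat session R1S2, as a
#'   fraction of `sigma_obs` (default 0.1).
#' @param shape_scan_factor Multiplier on `sigma_scan` for shape-class
#'   features (default 0.2), making shape the most robust class.
#' @param base_level Baseline feature level (default 10).
#' @param seed Integer root seed; per-feature substreams are derived
#'   deterministically from `(seed, feature index)`, so subsetting the
#'   catalog does not change other features' values.
#' @return A validated list of class `"phantom_config"`.
#' @export
phantom_config <- function(n_types = 4L, n_objects_per_type = 4L,
                           sequences = mri_sequences,
                           sigma_type = 3, sigma_obj = 1,
                           sigma_scan = 1, sigma_obs = 0.5,
                           obs_shift = 0.5, eps_intra = 0.1,
                           shape_scan_factor = 0.2,
                           base_level = 10, seed = 20210709L) {
  cfg <- list(
    n_types = as.integer(n_types),
    n_objects_per_type = as.integer(n_objects_per_type),
    sequences = as.character(sequences),
    sigma_type = sigma_type, sigma_obj = sigma_obj,
    sigma_scan = sigma_scan, sigma_obs = sigma_obs,
    obs_shift = obs_shift, eps_intra = eps_intra,
    shape_scan_factor = shape_scan_factor,
    base_level = base_level, seed = as.integer(seed)
  )
  sigmas <- c("sigma_type", "sigma_obj", "sigma_scan", "sigma_obs",
              "eps_intra", "shape_scan_factor")
  for (s in sigmas) {
    if (!is.finite(cfg[[s]]) || cfg[[s]] < 0) {
      stop("phantom config '", s, "' must be finite and >= 0",
           call. = FALSE)
    }
  }
  if (length(cfg$sequences) == 0L) {
    stop("phantom config needs at least one sequence", call. = FALSE)
  }
  if (cfg$n_types < 1L || cfg$n_objects_per_type < 1L) {
    stop("phantom config needs at least one type and one object per type",
         call. = FALSE)
  }
  structure(cfg, class = "phantom_config")
}

#' Generate a synthetic scan-rescan feature table
#'
#' Produces the complete design — every object x sequence x non-excluded
#' feature x 2 scans x 3 sessions — under the Gaussian variance-components
#' model described in [phantom_config()]. With the default design (16
#' objects, 5 sequences, 106 features) the table has 50,880 records.
#' Identical configuration and seed yield identical output.
#'
#' @param config A [phantom_config()].
#' @param catalog Feature catalog; excluded features are omitted.
#' @return A long feature table (tibble) as accepted by the analysis
#'   functions.
#' @export
generate_phantom_dataset <- function(config = phantom_config(),
                                     catalog = build_feature_catalog()) {
  stopifnot(inherits(config, "phantom_config"))
  keep <- which(!catalog$excluded)
  feats <- catalog$feature_name[keep]
  feat_class <- as.character(catalog$feature_class)[keep]
  # substream index from the feature's identity in the full catalog, so
  # subsetting a catalog never changes other features' values
  feat_idx <- match(feats, build_feature_catalog()$feature_name)
  feat_idx[is.na(feat_idx)] <- 200L + which(is.na(feat_idx))

  if (config$n_types == 4L) {
    types <- object_types
  } else {
    types <- paste0("type", seq_len(config$n_types))
  }
  obj_type <- rep(types, each = config$n_objects_per_type)
  object_id <- paste0(obj_type,
                      rep(seq_len(config$n_objects_per_type),
                          times = config$n_types))
  n_obj <- length(object_id)
  n_seq <- length(config$sequences)

  # fixed record order per feature: sequence > object > scan > session
  design <- tidyr::expand_grid(
    sequence = config$sequences,
    object_id = object_id,
    scan = 1:2,
    session = session_labels
  )
  design$object_type <- obj_type[match(design$object_id, object_id)]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })

  type_of_obj <- match(obj_type, types)
  values <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    # substream derived from (root seed, catalog index); < 2^31
    set.seed((config$seed + 7919L * feat_idx[i]) %% 2147483647L)
    s_scan <- config$sigma_scan *
      if (feat_class[i] == "shape") config$shape_scan_factor else 1
    v_seq <- vector("list", n_seq)
    for (s in seq_len(n_seq)) {
      t_eff <- stats::rnorm(config$n_types, 0, config$sigma_type)
      b_eff <- stats::rnorm(n_obj, 0, config$sigma_obj)
      e_scan <- matrix(stats::rnorm(n_obj * 2L, 0, s_scan), n_obj, 2L)
      o_r1s2 <- matrix(stats::rnorm(n_obj * 2L, 0,
                                    config$sigma_obs * config$eps_intra),
                       n_obj, 2L)
      o_r2 <- matrix(config$obs_shift +
                       stats::rnorm(n_obj * 2L, 0, config$sigma_obs),
                     n_obj, 2L)
      # order: object > scan > session (R1S1, R1S2, R2)
      base <- config$base_level + t_eff[type_of_obj] + b_eff
      v <- numeric(n_obj * 6L)
      pos <- 1L
      for (o in seq_len(n_obj)) {
        for (sc in 1:2) {
          core <- base[o] + e_scan[o, sc]
          v[pos:(pos + 2L)] <- core + c(0, o_r1s2[o, sc], o_r2[o, sc])
          pos <- pos + 3L
        }
      }
      v_seq[[s]] <- v
    }
    values[[i]] <- unlist(v_seq, use.names = FALSE)
  }

  out <- design[rep(seq_len(nrow(design)), times = length(feats)), ]
  out$feature_name <- rep(feats, each = nrow(design))
  out$value <- unlist(values, use.names = FALSE)
  out <- out[, .feature_table_cols]
  tibble::as_tibble(out)
}

#' Closed-form scan-rescan CCC of the generative model
#'
#' Under the variance-components model, the scan-rescan CCC of a feature
#' converges (in the number of objects) to
#' \deqn{\frac{\sigma_b^2}{\sigma_b^2 + \sigma_{scan}^2}}
#' with \eqn{\sigma_b^2 = \sigma_{type}^2 + \sigma_{obj}^2}: both scans
#' share the object signal and differ only by the rescan noise.
#'
#' @param sigma_between Between-object spread
#'   \eqn{\sqrt{\sigma_{type}^2 + \sigma_{obj}^2}} (>= 0).
#' @param sigma_scan Rescan noise (>= 0). Not both arguments may be zero.
#' @return The limiting CCC, in \[0, 1\].
#' @examples
#' expected_ccc(3, 4)  # 9/25
#' @export
expected_ccc <- function(sigma_between, sigma_scan) {
  stopifnot(sigma_between >= 0, sigma_scan >= 0)
  if (sigma_between == 0 && sigma_scan == 0) {
    stop("expected CCC is undefined when both spreads are zero",
         call. = FALSE)
  }
  sigma_between^2 / (sigma_between^2 + sigma_scan^2)
}

#' Closed-form observer ICC of the generative model
#'
#' For a two-rater block where the reference rating is noise-free and the
#' second rating adds a systematic shift `d` and noise with spread
#' `sigma_noise`, the absolute-agreement single-measures ICC converges to
#' \deqn{\frac{\sigma_b^2}{\sigma_b^2 + \sigma_{noise}^2 / 2 + d^2 / 2}}
#' (the rater shift enters as a rater variance component, the one-sided
#' rating noise splits evenly into the residual). For the generator's
#' inter-observer arm, `sigma_between` pools type, object and scan
#' spreads (subjects are object x scan combinations, so the scan noise is
#' shared within subject); for the intra-observer arm the noise is
#' `sigma_obs * eps_intra` and the shift is 0.
#'
#' @param sigma_between Between-subject spread (>= 0).
#' @param sigma_noise Rating noise of the second rater (>= 0).
#' @param shift Systematic offset of the second rater (default 0).
#' @return The limiting ICC, in \[0, 1\].
#' @export
expected_icc <- function(sigma_between, sigma_noise, shift = 0) {
  stopifnot(sigma_between >= 0, sigma_noise >= 0)
  if (sigma_between == 0 && sigma_noise == 0 && shift == 0) {
    stop("expected ICC is undefined when all components are zero",
         call. = FALSE)
  }
  sigma_between^2 /
    (sigma_between^2 + sigma_noise^2 / 2 + shift^2 / 2)
}
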