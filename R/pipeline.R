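# End-to-end pipeline: simulate (or read) a feature table, compute the
# stability table (CCC/DR/CCC_corr/ICCs), select robust-and-reproducible
# features, screen pairwise discrimination, and emit report tables plus a
# machine-readable summary.

.default_pipeline_config <- function() {
  list(
    input = NULL,             # CSV path; NULL -> simulate
    seed = 20210709L,
    simulation = list(),      # overrides passed to phantom_config()
    robust_session = "R1S1",
    cutoffs = c(0.85, 0.90, 0.95),
    ccc_cut = 0.90, dr_cut = 0.90, icc_cut = 0.75,
    gate_on = "ccc",
    icc_variant = "absolute_agreement_single",
    moments = "population",
    combined = "mean_of_fractions",
    two_sided_null = FALSE
  )
}

#' Read a pipeline configuration file
#'
#' YAML or JSON with any subset of the pipeline settings; unspecified
#' settings take their defaults. See [run_pipeline()] for the fields.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A complete configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- utils::modifyList(.default_pipeline_config(), user)
  cfg
}

#' Run the full stability and discrimination pipeline
#'
#' Composes all analysis stages on a measured or simulated feature table
#' and (optionally) writes the report bundle: `stability.csv` (per
#' feature/sequence CCC, DR, CCC_corr, ICCs), `rrf.json` (selected
#' feature sets per sequence and their cross-sequence intersection),
#' `gini.csv` (the pairwise Gini grid), `ranking.csv` (per-feature
#' success ranking), and `summary.json` (robust fractions per class and
#' sequence at all cutoffs, ICC category tallies, success rates, and the
#' exact null-model numbers).
#'
#' @param config A configuration list (missing entries take defaults), or
#'   a path accepted by [read_pipeline_config()]. Fields: `input` (CSV
#'   path, or `NULL` to simulate), `seed`, `simulation` (overrides for
#'   [phantom_config()]), `robust_session`, `cutoffs`, `ccc_cut`,
#'   `dr_cut`, `icc_cut`, `gate_on`, `icc_variant`, `moments`,
#'   `combined`, `two_sided_null`.
#' @param out_dir Directory for the report bundle; `NULL` writes nothing.
#' @param quiet Suppress the settings log.
#' @return (Invisibly) a list with `data`, `stability`, `stratification`,
#'   `rrf`, `gini_grid`, `successes`, `ranking`, `null_model`, `summary`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(.default_pipeline_config(), config)
  catalog <- build_feature_catalog()
  say <- function(...) if (!quiet) message("[radstab] ", ...)

  say("settings: seed=", cfg$seed,
      " session=", cfg$robust_session,
      " cutoffs=", paste(cfg$cutoffs, collapse = "/"),
      " gates ccc>=", cfg$ccc_cut, " dr>=", cfg$dr_cut,
      " icc>=", cfg$icc_cut, " gate_on=", cfg$gate_on,
      " icc_variant=", cfg$icc_variant,
      " moments=", cfg$moments,
      " null=", if (isTRUE(cfg$two_sided_null)) "two-sided" else
        "one-sided")

  x <- tryCatch({
    if (is.null(cfg$input)) {
      sim <- utils::modifyList(list(seed = cfg$seed), cfg$simulation)
      say("simulating phantom dataset")
      generate_phantom_dataset(do.call(phantom_config, sim), catalog)
    } else {
      say("reading feature table: ", cfg$input)
      read_feature_table(cfg$input, catalog)
    }
  }, error = function(e) stop("[input] ", conditionMessage(e),
                              call. = FALSE))

  stability <- tryCatch(
    stability_table(x, session = cfg$robust_session,
                    variant = cfg$icc_variant, moments = cfg$moments),
    error = function(e) stop("[stability] ", conditionMessage(e),
                             call. = FALSE))
  strat <- tryCatch(
    stratify_robustness(stability, cutoffs = cfg$cutoffs,
                        catalog = catalog, combined = cfg$combined),
    error = function(e) stop("[stratify] ", conditionMessage(e),
                             call. = FALSE))
  rrf <- tryCatch(
    select_rrf(stability, ccc_cut = cfg$ccc_cut, dr_cut = cfg$dr_cut,
               icc_cut = cfg$icc_cut, gate_on = cfg$gate_on),
    error = function(e) stop("[select] ", conditionMessage(e),
                             call. = FALSE))
  grid <- tryCatch(
    pairwise_gini_grid(x),
    error = function(e) stop("[discriminate] ", conditionMessage(e),
                             call. = FALSE))
  succ_seq <- success_counts(grid, "sequence", catalog)
  succ_cls <- success_counts(grid, "class_sequence", catalog)
  ranking <- success_counts(grid, "feature", catalog)

  n_rep <- grid$n1[which(!grid$incomplete)[1]]
  n_features <- sum(!catalog$excluded)
  n_pairs <- max(succ_seq$n_pairs)
  p_perfect <- perfect_separation_pvalue(n_rep, n_rep,
                                         two_sided = cfg$two_sided_null)
  fdr <- group_fdr(p_perfect, n_features)
  null_model <- list(
    n_replicates = n_rep, n_features = n_features, n_pairs = n_pairs,
    p_perfect = p_perfect, fdr_single = fdr,
    p_all_pairs = all_pairs_bound(fdr, n_pairs)
  )

  icc_cat <- stability |>
    tidyr::pivot_longer(dplyr::all_of(c("icc_intra", "icc_inter")),
                        names_to = "arm", values_to = "icc_value") |>
    dplyr::filter(!is.na(.data$icc_value)) |>
    dplyr::count(.data$arm,
                 category = categorize_icc(.data$icc_value))

  summary <- list(
    n_features_catalog = nrow(catalog),
    n_features_analysis = n_features,
    n_gini_scores = sum(!grid$incomplete),
    n_object_pairs = n_pairs,
    n_rrf_per_sequence = lengths(rrf$per_sequence),
    n_rrf_intersection = length(rrf$intersection),
    robust_fractions_by_sequence = strat$by_sequence,
    robust_fractions_by_class_sequence = strat$by_class_sequence,
    robust_fractions_by_class_combined = strat$by_class_combined,
    icc_categories = icc_cat,
    success_rates_by_sequence = succ_seq,
    success_rates_by_class = succ_cls,
    null_model = null_model,
    settings = cfg[c("seed", "robust_session", "cutoffs", "ccc_cut",
                     "dr_cut", "icc_cut", "gate_on", "icc_variant",
                     "moments", "combined", "two_sided_null")]
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(stability, file.path(out_dir, "stability.csv"))
    jsonlite::write_json(rrf, file.path(out_dir, "rrf.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_csv(grid, file.path(out_dir, "gini.csv"))
    readr::write_csv(ranking, file.path(out_dir, "ranking.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    say("report bundle written to ", out_dir)
  }

  invisible(list(data = x, stability = stability, stratification = strat,
                 rrf = rrf, gini_grid = grid,
                 successes = list(by_sequence = succ_seq,
                                  by_class = succ_cls),
                 ranking = ranking, null_model = null_model,
                 summary = summary))
}
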