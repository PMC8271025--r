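# Long-format feature tables: one record per
# (object, sequence, scan, session, feature). The three segmentation
# sessions are reader 1 session 1 (R1S1), reader 1 session 2 one month
# later (R1S2), and reader 2 (R2); the intra-observer pair is
# (R1S1, R1S2) and the inter-observer pair is (R1S1, R2).

#' @name design-constants
#' @title Study design constants
#' @description Default levels of the phantom study design: the five MRI
#'   sequences, the four object (fruit) types, and the three segmentation
#'   session labels.
#' @format Character vectors.
NULL

#' @rdname design-constants
#' @export
mri_sequences <- c("HASTE", "T2w TSE", "FLAIR", "T2 map", "T1w TSE")

#' @rdname design-constants
#' @export
object_types <- c("apple", "lime", "onion", "kiwi")

#' @rdname design-constants
#' @export
session_labels <- c("R1S1", "R1S2", "R2")

.feature_table_cols <- c("object_id", "object_type", "sequence", "scan",
                         "session", "feature_name", "value")

.key_cols <- c("object_id", "sequence", "scan", "session", "feature_name")

#' Validate a long-format feature table
#'
#' Checks the structural contract of a feature table: required columns,
#' unique `(object_id, sequence, scan, session, feature_name)` keys,
#' known session labels and scans, and (when a catalog is supplied) that
#' every feature name is part of the catalog.
#'
#' @param x A data frame of feature records.
#' @param catalog Optional feature catalog from [build_feature_catalog()].
#' @return `x` invisibly, as a tibble, if valid; otherwise an error.
#' @export
validate_feature_table <- function(x, catalog = NULL) {
  missing_cols <- setdiff(.feature_table_cols, names(x))
  if (length(missing_cols) > 0L) {
    stop("feature table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!all(x$scan %in% c(1L, 2L))) {
    stop("feature table 'scan' must be 1 or 2", call. = FALSE)
  }
  if (!all(x$session %in% session_labels)) {
    stop("feature table 'session' must be one of ",
         paste(session_labels, collapse = ", "), call. = FALSE)
  }
  key <- do.call(paste, c(x[.key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- x[duplicated(key), .key_cols][1, ]
    stop("duplicate feature-table key, e.g. (",
         paste(unlist(dup), collapse = ", "), ")", call. = FALSE)
  }
  if (!is.null(catalog)) {
    unknown <- setdiff(unique(x$feature_name), catalog$feature_name)
    if (length(unknown) > 0L) {
      stop("feature table contains features absent from the catalog: ",
           paste(utils::head(unknown, 5L), collapse = ", "),
           if (length(unknown) > 5L) ", ...", call. = FALSE)
    }
  }
  invisible(x)
}

#' Read a feature table from CSV
#'
#' @param path Path to a comma-separated file with header columns
#'   `object_id, object_type, sequence, scan, session, feature_name, value`.
#' @param catalog Optional catalog to validate feature names against.
#' @return A validated tibble of feature records.
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(path, catalog = NULL) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      object_id = readr::col_character(),
      object_type = readr::col_character(),
      sequence = readr::col_character(),
      scan = readr::col_integer(),
      session = readr::col_character(),
      feature_name = readr::col_character(),
      value = readr::col_double()
    )
  )
  validate_feature_table(x, catalog)
  x
}

#' Write a feature table to CSV
#'
#' Values are serialized with 12 significant digits, so write-then-read
#' round-trips records up to that precision.
#'
#' @param x A feature table (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  x <- validate_feature_table(x)
  x$value <- formatC(x$value, digits = 12L, format = "g")
  readr::write_csv(x, path)
  invisible(path)
}

# Reshape the 6 replicate values (2 scans x 3 sessions) of each
# object/feature/sequence into columns; used by the analysis modules.
.replicate_wide <- function(x) {
  x |>
    dplyr::mutate(rep = paste0("s", .data$scan, "_", .data$session)) |>
    dplyr::select(dplyr::all_of(c("object_id", "object_type", "sequence",
                                  "feature_name", "rep", "value"))) |>
    tidyr::pivot_wider(names_from = "rep", values_from = "value")
}
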