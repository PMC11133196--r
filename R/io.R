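#' Long-format response-table schema
#'
#' Response data live in a long-format data frame of class `response_table`
#' with one row per person x item x occasion and columns
#' `person_id`, `item_id`, `trait`, `occasion`, `format` ("VAS"/"DRS"),
#' `value_low`, `value_high` (equal for VAS), `reverse_coded`, `block_order`
#' ("VAS_first"/"DRS_first"), `response_time_s`, `serious`.
#' The table carries a `scale_max` attribute (default 100).
#'
#' @name response-format
#' @keywords internal
NULL

.rt_columns <- c("person_id", "item_id", "trait", "occasion", "format",
                 "value_low", "value_high", "reverse_coded", "block_order",
                 "response_time_s", "serious")

#' Construct a validated response table
#'
#' @param df Data frame with the columns documented in
#'   [response-format]; `response_time_s` and `serious` may be missing and
#'   are filled with `NA`.
#' @param scale_max Upper end of the response scale.
#' @param allow_duplicates Permit multiple rows per (person, item, occasion)?
#'   Raw exports may contain duplicate submissions which
#'   [apply_exclusions()] resolves; cleaned tables must be unique.
#' @return A `response_table` (data frame with a `scale_max` attribute).
#' @export
response_table <- function(df, scale_max = 100, allow_duplicates = TRUE) {
  for (opt in c("response_time_s", "serious")) if (is.null(df[[opt]])) df[[opt]] <- NA
  missing_cols <- setdiff(.rt_columns, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, .rt_columns]
  df$person_id <- as.character(df$person_id)
  df$item_id <- as.character(df$item_id)
  df$trait <- as.character(df$trait)
  df$occasion <- as.integer(df$occasion)
  df$format <- as.character(df$format)
  df$reverse_coded <- as.logical(df$reverse_coded)
  df$block_order <- as.character(df$block_order)
  df$serious <- as.logical(df$serious)

  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      stop("validation error (", what, ") in row(s): ",
           paste(head(idx, 5L), collapse = ", "),
           if (length(idx) > 5L) " ..." else "")
    }
  }
  bad(!df$format %in% c("VAS", "DRS"), "format must be VAS or DRS")
  bad(is.na(df$occasion) | df$occasion < 1L, "occasion must be >= 1")
  bad(!is.na(df$block_order) & !df$block_order %in% c("VAS_first", "DRS_first"),
      "unknown block_order")
  bad(!is.finite(df$value_low) | !is.finite(df$value_high),
      "non-finite response value")
  bad(df$value_low < 0 | df$value_high > scale_max,
      paste0("value outside [0, ", scale_max, "]"))
  bad(df$value_low > df$value_high, "value_low > value_high")
  bad(df$format == "VAS" & df$value_low != df$value_high,
      "VAS requires value_low == value_high")
  bad(!is.na(df$response_time_s) & df$response_time_s < 0,
      "negative response time")

  key_pif <- paste(df$person_id, df$item_id, sep = "\r")
  fmt_tab <- tapply(df$format, key_pif, function(f) length(unique(f)))
  if (any(fmt_tab > 1L)) {
    stop("person-item pairs with inconsistent format across occasions: ",
         paste(head(names(fmt_tab)[fmt_tab > 1L], 3L), collapse = "; "))
  }
  if (!allow_duplicates) {
    key <- paste(df$person_id, df$item_id, df$occasion, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (person, item, occasion) records in row(s): ",
           paste(head(which(duplicated(key)), 5L), collapse = ", "))
    }
  }
  rownames(df) <- NULL
  structure(df, scale_max = scale_max,
            class = c("response_table", "data.frame"))
}

#' Scale maximum of a response table
#' @param table A `response_table`.
#' @return The table's `scale_max` attribute (100 if absent).
#' @export
scale_max <- function(table) {
  sm <- attr(table, "scale_max")
  if (is.null(sm)) 100 else sm
}

#' Read a long-format response CSV
#'
#' @param path CSV file with a header row; columns as in
#'   [response-format]. `dialect` maps nonstandard column names.
#' @param dialect Named character vector `c(standard_name = file_name, ...)`
#'   for files whose headers differ from the canonical names.
#' @param scale_max Upper end of the response scale.
#' @param allow_duplicates Passed to [response_table()].
#' @return A validated `response_table`; rows violating record invariants
#'   raise an error naming the offending row(s).
#' @examples
#' path <- system.file("extdata", "example_responses.csv", package = "drsirt")
#' tab <- read_responses(path)
#' head(reverse_code(tab))
#' @export
read_responses <- function(path, dialect = NULL, scale_max = 100,
                           allow_duplicates = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      if (dialect[[std]] %in% names(df)) {
        names(df)[names(df) == dialect[[std]]] <- std
      }
    }
  }
  response_table(df, scale_max = scale_max, allow_duplicates = allow_duplicates)
}

#' Write a response table to CSV
#'
#' Writes one row per record with the canonical column order and full float
#' precision, so that [read_responses()] recovers an identical table and two
#' writes of the same table are byte-identical.
#'
#' @param table A `response_table`.
#' @param path Output file path.
#' @export
write_responses <- function(table, path) {
  df <- as.data.frame(table)[, .rt_columns]
  # full precision, stable representation
  for (cc in c("value_low", "value_high", "response_time_s")) {
    df[[cc]] <- vapply(df[[cc]], function(v)
      if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE),
      character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(NULL)
}

#' Reverse-code flagged records
#'
#' Reflects responses about the scale midpoint: a VAS value `v` becomes
#' `scale_max - v`; a DRS interval `(low, high)` becomes
#' `(scale_max - high, scale_max - low)`, which preserves the interval width
#' and the ordering of the bounds. The `reverse_coded` flag is cleared, so
#' applying the operation twice (after re-flagging) restores the original.
#'
#' @param table A `response_table` (or plain data frame with the same
#'   columns).
#' @param scale_max Response-scale maximum; defaults to the table attribute.
#' @return The table with flagged rows reflected and flags cleared.
#' @export
reverse_code <- function(table, scale_max = NULL) {
  if (is.null(scale_max)) scale_max <- drsirt::scale_max(table)
  i <- which(table$reverse_coded %in% TRUE)
  if (length(i)) {
    lo <- table$value_low[i]; hi <- table$value_high[i]
    table$value_low[i] <- scale_max - hi
    table$value_high[i] <- scale_max - lo
    table$reverse_coded[i] <- FALSE
  }
  table
}
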