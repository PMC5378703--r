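# Reading and writing the package's tabular interchange formats.

#' Write an item-parameter table
#'
#' CSV schema (versioned, strict on read): columns `item_id`, `role`
#' (`unique`/`anchor`), `item_type` (`MC`/`SR`/`CR`), `model`
#' (`1PL`/`2PL`/`3PL`/`PC`/`GPC`), `a`, `b`, `c`, `d1`..`d4` (empty where
#' not applicable). `format = "json"` writes the same records as a JSON
#' array with a `schema` header.
#'
#' @param params item-parameter table.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_item_params <- function(params, path, format = c("csv", "json")) {
  format <- match.arg(format)
  validate_item_params(params)
  if (format == "csv") {
    write.csv(params, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(
      list(schema = "eqmisfit-item-params-1", items = params),
      path, dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an item-parameter table
#'
#' @param path a CSV or JSON file written by [write_item_params()] (format
#'   inferred from the extension).
#' @return a validated item-parameter table.
#' @export
read_item_params <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$schema, "eqmisfit-item-params-1"))
      stop("unrecognized item-parameter JSON schema")
    df <- as.data.frame(obj$items, stringsAsFactors = FALSE)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  for (col in c("a", "b", "c", "d1", "d2", "d3", "d4")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }
  df$c[is.na(df$c)] <- 0
  validate_item_params(df)
  df
}

#' Write a conversion table as CSV
#'
#' Columns `nc_score`, `equated_score`, `theta`, `extrapolated`; the theta
#' of an extrapolated row is empty, never a fake numeric.
#'
#' @param table a `conversion_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_conversion_table <- function(table, path) {
  validate_conversion_table(table)
  write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a conversion table written by [write_conversion_table()]
#' @param path CSV file.
#' @return a validated `conversion_table`.
#' @export
read_conversion_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$extrapolated <- as.logical(df$extrapolated)
  df$theta <- as.numeric(df$theta)
  class(df) <- c("conversion_table", "data.frame")
  validate_conversion_table(df)
  df
}

#' Write a response matrix with side-car metadata
#'
#' The scores go to `path` as CSV (persons x items, header row of item
#' ids); the item structure, condition and seed go to `paste0(path,
#' ".meta.json")`.
#'
#' @param x a [response_matrix()].
#' @param path output CSV file.
#' @param condition optional condition description list stored in the
#'   side-car.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(x, path, condition = NULL) {
  items <- response_items(x)
  write.csv(as.data.frame(unclass(x)), path, row.names = FALSE)
  jsonlite::write_json(
    list(schema = "eqmisfit-responses-1", condition = condition,
         items = items),
    paste0(path, ".meta.json"),
    dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a response matrix written by [write_response_matrix()]
#' @param path CSV file (its `.meta.json` side-car must sit next to it).
#' @return a [response_matrix()].
#' @export
read_response_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$schema, "eqmisfit-responses-1"))
    stop("unrecognized response-matrix metadata schema")
  items <- as.data.frame(meta$items, stringsAsFactors = FALSE)
  for (col in c("a", "b", "c", "d1", "d2", "d3", "d4"))
    items[[col]] <- as.numeric(items[[col]])
  items$c[is.na(items$c)] <- 0
  scores <- as.matrix(read.csv(path, check.names = FALSE))
  response_matrix(scores, items)
}
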