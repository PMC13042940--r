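# Tabular I/O: tab-separated time series and JSON parameter/result files.
# Column and key names carry unit suffixes (nm, pN, uA, mV, kOhm, nF, Hz, s)
# to prevent unit drift; numeric values round-trip losslessly at 17
# significant digits with a "." decimal separator regardless of locale.

#' Read a tab-separated time series or table
#'
#' @param path File path.
#' @param required Character vector of column names that must be present.
#' @return A data frame.
#' @export
read_timeseries <- function(path, required = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          dec = ".", fileEncoding = "UTF-8")
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      stop(sprintf("schema error: missing required column(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  for (cn in names(df)) {
    if (is.character(df[[cn]])) {
      if (any(grepl("^-?[0-9]+,[0-9]+$", df[[cn]]))) {
        stop(sprintf("schema error: column '%s' uses ',' as decimal separator; '.' is required",
                     cn), call. = FALSE)
      }
      v <- suppressWarnings(as.numeric(df[[cn]]))
      if (!anyNA(v[!is.na(df[[cn]])])) df[[cn]] <- v
    }
  }
  df
}

#' Write a tab-separated time series or table
#'
#' Numeric columns are written with 17 significant digits so that
#' write-then-read is an identity for doubles.
#'
#' @param df Data frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(df, path) {
  out <- as.data.frame(df)
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a flat parameter/result list as JSON
#'
#' @param x Named list of scalars (or shallow lists of scalars).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_params <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a JSON parameter/result file
#'
#' @param path File path.
#' @return A named list.
#' @export
read_params <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
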