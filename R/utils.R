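# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
derive_seed <- function(seed, offset) {
  # keep derived seeds inside the 32-bit integer range
  as.integer((as.numeric(seed) * 1009 + offset * 101) %% (.Machine$integer.max - 1L)) + 1L
}

#' Names of the diagnosis columns of a family dataset
#' @param data a `family_dataset` (or any data frame with `dx_` columns).
#' @return character vector of column names.
#' @keywords internal
#' @noRd
dx_cols <- function(data) grep("^dx_", names(data), value = TRUE)

#' Extract the binary diagnosis matrix from a family dataset
#' @keywords internal
#' @noRd
dx_matrix <- function(data) {
  cols <- dx_cols(data)
  if (length(cols) == 0L) stop("no diagnosis (dx_*) columns found")
  as.matrix(data[, cols, drop = FALSE])
}

assert_family_dataset <- function(data) {
  req <- c("family_id", "person_id", "role", "relationship", "age", "id_severity")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("not a family dataset; missing columns: ", paste(miss, collapse = ", "))
  invisible(data)
}

#' Write a family dataset to delimited text
#'
#' @param data a `family_dataset`.
#' @param path output CSV path (UTF-8, header row).
#' @return `path`, invisibly.
#' @export
write_family_csv <- function(data, path) {
  assert_family_dataset(data)
  data.table::fwrite(as.data.frame(data), path)
  invisible(path)
}

#' Read a family dataset from delimited text
#'
#' @param path CSV path previously written by [write_family_csv()] or following
#'   the same layout (one row per person, `dx_*` binary diagnosis columns).
#' @return a `family_dataset` data frame.
#' @export
read_family_csv <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  assert_family_dataset(d)
  class(d) <- c("family_dataset", "data.frame")
  d
}
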