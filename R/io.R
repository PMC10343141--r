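# Delimited-text readers/writers for abundance tables and responses.
# Microbiome tables usually come as counts; rows are closed to proportions
# on load.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

#' Load a sample-by-component abundance table
#'
#' Reads a delimited text file (comma or tab, auto-detected) with sample
#' identifiers in the first column and components in the remaining
#' columns. Counts are closed to proportions. An optional response column
#' is split off by name.
#'
#' @param path File path.
#' @param response Optional name of a response column in the same file.
#' @param transpose If `TRUE` the file stores components as rows and
#'   samples as columns.
#' @param sep Field separator; default auto-detect.
#' @param components Optional character vector: keep exactly these
#'   component columns (in this order) and drop the rest before closing.
#' @return List with `X` (a `composition_table`) and `y` (response vector
#'   or `NULL`).
#' @export
load_table <- function(path, response = NULL, transpose = FALSE, sep = NULL,
                       components = NULL) {
  if (!file.exists(path)) stop_ck("schema_error", "file not found: %s", path)
  sep <- sep %||% detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(rownames(df))) {
    stop_ck("schema_error", "duplicate identifiers in first column")
  }
  y <- NULL
  if (!is.null(response)) {
    if (transpose) {
      if (!response %in% rownames(df)) {
        stop_ck("schema_error", "response row '%s' not found", response)
      }
      y <- unlist(df[response, ], use.names = FALSE)
      df <- df[setdiff(rownames(df), response), , drop = FALSE]
    } else {
      if (!response %in% colnames(df)) {
        stop_ck("schema_error", "response column '%s' not found", response)
      }
      y <- df[[response]]
      df <- df[, setdiff(colnames(df), response), drop = FALSE]
    }
  }
  M <- as.matrix(df)
  if (transpose) M <- t(M)
  if (!is.null(components)) {
    missing <- setdiff(components, colnames(M))
    if (length(missing)) {
      stop_ck("schema_error", "components absent from table: %s",
              paste(missing, collapse = ", "))
    }
    M <- M[, components, drop = FALSE]
  }
  if (!is.numeric(M)) {
    M2 <- suppressWarnings(apply(M, 2, as.numeric))
    if (anyNA(M2)) {
      bad <- colnames(M)[apply(is.na(M2), 2, any)]
      stop_ck("schema_error", "non-numeric columns: %s",
              paste(bad, collapse = ", "))
    }
    dimnames(M2) <- dimnames(M)
    M <- M2
  }
  rs <- rowSums(M)
  if (any(abs(rs - 1) > RECLOSE_TOL)) {
    message("closing counts to proportions (row sums ranged ",
            format(min(rs)), "..", format(max(rs)), ")")
    M <- M / rs
  }
  X <- composition_table(M)
  if (!is.null(y) && is.character(y) && !anyNA(suppressWarnings(as.numeric(y)))) {
    y <- as.numeric(y)
  }
  list(X = X, y = y)
}

#' Write a composition table (or any matrix) as delimited text
#'
#' @param X Matrix with dimnames.
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_table_ck <- function(X, path, sep = "\t") {
  utils::write.table(as.data.frame(unclass(X)), path, sep = sep,
                     quote = FALSE, col.names = NA)
  invisible(path)
}
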