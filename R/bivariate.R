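#' Paired bivariate observations
#'
#' Container for paired `(x, y)` observations — the substrate of every
#' regression fit in the package. Rows with non-finite values in either
#' variable are dropped and counted, so downstream fits never see `NA`s.
#'
#' @param x,y Numeric vectors of equal length.
#' @param labels Character vector of length 2 naming the x and y variables
#'   (e.g., `c("TChla", "bbp700")`). Used for orientation checks and reports.
#' @param units Optional character vector of length 2 with the units of x
#'   and y (e.g., `c("mg m-3", "m-1")`).
#'
#' @return An object of class `bivariate_data`: a list with elements `x`,
#'   `y`, `labels`, `units`, `n` (pair count after cleaning) and
#'   `n_dropped` (rows removed because of non-finite values).
#' @examples
#' d <- bivariate_data(c(1, 2, 3, 4, 5), c(2, 3, 5, 4, 6))
#' d$n
#' @export
bivariate_data <- function(x, y, labels = c("x", "y"), units = c("", "")) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length (got ", length(x), " and ",
         length(y), ")")
  }
  if (length(labels) != 2L) stop("labels must have length 2")
  x <- as.numeric(x)
  y <- as.numeric(y)
  keep <- is.finite(x) & is.finite(y)
  out <- structure(
    list(
      x = x[keep],
      y = y[keep],
      labels = as.character(labels),
      units = as.character(units),
      n = sum(keep),
      n_dropped = sum(!keep)
    ),
    class = "bivariate_data"
  )
  out
}

#' @export
print.bivariate_data <- function(x, ...) {
  cat("<bivariate_data> ", x$labels[1], " vs ", x$labels[2],
      ": n = ", x$n, sep = "")
  if (x$n_dropped > 0) cat(" (", x$n_dropped, " rows dropped)", sep = "")
  cat("\n")
  invisible(x)
}

#' Read paired observations from a delimited text file
#'
#' Expects a header row; the two columns to use are named explicitly so
#' extra columns (time, depth, ...) are tolerated.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param x_col,y_col Column names for the x and y variables.
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#' @return A [bivariate_data] object labelled with the column names.
#' @export
read_bivariate <- function(path, x_col, y_col, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(x_col, y_col)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path,
           " (available: ", paste(names(df), collapse = ", "), ")")
    }
  }
  bivariate_data(df[[x_col]], df[[y_col]], labels = c(x_col, y_col))
}

# Internal: coerce data frames / matrices with columns x, y for convenience.
as_bivariate <- function(data) {
  if (inherits(data, "bivariate_data")) return(data)
  if (is.data.frame(data) && all(c("x", "y") %in% names(data))) {
    return(bivariate_data(data$x, data$y))
  }
  stop("expected a bivariate_data object (see bivariate_data())")
}
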