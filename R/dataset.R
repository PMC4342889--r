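#' Construct a single-site dataset
#'
#' Bundles one site's response vector and covariate matrix, the only
#' observation-level object in the package. Sites never transmit this object;
#' they exchange [site_summary()] aggregates instead.
#'
#' @param y Integer vector of responses coded `1..K`.
#' @param X Numeric covariate matrix with one row per observation. A data
#'   frame of numeric columns is accepted and converted.
#' @param K Number of response categories (`>= 3`). Defaults to `max(y)`;
#'   supply explicitly when a small site happens to lack the top category.
#'
#' @return An object of class `grid_dataset`: a list with elements `y`
#'   (integer vector), `X` (numeric matrix, `n x m`), `K`, `n` and `m`.
#' @examples
#' d <- grid_dataset(c(1, 2, 3, 3), matrix(rnorm(8), 4, 2), K = 3)
#' d$n
#' @export
grid_dataset <- function(y, X, K = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  storage.mode(X) <- "double"
  if (anyNA(y) || anyNA(X)) {
    stop("grid_dataset: missing values are not allowed in y or X")
  }
  if (any(y != round(y))) {
    stop("grid_dataset: response values must be integers")
  }
  y <- as.integer(y)
  if (is.null(K)) K <- max(y)
  K <- as.integer(K)
  if (length(y) != nrow(X)) {
    stop("grid_dataset: length(y) must equal nrow(X)")
  }
  if (length(y) < 1L) stop("grid_dataset: need at least one observation")
  if (any(y < 1L) || any(y > K)) {
    bad <- which(y < 1L | y > K)[1L]
    stop(sprintf("grid_dataset: response out of range 1..%d at row %d", K, bad))
  }
  if (K < 3L) stop("grid_dataset: K must be at least 3")
  structure(
    list(y = y, X = X, K = K, n = length(y), m = ncol(X)),
    class = "grid_dataset"
  )
}

#' @export
print.grid_dataset <- function(x, ...) {
  cat(sprintf(
    "<grid_dataset> n = %d observations, m = %d covariates, K = %d categories\n",
    x$n, x$m, x$K
  ))
  tab <- tabulate(x$y, nbins = x$K)
  cat("response counts:", paste(sprintf("%d:%d", seq_len(x$K), tab),
    collapse = "  "
  ), "\n")
  invisible(x)
}

#' Read one site's data from a CSV file
#'
#' Reads a header CSV and extracts the named response and covariate columns
#' in the given order. The response must already be coded `1..K`.
#'
#' @param path Path to a CSV file with a header row.
#' @param response Name of the response column.
#' @param covariates Character vector of covariate column names.
#' @param K Number of categories; inferred from the data when `NULL`.
#' @return A [grid_dataset()].
#' @export
read_site_csv <- function(path, response, covariates, K = NULL) {
  if (!file.exists(path)) stop("read_site_csv: file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(c(response, covariates), names(raw))
  if (length(missing_cols)) {
    stop(
      "read_site_csv: column(s) not found in ", path, ": ",
      paste(missing_cols, collapse = ", ")
    )
  }
  if (response %in% covariates) {
    stop("read_site_csv: response column may not also be a covariate")
  }
  y <- raw[[response]]
  if (!is.numeric(y) || any(is.na(y)) || any(y != round(y))) {
    bad <- which(is.na(y) | suppressWarnings(y != round(y)))[1L]
    stop(sprintf(
      "read_site_csv: non-integer or missing response in column '%s', row %s",
      response, ifelse(is.na(bad), "?", bad)
    ))
  }
  Xdf <- raw[covariates]
  for (cn in covariates) {
    if (!is.numeric(Xdf[[cn]])) {
      stop(sprintf("read_site_csv: covariate column '%s' is not numeric", cn))
    }
    if (anyNA(Xdf[[cn]])) {
      stop(sprintf(
        "read_site_csv: missing value in column '%s', row %d",
        cn, which(is.na(Xdf[[cn]]))[1L]
      ))
    }
  }
  X <- as.matrix(Xdf)
  colnames(X) <- covariates
  grid_dataset(y, X, K = K)
}

#' Write a dataset back to CSV
#'
#' Values are written with full double precision (17 significant digits) so a
#' write/read round trip is exact.
#'
#' @param data A [grid_dataset()].
#' @param path Output file path.
#' @param response Column name for the response (default `"y"`).
#' @return `path`, invisibly.
#' @export
write_site_csv <- function(data, path, response = "y") {
  stopifnot(inherits(data, "grid_dataset"))
  cn <- colnames(data$X)
  if (is.null(cn)) cn <- paste0("x", seq_len(data$m))
  df <- data.frame(data$y, data$X)
  names(df) <- c(response, cn)
  # format() with 17 digits keeps doubles bit-exact through the round trip
  for (j in seq_along(df)[-1L]) {
    df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
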