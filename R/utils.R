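#' @keywords internal
"_PACKAGE"

## E-values printed as "0.0" by aligners are floored here so that
## -log10() stays finite downstream.
EVALUE_FLOOR <- 1e-180

#' Canonical unordered pair key
#'
#' Builds an order-insensitive string key for a protein (or gene) pair so
#' that pairs can be stored in sets and compared regardless of the order
#' in which the two members were given.
#'
#' @param a,b character vectors of identifiers (recycled to equal length).
#' @return character vector of keys, one per pair.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Split pair keys back into a two-column matrix
#' @param key character vector produced by [pair_key()].
#' @return character matrix with columns `a` and `b`.
#' @export
pair_unkey <- function(key) {
  parts <- strsplit(key, "\r", fixed = TRUE)
  m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  colnames(m) <- c("a", "b")
  m
}

clip01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_campnets <- function(...) stop(..., call. = FALSE)

## read a tab-separated text file, dropping '#' comment lines
read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop_campnets("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
}
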