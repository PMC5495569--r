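#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a global seed and a key
#'
#' A single experiment-level seed is fanned out to per-rat / per-unit /
#' per-stage seeds by hashing a string key into the seed, so that adding a
#' unit (or reordering rats) never perturbs the random stream of any other
#' component.
#'
#' @param seed Integer global seed.
#' @param ... Character or numeric key components; concatenated with "/".
#' @return An integer in `[0, 2^31 - 20)`, suitable for `set.seed()`.
#' @examples
#' substream_seed(1, "unit", 7)
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  # 2147483629 is prime and < 2^31; h * 48271 stays < 2^53 so doubles are exact
  h <- as.double(seed %% 2147483629)
  for (code in utf8ToInt(key)) h <- (h * 48271 + code) %% 2147483629
  as.integer(h)
}

#' Percentage with fixed rounding
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @param digits Decimal places (default 2, matching reported compositions).
#' @return `round(100 * k / n, digits)`; `NA` with a warning if `n == 0`.
#' @examples
#' pct(8, 130)   # 6.15
#' pct(20, 21, 1) # 95.2
#' @export
pct <- function(k, n, digits = 2) {
  if (n == 0) {
    warning("zero denominator in pct()")
    return(NA_real_)
  }
  round(100 * k / n, digits)
}

#' Write a table as TSV (stable, unquoted)
#'
#' @param x Data frame.
#' @param file Output path.
#' @export
write_tsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param file Input path.
#' @return Data frame.
#' @export
read_tsv <- function(file) {
  utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
}
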