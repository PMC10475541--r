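#' Exact integer codes
#'
#' Encodings and profile codes are exact non-negative integers that routinely
#' exceed the 2^53 range where a double is exact, so the package represents
#' them as decimal strings and performs all arithmetic with exact
#' arbitrary-precision routines. `as_code()` normalizes user input (character
#' or smallish numeric) to this representation.
#'
#' @param x a character vector of decimal integers, or a numeric vector of
#'   integer-valued doubles no larger than 2^53.
#' @return `as_code()` returns a character vector of decimal integers.
#' @examples
#' as_code(223417708453)
#' big_mul("223417708453", "397")
#' @export
as_code <- function(x) {
  if (is.numeric(x)) {
    if (any(!is.finite(x) | x < 0 | x != trunc(x)))
      stop("codes must be non-negative integers", call. = FALSE)
    if (any(x > 2^53))
      stop("numeric input larger than 2^53 is not exact; pass a string",
           call. = FALSE)
    x <- sprintf("%.0f", x)
  }
  if (!is.character(x)) stop("codes must be character or numeric", call. = FALSE)
  if (any(!grepl("^[0-9]+$", x)))
    stop("not a non-negative integer: ",
         paste(sQuote(x[!grepl("^[0-9]+$", x)]), collapse = ", "), call. = FALSE)
  sub("^0+(?=.)", "", x, perl = TRUE)
}

#' @rdname as_code
#' @param a,b decimal integer strings (or numerics accepted by `as_code()`);
#'   recycled to a common length.
#' @return `big_mul()` and `big_mod()` return decimal integer strings;
#'   `big_cmp()` returns -1/0/1; `divides()` returns a logical vector that is
#'   `TRUE` where `a` divides `b` exactly.
#' @export
big_mul <- function(a, b) .big_mul(as_code(a), as_code(b))

#' @rdname as_code
#' @export
big_mod <- function(a, b) .big_mod(as_code(a), as_code(b))

#' @rdname as_code
#' @export
big_cmp <- function(a, b) .big_cmp(as_code(a), as_code(b))

#' @rdname as_code
#' @export
divides <- function(a, b) .big_divisible(as_code(b), as_code(a))

# ascending numeric order of decimal strings: shorter first, then lexicographic
big_order <- function(x) order(nchar(x), x, method = "radix")
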