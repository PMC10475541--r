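#' The characteristic-to-prime registry
#'
#' Every clinical characteristic that appears in the formalized ICHD-3 criteria
#' is bound to a unique prime number; a set of characteristics is then encoded
#' as the product of its primes, so that set inclusion becomes exact
#' divisibility. Negative findings ("No photophobia") are ordinary
#' characteristics with their own primes, never a logical NOT.
#'
#' The bundled registry has 103 entries whose primes are exactly the first 103
#' primes (2 through 563). It is shipped as a plain TSV
#' (`extdata/characteristic-primes.tsv`) so users can extend it; new
#' characteristics should take the next unused primes.
#'
#' Label matching is exact after canonical normalization: whitespace is
#' trimmed, internal runs of spaces collapse to one, and comparison is
#' case-insensitive. The stored form keeps the registry's exact casing and
#' spelling (including "Not aggrevated by activity").
#'
#' @param path path to a registry TSV with columns `prime` and `name`.
#' @return a `prime_registry`: a data frame with columns `prime` (integer) and
#'   `name` (character).
#' @examples
#' reg <- headache_registry()
#' lookup_prime(reg, "Unilateral")
#' lookup_name(reg, 563)
#' @export
load_registry <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("prime", "name") %in% names(df)))
    stop("registry file needs columns 'prime' and 'name'", call. = FALSE)
  new_registry(df$name, as.integer(df$prime))
}

#' @rdname load_registry
#' @param name character vector of characteristic labels.
#' @param prime integer vector of primes, same length as `name`.
#' @export
new_registry <- function(name, prime) {
  stopifnot(length(name) == length(prime))
  df <- data.frame(prime = as.integer(prime), name = as.character(name),
                   stringsAsFactors = FALSE)
  attr(df, "norm") <- normalize_label(df$name)
  class(df) <- c("prime_registry", "data.frame")
  df
}

#' @rdname load_registry
#' @export
headache_registry <- function() {
  if (is.null(the$registry))
    the$registry <- load_registry(ichdprime_file("characteristic-primes.tsv"))
  the$registry
}

#' Canonical label normalization
#'
#' Trims leading/trailing whitespace, collapses internal runs of whitespace to
#' a single space, and lowercases, so that lookups tolerate the casing and
#' spacing drift found in hand-curated tables.
#'
#' @param x character vector of labels.
#' @return normalized character vector.
#' @export
normalize_label <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))

#' Look up the prime bound to a characteristic, or the reverse
#'
#' @param registry a `prime_registry`.
#' @param name character vector of characteristic labels (normalized before
#'   matching).
#' @return `lookup_prime()`: the integer primes; `lookup_name()`: the canonical
#'   labels.
#' @examples
#' lookup_prime(headache_registry(), c("Unilateral", "Nausea/vomiting"))
#' @export
lookup_prime <- function(registry, name) {
  idx <- match(normalize_label(name), attr(registry, "norm"))
  if (anyNA(idx))
    stop("unknown characteristic: ",
         paste(sQuote(name[is.na(idx)]), collapse = ", "), call. = FALSE)
  registry$prime[idx]
}

#' @rdname lookup_prime
#' @param prime integer vector of primes.
#' @export
lookup_name <- function(registry, prime) {
  idx <- match(as.integer(prime), registry$prime)
  if (anyNA(idx))
    stop("unassigned prime: ",
         paste(prime[is.na(idx)], collapse = ", "), call. = FALSE)
  registry$name[idx]
}

is_prime_int <- function(n) {
  n <- as.integer(n)
  vapply(n, function(x) {
    if (is.na(x) || x < 2L) return(FALSE)
    if (x < 4L) return(TRUE)
    if (x %% 2L == 0L) return(FALSE)
    d <- 3L
    while (d * d <= x) {
      if (x %% d == 0L) return(FALSE)
      d <- d + 2L
    }
    TRUE
  }, logical(1))
}

#' Validate a registry
#'
#' Checks that every prime is in fact prime, and that primes and (normalized)
#' names are each pairwise distinct, so that the registry is a bijection.
#' Failures are reported, not raised.
#'
#' @param registry a `prime_registry`.
#' @return a `registry_validation` list with the entry `count`, the offending
#'   entries under `primality_failures`, `duplicate_primes` and
#'   `duplicate_names`, and `valid`.
#' @examples
#' validate_registry(headache_registry())
#' @export
validate_registry <- function(registry) {
  bad_prime <- registry$name[!is_prime_int(registry$prime)]
  dup_p <- unique(registry$prime[duplicated(registry$prime)])
  norm <- normalize_label(registry$name)
  dup_n <- unique(registry$name[duplicated(norm)])
  out <- list(count = nrow(registry),
              primality_failures = bad_prime,
              duplicate_primes = dup_p,
              duplicate_names = dup_n,
              valid = length(bad_prime) + length(dup_p) + length(dup_n) == 0)
  class(out) <- "registry_validation"
  out
}

#' @export
print.registry_validation <- function(x, ...) {
  cat("Prime registry:", x$count, "entries\n")
  if (x$valid) cat("  all primes prime, all primes and names unique\n")
  if (length(x$primality_failures))
    cat("  non-prime entries:", paste(x$primality_failures, collapse = ", "), "\n")
  if (length(x$duplicate_primes))
    cat("  duplicated primes:", paste(x$duplicate_primes, collapse = ", "), "\n")
  if (length(x$duplicate_names))
    cat("  duplicated names:", paste(x$duplicate_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.prime_registry <- function(x, ...) {
  cat("<prime_registry> ", nrow(x), " characteristics, primes ",
      min(x$prime), "..", max(x$prime), "\n", sep = "")
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
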