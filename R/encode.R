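#' Encode characteristic sets as integers
#'
#' A conjunct (one AND-branch of a criteria formula's disjunctive normal form)
#' or a patient profile is encoded as the product of the primes of its
#' characteristics. Because primes are the multiplicative atoms of the
#' integers, the encoding of a set S divides the encoding of a set T exactly
#' when S is a subset of T -- the arithmetic fact the whole diagnosis method
#' rests on.
#'
#' @param labels character vector of characteristic labels (a set: duplicates
#'   are an error).
#' @param registry a `prime_registry`; defaults to the bundled one.
#' @return a decimal integer string. The empty set encodes to `"1"`.
#' @examples
#' encode_conjunct(c("Greater than 5 episodes", "4 to 72 h", "Unilateral",
#'                   "Pulsating", "Nausea/vomiting"))
#' @export
encode_conjunct <- function(labels, registry = headache_registry()) {
  if (anyDuplicated(normalize_label(labels)))
    stop("duplicate characteristics in conjunct", call. = FALSE)
  .big_prod(lookup_prime(registry, labels))
}

#' @rdname encode_conjunct
#' @details `encode_profile()` is the same product for a patient's
#'   characteristic set.
#' @export
encode_profile <- function(labels, registry = headache_registry()) {
  if (length(labels) == 0L) return("1")
  if (anyDuplicated(normalize_label(labels)))
    stop("duplicate characteristics in profile", call. = FALSE)
  .big_prod(lookup_prime(registry, labels))
}

#' Encode a conjunct list as a sorted encoding list
#'
#' One encoding per conjunct, in ascending numeric order, with exact
#' duplicates removed. This is the list format in which a diagnosis's criteria
#' are stored: a profile satisfies the criteria iff its code is divisible by
#' at least one list member.
#'
#' @param conjuncts a list of character vectors (e.g. from [to_dnf()]).
#' @param registry a `prime_registry`.
#' @return character vector of decimal integer strings, ascending.
#' @export
encode_criteria <- function(conjuncts, registry = headache_registry()) {
  if (length(conjuncts) == 0L) return(character(0))
  enc <- vapply(conjuncts, encode_conjunct, character(1), registry = registry)
  unique(enc[big_order(enc)])
}

#' Decode an integer back to characteristics
#'
#' Trial division over the registry primes. The result is a multiset: a
#' squared prime yields its label twice. Any residual factor outside the
#' registry is an error.
#'
#' @param value decimal integer string (or numeric up to 2^53).
#' @param registry a `prime_registry`.
#' @return character vector of labels (with multiplicity); `"1"` decodes to
#'   `character(0)`.
#' @examples
#' decode_encoding("2106413")
#' @export
decode_encoding <- function(value, registry = headache_registry()) {
  value <- as_code(value)
  stopifnot(length(value) == 1L)
  f <- .big_factor(value, registry$prime)
  if (f$residue != "1")
    stop("unencodable integer: residual factor ", f$residue,
         " is not a product of registry primes", call. = FALSE)
  rep(registry$name, f$exponents[1L, ])
}

# exponent matrix (rows = values) over the registry primes; errors on residue
factor_matrix <- function(values, registry) {
  f <- .big_factor(values, registry$prime)
  bad <- f$residue != "1"
  if (any(bad))
    stop("unencodable integer(s): ", paste(values[bad], collapse = ", "),
         call. = FALSE)
  f$exponents
}
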