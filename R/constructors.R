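#' Build small registries and catalogs in code
#'
#' Convenience constructors used in examples and tests: `toy_registry()`
#' binds the given labels to the first primes; `new_catalog()` builds a
#' catalog entry per diagnosis from explicit conjunct lists (labels are
#' encoded and validated against the registry exactly as the file loader
#' does).
#'
#' @param labels character vector of characteristic labels.
#' @return `toy_registry()`: a `prime_registry`.
#' @examples
#' reg <- toy_registry(c("a", "b", "c"))
#' cat2 <- new_catalog(list(D1 = list(c("a", "b")), D2 = list("c")), reg)
#' cat2[["D1"]]$encodings
#' @export
toy_registry <- function(labels) {
  new_registry(labels, first_primes(length(labels)))
}

first_primes <- function(n) {
  out <- integer(0)
  candidate <- 2L
  while (length(out) < n) {
    if (is_prime_int(candidate)) out <- c(out, candidate)
    candidate <- candidate + 1L
  }
  out
}

#' @rdname toy_registry
#' @param conjuncts_by_diagnosis a named list; each element is a diagnosis's
#'   list of conjuncts (character vectors of labels). Names become codes.
#' @param registry a `prime_registry`.
#' @param names optional character vector of display names (defaults to the
#'   codes).
#' @return `new_catalog()`: a `criteria_catalog`.
#' @export
new_catalog <- function(conjuncts_by_diagnosis, registry,
                        names = base::names(conjuncts_by_diagnosis)) {
  codes <- base::names(conjuncts_by_diagnosis)
  stopifnot(!is.null(codes), !anyDuplicated(codes))
  entries <- lapply(seq_along(conjuncts_by_diagnosis), function(i) {
    conjuncts <- lapply(conjuncts_by_diagnosis[[i]], function(x)
      sort(unique(as.character(x))))
    encodings <- encode_criteria(conjuncts, registry)
    expo <- factor_matrix(encodings, registry)
    entry <- list(code = codes[[i]], name = names[[i]],
                  id = paste(codes[[i]], names[[i]]),
                  conjuncts = lapply(seq_len(nrow(expo)), function(r)
                    registry$name[expo[r, ] > 0L]),
                  encodings = encodings,
                  support = expo > 0L)
    class(entry) <- "diagnosis_criteria"
    entry
  })
  base::names(entries) <- codes
  structure(entries, class = "criteria_catalog", registry = registry)
}
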