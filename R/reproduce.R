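#' Reproduce the headline results of the dual-diagnosis analysis
#'
#' Runs the full pipeline on the bundled knowledge base -- registry
#' validation, catalog and contradiction loading, take-two enumeration,
#' contradiction filtering, deduplication and classification -- and reports
#' each headline quantity alongside its published reference value with a
#' match flag.
#'
#' @param catalog a `criteria_catalog`.
#' @param contradictions a `contradiction_set`.
#' @param curation an `overlap_curation`.
#' @param registry a `prime_registry`.
#' @return a `reproduction_report`: a data frame with columns `quantity`,
#'   `value`, `reference`, `match`.
#' @examples
#' \donttest{
#' reproduce_results()
#' }
#' @export
reproduce_results <- function(catalog = headache_catalog(),
                              contradictions = headache_contradictions(),
                              curation = headache_curation(),
                              registry = headache_registry()) {
  val <- validate_registry(registry)
  res <- enumerate_dual_diagnoses(catalog, contradictions, within = TRUE)
  cls <- classify_pairs(res$pairs, catalog, curation)
  quantities <- c(
    registry_size = val$count,
    total_encodings = sum(vapply(catalog, function(d) length(d$encodings),
                                 integer(1))),
    contradiction_rows = attr(contradictions, "n_rows"),
    survivors_ordered = res$summary$survivors_ordered_all,
    survivors_unordered = res$summary$survivors_unordered_all,
    dual_diagnosis_pairs = res$summary$unique_pairs,
    subset_intersecting = unname(cls$counts[["SUBSET_INTERSECTING"]]),
    intersecting_non_subset = unname(cls$counts[["INTERSECTING_NON_SUBSET"]]),
    non_intersecting = unname(cls$counts[["NON_INTERSECTING"]]))
  reference <- c(registry_size = 103, total_encodings = 578,
                 contradiction_rows = 99, survivors_ordered = 253842,
                 survivors_unordered = NA, dual_diagnosis_pairs = 145,
                 subset_intersecting = 2, intersecting_non_subset = 14,
                 non_intersecting = 129)
  report <- data.frame(quantity = names(quantities),
                       value = unname(quantities),
                       reference = unname(reference[names(quantities)]),
                       stringsAsFactors = FALSE)
  report$match <- ifelse(is.na(report$reference), NA,
                         report$value == report$reference)
  class(report) <- c("reproduction_report", "data.frame")
  report
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat("Reproduction report\n")
  for (i in seq_len(nrow(x))) {
    flag <- if (is.na(x$match[i])) "   " else if (x$match[i]) "ok " else "XX "
    ref <- if (is.na(x$reference[i])) "" else sprintf(" (reference %s",
                                                      x$reference[i])
    if (nzchar(ref)) ref <- paste0(ref, ")")
    cat(sprintf("  %s%-26s %8s%s\n", flag, x$quantity[i],
                format(x$value[i], big.mark = ","), ref))
  }
  invisible(x)
}

#' Generate random consistent patient profiles
#'
#' Each profile starts from one randomly chosen conjunct of a randomly chosen
#' diagnosis (so it satisfies that diagnosis by construction) and adds up to
#' `max_extras` random further characteristics, each accepted only if it
#' creates no contradiction with the profile so far. Uses R's RNG: call
#' `set.seed()` for reproducibility.
#'
#' @param n number of profiles.
#' @param catalog a `criteria_catalog`.
#' @param contradictions a `contradiction_set`.
#' @param registry a `prime_registry`.
#' @param max_extras maximum number of added characteristics (0 to
#'   `max_extras` are added, uniformly).
#' @return a list of `headache_profile` objects, each with a `source`
#'   attribute naming the seeding diagnosis code.
#' @examples
#' set.seed(1)
#' profs <- generate_fixture_profiles(3)
#' attr(profs[[1]], "source")
#' @export
generate_fixture_profiles <- function(n, catalog = headache_catalog(),
                                      contradictions = headache_contradictions(),
                                      registry = headache_registry(),
                                      max_extras = 4L) {
  stopifnot(n >= 1L)
  codes <- names(catalog)
  lapply(seq_len(n), function(i) {
    code <- sample(codes, 1L)
    entry <- catalog[[code]]
    conj <- entry$conjuncts[[sample.int(length(entry$conjuncts), 1L)]]
    labels <- conj
    n_extra <- sample.int(max_extras + 1L, 1L) - 1L
    candidates <- sample(setdiff(registry$name, labels))
    added <- 0L
    for (cand in candidates) {
      if (added >= n_extra) break
      trial <- c(labels, cand)
      primes <- lookup_prime(registry, trial)
      clash <- any(contradictions$prime_a %in% primes &
                   contradictions$prime_b %in% primes)
      if (!clash) {
        labels <- trial
        added <- added + 1L
      }
    }
    prof <- new_profile(labels, registry)
    attr(prof, "source") <- code
    prof
  })
}
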