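#' Patient profiles
#'
#' A profile is the set of characteristics a patient exhibits, together with
#' its integer code (the product of the characteristics' primes).
#'
#' @param labels character vector of characteristic labels.
#' @param registry a `prime_registry`.
#' @return a `headache_profile` with fields `characteristics` (canonical
#'   labels) and `code` (decimal integer string).
#' @examples
#' p <- new_profile(c("Greater than 5 episodes", "4 to 72 h", "Unilateral",
#'                    "Pulsating", "Nausea/vomiting", "Photophobia"))
#' p$code
#' @export
new_profile <- function(labels, registry = headache_registry()) {
  labels <- unique(as.character(labels))
  canonical <- if (length(labels)) lookup_name(registry,
                                              lookup_prime(registry, labels))
               else character(0)
  structure(list(characteristics = canonical,
                 code = encode_profile(canonical, registry)),
            class = "headache_profile")
}

#' @export
print.headache_profile <- function(x, ...) {
  cat("<headache_profile> code ", x$code, "\n  ", sep = "")
  cat(paste(x$characteristics, collapse = "; "), "\n")
  invisible(x)
}

as_profile <- function(x, registry) {
  if (inherits(x, "headache_profile")) x else new_profile(x, registry)
}

#' Test a profile against one diagnosis by divisibility
#'
#' A profile satisfies a diagnosis exactly when its code is divisible, without
#' remainder, by at least one of the diagnosis's criteria encodings: the
#' dividing encoding is one fully satisfied conjunct of the criteria's
#' disjunctive normal form.
#'
#' @param profile_code a decimal integer string (or numeric up to 2^53), or a
#'   `headache_profile`.
#' @param criteria a `diagnosis_criteria` entry.
#' @param all_witnesses if `TRUE`, report every dividing encoding, not only
#'   the smallest.
#' @return a `diagnosis_verdict` with `diagnosis`, `satisfied`, `witness`
#'   (the smallest dividing encoding, or `NA`) and optionally `witnesses`.
#' @examples
#' cat21 <- headache_catalog()
#' matches("88696830255841", cat21[["1.1"]])
#' @export
matches <- function(profile_code, criteria, all_witnesses = FALSE) {
  if (inherits(profile_code, "headache_profile"))
    profile_code <- profile_code$code
  profile_code <- as_code(profile_code)
  div <- .big_divisible(rep(profile_code, length(criteria$encodings)),
                        criteria$encodings)
  witnesses <- criteria$encodings[div]
  out <- list(diagnosis = criteria$id,
              satisfied = any(div),
              witness = if (any(div)) witnesses[[1L]] else NA_character_)
  if (all_witnesses) out$witnesses <- witnesses
  class(out) <- "diagnosis_verdict"
  out
}

#' @export
print.diagnosis_verdict <- function(x, ...) {
  cat("<diagnosis_verdict> ", x$diagnosis, ": ",
      if (x$satisfied) paste0("satisfied (witness ", x$witness, ")")
      else "not satisfied", "\n", sep = "")
  invisible(x)
}

#' Diagnose a profile against the whole catalog
#'
#' Applies the divisibility rule for every diagnosis and returns those
#' satisfied. An internally contradictory profile (one that violates the
#' contradiction table) is still diagnosed, but a warning lists the violated
#' pairs: a single real headache cannot be contradictory, so a violation
#' signals a data-quality problem or a profile mixing two distinct headaches.
#'
#' @param profile a `headache_profile` or character vector of labels.
#' @param catalog a `criteria_catalog`.
#' @param contradictions a `contradiction_set` used for the consistency
#'   warning, or `NULL` to skip the check.
#' @param registry a `prime_registry`.
#' @return a data frame with one row per satisfied diagnosis: `code`,
#'   `diagnosis`, `witness` (the smallest dividing encoding), in catalog
#'   order.
#' @examples
#' diagnose(c("Greater than 5 episodes", "4 to 72 h", "Unilateral",
#'            "Pulsating", "Nausea/vomiting", "Photophobia"))
#' @export
diagnose <- function(profile, catalog = headache_catalog(),
                     contradictions = headache_contradictions(),
                     registry = headache_registry()) {
  profile <- as_profile(profile, registry)
  if (!is.null(contradictions)) {
    viol <- check_consistency(profile, contradictions)
    if (nrow(viol))
      warning("profile is internally contradictory: ",
              paste(sprintf("(%s | %s)", viol$a, viol$b), collapse = "; "),
              call. = FALSE)
  }
  verdicts <- lapply(catalog, function(d) matches(profile$code, d))
  sat <- vapply(verdicts, `[[`, logical(1), "satisfied")
  data.frame(
    code = vapply(catalog[sat], `[[`, character(1), "code"),
    diagnosis = vapply(catalog[sat], `[[`, character(1), "name"),
    witness = vapply(verdicts[sat], `[[`, character(1), "witness"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Check a profile against the contradiction table
#'
#' A contradiction pair is violated exactly when its two-prime code divides
#' the profile code, i.e. when both characteristics are present.
#'
#' @param profile a `headache_profile` or character vector of labels.
#' @param contradictions a `contradiction_set`.
#' @param registry a `prime_registry`.
#' @return the violated rows of the contradiction set (zero rows means the
#'   profile is consistent).
#' @examples
#' nrow(check_consistency(c("Bilateral location", "Unilateral")))
#' @export
check_consistency <- function(profile,
                              contradictions = headache_contradictions(),
                              registry = headache_registry()) {
  profile <- as_profile(profile, registry)
  hit <- .big_divisible(rep(profile$code, nrow(contradictions)),
                        contradictions$code)
  as.data.frame(contradictions)[hit, , drop = FALSE]
}
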