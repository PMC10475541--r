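#' The criteria catalog
#'
#' The catalog holds, for each of 21 primary headache disorders (migraine 1.1,
#' 1.2, 1.3; tension-type headache 2.1-2.3; the trigeminal autonomic
#' cephalalgias 3.1-3.4; and the other primary headache disorders of ICHD-3
#' chapter 4), the list of conjuncts of its criteria's disjunctive normal form
#' and their integer encodings. The bundled catalog carries 578 encodings in
#' total.
#'
#' The ground truth of the bundled catalog is the encoding list itself: the
#' loader factorizes every integer over the registry primes to recover the
#' conjuncts, re-encodes them, and fails fast on any mismatch, so a corrupted
#' file cannot load. Where a diagnosis also carries a formula-level
#' definition (19 of the 21 do), the formula's DNF expansion is validated
#' against the encoding list integer-for-integer at load time; migraine with
#' aura (1.2) and chronic migraine (1.3) are conjunct-list-defined only,
#' because their published expansions do not follow a single at-least-k
#' convention.
#'
#' Excluded by construction: "probable" diagnoses, complications of migraine,
#' the episodic syndromes, secondary headaches, and the ubiquitous ICHD-3
#' criterion "not better accounted for by another ICHD-3 diagnosis" (which is
#' recursive over the whole classification and is not encodable).
#'
#' @param path path to a criteria TSV with columns `code`, `diagnosis`,
#'   `encoding` (one row per encoding).
#' @param registry a `prime_registry`.
#' @param formulas_path optional path to a JSON file of formula definitions
#'   keyed by diagnosis code; each is validated against the encodings.
#' @return a `criteria_catalog`: a named list (by ICHD-3 code) of
#'   `diagnosis_criteria` entries with fields `code`, `name`, `id`,
#'   `conjuncts`, `encodings`, `support` (logical conjunct-by-prime incidence
#'   matrix) and optionally `formula`.
#' @examples
#' cat21 <- headache_catalog()
#' length(cat21)
#' sum(vapply(cat21, function(d) length(d$encodings), integer(1)))
#' @export
load_catalog <- function(path, registry = headache_registry(),
                         formulas_path = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                   colClasses = "character")
  if (!all(c("code", "diagnosis", "encoding") %in% names(df)))
    stop("catalog file needs columns 'code', 'diagnosis', 'encoding'",
         call. = FALSE)
  formulas <- list()
  if (!is.null(formulas_path))
    formulas <- jsonlite::fromJSON(formulas_path, simplifyVector = FALSE)

  codes <- unique(df$code)
  entries <- lapply(codes, function(cd) {
    rows <- df[df$code == cd, ]
    name <- rows$diagnosis[[1L]]
    values <- as_code(rows$encoding)
    expo <- factor_matrix(values, registry)
    if (any(expo > 1L))
      stop("catalog encodings must be square-free; offender in ", cd,
           call. = FALSE)
    conjuncts <- lapply(seq_len(nrow(expo)), function(i)
      registry$name[expo[i, ] == 1L])
    recomputed <- encode_criteria(conjuncts, registry)
    if (!setequal(recomputed, values) || length(recomputed) != length(values))
      stop("encoding mismatch for ", cd, " ", name,
           "; missing: ", paste(setdiff(recomputed, values), collapse = ", "),
           "; unexpected: ", paste(setdiff(values, recomputed), collapse = ", "),
           call. = FALSE)
    ord <- big_order(values)
    entry <- list(code = cd, name = name, id = paste(cd, name),
                  conjuncts = conjuncts[ord],
                  encodings = values[ord],
                  support = expo[ord, , drop = FALSE] > 0L)
    if (!is.null(formulas[[cd]])) {
      f <- formula_from_list(formulas[[cd]])
      from_formula <- encode_criteria(to_dnf(f), registry)
      if (!identical(from_formula, entry$encodings))
        stop("formula definition for ", cd,
             " does not reproduce its encodings", call. = FALSE)
      entry$formula <- f
    }
    class(entry) <- "diagnosis_criteria"
    entry
  })
  names(entries) <- codes
  structure(entries, class = "criteria_catalog", registry = registry)
}

#' @rdname load_catalog
#' @export
headache_catalog <- function() {
  if (is.null(the$catalog))
    the$catalog <- load_catalog(ichdprime_file("criteria-encodings.tsv"),
                                headache_registry(),
                                ichdprime_file("criteria-formulas.json"))
  the$catalog
}

#' @export
print.diagnosis_criteria <- function(x, ...) {
  cat("<diagnosis_criteria> ", x$id, "\n  ", length(x$encodings),
      " encoding(s); ", sum(colSums(x$support) > 0),
      " distinct characteristics",
      if (!is.null(x$formula)) "; formula-defined" else "", "\n", sep = "")
  invisible(x)
}

#' @export
print.criteria_catalog <- function(x, ...) {
  n_enc <- vapply(x, function(d) length(d$encodings), integer(1))
  cat("<criteria_catalog> ", length(x), " diagnoses, ", sum(n_enc),
      " encodings\n", sep = "")
  for (d in x) cat(sprintf("  %-6s %-50s %4d\n", d$code, d$name,
                           length(d$encodings)))
  invisible(x)
}

#' Audit a catalog
#'
#' Reports per-diagnosis encoding counts, square-freeness, factor-base closure
#' (every prime factor of every encoding is a registry prime) and grand
#' totals.
#'
#' @param catalog a `criteria_catalog`.
#' @param registry a `prime_registry`.
#' @return a `catalog_audit` list with `per_diagnosis` (data frame),
#'   `total_encodings`, `all_square_free`, `factor_base_closed`.
#' @export
audit_catalog <- function(catalog, registry = headache_registry()) {
  per <- data.frame(
    code = vapply(catalog, `[[`, character(1), "code"),
    diagnosis = vapply(catalog, `[[`, character(1), "name"),
    n_encodings = vapply(catalog, function(d) length(d$encodings), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  square_free <- TRUE
  closed <- TRUE
  for (d in catalog) {
    if (length(d$encodings) == 0L) next
    f <- .big_factor(d$encodings, registry$prime)
    if (any(f$exponents > 1L)) square_free <- FALSE
    if (any(f$residue != "1")) closed <- FALSE
  }
  out <- list(per_diagnosis = per,
              total_encodings = sum(per$n_encodings),
              all_square_free = square_free,
              factor_base_closed = closed)
  class(out) <- "catalog_audit"
  out
}

#' @export
print.catalog_audit <- function(x, ...) {
  cat("Catalog audit:", nrow(x$per_diagnosis), "diagnoses,",
      x$total_encodings, "encodings\n")
  cat("  square-free:", x$all_square_free,
      "| factor base closed:", x$factor_base_closed, "\n")
  print(x$per_diagnosis)
  invisible(x)
}

#' The contradiction table
#'
#' A hand-curated list of pairs of characteristics that cannot both hold of a
#' single headache (mutually exclusive durations, a finding and its negation,
#' incompatible frequencies, ...). Each pair is encoded as the product of its
#' two primes; a profile or composite is inconsistent exactly when it is
#' divisible by one of these two-prime codes.
#'
#' The bundled table carries 99 rows as published; 5 rows repeat an earlier
#' pair with the order reversed, so 94 distinct unordered pairs remain after
#' normalization. Divisibility filtering is unaffected by the repeats.
#'
#' @param path path to a TSV with columns `a` and `b` (characteristic labels).
#' @param registry a `prime_registry`.
#' @return a `contradiction_set`: a data frame with columns `a`, `b`
#'   (canonical labels), `prime_a`, `prime_b` and `code` (the two-prime
#'   product), one row per distinct unordered pair; attribute `n_rows` is the
#'   number of rows read before deduplication.
#' @examples
#' ctr <- headache_contradictions()
#' nrow(ctr)          # distinct pairs
#' attr(ctr, "n_rows")  # rows as published
#' @export
load_contradictions <- function(path, registry = headache_registry()) {
  df <- read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("a", "b") %in% names(df)))
    stop("contradiction file needs columns 'a' and 'b'", call. = FALSE)
  norm <- attr(registry, "norm")
  ia <- match(normalize_label(df$a), norm)
  ib <- match(normalize_label(df$b), norm)
  bad <- is.na(ia) | is.na(ib)
  if (any(bad))
    stop("unresolvable contradiction rows: ",
         paste(sprintf("(%s, %s)", df$a[bad], df$b[bad]), collapse = "; "),
         call. = FALSE)
  if (any(ia == ib))
    stop("a contradiction pair must join two distinct characteristics",
         call. = FALSE)
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  keep <- !duplicated(paste(lo, hi))
  out <- data.frame(
    a = registry$name[lo[keep]],
    b = registry$name[hi[keep]],
    prime_a = registry$prime[lo[keep]],
    prime_b = registry$prime[hi[keep]],
    stringsAsFactors = FALSE)
  out$code <- .big_mul(as.character(out$prime_a), as.character(out$prime_b))
  attr(out, "n_rows") <- nrow(df)
  class(out) <- c("contradiction_set", "data.frame")
  out
}

#' @rdname load_contradictions
#' @export
headache_contradictions <- function() {
  if (is.null(the$contradictions))
    the$contradictions <- load_contradictions(
      ichdprime_file("contradictions.tsv"), headache_registry())
  the$contradictions
}

#' @export
print.contradiction_set <- function(x, ...) {
  cat("<contradiction_set> ", nrow(x), " distinct pairs (",
      attr(x, "n_rows"), " rows as curated)\n", sep = "")
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
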