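#' Enumerate pairwise encoding products across the catalog
#'
#' Every take-two combination of criteria encodings, multiplied together,
#' describes a candidate clinical profile satisfying two conjuncts at once.
#' Pairings are generated unordered (each unordered pair of encodings exactly
#' once), in deterministic catalog-then-encoding order. With
#' `within = FALSE` only cross-diagnosis pairings are generated; with
#' `within = TRUE` pairings of two conjuncts of the same diagnosis are
#' included as well, which is the convention under which the published
#' composite count is reproduced (see the summary of
#' [enumerate_dual_diagnoses()]).
#'
#' A characteristic shared by the two conjuncts yields a squared prime in the
#' composite; the composite is kept as-is, since divisibility by the
#' two-prime contradiction codes is unaffected.
#'
#' @param catalog a `criteria_catalog`.
#' @param within include same-diagnosis conjunct pairings?
#' @param composites compute the composite product strings? (Exact but
#'   costlier than the pairing bookkeeping; filtering does not need them.)
#' @return a `pairing_records` data frame with one row per unordered pairing:
#'   `diag_a`, `diag_b` (ICHD-3 codes), `conjunct_a`, `conjunct_b` (indices
#'   into each diagnosis's encoding list), `encoding_a`, `encoding_b`, and
#'   `composite` (if requested); the conjunct-by-prime incidence needed for
#'   filtering travels in attributes.
#' @examples
#' toy <- new_catalog(list(D1 = list(c("a", "b")), D2 = list(c("c", "d"))),
#'                    toy_registry(c("a", "b", "c", "d")))
#' enumerate_pairings(toy)$composite
#' @export
enumerate_pairings <- function(catalog, within = FALSE, composites = TRUE) {
  flat_diag <- unlist(lapply(catalog, function(d)
    rep(d$code, length(d$encodings))), use.names = FALSE)
  flat_idx <- unlist(lapply(catalog, function(d)
    seq_along(d$encodings)), use.names = FALSE)
  flat_enc <- unlist(lapply(catalog, `[[`, "encodings"), use.names = FALSE)
  support <- do.call(rbind, lapply(catalog, `[[`, "support"))
  n <- length(flat_enc)
  if (n < 2L) stop("catalog must contribute at least two encodings", call. = FALSE)

  # all unordered index pairs i < j
  ia <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  ib <- sequence((n - 1L):1L, from = 2L:n)
  if (!within) {
    keep <- flat_diag[ia] != flat_diag[ib]
    ia <- ia[keep]; ib <- ib[keep]
  }
  records <- data.frame(
    diag_a = flat_diag[ia], diag_b = flat_diag[ib],
    conjunct_a = flat_idx[ia], conjunct_b = flat_idx[ib],
    encoding_a = flat_enc[ia], encoding_b = flat_enc[ib],
    stringsAsFactors = FALSE)
  if (composites)
    records$composite <- .big_mul(records$encoding_a, records$encoding_b)
  attr(records, "support") <- support
  attr(records, "support_primes") <- attr(catalog, "registry")$prime
  attr(records, "flat_a") <- ia
  attr(records, "flat_b") <- ib
  class(records) <- c("pairing_records", "data.frame")
  records
}

#' Filter pairings against the contradiction table
#'
#' Keeps exactly the records whose composite is divisible by no contradiction
#' code. Because every contradiction code is the product of two distinct
#' primes, divisibility is equivalent to both primes appearing in the union
#' of the two conjuncts' supports, which is how the filter is computed; the
#' equivalence with literal long division is asserted in the test suite.
#'
#' @param records a `pairing_records` data frame from [enumerate_pairings()].
#' @param contradictions a `contradiction_set`.
#' @return the surviving records (attributes preserved).
#' @export
filter_consistent <- function(records, contradictions = headache_contradictions()) {
  support <- attr(records, "support")
  primes <- attr(records, "support_primes")
  ia <- attr(records, "flat_a")
  ib <- attr(records, "flat_b")
  if (is.null(support) || is.null(ia))
    stop("records must come from enumerate_pairings()", call. = FALSE)
  ok <- rep(TRUE, nrow(records))
  for (k in seq_len(nrow(contradictions))) {
    ca <- match(contradictions$prime_a[k], primes)
    cb <- match(contradictions$prime_b[k], primes)
    has_a <- support[ia, ca] | support[ib, ca]
    has_b <- support[ia, cb] | support[ib, cb]
    ok <- ok & !(has_a & has_b)
  }
  out <- records[ok, , drop = FALSE]
  attr(out, "support") <- support
  attr(out, "support_primes") <- primes
  attr(out, "flat_a") <- ia[ok]
  attr(out, "flat_b") <- ib[ok]
  class(out) <- class(records)
  out
}

#' Deduplicate surviving pairings to diagnosis pairs
#'
#' Many distinct composites witness the same unordered pair of diagnoses;
#' deduplication yields the set of logically possible dual diagnoses.
#' Same-diagnosis pairings, if present, are not dual diagnoses and are
#' dropped here.
#'
#' @param records surviving `pairing_records`.
#' @param catalog the `criteria_catalog` the records came from (for names).
#' @return a data frame with one row per distinct unordered diagnosis pair:
#'   `code_a`, `code_b`, `diagnosis_a`, `diagnosis_b`, ordered by code.
#' @export
dedupe_pairs <- function(records, catalog = headache_catalog()) {
  cross <- records[records$diag_a != records$diag_b, , drop = FALSE]
  swap <- mixed_code_gt(cross$diag_a, cross$diag_b)
  lo <- ifelse(swap, cross$diag_b, cross$diag_a)
  hi <- ifelse(swap, cross$diag_a, cross$diag_b)
  key <- paste(lo, hi)
  keep <- !duplicated(key)
  out <- data.frame(code_a = lo[keep], code_b = hi[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(code_rank(out$code_a), code_rank(out$code_b)), ,
             drop = FALSE]
  nm <- vapply(catalog, `[[`, character(1), "name")
  out$diagnosis_a <- unname(nm[out$code_a])
  out$diagnosis_b <- unname(nm[out$code_b])
  rownames(out) <- NULL
  out
}

# numeric-aware ordering of dotted ICHD-3 codes ("4.6.1" etc.)
code_rank <- function(code) {
  parts <- strsplit(code, ".", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    sum(p * 1000^((3 - seq_along(p))))
  }, numeric(1))
}

mixed_code_gt <- function(a, b) code_rank(a) > code_rank(b)

#' Run the full dual-diagnosis enumeration
#'
#' Enumerates all take-two encoding pairings, filters out those containing a
#' contradictory characteristic pair, and deduplicates the survivors to the
#' set of logically possible dual diagnoses. The summary reports both
#' counting conventions side by side: unordered vs ordered (x2), and
#' cross-diagnosis-only vs all pairings including same-diagnosis conjunct
#' pairs. The published total of 253,842 composites corresponds to ordered
#' counting over all pairings.
#'
#' @param catalog a `criteria_catalog`.
#' @param contradictions a `contradiction_set`.
#' @param within include same-diagnosis pairings in the enumeration
#'   (default `TRUE`, the convention of the published count).
#' @param composites carry composite product strings on the records.
#' @return a `dual_diagnosis_result` list: `survivors` (records), `pairs`
#'   (deduplicated diagnosis pairs) and `summary` (named list of counts).
#' @examples
#' \donttest{
#' res <- enumerate_dual_diagnoses()
#' res$summary$survivors_ordered_all
#' nrow(res$pairs)
#' }
#' @export
enumerate_dual_diagnoses <- function(catalog = headache_catalog(),
                                     contradictions = headache_contradictions(),
                                     within = TRUE, composites = FALSE) {
  records <- enumerate_pairings(catalog, within = within,
                                composites = composites)
  survivors <- filter_consistent(records, contradictions)
  pairs <- dedupe_pairs(survivors, catalog)
  cross_total <- sum(records$diag_a != records$diag_b)
  cross_surv <- sum(survivors$diag_a != survivors$diag_b)
  summary <- list(
    pairings_unordered_all = nrow(records),
    pairings_unordered_cross = cross_total,
    survivors_unordered_all = nrow(survivors),
    survivors_ordered_all = 2L * nrow(survivors),
    survivors_unordered_cross = cross_surv,
    survivors_ordered_cross = 2L * cross_surv,
    unique_pairs = nrow(pairs))
  structure(list(survivors = survivors, pairs = pairs, summary = summary),
            class = "dual_diagnosis_result")
}

#' @export
print.dual_diagnosis_result <- function(x, ...) {
  s <- x$summary
  cat("<dual_diagnosis_result>\n")
  cat("  pairings (unordered):", s$pairings_unordered_all,
      "| cross-diagnosis:", s$pairings_unordered_cross, "\n")
  cat("  survivors unordered/ordered:", s$survivors_unordered_all, "/",
      s$survivors_ordered_all, "\n")
  cat("  cross-diagnosis survivors unordered/ordered:",
      s$survivors_unordered_cross, "/", s$survivors_ordered_cross, "\n")
  cat("  distinct dual-diagnosis pairs:", s$unique_pairs, "\n")
  invisible(x)
}

#' Write enumeration outputs to a directory
#'
#' Writes the surviving records as TSV, the deduplicated pair list as TSV and
#' the summary as JSON, for audit.
#'
#' @param result a `dual_diagnosis_result`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_dual_diagnoses <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(survivors = file.path(dir, "survivors.tsv"),
             pairs = file.path(dir, "dual-diagnosis-pairs.tsv"),
             summary = file.path(dir, "summary.json"))
  write.table(as.data.frame(result$survivors), paths[["survivors"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$pairs, paths[["pairs"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$summary, paths[["summary"]], auto_unbox = TRUE)
  invisible(paths)
}
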