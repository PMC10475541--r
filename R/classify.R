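#' Overlap curation for the dual-diagnosis analysis
#'
#' The classifier sorts each dual-diagnosis pair into one of three classes:
#' subset-intersecting, intersecting without a subset relationship, or
#' non-intersecting. The subset test is pure arithmetic (divisibility between
#' criteria encodings). The intersection test, however, asks whether two
#' diagnoses overlap *phenotypically*, and a purely literal shared-prime test
#' does not capture that: many diagnoses share only generic bookkeeping
#' characteristics (minimum episode counts, pain severity, laterality,
#' three-month chronicity, the cranial autonomic accompaniments common to all
#' trigeminal autonomic cephalalgias), while genuinely overlapping duration
#' ranges ("1 to 600 s" vs "Up to few seconds") are distinct labels with
#' distinct primes.
#'
#' The curation is therefore shipped as three transparent, editable data
#' layers:
#' \describe{
#'   \item{nonspecific}{characteristic labels excluded as evidence of
#'     phenotypic overlap (16 generic labels);}
#'   \item{overlap}{unordered label pairs whose clinical ranges genuinely
#'     intersect (7 duration/onset-window pairs);}
#'   \item{pair_annotations}{unordered diagnosis-code pairs judged to overlap
#'     as whole phenotypes where no single label pair expresses it (2
#'     entries, both involving the strictly side-locked nummular headache).}
#' }
#' `empty_curation()` disables all three layers, reducing the intersection
#' test to the literal shared-prime rule (equivalently `gcd > 1` on the
#' products of all encodings).
#'
#' @param overlap_path,nonspecific_path,annotations_path paths to the three
#'   TSV layers; each may be `NULL` for an empty layer.
#' @param registry a `prime_registry` used to validate labels.
#' @return an `overlap_curation` list with elements `overlap` (data frame
#'   `a`, `b`, `rationale`), `nonspecific` (character), `pair_annotations`
#'   (data frame `diagnosis_a`, `diagnosis_b`, `rationale`).
#' @examples
#' cur <- headache_curation()
#' nrow(cur$overlap)
#' @export
load_curation <- function(overlap_path = NULL, nonspecific_path = NULL,
                          annotations_path = NULL,
                          registry = headache_registry()) {
  overlap <- if (is.null(overlap_path))
    data.frame(a = character(0), b = character(0), rationale = character(0),
               stringsAsFactors = FALSE)
  else read.delim(overlap_path, stringsAsFactors = FALSE, encoding = "UTF-8")
  nonspecific <- if (is.null(nonspecific_path)) character(0)
  else read.delim(nonspecific_path, stringsAsFactors = FALSE,
                  encoding = "UTF-8")$name
  annotations <- if (is.null(annotations_path))
    data.frame(diagnosis_a = character(0), diagnosis_b = character(0),
               rationale = character(0), stringsAsFactors = FALSE)
  else read.delim(annotations_path, stringsAsFactors = FALSE,
                  colClasses = "character", encoding = "UTF-8")
  # all labels must resolve, and an overlap pair must not be contradictory
  if (nrow(overlap)) {
    lookup_prime(registry, overlap$a)
    lookup_prime(registry, overlap$b)
    if (any(normalize_label(overlap$a) == normalize_label(overlap$b)))
      stop("an overlap pair must join two distinct labels", call. = FALSE)
  }
  if (length(nonspecific)) lookup_prime(registry, nonspecific)
  structure(list(overlap = overlap, nonspecific = nonspecific,
                 pair_annotations = annotations),
            class = "overlap_curation")
}

#' @rdname load_curation
#' @export
headache_curation <- function() {
  if (is.null(the$curation))
    the$curation <- load_curation(
      ichdprime_file("overlap-curation.tsv"),
      ichdprime_file("nonspecific-characteristics.tsv"),
      ichdprime_file("pair-overlap-annotations.tsv"),
      headache_registry())
  the$curation
}

#' @rdname load_curation
#' @export
empty_curation <- function() {
  structure(list(
    overlap = data.frame(a = character(0), b = character(0),
                         rationale = character(0), stringsAsFactors = FALSE),
    nonspecific = character(0),
    pair_annotations = data.frame(diagnosis_a = character(0),
                                  diagnosis_b = character(0),
                                  rationale = character(0),
                                  stringsAsFactors = FALSE)),
    class = "overlap_curation")
}

#' All characteristics appearing in a diagnosis's criteria
#'
#' The union of the decoded conjuncts over all encodings.
#'
#' @param criteria a `diagnosis_criteria` entry.
#' @return sorted character vector of labels.
#' @examples
#' characteristic_union(headache_catalog()[["4.10"]])
#' @export
characteristic_union <- function(criteria) {
  sort(unique(unlist(criteria$conjuncts, use.names = FALSE)))
}

#' Subset relationship between two diagnoses
#'
#' One diagnosis is subset-related to another when some conjunct of one is a
#' superset of some conjunct of the other, i.e. some encoding of one is
#' divisible by some encoding of the other: one way of satisfying the first
#' outright satisfies the second. The test is existential over conjunct
#' pairs, which is the reading under which chronic migraine (whose conjuncts
#' extend the migraine-without-aura or migraine-with-aura branches) is
#' subset-related to both parent migraine diagnoses.
#'
#' @param c1,c2 `diagnosis_criteria` entries.
#' @return a list: `related` (logical) and `witness` (the first dividing pair
#'   of encodings, as `c(divisor, multiple)`, or `NULL`).
#' @examples
#' cat21 <- headache_catalog()
#' subset_related(cat21[["1.3"]], cat21[["1.1"]])$related
#' @export
subset_related <- function(c1, c2) {
  for (swap in c(FALSE, TRUE)) {
    small <- if (swap) c2 else c1
    big <- if (swap) c1 else c2
    for (e in small$encodings) {
      hit <- .big_divisible(big$encodings, rep(e, length(big$encodings)))
      if (any(hit))
        return(list(related = TRUE,
                    witness = c(divisor = e,
                                multiple = big$encodings[hit][[1L]])))
    }
  }
  list(related = FALSE, witness = NULL)
}

#' Phenotypic intersection between two diagnoses
#'
#' True when the two diagnoses' characteristic unions share a label that is
#' not curated as nonspecific, when some cross pair of their labels is a
#' curated overlap pair, or when the diagnosis pair itself carries a curated
#' pair-level overlap annotation. With `empty_curation()` this reduces to the
#' literal shared-prime test.
#'
#' @param c1,c2 `diagnosis_criteria` entries.
#' @param curation an `overlap_curation`.
#' @return a list: `intersecting` (logical) and `evidence` (data frame with
#'   columns `type` -- `"shared"`, `"overlap"` or `"annotation"` -- and
#'   `detail`).
#' @examples
#' cat21 <- headache_catalog()
#' intersecting(cat21[["3.2"]], cat21[["3.4"]], empty_curation())$intersecting
#' @export
intersecting <- function(c1, c2, curation = headache_curation()) {
  u1 <- characteristic_union(c1)
  u2 <- characteristic_union(c2)
  shared <- setdiff(intersect(u1, u2), curation$nonspecific)
  evidence <- data.frame(type = character(0), detail = character(0),
                         stringsAsFactors = FALSE)
  if (length(shared))
    evidence <- rbind(evidence, data.frame(type = "shared", detail = shared,
                                           stringsAsFactors = FALSE))
  if (nrow(curation$overlap)) {
    hit <- (curation$overlap$a %in% u1 & curation$overlap$b %in% u2) |
           (curation$overlap$a %in% u2 & curation$overlap$b %in% u1)
    if (any(hit))
      evidence <- rbind(evidence, data.frame(
        type = "overlap",
        detail = sprintf("%s ~ %s", curation$overlap$a[hit],
                         curation$overlap$b[hit]),
        stringsAsFactors = FALSE))
  }
  ann <- curation$pair_annotations
  if (nrow(ann)) {
    hit <- (ann$diagnosis_a == c1$code & ann$diagnosis_b == c2$code) |
           (ann$diagnosis_a == c2$code & ann$diagnosis_b == c1$code)
    if (any(hit))
      evidence <- rbind(evidence, data.frame(
        type = "annotation", detail = ann$rationale[hit],
        stringsAsFactors = FALSE))
  }
  list(intersecting = nrow(evidence) > 0L, evidence = evidence)
}

#' Classify dual-diagnosis pairs
#'
#' Labels each pair `SUBSET_INTERSECTING`, `INTERSECTING_NON_SUBSET` or
#' `NON_INTERSECTING`, with precedence subset > intersecting >
#' non-intersecting, and reports per-class counts. The classification is
#' symmetric in each pair's order.
#'
#' @param pairs a data frame with columns `code_a`, `code_b` (e.g. from
#'   [dedupe_pairs()]).
#' @param catalog a `criteria_catalog`.
#' @param curation an `overlap_curation`.
#' @return a `pair_classification` list: `classes` (the input data frame plus
#'   `label` and `evidence` columns) and `counts` (named integer vector over
#'   the three labels).
#' @examples
#' \donttest{
#' res <- enumerate_dual_diagnoses()
#' cls <- classify_pairs(res$pairs)
#' cls$counts
#' }
#' @export
classify_pairs <- function(pairs, catalog = headache_catalog(),
                           curation = headache_curation()) {
  labels <- character(nrow(pairs))
  evidence <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    c1 <- catalog[[pairs$code_a[i]]]
    c2 <- catalog[[pairs$code_b[i]]]
    sub <- subset_related(c1, c2)
    if (sub$related) {
      labels[i] <- "SUBSET_INTERSECTING"
      evidence[i] <- sprintf("%s divides %s", sub$witness[["divisor"]],
                             sub$witness[["multiple"]])
      next
    }
    inter <- intersecting(c1, c2, curation)
    if (inter$intersecting) {
      labels[i] <- "INTERSECTING_NON_SUBSET"
      evidence[i] <- paste(inter$evidence$detail, collapse = "; ")
    } else {
      labels[i] <- "NON_INTERSECTING"
      evidence[i] <- ""
    }
  }
  classes <- cbind(pairs, label = labels, evidence = evidence,
                   stringsAsFactors = FALSE)
  lvl <- c("SUBSET_INTERSECTING", "INTERSECTING_NON_SUBSET", "NON_INTERSECTING")
  counts <- setNames(tabulate(factor(labels, levels = lvl), nbins = 3L), lvl)
  structure(list(classes = classes, counts = counts),
            class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  cat("<pair_classification> ", nrow(x$classes), " pairs\n", sep = "")
  for (l in names(x$counts)) cat(sprintf("  %-24s %4d\n", l, x$counts[[l]]))
  invisible(x)
}
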