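#' Criteria formulas
#'
#' ICHD-3 criteria are propositional statements over clinical characteristics.
#' A formula is built from four node kinds: `hx_atom(name)` for a single
#' characteristic, `hx_all(...)` for a conjunction, `hx_any(...)` for a
#' disjunction, and `hx_at_least(k, ...)` for the classification's frequent
#' "at least k of the following n" clauses. Negated findings are ordinary
#' atoms over negation characteristics ("No photophobia"); there is no NOT
#' node.
#'
#' @param name characteristic label.
#' @param ... child formulas (or, for convenience, bare label strings, which
#'   are promoted to atoms).
#' @param k minimum number of children that must hold, `1 <= k <= n`.
#' @return an `hx_formula`.
#' @examples
#' f <- hx_all("Greater than 5 episodes", "4 to 72 h",
#'             hx_at_least(2, "Unilateral", "Pulsating",
#'                         "Moderate to severe",
#'                         "Aggravated by physical activity"),
#'             hx_any("Nausea/vomiting",
#'                    hx_all("Photophobia", "Phonophobia")))
#' length(to_dnf(f))
#' @export
hx_atom <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(kind = "atom", name = name), class = "hx_formula")
}

as_formula_node <- function(x) {
  if (inherits(x, "hx_formula")) return(x)
  if (is.character(x) && length(x) == 1L) return(hx_atom(x))
  stop("formula children must be hx_formula objects or single labels",
       call. = FALSE)
}

#' @rdname hx_atom
#' @export
hx_all <- function(...) {
  children <- lapply(list(...), as_formula_node)
  if (length(children) < 1L) stop("hx_all needs at least one child", call. = FALSE)
  structure(list(kind = "all", children = children), class = "hx_formula")
}

#' @rdname hx_atom
#' @export
hx_any <- function(...) {
  children <- lapply(list(...), as_formula_node)
  if (length(children) < 1L) stop("hx_any needs at least one child", call. = FALSE)
  structure(list(kind = "any", children = children), class = "hx_formula")
}

#' @rdname hx_atom
#' @export
hx_at_least <- function(k, ...) {
  children <- lapply(list(...), as_formula_node)
  k <- as.integer(k)
  if (k < 1L || k > length(children))
    stop("hx_at_least requires 1 <= k <= number of children", call. = FALSE)
  structure(list(kind = "at_least", k = k, children = children),
            class = "hx_formula")
}

#' Expand an at-least-k clause to its AND-groups
#'
#' Returns all subsets of the items of cardinality >= k, each as an `hx_all`
#' group: sum over j = k..n of choose(n, j) groups. The expansion is
#' deliberately NOT minimized (supersets are retained); the catalog's
#' published encodings follow this convention, e.g. the migraine-without-aura
#' "at least 2 of 4" clause contributes 11 groups (6 pairs + 4 triples + 1
#' quadruple), not the 6 of a minimized normal form. Order is deterministic:
#' by subset size, then lexicographically by item position.
#'
#' @param k minimum cardinality, `1 <= k <= length(items)`.
#' @param items a list of formulas (or labels).
#' @return a list of `hx_all` groups.
#' @examples
#' length(expand_at_least(2, list("a", "b", "c", "d")))  # 11
#' @export
expand_at_least <- function(k, items) {
  items <- lapply(items, as_formula_node)
  n <- length(items)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k out of range", call. = FALSE)
  groups <- list()
  for (size in k:n) {
    idx <- utils::combn(n, size, simplify = FALSE)
    for (sel in idx)
      groups[[length(groups) + 1L]] <- do.call(hx_all, items[sel])
  }
  groups
}

#' Disjunctive normal form of a formula
#'
#' Expands a formula to a list of conjuncts (character vectors of
#' characteristic labels) whose disjunction is logically equivalent to the
#' formula -- equivalent-with-redundancy when `at_least` nodes are present,
#' since their expansion keeps non-minimal subsets. Within a conjunct repeated
#' atoms collapse; exact duplicate conjuncts are dropped. No absorption or
#' subsumption across conjuncts is performed, by design: the bundled catalog's
#' encoding counts require the non-minimized convention.
#'
#' @param formula an `hx_formula`.
#' @return a list of character vectors, each sorted alphabetically; order of
#'   conjuncts is deterministic.
#' @examples
#' to_dnf(hx_all("a", hx_any("b", "c")))
#' @export
to_dnf <- function(formula) {
  stopifnot(inherits(formula, "hx_formula"))
  conjuncts <- dnf_rec(formula)
  keys <- vapply(conjuncts, paste, character(1), collapse = "\r")
  conjuncts[!duplicated(keys)]
}

dnf_rec <- function(f) {
  switch(f$kind,
    atom = list(f$name),
    any = do.call(c, lapply(f$children, dnf_rec)),
    at_least = do.call(c, lapply(expand_at_least(f$k, f$children), dnf_rec)),
    all = {
      parts <- lapply(f$children, dnf_rec)
      out <- list(character(0))
      for (part in parts) {
        out <- unlist(lapply(out, function(acc) {
          lapply(part, function(con) sort(unique(c(acc, con))))
        }), recursive = FALSE)
      }
      out
    },
    stop("malformed formula node", call. = FALSE)
  )
}

#' Evaluate a formula against a profile
#'
#' Standard propositional semantics: an atom is true iff its label is in the
#' profile (after canonical normalization); `all`/`any` are conjunction and
#' disjunction; `at_least(k, ...)` is true iff at least k children are true.
#'
#' @param formula an `hx_formula`.
#' @param profile character vector of characteristic labels.
#' @return logical scalar.
#' @examples
#' evaluate_formula(hx_at_least(2, "a", "b", "c"), c("a", "c"))
#' @export
evaluate_formula <- function(formula, profile) {
  stopifnot(inherits(formula, "hx_formula"))
  prof <- normalize_label(profile)
  eval_rec <- function(f) {
    switch(f$kind,
      atom = normalize_label(f$name) %in% prof,
      all = all(vapply(f$children, eval_rec, logical(1))),
      any = any(vapply(f$children, eval_rec, logical(1))),
      at_least = sum(vapply(f$children, eval_rec, logical(1))) >= f$k,
      stop("malformed formula node", call. = FALSE)
    )
  }
  eval_rec(formula)
}

#' Read and write formulas as JSON
#'
#' The serialized form is a nested object with a `kind` field (`"atom"`,
#' `"all"`, `"any"`, `"at_least"`), a `name` for atoms, `children` for the
#' operators, and `k` for `at_least` nodes.
#'
#' @param x an `hx_formula` (for `formula_to_json`) or a JSON string / parsed
#'   list (for `formula_from_json`).
#' @return `formula_to_json()`: a JSON string; `formula_from_json()`: an
#'   `hx_formula`.
#' @export
formula_to_json <- function(x) {
  jsonlite::toJSON(formula_to_list(x), auto_unbox = TRUE)
}

formula_to_list <- function(f) {
  stopifnot(inherits(f, "hx_formula"))
  switch(f$kind,
    atom = list(kind = "atom", name = f$name),
    all = list(kind = "all", children = lapply(f$children, formula_to_list)),
    any = list(kind = "any", children = lapply(f$children, formula_to_list)),
    at_least = list(kind = "at_least", k = f$k,
                    children = lapply(f$children, formula_to_list))
  )
}

#' @rdname formula_to_json
#' @export
formula_from_json <- function(x) {
  if (is.character(x)) x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  formula_from_list(x)
}

formula_from_list <- function(node) {
  switch(as.character(node$kind),
    atom = hx_atom(node$name),
    all = do.call(hx_all, lapply(node$children, formula_from_list)),
    any = do.call(hx_any, lapply(node$children, formula_from_list)),
    at_least = do.call(hx_at_least,
                       c(list(node$k), lapply(node$children, formula_from_list))),
    stop("unknown formula node kind: ", node$kind, call. = FALSE)
  )
}

#' @export
print.hx_formula <- function(x, ...) {
  fmt <- function(f) {
    switch(f$kind,
      atom = f$name,
      all = paste0("(", paste(vapply(f$children, fmt, character(1)),
                              collapse = " AND "), ")"),
      any = paste0("(", paste(vapply(f$children, fmt, character(1)),
                              collapse = " OR "), ")"),
      at_least = paste0("atLeast(", f$k, "; ",
                        paste(vapply(f$children, fmt, character(1)),
                              collapse = ", "), ")")
    )
  }
  cat(fmt(x), "\n")
  invisible(x)
}
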