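# Toy knowledge base used across tests: four labels on the first four primes.
toy_reg <- toy_registry(c("a", "b", "c", "d"))

toy_contradictions <- function(pairs, registry = toy_reg) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  write.table(data.frame(a = vapply(pairs, `[[`, "", 1L),
                         b = vapply(pairs, `[[`, "", 2L)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_contradictions(path, registry)
}

# random formula generator over a fixed atom pool (includes at_least nodes)
random_formula <- function(atoms, depth = 3L) {
  if (depth == 0L || runif(1) < 0.35) return(hx_atom(sample(atoms, 1L)))
  n_children <- sample(2:3, 1L)
  children <- replicate(n_children, random_formula(atoms, depth - 1L),
                        simplify = FALSE)
  kind <- sample(c("all", "any", "at_least"), 1L)
  switch(kind,
    all = do.call(hx_all, children),
    any = do.call(hx_any, children),
    at_least = do.call(hx_at_least,
                       c(list(sample.int(n_children, 1L)), children)))
}

# satisfaction of a DNF (list of label vectors) by a profile
dnf_satisfied <- function(conjuncts, profile) {
  any(vapply(conjuncts, function(cj) all(cj %in% profile), logical(1)))
}

# Euclid's algorithm on decimal strings, an independent route to shared-factor
# detection (uses only the big_mod primitive)
big_gcd <- function(a, b) {
  while (b != "0") {
    r <- big_mod(a, b)
    a <- b
    b <- r
  }
  a
}

# brute-force consistency of a label set against a contradiction table
brute_consistent <- function(labels, contradictions) {
  !any(contradictions$a %in% labels & contradictions$b %in% labels)
}
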