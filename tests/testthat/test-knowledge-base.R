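test_that("the bundled catalog has 21 diagnoses and 578 encodings", {
  cat21 <- headache_catalog()
  expect_length(cat21, 21L)
  n_enc <- vapply(cat21, function(d) length(d$encodings), integer(1))
  expect_identical(sum(n_enc), 578L)
  expect_identical(cat21[["4.10"]]$encodings, "1145520433")
  expect_identical(cat21[["4.2"]]$encodings, "2106413")
  expect_identical(length(cat21[["1.1"]]$encodings), 22L)
  expect_identical(cat21[["1.1"]]$encodings[[1L]], "7580756461")
  expect_true("223417708453" %in% cat21[["1.1"]]$encodings)
})

test_that("catalog loading fails fast on corruption", {
  src <- read.delim(ichdprime:::ichdprime_file("criteria-encodings.tsv"),
                    colClasses = "character")
  # altering one integer away from a product of registry primes
  bad <- src
  bad$encoding[bad$encoding == "1145520433"] <- as.character(1145520433 * 1009)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_catalog(path), "unencodable")
  # a squared factor is not a characteristic set
  bad2 <- src
  bad2$encoding[bad2$encoding == "2106413"] <- big_mul("2106413", "67")
  write.table(bad2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_catalog(path), "square-free")
})

test_that("catalog audit reports totals, square-freeness and closure", {
  audit <- audit_catalog(headache_catalog())
  expect_identical(audit$total_encodings, 578L)
  expect_true(audit$all_square_free)
  expect_true(audit$factor_base_closed)
  expect_identical(nrow(audit$per_diagnosis), 21L)
})

test_that("the contradiction table has 99 curated rows, 94 distinct pairs", {
  ctr <- headache_contradictions()
  expect_identical(attr(ctr, "n_rows"), 99L)
  expect_identical(nrow(ctr), 94L)
  # every code is a product of two distinct registry primes
  expect_true(all(ctr$prime_a != ctr$prime_b))
  expect_identical(ctr$code,
                   big_mul(as.character(ctr$prime_a), as.character(ctr$prime_b)))
  i <- which(ctr$a == "Bilateral location" & ctr$b == "Unilateral")
  expect_identical(ctr$code[i], "27719")
})

test_that("contradiction rows deduplicate as unordered pairs", {
  ctr <- toy_contradictions(list(c("a", "b"), c("b", "a"), c("A ", "b")))
  expect_identical(nrow(ctr), 1L)
  expect_identical(attr(ctr, "n_rows"), 3L)
  expect_error(toy_contradictions(list(c("a", "z"))), "unresolvable")
  expect_error(toy_contradictions(list(c("a", "A"))), "distinct")
})

test_that("criteria branches are internally satisfiable", {
  # no conjunct of any diagnosis contains both members of a contradiction
  # pair, so no contradiction code divides any single encoding
  cat21 <- headache_catalog()
  ctr <- headache_contradictions()
  for (d in cat21) {
    for (k in seq_len(nrow(ctr))) {
      both <- vapply(d$conjuncts, function(cj)
        all(c(ctr$a[k], ctr$b[k]) %in% cj), logical(1))
      expect_false(any(both))
    }
    # arithmetic double-check on the encodings themselves
    for (e in d$encodings)
      expect_false(any(divides(ctr$code, e)))
  }
})

test_that("bundled formula definitions reproduce their encoding blocks", {
  cat21 <- headache_catalog()
  with_formula <- names(which(vapply(cat21, function(d)
    !is.null(d$formula), logical(1))))
  expect_length(with_formula, 19L)
  expect_false(any(c("1.2", "1.3") %in% with_formula))
  for (cd in with_formula)
    expect_identical(encode_criteria(to_dnf(cat21[[cd]]$formula)),
                     cat21[[cd]]$encodings)
})
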