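test_that("characteristic unions decode the criteria", {
  cat21 <- headache_catalog()
  expect_setequal(characteristic_union(cat21[["4.10"]]),
                  c("Clearly remembered onset", "Constant",
                    "More than 3 months", "Unremitting within 24 h"))
  expect_setequal(characteristic_union(cat21[["4.2"]]),
                  c("Brought on by exercise", "Greater than 2 episodes",
                    "Less than 48 h"))
})

test_that("subset relationships are detected by cross-divisibility", {
  cat21 <- headache_catalog()
  expect_true(subset_related(cat21[["1.3"]], cat21[["1.1"]])$related)
  expect_true(subset_related(cat21[["1.3"]], cat21[["1.2"]])$related)
  expect_false(subset_related(cat21[["4.2"]], cat21[["4.10"]])$related)
  # witness divides as claimed
  w <- subset_related(cat21[["1.3"]], cat21[["1.1"]])$witness
  expect_true(divides(w[["divisor"]], w[["multiple"]]))
  expect_true(w[["divisor"]] %in% cat21[["1.1"]]$encodings)
})

test_that("intersection detection distinguishes literal, curated and none", {
  cat21 <- headache_catalog()
  none <- empty_curation()
  # cold-stimulus vs nummular share nothing at all
  expect_false(intersecting(cat21[["4.5"]], cat21[["4.8"]], none)$intersecting)
  # paroxysmal hemicrania vs hemicrania continua share a literal prime
  # (indomethacin response, 191)
  hit <- intersecting(cat21[["3.2"]], cat21[["3.4"]], none)
  expect_true(hit$intersecting)
  expect_true("Indomethacin responsive" %in% hit$evidence$detail)
  # primary stabbing vs SUNCT intersect only through curated range overlap
  cur <- headache_curation()
  expect_false(intersecting(cat21[["4.7"]], cat21[["3.3"]], none)$intersecting)
  sunct <- intersecting(cat21[["4.7"]], cat21[["3.3"]], cur)
  expect_true(sunct$intersecting)
  expect_true(any(sunct$evidence$type == "overlap"))
})

test_that("classification is symmetric and respects precedence", {
  cat21 <- headache_catalog()
  cur <- headache_curation()
  pairs <- data.frame(code_a = c("1.1", "1.1", "4.5"),
                      code_b = c("1.3", "1.2", "4.8"),
                      stringsAsFactors = FALSE)
  fwd <- classify_pairs(pairs, cat21, cur)
  rev_pairs <- data.frame(code_a = pairs$code_b, code_b = pairs$code_a,
                          stringsAsFactors = FALSE)
  bwd <- classify_pairs(rev_pairs, cat21, cur)
  expect_identical(fwd$classes$label, bwd$classes$label)
  expect_identical(fwd$classes$label,
                   c("SUBSET_INTERSECTING", "INTERSECTING_NON_SUBSET",
                     "NON_INTERSECTING"))
  # a subset pair always carries shared characteristics too
  expect_true(intersecting(cat21[["1.1"]], cat21[["1.3"]],
                           empty_curation())$intersecting)
})

test_that("with empty curation, intersection equals the gcd oracle", {
  cat21 <- headache_catalog()
  small <- Filter(function(d) length(d$encodings) <= 10L, cat21)
  codes <- names(small)
  set.seed(37)
  combos <- utils::combn(codes, 2L)
  pick <- sample(ncol(combos), 40L)
  for (i in pick) {
    c1 <- small[[combos[1L, i]]]
    c2 <- small[[combos[2L, i]]]
    p1 <- Reduce(big_mul, c1$encodings)
    p2 <- Reduce(big_mul, c2$encodings)
    expect_identical(intersecting(c1, c2, empty_curation())$intersecting,
                     big_gcd(p1, p2) != "1")
  }
})

test_that("a toy pair of disjoint one-conjunct diagnoses is non-intersecting", {
  toy <- new_catalog(list(D1 = list(c("a", "b")), D2 = list(c("c", "d"))),
                     toy_reg)
  pairs <- data.frame(code_a = "D1", code_b = "D2", stringsAsFactors = FALSE)
  cls <- classify_pairs(pairs, toy, empty_curation())
  expect_identical(cls$classes$label, "NON_INTERSECTING")
  expect_identical(unname(cls$counts), c(0L, 0L, 1L))
})
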