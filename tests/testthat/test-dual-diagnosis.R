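test_that("pairing enumeration covers each unordered cross pair once", {
  toy <- new_catalog(list(D1 = list(c("a", "b")), D2 = list(c("c", "d"))),
                     toy_reg)
  rec <- enumerate_pairings(toy)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$composite, "210")  # 6 * 35

  toy2 <- new_catalog(list(D1 = list(c("a", "b"), c("a", "c")),
                           D2 = list(c("c", "d"))), toy_reg)
  expect_identical(nrow(enumerate_pairings(toy2)), 2L)
  # within-diagnosis pairings only when asked
  expect_identical(nrow(enumerate_pairings(toy2, within = TRUE)), 3L)
})

test_that("enumeration count matches the closed form on the full catalog", {
  cat21 <- headache_catalog()
  n <- vapply(cat21, function(d) length(d$encodings), integer(1))
  rec <- enumerate_pairings(cat21, composites = FALSE)
  expect_identical(nrow(rec),
                   as.integer((sum(n)^2 - sum(n^2)) / 2))
  rec_all <- enumerate_pairings(cat21, within = TRUE, composites = FALSE)
  expect_identical(nrow(rec_all), as.integer(sum(n) * (sum(n) - 1) / 2))
})

test_that("the contradiction filter keeps exactly the consistent composites", {
  toy <- new_catalog(list(D1 = list(c("a", "b")), D2 = list(c("c", "d"))),
                     toy_reg)
  ctr <- toy_contradictions(list(c("b", "c")))  # code 15 divides 210
  rec <- enumerate_pairings(toy)
  expect_identical(nrow(filter_consistent(rec, ctr)), 0L)
  # a contradiction not covered by either conjunct leaves the record alone
  ctr2 <- toy_contradictions(list(c("a", "c")))
  expect_identical(nrow(filter_consistent(rec, ctr2)), 0L)  # 2*5 divides 210
  ctr3 <- toy_contradictions(list(c("a", "d"), c("b", "d")))
  expect_identical(nrow(filter_consistent(rec, ctr3)), 0L)
  toy_bc <- new_catalog(list(D1 = list(c("a", "b")), D2 = list(c("c"))),
                        toy_reg)
  expect_identical(nrow(filter_consistent(enumerate_pairings(toy_bc), ctr3)),
                   1L)
})

test_that("filtering equals brute force on a toy instance", {
  labels <- letters[1:8]
  reg8 <- toy_registry(labels)
  toy <- new_catalog(list(
    D1 = list(c("a", "b"), c("a", "c"), c("d")),
    D2 = list(c("c", "e"), c("f", "g")),
    D3 = list(c("b", "h"), c("e", "h"))), reg8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(a = c("a", "e", "b"), b = c("e", "f", "c")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  ctr <- load_contradictions(path, reg8)

  rec <- enumerate_pairings(toy)
  surv <- filter_consistent(rec, ctr)
  # brute force: a pairing survives iff the union of its two conjuncts
  # contains no contradiction pair
  brute <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    u <- union(decode_encoding(rec$encoding_a[i], reg8),
               decode_encoding(rec$encoding_b[i], reg8))
    brute[i] <- brute_consistent(u, ctr)
  }
  expect_identical(surv$composite, rec$composite[brute])
  # and the support-based filter agrees with literal long division
  for (i in seq_len(nrow(rec)))
    expect_identical(brute[i], !any(divides(ctr$code, rec$composite[i])))
})

test_that("the full enumeration reproduces the published counts", {
  res <- enumerate_dual_diagnoses()
  s <- res$summary
  expect_identical(s$survivors_ordered_all, 253842L)
  expect_identical(s$survivors_unordered_all, 126921L)
  expect_identical(s$survivors_ordered_all, 2L * s$survivors_unordered_all)
  expect_identical(s$unique_pairs, 145L)
  expect_true(s$unique_pairs <= s$survivors_unordered_cross)
  # cross-diagnosis-only convention, for comparison
  expect_identical(s$survivors_ordered_cross, 156494L)
  expect_true(all(c("1.1", "4.5") %in%
                  c(res$pairs$code_a, res$pairs$code_b)))
  i <- which(res$pairs$code_a == "1.1" & res$pairs$code_b == "4.5")
  expect_length(i, 1L)  # migraine without aura x cold-stimulus headache
})

test_that("no survivor is divisible by any contradiction code", {
  res <- enumerate_dual_diagnoses(composites = TRUE)
  ctr <- headache_contradictions()
  surv <- res$survivors
  set.seed(31)
  idx <- sample.int(nrow(surv), 2000L)
  for (k in seq_len(nrow(ctr)))
    expect_false(any(divides(ctr$code[k], surv$composite[idx])))
  # every surviving composite is divisible by one encoding of each side
  idx2 <- sample.int(nrow(surv), 200L)
  expect_true(all(divides(surv$encoding_a[idx2], surv$composite[idx2])))
  expect_true(all(divides(surv$encoding_b[idx2], surv$composite[idx2])))
})
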