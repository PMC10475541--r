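mwoa_conjunct <- c("Greater than 5 episodes", "4 to 72 h", "Unilateral",
                   "Pulsating", "Nausea/vomiting")

test_that("encoding reproduces the worked examples", {
  expect_identical(encode_conjunct(mwoa_conjunct), "223417708453")
  # commutative: independent of input order
  expect_identical(encode_conjunct(rev(mwoa_conjunct)), "223417708453")
  expect_identical(encode_conjunct("Photophobia"), "397")
  # 83 * 97 * 263 * 541, the single new-daily-persistent-headache conjunct
  expect_identical(
    encode_conjunct(c("Clearly remembered onset", "Constant",
                      "More than 3 months", "Unremitting within 24 h")),
    "1145520433")
  expect_identical(encode_profile(c(mwoa_conjunct, "Photophobia")),
                   "88696830255841")
  expect_identical(encode_profile(character(0)), "1")
  # an intentionally inconsistent profile still encodes (53 * 523)
  expect_identical(encode_profile(c("Bilateral location", "Unilateral")),
                   "27719")
  expect_error(encode_profile(c("Unilateral", "unilateral")), "duplicate")
  expect_error(encode_conjunct(c("Unilateral", "Purple aura")),
               "unknown characteristic")
})

test_that("criteria encoding sorts ascending and drops duplicates", {
  conjuncts <- list(c("Photophobia"), c("Unilateral", "Pulsating"),
                    c("Pulsating", "Unilateral"), "4 to 72 h")
  enc <- encode_criteria(conjuncts)
  expect_identical(enc, c("23", "397", "220183"))
  expect_identical(encode_criteria(list()), character(0))
})

test_that("decoding factorizes over the registry and rejects residues", {
  expect_setequal(decode_encoding("2106413"),
                  c("Brought on by exercise", "Greater than 2 episodes",
                    "Less than 48 h"))
  expect_setequal(decode_encoding("4026427"),  # 61 * 149 * 443
                  c("Brought on by cold stimuli", "Greater than 2 episodes",
                    "Resolve within 30 min after removal of cold"))
  expect_identical(decode_encoding("1"), character(0))
  # 1009 is prime but unassigned
  expect_error(decode_encoding("1009"), "unencodable integer")
  expect_error(decode_encoding(big_mul("1009", "523")), "1009")
  # multiplicity is preserved for squared primes
  expect_identical(decode_encoding("273529"), c("Unilateral", "Unilateral"))
})

test_that("decode-encode is the identity on random characteristic sets", {
  reg <- headache_registry()
  set.seed(11)
  for (i in 1:200) {
    labels <- sample(reg$name, sample.int(15, 1L))
    expect_setequal(decode_encoding(encode_profile(labels), reg), labels)
  }
})

test_that("divisibility is equivalent to subset inclusion", {
  reg <- headache_registry()
  set.seed(13)
  for (i in 1:400) {
    s <- sample(reg$name, sample.int(10, 1L))
    t <- sample(reg$name, sample.int(12, 1L))
    expect_identical(divides(encode_profile(s, reg), encode_profile(t, reg)),
                     all(s %in% t))
    # and supersets always divide
    sup <- unique(c(s, sample(reg$name, 3L)))
    expect_true(divides(encode_profile(s, reg), encode_profile(sup, reg)))
  }
})
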