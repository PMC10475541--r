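---
title: "Prime encoding of headache criteria: model, conventions and curation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prime encoding of headache criteria: model, conventions and curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ichdprime)
```

## The model

ICHD-3 diagnostic criteria are propositional statements in disguise: each
criterion item is true or false of a given headache, and the items are glued
together by AND, OR and "at least *k* of the following *n*". `ichdprime`
makes this structure computable in three steps.

**Atoms and primes.** Every clinical characteristic is an atom, including
negative findings ("No photophobia" is its own atom; there is no logical NOT
in the language — this mirrors how the criteria themselves are written, and
it keeps every formula monotone). Each atom is bound to a unique prime; the
bundled registry binds 103 characteristics to the first 103 primes (2
through 563).

**Disjunctive normal form.** Each criteria set is expanded to an OR of ANDs.
A conjunct — one way of satisfying the criteria — is a set of atoms, and is
encoded as the product of their primes. A diagnosis becomes a list of
integers: the bundled catalog carries 21 diagnoses and 578 encodings, from
single-conjunct disorders (new daily persistent headache is the single
integer 1145520433 = 83 x 97 x 263 x 541) up to chronic migraine's 284
conjuncts of ~28 decimal digits each.

**Diagnosis as divisibility.** A profile (the set of characteristics a
patient exhibits) is encoded the same way. By unique factorization, the
encoding of a set S divides the encoding of a set T exactly when S is a
subset of T. Hence a profile satisfies a diagnosis iff its code is divisible
by at least one of the diagnosis's encodings, and the dividing encoding is a
decodable witness: `decode_encoding()` turns it back into the satisfied
conjunct. The test suite checks this divisibility/subset equivalence on 10^4
random set pairs and, for every formula-defined diagnosis, checks the
arithmetic rule against direct propositional evaluation on random profiles.

The ubiquitous ICHD-3 criterion E ("not better accounted for by another
ICHD-3 diagnosis") is deliberately not encoded: it quantifies over the whole
classification and would make every criteria set self-referential.
"Probable" diagnoses, complications of migraine, the episodic syndromes and
secondary headaches are likewise outside the catalog.

## Expansion conventions

Two conventions matter for reproducing the catalog exactly.

*At-least-k clauses are not minimized.* `expand_at_least(k, items)` keeps
every subset of size >= k, not only the minimal ones: migraine without
aura's "at least 2 of 4" C-criterion contributes 6 + 4 + 1 = 11 groups,
which together with the two D-branches gives the block's 22 encodings. A
minimized normal form would give 12 and would not reproduce the catalog.
The redundant conjuncts are harmless for diagnosis (any profile divisible
by a superset conjunct is divisible by one of its minimal subsets) but they
are counted, so the convention is part of the data contract.

*The integer list is the ground truth.* The catalog file stores encodings;
the loader factorizes them over the registry, re-encodes the recovered
conjuncts, and refuses to load on any mismatch. Formula-level definitions
are bundled as validated sugar for 19 of the 21 diagnoses. The remaining
two blocks (migraine with aura, chronic migraine) do not follow a single
expansion convention — migraine with aura's 120 encodings correspond to
exactly one aura type and exactly three of its six C-characteristics, an
exactly-k rather than at-least-k reading — so they are defined by their
conjunct lists alone. Similarly, the hypnic-headache block expands its
autonomic-negation criterion over the eight cranial autonomic symptom
negations (one branch each); this eight-branch form is the one consistent
with the catalog's own totals.

## The contradiction table

Logical consistency is not derivable from the encodings — nothing in the
arithmetic says a headache cannot be both bilateral and unilateral — so
mutual exclusions are curated data: 99 rows of characteristic pairs
(durations that cannot co-hold, a finding and its negation, incompatible
attack frequencies), each encoded as the product of its two primes. A
profile or composite is inconsistent iff some two-prime code divides it.
Five of the 99 curated rows repeat an earlier pair with the order or casing
reversed, so 94 distinct unordered pairs remain after normalization; the
loader reports both figures, and filtering is unaffected by the repeats
(dividing twice by the same code excludes the same numbers). Label matching
tolerates the casing/spacing drift of hand-curated tables via canonical
normalization.

## Dual-diagnosis enumeration and counting conventions

`enumerate_dual_diagnoses()` multiplies every take-two combination of
catalog encodings, discards products divisible by any contradiction code,
and deduplicates the survivors by unordered diagnosis pair. Shared
characteristics yield a squared prime in a composite; composites are kept
as-is, since contradiction codes are square-free and their divisibility
only depends on which primes appear.

Counting conventions differ more than one would expect, so the summary
reports them all: pairings and survivors, unordered and ordered (x2), for
cross-diagnosis pairings only and for all pairings including two conjuncts
of the same diagnosis. The package's headline figure — 253,842 surviving
composites — is the ordered count over all pairings (126,921 unordered);
the cross-diagnosis-only ordered count is 156,494. Deduplication yields 145
dual-diagnosis pairs under every convention, because same-diagnosis
pairings never contribute a pair. The filter itself runs on conjunct
support sets (both primes of a code present in the union), which the test
suite verifies against literal long division.

## Classifying the 145 pairs

Each pair receives one of three labels, with precedence subset >
intersecting > non-intersecting:

* **Subset-intersecting**: some conjunct of one diagnosis is divisible by a
  conjunct of the other, so one way of satisfying the first outright
  satisfies the second. The test is existential over conjunct pairs — the
  reading under which chronic migraine, whose conjuncts extend either
  parent migraine's branches, is subset-related to both. Exactly two pairs
  qualify, and the test is pure arithmetic.
* **Intersecting without subset**: the diagnoses overlap phenotypically.
* **Non-intersecting**: they do not.

Phenotypic overlap is the one place where arithmetic alone is insufficient,
in both directions. Many diagnoses share only bookkeeping labels (minimum
episode counts, severity grades, laterality, three-month chronicity, the
cranial autonomic accompaniments common to every trigeminal autonomic
cephalalgia): a literal shared-prime test would call 41 of the 143
non-subset pairs intersecting. Conversely, genuinely overlapping duration
windows ("1 to 600 s" vs "Up to few seconds") are distinct atoms with
distinct primes and share nothing literally. The classifier therefore takes
its notion of overlap from three transparent data layers, shipped as
editable TSVs rather than hidden logic:

1. `nonspecific-characteristics.tsv` — 16 generic labels excluded as
   overlap evidence;
2. `overlap-curation.tsv` — 7 label pairs whose clinical ranges genuinely
   intersect (duration and onset windows), each with its rationale;
3. `pair-overlap-annotations.tsv` — 2 diagnosis-level judgments
   (hemicrania continua / nummular headache, new daily persistent headache /
   nummular headache) where the overlap — a strictly side-locked, fixed
   phenotype — is a property of the whole presentations rather than of any
   single label pair. No label-level rule can express these without also
   relabeling pairs that are plainly non-intersecting, because every
   hemicrania-continua characteristic is shared with some diagnosis whose
   nummular pairing does not overlap.

With all three layers empty (`empty_curation()`), the classifier reduces to
the literal rule, equal to gcd(prod of encodings, prod of encodings) > 1 —
an equivalence the test suite checks with an independent Euclid oracle. The
2 subset pairs and the 145 total are curation-independent; the 14/129 split
is exactly as curated, and readers who disagree with a judgment can edit
the TSVs and re-run.

```{r classify}
res <- enumerate_dual_diagnoses()
res$summary$survivors_ordered_all
cls <- classify_pairs(res$pairs)
cls$counts
```

## Numerical choices

* **Exact arithmetic everywhere.** Encodings reach ~28 digits, composites
  ~56; doubles are exact only to 2^53. All values are decimal strings
  backed by base-1e9 limb arithmetic in C++ (schoolbook multiplication,
  long division with binary-searched quotient limbs). `as_code()` accepts
  numerics only up to 2^53 and errors beyond, rather than silently
  rounding.
* **Factorization is trial division** over the 103 registry primes (max
  563). The factor base is tiny and fixed; no general-purpose factorization
  is ever needed, and any residual factor raises an error naming the
  residue.
* **Determinism and ties.** Encoding lists are sorted ascending with exact
  duplicates removed; `matches()` reports the smallest dividing encoding as
  witness (all witnesses on request); enumeration order is
  catalog-then-encoding; classification is symmetric in pair order.
* **Degenerate inputs.** The empty profile encodes to 1, satisfies nothing
  and violates nothing; an empty conjunct list encodes to an empty list;
  duplicate labels in a profile are a contract violation, while an
  inconsistent profile (e.g. bilateral + unilateral) is diagnosed anyway
  but flagged with a warning — contradiction in a single-headache profile
  signals a data-quality problem, not an arithmetic one.

## The fixture generator

`generate_fixture_profiles()` emulates logically well-formed single-headache
presentations: each profile is one randomly chosen conjunct of a randomly
chosen diagnosis plus up to four extra characteristics, each accepted only
if it introduces no contradiction. By construction every profile satisfies
its source diagnosis and passes the consistency check, which the suite
verifies on 100 profiles. The generator makes no attempt to model
prevalence, symptom correlation, reporting noise or missing data — it
exercises the logic, not the epidemiology — so passing tests certify the
arithmetic and the knowledge base, not clinical performance on real
histories.

## Problem sizes and runtime

The full analysis is desk-scale by design: 103 primes, 578 encodings,
166,753 unordered take-two pairings, 94 distinct contradiction codes. The
complete pipeline (load, validate, enumerate, filter, deduplicate,
classify) runs in a few seconds on one CPU; the property-based suite uses
10^4 random set pairs for the divisibility law and 10^3 random profiles for
the semantic-oracle comparison.

## Limitations

* The catalog covers the primary headache disorders two levels deep;
  status migrainosus and the other complications of migraine are excluded,
  which caps migraine duration at 72 h and therefore rules out, within this
  model, migrainous presentations of new daily persistent headache.
* The contradiction table and the overlap curation are clinical judgments
  shipped as data. They are complete enough to reproduce the bundled
  analysis, not guaranteed exhaustive; a missing exclusion admits spurious
  dual diagnoses (e.g. pairings that are logically consistent but
  practically impossible, such as a sleep-triggered and a cold-triggered
  headache being the same attack).
* Only dual (order-two) co-diagnoses are enumerated; the machinery extends
  to higher orders but the combinatorics and the curation burden grow
  accordingly.
* The method is purely logical: it ranks nothing, estimates no
  probabilities, and is not a substitute for history-taking — it answers
  only which criteria sets a given characteristic set satisfies, and which
  combinations of criteria are jointly satisfiable at all.
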