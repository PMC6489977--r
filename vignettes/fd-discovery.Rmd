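---
title: "Mining minimal functional dependencies, equivalences and candidate keys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining minimal functional dependencies, equivalences and candidate keys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdminer)
```

## The problem

A functional dependency (FD) `X -> Y` over a relation `r(U)` holds when
every pair of tuples that agrees on the attribute set `X` also agrees on
`Y`. Minimal FDs — those whose right-hand side is not already determined
by a proper subset of the left-hand side — are the only ones worth
reporting, since all others follow from them by Armstrong's axioms
(reflexivity, augmentation, transitivity, and the derived union and
decomposition rules). Together with equivalent attribute sets
(`X <-> Y` when both directions hold) and candidate keys (minimal sets
whose closure is the whole schema), they summarize the redundancy
structure of a table: which columns duplicate each other, which can be
split into separate tables without information loss, which combinations
identify a record.

The intended inputs are long-and-narrow record tables — the shape typical
of clinical and demographic extracts, where the row count dwarfs the
column count. All values are treated as opaque tokens compared only for
equality: `"0"` and `"0.0"` are different values, and no type inference
is attempted, because any coercion that merges distinct tokens silently
changes which dependencies hold.

## The search

The candidate space is the power-set lattice over the schema `U`. For `n`
attributes there are `2^n - 1` nonempty subsets and `n * 2^(n-1) - n`
possible dependency arrows (`lattice_counts()`), so the space is
exponential in the column count and essentially indifferent to the row
count — the reason a level-wise traversal with aggressive pruning is the
right tool for this table shape.

### Validation by partition cardinality

`pi_X` partitions the rows by their projection on `X`; `card(pi_X)` is
its number of groups. The dependency `X -> A` holds iff
`card(pi_X) = card(pi_XA)`: appending `A` to the projection splits no
group exactly when rows agreeing on `X` already agree on `A`. Partitions
are computed by hashing projection tuples — plain partitions, not the
stripped-partition refinement some lattice algorithms use, because the
plain form is the simplest structure that realizes the cardinality test
and any optimization must leave every result unchanged. Cardinalities are
memoized per level while the search runs.

### The level-wise loop

At level `k`, every surviving candidate `X` is validated: the only
right-hand sides tested are `U \ (X u X*)`, where `X*` is the nontrivial
closure accumulated so far, so an attribute already known to be
determined by `X` (or by any subset of `X`) is never re-checked. After
the level is fully validated, equivalences are detected among
incomparable same-level candidates whose closures contain each other,
the next level is generated, and four pruning rules run on it:

1. *Equivalence pruning* — supersets of the deleted side of an
   equivalence are dropped. When `X <-> Y` is found, the two sides carry
   the same information, so only one side's supersets need exploring; the
   earlier-generated side (lexicographically smaller, under our
   generation order) is the one deleted.
2. *Redundancy pruning* — a candidate `S` contained in `X u X*` for some
   one-down subset `X` adds nothing beyond `X`'s closure and is dropped.
   These deletions are logged as redundancy, not as equivalences, keeping
   the reported equivalence list to incomparable pairs only.
3. *Closure propagation* — `S* := S* u (X* \ S)` over **all** one-down
   subsets `X` of each generated candidate, including subsets that were
   themselves pruned (their closures are resolved recursively from their
   own subsets and memoized). Propagating through deleted candidates is
   what keeps later levels from re-checking dependencies that are already
   implied — skipping them is precisely the error that makes a naive
   implementation emit non-minimal FDs.
4. *Key pruning* — if `S u S* = U` for a proper subset `S` of `U`, then
   `S` is a superkey; its supersets can only yield non-minimal
   dependencies and are dropped.

Candidate generation uses the strict apriori rule: a set of size `k+1`
enters the next level only when *all* of its `k`-subsets are present in
the current one. With the permissive pairwise-join rule, a key `AB` in a
5-attribute schema would still generate `ABCD` and lead to checking the
non-minimal `ABCD -> E`; under the strict rule `ABCD` is never generated
because `ABC` did not survive. The loop terminates when generation
returns the empty level (at most `|U|` iterations) or when the
configurable time budget (default 14 400 s) expires, in which case the
partial result is returned with `truncated = TRUE`.

One counting subtlety: the full set `U` satisfies `S u S* = U` vacuously,
carries no testable right-hand sides, and prunes nothing — yet it is
generated and counted as a checked candidate when all its subsets
survive. We count it, so an unpruned 4-attribute search checks
`4 + 6 + 4 + 1 = 15` candidates; the `candidates_checked` counter counts
candidates examined, one per candidate per level, not individual
cardinality comparisons.

### Key inference

Candidate keys are computed from the discovered dependency set
(equivalence pairs expanded into their two directions) rather than by
scanning the data again. An Armstrong-closure engine computes `X+` as a
least fixpoint; `minimum_coverage()` removes extraneous left-hand
attributes and implied dependencies (processing in canonical order, for
determinism); `candidate_keys()` seeds the search with the mandatory core
— attributes on no right-hand side of the minimum coverage, which belong
to every key — and expands breadth-first over the remaining attributes,
pruning supersets of keys already found. Breadth-first order plus the
core seed makes every returned set minimal without an explicit subset
check. A configurable cap (default 10 000 keys) aborts pathological
inputs, whose key count can be exponential.

Because the dependency set cannot see duplicated rows, each inferred key
is finally verified against the relation (`is_superkey()`); a table
containing two identical rows has no key, and none is reported.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `time_limit_seconds` | 14 400 s | wall-clock budget for the search; on expiry the partial result is flagged `truncated` |
| `separator` | auto | field separator; detection tries `,` `\|` `;` `:` `~` in that precedence on the first 20 non-empty lines and requires a consistent field count > 1 |
| `max_keys` | 10 000 | abort threshold for key enumeration |
| `distinct_values` | 8 | value-pool size per free attribute in the synthetic generator |

Ties in separator detection go to the earlier candidate in the
precedence order; a file in which no separator is consistent is treated
as single-column, unless a candidate character appears in the header, in
which case the file is reported as malformed. Empty cells become a single
reserved missing token equal to itself, keeping the dependency logic
two-valued; SQL-style null semantics would break the cardinality test.

## Numerical and representational choices

Attribute sets are canonicalized as sorted (radix order,
locale-independent) duplicate-free character vectors, so equal sets are
structurally identical and serve as registry keys; candidate generation
within a level is lexicographic on this canonical form, which is also the
documented "generated before" order used by equivalence pruning. Row
indices are 0-based nowhere and 1-based everywhere — partitions store
1-based row-index groups ordered by first occurrence. All counters are
exact integers; the only floating-point quantity anywhere is elapsed
time.

## The synthetic generator, and what passing tests mean

`generate_relation()` draws free attributes uniformly from a pool of
`distinct_values` tokens; each planted dependency's right-hand side is a
fixed seeded function of the left-hand-side projection (so the dependency
holds by construction), and planted equivalences are bijective
relabelings between two singleton attributes. `generate_fd_free_relation()`
rejection-samples independent columns until the brute-force oracle
certifies that no nontrivial dependency holds; with 500 rows and pools of
8 values per column, accidental dependencies are overwhelmingly unlikely
and the first draw almost always passes. Randomness is confined to a
single seeded generator per call, and the caller's RNG state is restored.

The generator emulates *dependency structure only*. Real record tables
have skewed value distributions, missingness patterns, near-dependencies
violated by a handful of rows, and coding conventions — none of which are
simulated. Tests passing on synthetic relations therefore certify the
combinatorics of discovery (soundness, minimality, completeness modulo
equivalence, key inference), not robustness to the statistical texture of
production data. Approximate or partial dependencies are out of scope
throughout.

The verification suite runs the discovery loop against brute-force
oracles built on the literal tuple-pair definition — a code path
deliberately disjoint from the partition machinery — across hundreds of
seeded random relations of 2–6 attributes and 10–200 rows, sizes at which
exhaustive subset enumeration is exact and fast; the oracles guard
against schemas wider than 10 attributes.

## Known limitations

- The lattice is exponential in the attribute count: tables beyond
  roughly 14 columns are out of reach of any level-wise method, and the
  time limit exists for exactly that case.
- Only exact dependencies are mined; a dependency violated by one row is
  simply absent.
- Equivalence detection is restricted to incomparable same-level pairs;
  subset–superset redundancy is handled by pruning rule 2 instead, so the
  reported equivalence list never contains comparable sets.
- Reported FDs are decomposed to single right-hand attributes; merged
  right-hand sides are a display choice left to the consumer of the
  report.
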