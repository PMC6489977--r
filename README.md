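# fdminer

Functional-dependency discovery for tabular data, in R.

A functional dependency (FD) `X -> Y` over a relation `r(U)` asserts that
any two rows agreeing on the attribute set `X` also agree on `Y`. FDs, the
equivalent attribute sets they induce (`X <-> Y` when both directions
hold), and candidate keys (minimal attribute sets that uniquely identify
every row) are the raw material of table decomposition, database
normalization and data cleansing. They matter in particular for clinical
and demographic record tables, which tend to be long and narrow — many
rows, few columns — exactly the shape where a level-wise lattice search is
the efficient way to find them.

`fdminer` discovers **all minimal FDs**, the equivalences among attribute
sets, and the candidate keys of a delimited table. It is usable as a
library, and as a command-line tool that writes a plain-text
`<dataset>.FD_Info.txt` report.

## The algorithm

The search space is the power-set lattice of the schema `U`
(`2^n - 1` nonempty subsets, `n * 2^(n-1) - n` possible dependency arrows;
see `lattice_counts()`). The search walks the lattice level by level, in
the style of the FD_Mine family of lattice-traversal algorithms:

- **Validation** uses partition cardinality: `X -> A` holds iff
  `card(pi_X) = card(pi_XA)`, where `pi_X` groups rows by their projection
  on `X`. This tests a dependency without touching tuple pairs, so row
  count enters the cost only once per partition.
- **Closure bookkeeping.** Every candidate `X` carries its nontrivial
  closure `X* = X+ \ X`; only attributes in `U \ (X u X*)` are ever tested
  as right-hand sides. Closures propagate to the next level through *all*
  one-down subsets of each generated candidate — including pruned ones —
  so the closure of a deleted candidate is never lost among its supersets.
- **Pruning.** Four rules run between levels: supersets of the deleted
  side of an equivalence are dropped (justified by Armstrong-axiom
  lemmas); candidates contained in a subset's closure are dropped as
  redundant; closures are propagated; and supersets of discovered keys are
  dropped.
- **Candidate generation** uses the strict apriori rule: a set of size
  `k+1` is generated only when all of its `k`-subsets survived. This
  strictness is what guarantees that no non-minimal dependency (e.g.
  `ABCD -> E` when `AB` is already a key) is ever checked.
- **Key inference.** The discovered FDs (equivalences expanded into both
  directions) feed an Armstrong-closure engine: reduction to a minimum
  coverage, then a core-seeded breadth-first search for all minimal `X`
  with `X+ = U`, verified against the data so duplicate rows never yield a
  spurious key.

Brute-force oracles (`brute_force_minimal_fds()`, `brute_force_keys()`),
built on the literal tuple-pair definition rather than partitions, and a
seeded synthetic-relation generator with planted structure
(`generate_relation()`, `generate_fd_free_relation()`) support desk-scale
verification of every piece.

## Worked example

The package ships a 7-row, 5-attribute example table:

```sh
fdtool $(Rscript -e 'cat(system.file("extdata", "example7x5.csv", package = "fdminer"))')
```

or equivalently from R:

```r
library(fdminer)
r <- read_relation(system.file("extdata", "example7x5.csv", package = "fdminer"))
run_fdmine(r)
```

prints (and saves to `example7x5.FD_Info.txt`):

```
Functional Dependencies
-----------------------
{A} -> {D}
{D} -> {A}
{B, D} -> {E}
{B, E} -> {A}
{B, E} -> {D}
{C, E} -> {A}
{C, E} -> {D}

Equivalences
------------
{A} <-> {D}
{B, D} <-> {B, E}

Candidate Keys
--------------
{A, B, C}
{B, C, D}
{B, C, E}

Summary
-------
Rows: 7
Attributes: 5
FDs found: 7
Equivalences found: 2
Candidates checked: 11
Elapsed seconds: 0.039
```

Reading the output: columns `A` and `D` carry the same information (each
determines the other), so they are reported as an equivalence and only one
side's supersets are explored — 11 candidates were checked out of the 30
nonempty proper subsets of the schema. Any of the three keys identifies a
row uniquely; every other FD in the table is implied by the listed minimal
ones together with the equivalences. `{A, B} -> {E}` is not listed
because it follows from `{A} <-> {D}` and `{B, D} -> {E}`.

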