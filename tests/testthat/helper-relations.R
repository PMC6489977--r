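# Shared fixtures and comparison helpers.

# The 7x5 worked example: A and D are mutually determining, the candidate
# keys are {A,B,C}, {B,C,D}, {B,C,E}.
example_relation <- function() {
  fd_relation(
    data.frame(
      A = c(0, 0, 0, 0, 4, 4, 0),
      B = c(0, 1, 2, 3, 1, 3, 0),
      C = c(0, 0, 0, 1, 1, 1, 1),
      D = c(2, 2, 2, 2, 1, 1, 2),
      E = c(0, 0, 2, 0, 4, 2, 0)
    ),
    name = "example7x5"
  )
}

set_keys <- function(sets) sort(vapply(sets, function(s) paste(s, collapse = ","), character(1)))

fd_keys <- function(fds) {
  sort(vapply(fds, function(f) {
    paste0(paste(f$lhs, collapse = ","), ">", f$rhs)
  }, character(1)))
}

expect_same_sets <- function(actual, expected) {
  expect_identical(set_keys(actual), set_keys(expected))
}

# Closure-equality of two dependency sets over every subset of the universe.
closures_agree <- function(universe, f1, f2) {
  universe <- as_attrset(universe)
  for (k in seq_along(universe)) {
    for (x in utils::combn(universe, k, simplify = FALSE)) {
      if (!setequal(armstrong_closure(x, f1), armstrong_closure(x, f2))) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Dependency set implied by a discovery result: emitted FDs plus both
# directions of every equivalence.
result_fdset <- function(result, universe) {
  eq_fds <- list()
  for (e in result$equivalences) {
    x <- e[[1]]; y <- e[[2]]
    for (a in setdiff(y, x)) eq_fds <- c(eq_fds, list(fd(x, a)))
    for (a in setdiff(x, y)) eq_fds <- c(eq_fds, list(fd(y, a)))
  }
  fdset(universe, c(result$fds, eq_fds))
}

# Small random relation with optional planted structure, deterministic in
# `seed`.
random_relation <- function(seed, n_attrs = NULL, n_rows = NULL) {
  set.seed(seed)
  if (is.null(n_attrs)) n_attrs <- sample(2:6, 1)
  if (is.null(n_rows)) n_rows <- sample(10:200, 1)
  attrs <- LETTERS[seq_len(n_attrs)]
  planted_fds <- list()
  planted_eqs <- list()
  free <- attrs
  if (n_attrs >= 3 && runif(1) < 0.5) {
    rhs <- sample(attrs, 1)
    lhs <- sample(setdiff(attrs, rhs), sample(1:2, 1))
    planted_fds <- list(fd(lhs, rhs))
    free <- setdiff(free, c(rhs, lhs))  # keep the equivalence disjoint from the FD
  }
  if (length(free) >= 2 && runif(1) < 0.4) {
    pair <- sample(free, 2)
    planted_eqs <- list(pair)
  }
  spec <- synthetic_spec(
    n_rows, attrs,
    planted_fds = planted_fds,
    planted_equivalences = planted_eqs,
    distinct_values = sample(3:8, 1),
    seed = seed
  )
  list(relation = generate_relation(spec), spec = spec)
}
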