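# Desk-scale verification kit: brute-force oracles that work straight from
# the defining pairwise condition (independent of the partition machinery),
# and a seeded generator of synthetic relations with planted dependency
# structure. The synthetic relations emulate only dependency structure —
# value distributions are uniform and carry none of the skew, missingness
# or coding conventions of real clinical record tables.

# Pairwise agreement matrix: one row per unordered tuple pair, one column
# per attribute; entry 1 iff the pair agrees on that attribute. This is the
# literal pairwise dependency condition, vectorized.
pair_agreement <- function(relation) {
  n <- n_rows(relation)
  if (n < 2L) {
    return(matrix(1L, nrow = 0L, ncol = n_attributes(relation),
                  dimnames = list(NULL, relation$attributes)))
  }
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L, from = 2L:n)
  agree <- matrix(0L, nrow = length(ii), ncol = n_attributes(relation),
                  dimnames = list(NULL, relation$attributes))
  for (c in seq_len(n_attributes(relation))) {
    agree[, c] <- as.integer(relation$data[ii, c] == relation$data[jj, c])
  }
  agree
}

# X -> A by the pairwise definition: every pair agreeing on all of X also
# agrees on A.
pairwise_fd_holds <- function(agree, lhs, rhs) {
  if (nrow(agree) == 0L) return(TRUE)
  k <- length(lhs)
  lhs_agree <- .rowSums(agree[, lhs, drop = FALSE], nrow(agree), k) == k
  all(agree[lhs_agree, rhs] == 1L)
}

#' Brute-force enumeration of all minimal functional dependencies
#'
#' Implementation-independent oracle: for each right-hand attribute A, scans
#' the subsets of U \ {A} in increasing size and records X -> A when the
#' pairwise dependency condition passes and no recorded proper subset of X
#' already determines A. Uses the defining tuple-pair check, not partitions,
#' so it shares no code path with the lattice search it verifies.
#'
#' @param relation An [fd_relation()] with at most 10 attributes.
#' @return An [fdset()] of the minimal dependencies.
#' @export
brute_force_minimal_fds <- function(relation) {
  U <- as_attrset(relation$attributes)
  if (length(U) > 10L) {
    stop("brute-force oracle is limited to 10 attributes", call. = FALSE)
  }
  agree <- pair_agreement(relation)
  fds <- list()
  for (a in U) {
    rest <- setdiff(U, a)
    found <- list()
    for (k in seq_along(rest)) {
      for (x in utils::combn(rest, k, simplify = FALSE)) {
        if (any(vapply(found, function(f) all(f %in% x), logical(1)))) next
        if (pairwise_fd_holds(agree, x, a)) found[[length(found) + 1L]] <- x
      }
    }
    for (x in found) fds[[length(fds) + 1L]] <- fd(x, a)
  }
  fdset(U, fds)
}

#' Brute-force enumeration of all candidate keys
#'
#' Scans attribute subsets in increasing size and returns every minimal set
#' on which no two rows agree (distinct-projection count equals the row
#' count). When the relation contains two fully identical rows no set
#' separates them and the result is empty.
#'
#' @param relation An [fd_relation()] with at most 10 attributes.
#' @return List of canonical attribute sets.
#' @export
brute_force_keys <- function(relation) {
  U <- as_attrset(relation$attributes)
  if (length(U) > 10L) {
    stop("brute-force oracle is limited to 10 attributes", call. = FALSE)
  }
  n <- n_rows(relation)
  keys <- list()
  for (k in seq_along(U)) {
    for (x in utils::combn(U, k, simplify = FALSE)) {
      if (any(vapply(keys, function(f) all(f %in% x), logical(1)))) next
      if (length(unique(projection_keys(relation, x))) == n) {
        keys[[length(keys) + 1L]] <- x
      }
    }
  }
  sort_sets_by_size(keys)
}

#' Specification for a synthetic relation
#'
#' Describes the planted structure of a generated table: free attributes
#' drawn independently from a value pool, dependent attributes computed as
#' deterministic functions of their left-hand sides (so the planted
#' dependencies hold by construction), and equivalences planted as value
#' bijections between two singleton attributes.
#'
#' @param n_rows Number of tuples to generate.
#' @param attributes Character vector of attribute names.
#' @param planted_fds List of [fd()]s (or `list(lhs=, rhs=)`) to plant; the
#'   dependency graph must be acyclic.
#' @param planted_equivalences List of length-2 character vectors naming
#'   pairs of singleton attributes to make mutually determining.
#' @param distinct_values Size of the value pool per free attribute
#'   (default 8).
#' @param seed Integer seed; the same spec and seed yield an identical
#'   relation.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_rows, attributes,
                           planted_fds = list(),
                           planted_equivalences = list(),
                           distinct_values = 8L,
                           seed = 1L) {
  stopifnot(n_rows >= 1L, length(attributes) >= 1L, distinct_values >= 1L)
  attributes <- as.character(attributes)
  planted_fds <- lapply(planted_fds, function(f) {
    if (inherits(f, "fd")) f else fd(f$lhs, f$rhs)
  })
  used <- unique(unlist(c(lapply(planted_fds, function(f) c(f$lhs, f$rhs)),
                          planted_equivalences)))
  if (!all(used %in% attributes)) {
    stop("planted structure references undeclared attribute(s)", call. = FALSE)
  }
  for (e in planted_equivalences) {
    if (length(e) != 2L) {
      stop("planted equivalences must be pairs of singleton attributes",
           call. = FALSE)
    }
  }
  structure(
    list(n_rows = as.integer(n_rows), attributes = attributes,
         planted_fds = planted_fds,
         planted_equivalences = planted_equivalences,
         distinct_values = as.integer(distinct_values),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Topological order of derived attributes; errors on cyclic plans or on an
# attribute with two defining dependencies.
derivation_order <- function(spec) {
  rhs <- vapply(spec$planted_fds, `[[`, character(1), "rhs")
  if (anyDuplicated(rhs)) {
    stop("an attribute may be the right-hand side of at most one planted dependency",
         call. = FALSE)
  }
  eq_derived <- vapply(spec$planted_equivalences, `[[`, character(1), 2L)
  if (any(rhs %in% eq_derived)) {
    stop("attribute both planted as dependency rhs and equivalence mirror",
         call. = FALSE)
  }
  order <- character(0)
  remaining <- spec$planted_fds
  free <- setdiff(spec$attributes, c(rhs, eq_derived))
  known <- free
  while (length(remaining) > 0L) {
    ready <- vapply(remaining, function(f) all(f$lhs %in% known), logical(1))
    if (!any(ready)) {
      stop("planted dependency graph is cyclic", call. = FALSE)
    }
    order <- c(order, vapply(remaining[ready], `[[`, character(1), "rhs"))
    known <- c(known, order)
    remaining <- remaining[!ready]
  }
  list(free = free, derived = order, eq_derived = eq_derived)
}

#' Generate a synthetic relation with planted structure
#'
#' Free attributes are sampled uniformly from a pool of
#' `distinct_values` tokens. Each planted dependency's right-hand side is a
#' seeded deterministic function of the left-hand-side projection (distinct
#' lhs values map through a random but fixed table), so the dependency holds
#' by construction. Equivalences are planted as bijective relabelings, so
#' both directions hold.
#'
#' @param spec A [synthetic_spec()].
#' @return An [fd_relation()].
#' @export
generate_relation <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  plan <- derivation_order(spec)
  cols <- list()
  # randomness is confined to this call; the caller's RNG state is restored
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(spec$seed)
  pool <- function(m) sprintf("v%d", seq_len(m))
  for (a in plan$free) {
    cols[[a]] <- sample(pool(spec$distinct_values), spec$n_rows, replace = TRUE)
  }
  for (a in plan$derived) {
    f <- spec$planted_fds[[which(vapply(spec$planted_fds, `[[`, character(1), "rhs") == a)]]
    lhs_key <- do.call(paste, c(cols[f$lhs], sep = "\x1f"))
    levels <- unique(lhs_key)
    # fixed random table from lhs value to rhs value
    table <- sample(pool(spec$distinct_values), length(levels), replace = TRUE)
    cols[[a]] <- table[match(lhs_key, levels)]
  }
  for (e in spec$planted_equivalences) {
    src <- e[[1L]]; dst <- e[[2L]]
    if (is.null(cols[[src]])) {
      stop(sprintf("equivalence source '%s' must be free or derived", src),
           call. = FALSE)
    }
    levels <- unique(cols[[src]])
    relabel <- paste0("w", sample(seq_along(levels)))  # bijection
    cols[[dst]] <- relabel[match(cols[[src]], levels)]
  }
  df <- as.data.frame(cols[spec$attributes], optional = TRUE,
                      stringsAsFactors = FALSE)
  names(df) <- spec$attributes
  fd_relation(df, name = sprintf("synthetic_seed%d", spec$seed))
}

#' Generate a relation with no nontrivial functional dependencies
#'
#' Draws independent uniform columns and rejection-samples until the
#' brute-force oracle confirms that no nontrivial dependency holds. Requires
#' enough rows per value (at least 4 x pool size) for collisions to break
#' accidental dependencies with high probability.
#'
#' @param n_rows Number of tuples (>= 4 x `distinct_values`).
#' @param attributes Character vector of attribute names.
#' @param seed Integer seed.
#' @param distinct_values Value-pool size per column (default 8).
#' @return An [fd_relation()] verified dependency-free by
#'   [brute_force_minimal_fds()].
#' @export
generate_fd_free_relation <- function(n_rows, attributes, seed,
                                      distinct_values = 8L) {
  if (n_rows < 4L * distinct_values) {
    stop("`n_rows` must be at least 4 x `distinct_values`", call. = FALSE)
  }
  for (round in seq_len(100L)) {
    spec <- synthetic_spec(n_rows, attributes,
                           distinct_values = distinct_values,
                           seed = seed + (round - 1L) * 10007L)
    rel <- generate_relation(spec)
    if (length(brute_force_minimal_fds(rel)$fds) == 0L) {
      rel$name <- sprintf("fd_free_seed%d", seed)
      return(rel)
    }
  }
  stop("failed to generate a dependency-free relation in 100 rounds",
       call. = FALSE)
}
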