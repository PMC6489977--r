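# Level-wise discovery of minimal functional dependencies on the power-set
# lattice, with equivalence detection, four pruning rules, and persistent
# closure propagation so that the closures of deleted candidates are never
# lost among their supersets.
#
# Per level k the loop is: validate every candidate X against the
# right-hand pool U \ (X u X*); detect equivalences among the validated
# candidates; generate level k+1 with the strict apriori rule; prune the
# generated level. Candidate keys are inferred from the discovered
# dependency set at the end.

closure_get <- function(closures, x) {
  v <- closures[[set_key(x)]]
  if (is.null(v)) character(0) else v
}

closure_set <- function(closures, x, value) {
  closures[[set_key(x)]] <- as_attrset(value)
  invisible(NULL)
}

#' Resolve the nontrivial closure of an arbitrary attribute set
#'
#' Returns the stored nontrivial closure X* when `x` was generated as a
#' candidate; otherwise resolves it as the union of the closures of its
#' one-down subsets (recursively), minus `x` itself, and memoizes the
#' result. This realizes closure propagation across pruned candidates.
#'
#' @param x Canonical attribute set.
#' @param closures Environment mapping set keys to nontrivial closures.
#' @return Canonical attribute set X* (disjoint from `x`).
#' @keywords internal
closure_of_subset <- function(x, closures) {
  key <- set_key(x)
  v <- closures[[key]]
  if (!is.null(v)) return(v)
  if (length(x) <= 1L) return(character(0))
  acc <- unlist(lapply(one_down(x), closure_of_subset, closures = closures))
  v <- as_attrset(setdiff(acc, x))
  closures[[key]] <- v
  v
}

# Validate one level: for each candidate X (counted once), test X -> A by
# partition cardinality for every A in U \ (X u X*); record hits and grow X*.
obtain_fds <- function(relation, level, closures, state) {
  U <- state$universe
  for (x in level) {
    if (!is.null(state$deadline) && Sys.time() > state$deadline) {
      state$truncated <- TRUE
      return(invisible(NULL))
    }
    state$checked <- state$checked + 1L
    xstar <- closure_get(closures, x)
    pool <- setdiff(U, c(x, xstar))
    for (a in pool) {
      if (fd_holds(relation, x, a, cache = state$cache)) {
        state$fds[[length(state$fds) + 1L]] <- fd(x, a)
        xstar <- as_attrset(c(xstar, a))
      }
    }
    closure_set(closures, x, xstar)
  }
  invisible(NULL)
}

# Scan the validated level for equivalences (Theorem-2 style): incomparable
# X, Y with Y <= X u X* and X <= Y u Y*. The earlier-generated
# (lexicographically smaller) side is marked deleted; its supersets are
# removed by pruning rule 1.
obtain_equivalences <- function(level, closures, state) {
  n <- length(level)
  if (n < 2L) return(invisible(NULL))
  for (i in seq_len(n - 1L)) {
    x <- level[[i]]
    xplus <- c(x, closure_get(closures, x))
    for (j in (i + 1L):n) {
      y <- level[[j]]
      if (all(x %in% y) || all(y %in% x)) next  # comparable pairs are rule-2 territory
      if (all(y %in% xplus)) {
        yplus <- c(y, closure_get(closures, y))
        if (all(x %in% yplus)) {
          state$equivalences[[length(state$equivalences) + 1L]] <- list(x, y)
          state$deleted[[set_key(x)]] <- TRUE  # x generated before y
        }
      }
    }
  }
  invisible(NULL)
}

# Prune a freshly generated level. For each candidate S and each one-down
# subset X:
#   rule 1 — S contains a deleted equivalence side: delete S;
#   rule 2 — S <= X u X* (S adds nothing beyond X's closure): delete S;
#   rule 3 — S* := S* u (X* \ S) (closure propagation; runs even for
#             deleted S so descendants inherit it);
#   rule 4 — S u S* = U after propagation: S is a superkey, delete S.
prune_level <- function(next_level, closures, state) {
  U <- state$universe
  kept <- list()
  for (s in next_level) {
    drop <- FALSE
    sstar <- closure_get(closures, s)
    for (x in one_down(s)) {
      xstar <- closure_of_subset(x, closures)
      if (!is.null(state$deleted[[set_key(x)]])) drop <- TRUE          # rule 1
      if (all(s %in% c(x, xstar))) drop <- TRUE                        # rule 2
      sstar <- as_attrset(c(sstar, setdiff(xstar, s)))                 # rule 3
    }
    closure_set(closures, s, sstar)
    # rule 4 applies to proper subsets only: S = U satisfies S u S* = U
    # vacuously, carries no right-hand sides to test, and is still counted
    # as a candidate when all its subsets survive
    if (!drop && length(s) < length(U) && setequal(as_attrset(c(s, sstar)), U)) {
      state$superkeys[[length(state$superkeys) + 1L]] <- s
      drop <- TRUE
    }
    if (!drop) kept[[length(kept) + 1L]] <- s
  }
  kept
}

# Expand equivalence pairs into their two dependency directions
# (decomposed), for closure computations and key inference.
equivalence_fds <- function(equivalences) {
  out <- list()
  for (pair in equivalences) {
    x <- pair[[1L]]; y <- pair[[2L]]
    for (a in setdiff(y, x)) out[[length(out) + 1L]] <- fd(x, a)
    for (a in setdiff(x, y)) out[[length(out) + 1L]] <- fd(y, a)
  }
  out
}

#' Discover minimal functional dependencies, equivalences and keys
#'
#' Runs the level-wise lattice search on a relation: candidates of size k
#' are validated by partition cardinality, equivalent attribute sets are
#' detected and pruned, the next level is generated with the strict
#' all-subsets apriori rule, and closure values are propagated through
#' pruned candidates so no non-minimal dependency is ever checked. Candidate
#' keys are then inferred from the discovered dependency set (equivalences
#' expanded into both directions) with the Armstrong-closure engine, and
#' verified against the relation so that duplicate rows never yield a bogus
#' key.
#'
#' @param relation An [fd_relation()] with at least one attribute.
#' @param time_limit_seconds Wall-clock budget for the search; on expiry the
#'   partial result is returned with `truncated = TRUE`. Default 14400 s
#'   (4 h).
#' @return An object of class `fd_result` with fields `fds` (list of minimal
#'   [fd()]s), `equivalences` (list of unordered set pairs), `keys` (list of
#'   candidate keys), `candidates_checked`, `fds_found`,
#'   `equivalences_found`, `rows`, `attribute_count`, `elapsed_seconds`,
#'   `truncated`.
#' @examples
#' r <- fd_relation(data.frame(A = c(1, 1, 2), B = c("x", "x", "y"),
#'                             C = c(1, 2, 3)))
#' run_fdmine(r)
#' @export
run_fdmine <- function(relation, time_limit_seconds = 14400) {
  stopifnot(inherits(relation, "fd_relation"))
  if (n_attributes(relation) == 0L) {
    stop("relation has no attributes", call. = FALSE)
  }
  stopifnot(time_limit_seconds > 0)
  t0 <- proc.time()[["elapsed"]]
  state <- new.env(parent = emptyenv())
  state$universe <- as_attrset(relation$attributes)
  state$fds <- list()
  state$equivalences <- list()
  state$superkeys <- list()
  state$deleted <- new.env(parent = emptyenv())
  state$checked <- 0L
  state$truncated <- FALSE
  state$cache <- new.env(parent = emptyenv())
  state$deadline <- Sys.time() + time_limit_seconds
  closures <- new.env(parent = emptyenv())

  level <- lapply(state$universe, function(a) a)
  while (length(level) > 0L) {
    obtain_fds(relation, level, closures, state)
    if (state$truncated) break
    obtain_equivalences(level, closures, state)
    nxt <- apriori_gen(level)
    level <- prune_level(nxt, closures, state)
    # retain cached cardinalities only for sets still reachable (current
    # level and its one-up extensions are recomputed cheaply)
    if (length(state$cache) > 50000L) {
      rm(list = ls(state$cache, sorted = FALSE), envir = state$cache)
    }
  }

  eq_fds <- equivalence_fds(state$equivalences)
  all_fds <- c(state$fds, eq_fds)
  keys <- candidate_keys(fdset(state$universe, all_fds))
  # a closure-complete dependency set can still overstate keys when the
  # relation carries duplicate rows; verify against the data
  keys <- Filter(function(k) is_superkey(relation, k, cache = state$cache), keys)

  structure(
    list(
      fds = state$fds,
      equivalences = state$equivalences,
      keys = keys,
      candidates_checked = state$checked,
      fds_found = length(state$fds),
      equivalences_found = length(state$equivalences),
      rows = n_rows(relation),
      attribute_count = n_attributes(relation),
      elapsed_seconds = proc.time()[["elapsed"]] - t0,
      truncated = state$truncated
    ),
    class = "fd_result"
  )
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("<fd_result: %d FD(s), %d equivalence(s), %d candidate key(s)>\n",
              x$fds_found, x$equivalences_found, length(x$keys)))
  cat(sprintf("  rows %d, attributes %d, candidates checked %d, %.3f s%s\n",
              x$rows, x$attribute_count, x$candidates_checked,
              x$elapsed_seconds, if (x$truncated) " [TRUNCATED]" else ""))
  for (f in x$fds) cat(" ", format_fd(f), "\n")
  for (e in x$equivalences) {
    cat(sprintf("  {%s} <-> {%s}\n", paste(e[[1L]], collapse = ", "),
                paste(e[[2L]], collapse = ", ")))
  }
  for (k in x$keys) cat(sprintf("  key: {%s}\n", paste(k, collapse = ", ")))
  invisible(x)
}
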