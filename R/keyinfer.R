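# Armstrong-closure engine over a set of discovered functional
# dependencies: attribute-set closure, minimum coverage reduction, and
# candidate-key enumeration (core-seeded breadth-first search).

#' Construct a functional dependency
#'
#' Dependencies are stored in decomposed form: a canonical left-hand side
#' and a single right-hand attribute not contained in it.
#'
#' @param lhs Non-empty character vector (left-hand side).
#' @param rhs Single attribute name, not in `lhs`.
#' @return Object of class `fd` with fields `lhs`, `rhs`.
#' @export
fd <- function(lhs, rhs) {
  lhs <- as_attrset(lhs)
  stopifnot(length(lhs) >= 1L, length(rhs) == 1L)
  if (rhs %in% lhs) stop("trivial dependency: rhs is contained in lhs", call. = FALSE)
  structure(list(lhs = lhs, rhs = as.character(rhs)), class = "fd")
}

#' @export
print.fd <- function(x, ...) {
  cat(format_fd(x), "\n")
  invisible(x)
}

format_fd <- function(x) {
  sprintf("{%s} -> {%s}", paste(x$lhs, collapse = ", "), x$rhs)
}

fd_key <- function(x) paste(set_key(x$lhs), x$rhs, sep = "\x1e")

#' Construct a dependency set over a universe
#'
#' @param universe Character vector of all attributes (the schema U).
#' @param fds List of [fd()] objects; every referenced attribute must lie in
#'   `universe`. Duplicates are removed and the set is stored in canonical
#'   (lexicographic) order.
#' @return Object of class `fdset` with fields `universe`, `fds`.
#' @export
fdset <- function(universe, fds = list()) {
  universe <- as_attrset(universe)
  fds <- lapply(fds, function(f) {
    if (!inherits(f, "fd")) f <- fd(f$lhs, f$rhs)
    f
  })
  used <- unique(unlist(lapply(fds, function(f) c(f$lhs, f$rhs))))
  if (!all(used %in% universe)) {
    stop(sprintf("dependency references attribute(s) outside the universe: %s",
                 paste(setdiff(used, universe), collapse = ", ")), call. = FALSE)
  }
  keys <- vapply(fds, fd_key, character(1))
  keep <- !duplicated(keys)
  fds <- fds[keep][order(keys[keep], method = "radix")]
  structure(list(universe = universe, fds = fds), class = "fdset")
}

#' @export
print.fdset <- function(x, ...) {
  cat(sprintf("<fdset over {%s}: %d dependenc%s>\n",
              paste(x$universe, collapse = ","), length(x$fds),
              if (length(x$fds) == 1L) "y" else "ies"))
  for (f in x$fds) cat(" ", format_fd(f), "\n")
  invisible(x)
}

#' Armstrong closure of an attribute set
#'
#' Least fixpoint of the inference rules: starting from `x`, repeatedly add
#' the right-hand side of any dependency whose left-hand side is contained
#' in the current set, until nothing changes. The result is X+, every
#' attribute derivable from `x` by Armstrong's axioms.
#'
#' @param x Character vector, a subset of the universe (may be empty).
#' @param f An [fdset()].
#' @return Canonical attribute set X+.
#' @examples
#' f <- fdset(c("A", "B", "C"), list(fd("A", "B"), fd("B", "C")))
#' armstrong_closure("A", f)
#' @export
armstrong_closure <- function(x, f) {
  closure <- as_attrset(x)
  if (!all(closure %in% f$universe)) {
    stop("`x` must be a subset of the universe", call. = FALSE)
  }
  pending <- f$fds
  repeat {
    fired <- vapply(pending, function(d) all(d$lhs %in% closure), logical(1))
    if (!any(fired)) break
    added <- vapply(pending[fired], `[[`, character(1), "rhs")
    closure <- as_attrset(c(closure, added))
    pending <- pending[!fired]
    if (length(pending) == 0L) break
  }
  closure
}

#' Reduce a dependency set to a minimum coverage
#'
#' Returns an equivalent dependency set (identical Armstrong closure for
#' every subset of the universe) in which no left-hand attribute is
#' extraneous and no dependency is redundant. Dependencies are processed in
#' canonical order, so the result is deterministic.
#'
#' @param f An [fdset()] with single-attribute right-hand sides.
#' @return A reduced [fdset()] over the same universe.
#' @examples
#' f <- fdset(c("A", "B", "C"),
#'            list(fd("A", "B"), fd("B", "C"), fd("A", "C")))
#' minimum_coverage(f)
#' @export
minimum_coverage <- function(f) {
  fds <- f$fds
  # Left-reduction: drop lhs attributes whose removal leaves rhs derivable.
  for (i in seq_along(fds)) {
    d <- fds[[i]]
    for (a in d$lhs) {
      if (length(d$lhs) == 1L) break
      trimmed <- setdiff(d$lhs, a)
      cur <- fdset(f$universe, fds)
      if (d$rhs %in% armstrong_closure(trimmed, cur)) {
        d <- fd(trimmed, d$rhs)
        fds[[i]] <- d
      }
    }
  }
  # Redundancy elimination: drop any dependency implied by the rest.
  i <- 1L
  while (i <= length(fds)) {
    d <- fds[[i]]
    rest <- fdset(f$universe, fds[-i])
    if (d$rhs %in% armstrong_closure(d$lhs, rest)) {
      fds <- fds[-i]
    } else {
      i <- i + 1L
    }
  }
  fdset(f$universe, fds)
}

#' Enumerate candidate keys of a dependency set
#'
#' A candidate key is a minimal attribute set whose Armstrong closure is the
#' whole universe. The search seeds from the mandatory core — attributes
#' appearing on no right-hand side of the minimum coverage, which therefore
#' belong to every key — and expands breadth-first over the remaining
#' attributes, pruning supersets of keys already found. Breadth-first order
#' plus the core seed guarantees every returned set is minimal.
#'
#' @param f An [fdset()].
#' @param max_keys Abort with an error if more than this many keys are found
#'   (guards against pathological inputs). Default 10000.
#' @return List of canonical attribute sets, each a candidate key, in
#'   discovery (size, then lexicographic) order.
#' @examples
#' f <- fdset(c("A", "B", "C"), list(fd("A", "B"), fd("B", "C")))
#' candidate_keys(f)
#' @export
candidate_keys <- function(f, max_keys = 10000L) {
  U <- f$universe
  if (length(U) == 0L) return(list())
  mc <- minimum_coverage(f)
  rhs_attrs <- unique(vapply(mc$fds, `[[`, character(1), "rhs"))
  core <- setdiff(U, rhs_attrs)
  free <- setdiff(U, core)
  keys <- list()
  for (s in 0:length(free)) {
    combos <- if (s == 0L) list(character(0)) else {
      utils::combn(free, s, simplify = FALSE)
    }
    for (extra in combos) {
      cand <- as_attrset(c(core, extra))
      if (length(cand) == 0L) next
      if (any(vapply(keys, function(k) all(k %in% cand), logical(1)))) next
      if (setequal(armstrong_closure(cand, mc), U)) {
        keys <- c(keys, list(cand))
        if (length(keys) > max_keys) {
          stop(sprintf("more than %d candidate keys; aborting", max_keys),
               call. = FALSE)
        }
      }
    }
  }
  sort_sets_by_size(keys)
}

# Order sets by size, then lexicographically — the stable display order.
sort_sets_by_size <- function(sets) {
  if (length(sets) == 0L) return(sets)
  keys <- vapply(sets, set_key, character(1))
  sets[order(lengths(sets), keys, method = "radix")]
}
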