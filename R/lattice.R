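# Power-set-lattice bookkeeping: canonical attribute sets, oneDown subset
# generation, the strict all-subsets apriori rule for building the next
# candidate level, and closed-form lattice arithmetic.

#' Canonicalize an attribute set
#'
#' Attribute sets are represented as sorted, duplicate-free character
#' vectors (radix order, locale-independent), so equal sets are structurally
#' identical and usable as registry keys.
#'
#' @param x Character vector of attribute names.
#' @return Canonical attribute set.
#' @export
as_attrset <- function(x) {
  x <- as.character(x)
  sort(unique(x), method = "radix")
}

# Registry key for a canonical set.
set_key <- function(x) paste(x, collapse = "\x1f")

key_to_set <- function(key) {
  if (!nzchar(key)) character(0) else strsplit(key, "\x1f", fixed = TRUE)[[1L]]
}

# Sort a list of canonical attribute sets lexicographically by canonical
# form — the documented "generated before" order for equivalence pruning.
sort_sets <- function(sets) {
  if (length(sets) == 0L) return(sets)
  keys <- vapply(sets, set_key, character(1))
  sets[order(keys, method = "radix")]
}

#' All (k-1)-subsets of an attribute set
#'
#' The `oneDown` direction of the lattice: dropping each member in turn.
#'
#' @param x Canonical attribute set of size k.
#' @return List of the k sets of size k-1 (empty list for a singleton).
#' @examples
#' one_down(c("A", "B", "C"))
#' @export
one_down <- function(x) {
  k <- length(x)
  if (k <= 1L) return(list())
  lapply(seq_len(k), function(i) x[-i])
}

#' Generate the next candidate level (strict apriori rule)
#'
#' Builds the (k+1)-level from a k-level of surviving candidates: a set of
#' size k+1 is generated only when *all* of its k-subsets are present in the
#' current level. This strictness is what keeps every checked dependency
#' minimal — a superset of a pruned candidate is never regenerated.
#'
#' @param level List of canonical attribute sets, all of size k.
#' @return List of canonical sets of size k+1 in lexicographic order of
#'   canonical form; empty list when no candidate survives (the termination
#'   signal for the level-wise search).
#' @examples
#' apriori_gen(list(c("A"), c("B")))
#' @export
apriori_gen <- function(level) {
  if (length(level) == 0L) return(list())
  k <- length(level[[1L]])
  stopifnot(all(lengths(level) == k))
  have <- new.env(parent = emptyenv())
  for (x in level) assign(set_key(x), TRUE, envir = have)
  out <- new.env(parent = emptyenv())
  n <- length(level)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      u <- as_attrset(c(level[[i]], level[[j]]))
      if (length(u) != k + 1L) next
      ukey <- set_key(u)
      if (!is.null(out[[ukey]])) next
      ok <- all(vapply(one_down(u), function(s) !is.null(have[[set_key(s)]]),
                       logical(1)))
      if (ok) out[[ukey]] <- u
    }
  }
  keys <- sort(ls(out, sorted = FALSE), method = "radix")
  lapply(keys, function(kk) out[[kk]])
}

#' Size of the dependency search space
#'
#' Closed-form counts for the power-set lattice over `n` attributes: the
#' number of nonempty attribute subsets (`2^n - 1`), the number of
#' candidates once the full set U is discounted (`2^n - 2`), and the number
#' of edges (arrows) in the semi-lattice of possible dependencies
#' (`n * 2^(n-1) - n`).
#'
#' @param n Attribute count (>= 1).
#' @return Named numeric vector with elements `subsets`, `candidates`,
#'   `edges`.
#' @examples
#' lattice_counts(4)
#' @export
lattice_counts <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  c(subsets = 2^n - 1, candidates = 2^n - 2, edges = n * 2^(n - 1) - n)
}
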