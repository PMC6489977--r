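# Partitions of the row set by attribute-set projection, and the
# cardinality-based FD validation they support: X -> Y holds in r(U) iff
# card(pi_X) = card(pi_XY).

# Projection keys: one string per row, unique iff the projections differ.
# \x1f (ASCII unit separator) keeps multi-attribute keys unambiguous.
projection_keys <- function(relation, attrs) {
  idx <- match(attrs, relation$attributes)
  if (anyNA(idx)) {
    stop(sprintf("unknown attribute(s): %s",
                 paste(attrs[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  cols <- relation$data[, idx, drop = FALSE]
  if (nrow(cols) == 0L) return(character(0))
  do.call(paste, c(asplit(cols, 2L), sep = "\x1f"))
}

#' Partition a relation by an attribute set
#'
#' Groups row indices by equal projection on `attrs`: two rows land in the
#' same group iff they agree on every attribute of `attrs`. The number of
#' groups, `card(pi_X)`, is what drives dependency validation.
#'
#' @param relation An [fd_relation()].
#' @param attrs Non-empty character vector of attribute names.
#' @return An object of class `fd_partition` with fields `source` (the
#'   canonical attribute set), `groups` (list of 1-based row-index vectors,
#'   ordered by first occurrence) and `cardinality`.
#' @examples
#' r <- fd_relation(data.frame(C = c(0, 0, 0, 1, 1, 1, 1)))
#' compute_partition(r, "C")$groups
#' @export
compute_partition <- function(relation, attrs) {
  attrs <- as_attrset(attrs)
  if (length(attrs) == 0L) stop("`attrs` must be non-empty", call. = FALSE)
  keys <- projection_keys(relation, attrs)
  groups <- if (length(keys) == 0L) list() else {
    g <- split(seq_along(keys), factor(keys, levels = unique(keys)))
    names(g) <- NULL
    g
  }
  structure(
    list(source = attrs, groups = groups, cardinality = length(groups)),
    class = "fd_partition"
  )
}

#' @rdname compute_partition
#' @param partition An `fd_partition`.
#' @export
partition_cardinality <- function(partition) partition$cardinality

#' @export
print.fd_partition <- function(x, ...) {
  cat(sprintf("<fd_partition on {%s}: %d group(s)>\n",
              paste(x$source, collapse = ","), x$cardinality))
  invisible(x)
}

# card(pi_X) without materializing groups; memoized in `cache` (an
# environment keyed by the canonical set key) when one is supplied.
partition_card <- function(relation, attrs, cache = NULL) {
  key <- set_key(attrs)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  card <- length(unique(projection_keys(relation, attrs)))
  if (!is.null(cache)) cache[[key]] <- card
  card
}

#' Test a functional dependency by partition cardinality
#'
#' `lhs -> rhs` is satisfied iff `card(pi_lhs) = card(pi_(lhs u rhs))`:
#' adding `rhs` to the projection splits no group exactly when rows agreeing
#' on `lhs` already agree on `rhs`.
#'
#' @param relation An [fd_relation()].
#' @param lhs Non-empty attribute set (left-hand side).
#' @param rhs A single attribute name. When `rhs` is in `lhs` the dependency
#'   is trivial and holds by reflexivity.
#' @param cache Optional environment memoizing partition cardinalities.
#' @return `TRUE` or `FALSE`.
#' @export
fd_holds <- function(relation, lhs, rhs, cache = NULL) {
  lhs <- as_attrset(lhs)
  if (length(lhs) == 0L) stop("`lhs` must be non-empty", call. = FALSE)
  stopifnot(length(rhs) == 1L)
  if (rhs %in% lhs) return(TRUE)
  if (!rhs %in% relation$attributes) {
    stop(sprintf("unknown attribute: %s", rhs), call. = FALSE)
  }
  partition_card(relation, lhs, cache) ==
    partition_card(relation, as_attrset(c(lhs, rhs)), cache)
}

#' Test whether an attribute set is a superkey
#'
#' `attrs` is a superkey when no two rows agree on it, i.e. its partition
#' has one group per row.
#'
#' @inheritParams fd_holds
#' @param attrs Non-empty attribute set.
#' @return `TRUE` or `FALSE`.
#' @export
is_superkey <- function(relation, attrs, cache = NULL) {
  attrs <- as_attrset(attrs)
  if (length(attrs) == 0L) stop("`attrs` must be non-empty", call. = FALSE)
  partition_card(relation, attrs, cache) == n_rows(relation)
}
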