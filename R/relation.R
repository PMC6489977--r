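# Relation model and delimited-text loading.
#
# A relation r(U) is an ordered attribute schema U plus a body of tuples.
# Values are opaque tokens compared only for equality; nothing is ever
# coerced numerically, so "0" and "0.0" are distinct values.

#' Construct a relation
#'
#' A relation is the unit of input for functional-dependency discovery: a
#' schema of uniquely named attributes and a body of row tuples whose values
#' are treated as opaque, equality-comparable tokens.
#'
#' @param data A data frame or character matrix. Column names become the
#'   attribute schema; every cell is converted to character.
#' @param name Text label for the relation (used in reports). Defaults to
#'   `"relation"`.
#' @return An object of class `fd_relation` with fields `name`, `attributes`
#'   (ordered character vector) and `data` (character matrix, possibly with
#'   zero rows).
#' @examples
#' r <- fd_relation(data.frame(A = c(1, 1, 2), B = c("x", "x", "y")))
#' n_rows(r)
#' @export
fd_relation <- function(data, name = "relation") {
  if (is.data.frame(data)) {
    attrs <- names(data)
    mat <- vapply(data, function(col) as.character(col), character(nrow(data)))
    if (nrow(data) == 1L) mat <- matrix(mat, nrow = 1L)
    if (nrow(data) == 0L) mat <- matrix(character(0), nrow = 0L, ncol = length(attrs))
  } else if (is.matrix(data)) {
    attrs <- colnames(data)
    mat <- data
    storage.mode(mat) <- "character"
  } else {
    stop("`data` must be a data frame or matrix", call. = FALSE)
  }
  if (is.null(attrs)) stop("input has no attribute (column) names", call. = FALSE)
  mat[is.na(mat)] <- ""
  dimnames(mat) <- NULL
  new_relation(name, attrs, mat)
}

new_relation <- function(name, attributes, data) {
  attributes <- as.character(attributes)
  if (any(!nzchar(attributes))) {
    stop("attribute names must be non-empty", call. = FALSE)
  }
  dup <- attributes[duplicated(attributes)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate attribute name(s): %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  stopifnot(is.matrix(data), ncol(data) == length(attributes))
  structure(
    list(name = name, attributes = attributes, data = data),
    class = "fd_relation"
  )
}

#' @rdname fd_relation
#' @param relation An `fd_relation`.
#' @export
n_rows <- function(relation) nrow(relation$data)

#' @rdname fd_relation
#' @export
n_attributes <- function(relation) length(relation$attributes)

#' @export
print.fd_relation <- function(x, ...) {
  cat(sprintf("<fd_relation '%s': %d rows x %d attributes>\n",
              x$name, n_rows(x), n_attributes(x)))
  cat("attributes:", paste(x$attributes, collapse = ", "), "\n")
  invisible(x)
}

# Separators recognised in .csv/.txt input, in tie-break precedence order.
fd_separators <- function() c(",", "|", ";", ":", "~")

#' Detect the field separator of delimited text
#'
#' Tries, in precedence order, the separators comma, bar, semicolon, colon
#' and tilde, and returns the first one that splits every sampled line into
#' the same number (> 1) of fields.
#'
#' @param sample_lines Character vector of (non-empty) lines, typically the
#'   head of the file.
#' @return A single separator character, or `NA_character_` when no separator
#'   qualifies and the input is a single-column file.
#' @examples
#' detect_separator(c("A,B,C", "0,1,2"))
#' detect_separator(c("A|B", "x|y"))
#' @export
detect_separator <- function(sample_lines) {
  sample_lines <- sample_lines[nzchar(sample_lines)]
  if (length(sample_lines) == 0L) {
    stop("cannot detect a separator: no non-empty lines", call. = FALSE)
  }
  for (sep in fd_separators()) {
    # field count = separator occurrences + 1 (robust to trailing empties)
    counts <- nchar(sample_lines) -
      nchar(gsub(sep, "", sample_lines, fixed = TRUE)) + 1L
    if (counts[1L] > 1L && all(counts == counts[1L])) return(sep)
  }
  # A candidate separator occurs in the header but never yields a consistent
  # field count: the file is malformed rather than single-column.
  present <- vapply(fd_separators(), function(s) grepl(s, sample_lines[1L], fixed = TRUE),
                    logical(1))
  if (any(present)) {
    stop("malformed file: inconsistent field counts for every candidate separator",
         call. = FALSE)
  }
  NA_character_
}

# Split one line on a single-character separator, keeping trailing empty
# fields (strsplit() drops them).
split_fields <- function(line, sep) {
  if (is.na(sep)) return(line)
  hits <- gregexpr(sep, line, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(line)
  starts <- c(1L, hits + 1L)
  stops <- c(hits - 1L, nchar(line))
  substring(line, starts, stops)
}

#' Read a delimited file into a relation
#'
#' The first row of the file is the attribute schema; every remaining row is
#' a tuple. Cells are whitespace-trimmed and kept as opaque strings; empty
#' cells become a single reserved missing token that is equal to itself, so
#' dependency checking stays two-valued.
#'
#' @param path Path to a `.csv` or `.txt` file (UTF-8, header row mandatory),
#'   or to an `.rds` file holding a serialized data frame.
#' @param separator Optional single separator character; when `NULL` it is
#'   auto-detected from the first 20 non-empty lines (see
#'   [detect_separator()]).
#' @return An [fd_relation()] named after the file.
#' @export
read_relation <- function(path, separator = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  name <- tools::file_path_sans_ext(basename(path))
  if (ext == "rds") {
    obj <- readRDS(path)
    if (!is.data.frame(obj)) stop("serialized input must be a data frame", call. = FALSE)
    return(fd_relation(obj, name = name))
  }
  if (!ext %in% c("csv", "txt")) {
    stop(sprintf("unsupported file extension '.%s' (expected .csv, .txt or .rds)", ext),
         call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
  if (is.null(separator)) {
    separator <- detect_separator(utils::head(lines, 20L))
  } else {
    if (!is.character(separator) || nchar(separator) != 1L) {
      stop("`separator` must be a single character", call. = FALSE)
    }
  }
  fields <- lapply(lines, split_fields, sep = separator)
  fields <- lapply(fields, trimws)
  header <- fields[[1L]]
  arity <- length(header)
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != arity)) {
    bad <- which(widths != arity)[1L]
    stop(sprintf("ragged row at line %d: %d field(s), expected %d",
                 line_no[-1L][bad], widths[bad], arity), call. = FALSE)
  }
  mat <- if (length(body) == 0L) {
    matrix(character(0), nrow = 0L, ncol = arity)
  } else {
    matrix(unlist(body, use.names = FALSE), nrow = length(body),
           ncol = arity, byrow = TRUE)
  }
  new_relation(name, header, mat)
}

#' Write a relation as delimited text
#'
#' Serializes the schema and body back to a header-plus-rows text file;
#' reading the result with [read_relation()] round-trips the relation.
#'
#' @param relation An `fd_relation`.
#' @param path Output file path.
#' @param separator Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_relation <- function(relation, path, separator = ",") {
  body <- if (n_rows(relation) == 0L) character(0) else {
    apply(relation$data, 1L, paste, collapse = separator)
  }
  lines <- c(paste(relation$attributes, collapse = separator), body)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
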