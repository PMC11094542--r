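#' ASV abundance tables
#'
#' An `asv_table` is a numeric samples x ASVs matrix carrying an
#' `is_relative` flag. Constructors accept either a matrix with dimnames or a
#' data frame whose first column holds sample identifiers; all user-facing
#' functions in the package accept any of these forms.
#'
#' Invariants enforced at construction: no negative entries, unique sample and
#' ASV identifiers, no all-zero sample rows, and (for relative tables) rows
#' summing to 1 within 1e-9.
#'
#' @param x numeric matrix (samples x ASVs, with dimnames) or data frame with
#'   an ID column first and one numeric column per ASV.
#' @param is_relative logical; `TRUE` if entries are per-sample relative
#'   abundances.
#' @return an `asv_table` (matrix subclass).
#' @export
asv_table <- function(x, is_relative = FALSE) {
  if (inherits(x, "asv_table")) return(x)
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    if (!is.numeric(m)) stopf("non-numeric abundance values in ASV table")
    rownames(m) <- ids
  } else if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stopf("ASV matrix must carry sample and ASV names as dimnames")
  } else {
    stopf("cannot interpret a %s as an ASV table", class(x)[1])
  }
  validate_asv_matrix(m, is_relative)
  structure(m, is_relative = is_relative, class = c("asv_table", class(m)))
}

validate_asv_matrix <- function(m, is_relative) {
  if (anyNA(m)) stopf("ASV table contains missing values")
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stopf("negative abundance at sample '%s', ASV '%s'",
          rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]])
  if (anyDuplicated(rownames(m))) stopf("duplicate sample IDs in ASV table")
  if (anyDuplicated(colnames(m))) stopf("duplicate ASV IDs in ASV table")
  rs <- rowSums(m)
  if (any(rs == 0))
    stopf("all-zero sample row: '%s'", rownames(m)[which(rs == 0)[1]])
  if (is_relative && any(abs(rs - 1) > 1e-9))
    stopf("relative-abundance rows must sum to 1 (sample '%s' sums to %g)",
          rownames(m)[which.max(abs(rs - 1))], rs[which.max(abs(rs - 1))])
  invisible(m)
}

# canonical numeric matrix view of any accepted table form
as_asv_matrix <- function(x, is_relative = FALSE) {
  unclass_matrix(asv_table(x, is_relative = is_relative))
}

unclass_matrix <- function(x) {
  attr(x, "is_relative") <- NULL
  class(x) <- setdiff(class(x), "asv_table")
  x
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %d samples x %d ASVs (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "is_relative"))) "relative" else "counts"))
  print(utils::head(unclass_matrix(x)[, seq_len(min(6, ncol(x))), drop = FALSE]))
  invisible(x)
}

#' @rdname asv_table
#' @param ... unused.
#' @export
as_tibble.asv_table <- function(x, ...) {
  tibble::as_tibble(unclass_matrix(x), rownames = "sample_id")
}

#' Is an ASV table on the relative-abundance scale?
#' @param x an `asv_table`.
#' @return logical flag.
#' @export
is_relative <- function(x) isTRUE(attr(x, "is_relative"))

#' Convert a count table to relative abundances
#'
#' Each sample row is divided by its own total, so rows sum to 1. Conversion
#' always uses the per-sample totals of the table as given; subset a table
#' only after converting, so abundance cutoffs refer to the whole community.
#'
#' @param table counts (`asv_table`, matrix or data frame). Already-relative
#'   tables pass through unchanged.
#' @return a relative `asv_table`.
#' @export
to_relative <- function(table) {
  tab <- asv_table(table, is_relative = is_relative_guess(table))
  if (is_relative(tab)) return(tab)
  m <- unclass_matrix(tab)
  m <- m / rowSums(m)
  asv_table(m, is_relative = TRUE)
}

is_relative_guess <- function(x) {
  if (inherits(x, "asv_table")) return(is_relative(x))
  FALSE
}
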