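#' Coerce and validate a binary item-response matrix
#'
#' Accepts a matrix or data frame of item scores and returns a validated
#' integer matrix with one row per subject and one column per item. Every
#' entry must be 0 or 1; missing values are rejected. At least three items
#' are required, because testing an item pair needs at least one remaining
#' item to condition on.
#'
#' @param data A matrix or data frame of 0/1 item scores (rows = subjects,
#'   columns = items).
#' @return An integer matrix with column names (items are named `V1`, `V2`,
#'   ... when the input has none).
#' @export
#' @examples
#' X <- as_item_matrix(data.frame(a = c(0, 1, 1), b = c(1, 0, 1), c = c(0, 0, 1)))
#' dim(X)
as_item_matrix <- function(data) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data)) {
    stop("`data` must be a matrix or data frame of item scores.", call. = FALSE)
  }
  if (anyNA(data)) stop("item scores must not contain missing values.", call. = FALSE)
  storage.mode(data) <- "integer"
  if (!all(data == 0L | data == 1L)) {
    stop("item scores must all be 0 or 1.", call. = FALSE)
  }
  if (ncol(data) < 3L) {
    stop("at least 3 items are required (J >= 3).", call. = FALSE)
  }
  if (nrow(data) < 1L) stop("at least one subject is required.", call. = FALSE)
  if (is.null(colnames(data))) colnames(data) <- paste0("V", seq_len(ncol(data)))
  rownames(data) <- NULL
  data
}

#' Read / write an item-response matrix as CSV
#'
#' The on-disk format is a plain CSV with a header row of item names and one
#' row of strictly 0/1 cells per subject.
#'
#' @param path File path.
#' @return `read_item_matrix()` returns a validated integer matrix;
#'   `write_item_matrix()` returns `path` invisibly.
#' @export
read_item_matrix <- function(path) {
  as_item_matrix(read.csv(path, check.names = FALSE))
}

#' @rdname read_item_matrix
#' @param data A matrix or data frame accepted by [as_item_matrix()].
#' @export
write_item_matrix <- function(data, path) {
  X <- as_item_matrix(data)
  write.csv(as.data.frame(X), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Number of item pairs
#'
#' @param J Number of items (at least 2).
#' @return `J * (J - 1) / 2`, the length of the vector of pairwise statistics.
#' @export
#' @examples
#' pair_count(10) # 45
pair_count <- function(J) {
  if (!is.numeric(J) || length(J) != 1L || is.na(J) || J < 2) {
    stop("`J` must be a single number >= 2.", call. = FALSE)
  }
  as.integer(J * (J - 1) / 2)
}

#' Canonical ordering of item pairs
#'
#' All pairwise statistics in the package are stacked into a vector of length
#' `K = J(J-1)/2` in lexicographic order of `(i, j)` with `i < j`; `k` is the
#' linear position in that ordering. The ordering is fixed for a whole run.
#'
#' @param J Number of items.
#' @return A tibble with columns `pair_i`, `pair_j`, `k`.
#' @export
pair_grid <- function(J) {
  if (J < 2) stop("`J` must be >= 2.", call. = FALSE)
  i <- rep(seq_len(J - 1L), times = (J - 1L):1L)
  j <- unlist(lapply(seq_len(J - 1L), function(a) (a + 1L):J), use.names = FALSE)
  tibble::tibble(pair_i = i, pair_j = as.integer(j), k = seq_along(i))
}
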