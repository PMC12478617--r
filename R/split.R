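#' Split subjects into a training and a test sample
#'
#' The CARP statistics estimate the conditioning weights in a training sample
#' and compute the conditional covariances in a disjoint test sample. The
#' split is a uniformly random partition: `round(fraction * N)` subjects go to
#' the training sample and the rest to the test sample. The default fraction
#' of 0.30 is the setting used throughout the simulation studies.
#'
#' @param n Number of subjects, or an object accepted by [as_item_matrix()]
#'   (its row count is used).
#' @param fraction Proportion of subjects in the training sample, in (0, 1).
#' @param seed Optional integer seed; when supplied, the partition is
#'   reproducible and the caller's RNG state is left untouched.
#' @return A list of class `acarp_split` with integer index vectors `train`
#'   and `test`, plus `fraction` and `seed`.
#' @export
#' @examples
#' s <- split_sample(10, fraction = 0.3, seed = 1)
#' length(s$train) # 3
split_sample <- function(n, fraction = 0.3, seed = NULL) {
  if (!is.numeric(n)) n <- nrow(as_item_matrix(n))
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 subjects to split.", call. = FALSE)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be a single value in (0, 1).", call. = FALSE)
  }
  n_train <- as.integer(round(fraction * n))
  if (n_train == 0L || n_train == n) {
    stop("degenerate split: round(fraction * N) must be strictly between 0 and N.",
         call. = FALSE)
  }
  train <- with_seed(seed, sort(sample.int(n, n_train)))
  structure(
    list(train = train, test = setdiff(seq_len(n), train),
         fraction = fraction, seed = seed),
    class = "acarp_split"
  )
}

# Evaluate `expr` under `seed` (if non-NULL) without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Spawn `n` replication seeds from one master seed. Substreams make
# replications order-independent: seeds are drawn up front, so running
# replication r never depends on having run 1..r-1.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
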