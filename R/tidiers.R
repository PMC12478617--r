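#' Tidy an omnibus test result
#'
#' @param x An `acarp_omnibus` object.
#' @param ... Unused.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p`, `reject`,
#'   `n_selected`, `n_excluded`.
#' @method tidy acarp_omnibus
#' @export
tidy.acarp_omnibus <- function(x, ...) {
  df <- if (is.numeric(x$df_or_weights) && length(x$df_or_weights) == 1L) {
    as.numeric(x$df_or_weights)
  } else NA_real_
  tibble::tibble(test = x$test, statistic = x$statistic, df = df,
                 p = x$p, reject = x$reject,
                 n_selected = x$n_selected, n_excluded = x$n_excluded)
}

#' @rdname tidy.acarp_omnibus
#' @method glance acarp_omnibus
#' @export
glance.acarp_omnibus <- function(x, ...) {
  tibble::tibble(test = x$test, reference = x$reference, p = x$p,
                 reject = x$reject, alpha = x$alpha)
}

#' Tidy pairwise statistics
#'
#' @param x An `acarp_pairstats` tibble.
#' @param ... Unused.
#' @return The underlying tibble (one row per item pair).
#' @method tidy acarp_pairstats
#' @export
tidy.acarp_pairstats <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "acarp_pairstats")
  attr(out, "context") <- NULL
  out
}

#' @rdname tidy.acarp_pairstats
#' @method glance acarp_pairstats
#' @export
glance.acarp_pairstats <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_degenerate = sum(x$degenerate),
    n_train = attr(x, "n_train"),
    n_test = attr(x, "n_test"),
    C = attr(x, "C"),
    continuity = attr(x, "continuity"),
    conditioning = attr(x, "conditioning"),
    min_mcc = min(x$mcc),
    min_z = suppressWarnings(min(x$z, na.rm = TRUE))
  )
}

#' Tidy a rejection grid
#'
#' @param x An `acarp_rejection` object.
#' @param ... Unused.
#' @return The `rates` tibble (one row per design x test cell).
#' @method tidy acarp_rejection
#' @export
tidy.acarp_rejection <- function(x, ...) x$rates

#' @rdname tidy.acarp_rejection
#' @method glance acarp_rejection
#' @export
glance.acarp_rejection <- function(x, ...) {
  tibble::tibble(
    n_designs = length(unique(x$rates$design)),
    n_tests = length(unique(x$rates$test)),
    alpha = x$alpha,
    max_rate = max(x$rates$rate, na.rm = TRUE),
    total_missing = sum(x$rates$n_missing)
  )
}
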