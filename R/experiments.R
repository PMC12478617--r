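#' Monte-Carlo rejection-rate grid
#'
#' Runs a set of simulation designs for a set of named omnibus tests and
#' tabulates rejection proportions, the Monte-Carlo backbone of the Type I
#' error and power studies. For every design x replication: generate a
#' response matrix, split, compute pairwise statistics once, and apply every
#' requested aggregation to them. Each replication gets its own seed spawned
#' up front from the master seed, so results are identical regardless of
#' execution order.
#'
#' A replication in which a test cannot be computed (e.g. every pair
#' degenerate) is recorded as missing and excluded from that cell's
#' denominator, with the count reported.
#'
#' @param designs An [sim_design()] object or list of them. Designs may be
#'   named; unnamed designs get `scenario/J/N` labels.
#' @param tests Character vector of test codes.
#' @param alpha Nominal significance level.
#' @param seed Master seed.
#' @param t,B,n_draws,C,conditioning Analysis settings (see
#'   [run_tests_on_stats()] and [pair_stats()]).
#' @param keep_pvalues Keep the per-replication p-values (needed for the
#'   p-value diagnostics)?
#' @return A list of class `acarp_rejection`: `rates` (tibble with `design`,
#'   `test`, `rate`, `n_rejected`, `n_reps`, `n_missing`), `pvalues` (tibble
#'   or NULL), `alpha`, `seed`.
#' @export
run_rejection_grid <- function(designs, tests, alpha = 0.05, seed = NULL,
                               t = 0.5, B = 1000, n_draws = 10000, C = 10,
                               conditioning = "carp", keep_pvalues = TRUE) {
  if (inherits(designs, "acarp_design")) designs <- list(designs)
  lapply(tests, parse_test_code)
  labels <- names(designs)
  auto <- vapply(designs, function(d)
    sprintf("%s J=%d N=%d", d$scenario, d$J, d$N), "")
  if (is.null(labels)) labels <- auto else labels[labels == ""] <- auto[labels == ""]
  labels <- make.unique(labels)

  total_reps <- sum(vapply(designs, `[[`, 1L, "n_reps"))
  rep_seeds <- if (is.null(seed)) rep(NA_integer_, total_reps) else
    spawn_seeds(seed, total_reps)
  offset <- 0L

  rate_rows <- list()
  pval_rows <- list()
  for (d in seq_along(designs)) {
    des <- designs[[d]]
    R <- des$n_reps
    P <- matrix(NA_real_, R, length(tests), dimnames = list(NULL, tests))
    REJ <- matrix(NA, R, length(tests), dimnames = list(NULL, tests))
    for (r in seq_len(R)) {
      ms <- rep_seeds[offset + r]
      ss <- if (is.na(ms)) rep(NA_integer_, 3) else spawn_seeds(ms, 3)
      res <- tryCatch({
        X <- simulate_irt(des, seed = if (is.na(ss[1])) NULL else ss[1])
        stats <- pair_stats(X, train_fraction = des$train_fraction, C = C,
                            continuity = des$continuity,
                            conditioning = conditioning,
                            seed = if (is.na(ss[2])) NULL else ss[2])
        run_tests_on_stats(stats, tests, alpha = alpha, t = t, B = B,
                           n_draws = n_draws,
                           seed = if (is.na(ss[3])) NULL else ss[3])
      }, error = function(e) NULL)
      if (!is.null(res)) {
        P[r, ] <- vapply(res, `[[`, 0, "p")
        REJ[r, ] <- vapply(res, `[[`, TRUE, "reject")
      }
    }
    offset <- offset + R
    ok <- !is.na(P[, 1L])
    rate_rows[[d]] <- tibble::tibble(
      design = labels[d], test = tests,
      n_rejected = colSums(REJ[ok, , drop = FALSE]),
      n_reps = sum(ok),
      n_missing = R - sum(ok),
      rate = .data$n_rejected / .data$n_reps
    )
    if (keep_pvalues) {
      pval_rows[[d]] <- tibble::tibble(
        design = labels[d],
        test = rep(tests, each = R),
        rep = rep(seq_len(R), times = length(tests)),
        p = as.vector(P),
        reject = as.vector(REJ)
      )
    }
  }
  structure(
    list(rates = dplyr::bind_rows(rate_rows),
         pvalues = if (keep_pvalues) dplyr::bind_rows(pval_rows) else NULL,
         alpha = alpha, seed = seed),
    class = "acarp_rejection"
  )
}

#' @export
print.acarp_rejection <- function(x, ...) {
  cat(sprintf("ACARP rejection grid (alpha = %g)\n", x$alpha))
  print(tidyr::pivot_wider(x$rates[, c("design", "test", "rate")],
                           names_from = "design", values_from = "rate"))
  invisible(x)
}

#' Schweder--Spjotvoll p-value diagnostics
#'
#' Sorts the replication p-values of each test within each design and pairs
#' them with their ranks. Plotted against rank, uniform p-values fall on the
#' diagonal; points above the diagonal (supra-uniform p-values) are the
#' signature of monotone homogeneity with informative items.
#'
#' @param x An [run_rejection_grid()] result (with p-values kept) or a data
#'   frame with columns `test` and `p` (optionally `design`).
#' @return A tibble of class `acarp_pvalues` with `design`, `test`, `rank`,
#'   `p`, `uniform_ref` (the diagonal reference `rank / (n + 1)`).
#' @export
pvalue_diagnostics <- function(x) {
  df <- if (inherits(x, "acarp_rejection")) {
    if (is.null(x$pvalues)) stop("grid was run with keep_pvalues = FALSE.", call. = FALSE)
    x$pvalues
  } else {
    tibble::as_tibble(x)
  }
  if (!"design" %in% names(df)) df$design <- "all"
  if (nrow(df) == 0L || !all(c("test", "p") %in% names(df))) {
    stop("need at least one p-value with `test` and `p` columns.", call. = FALSE)
  }
  out <- df |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::group_by(.data$design, .data$test) |>
    dplyr::arrange(.data$p, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  uniform_ref = .data$rank / (dplyr::n() + 1)) |>
    dplyr::ungroup() |>
    dplyr::select("design", "test", "rank", "p", "uniform_ref")
  class(out) <- c("acarp_pvalues", class(out))
  out
}

#' Binomial stochastic-dominance summary of rejection counts
#'
#' For each test, compares the empirical distribution of per-cell rejection
#' counts across the grid against the Binomial(n_reps, alpha) reference. The
#' Type I error is judged under control when the empirical cumulative
#' distribution lies above the binomial one at every count (rejections
#' stochastically smaller than nominal).
#'
#' @param rates An [run_rejection_grid()] result or its `rates` tibble.
#' @param alpha Reference binomial probability (defaults to the grid's).
#' @return A tibble with one row per test: `test`, `n_cells`, `dominated`
#'   (logical), `max_cdf_violation` (0 when dominance holds), and
#'   `max_rate`. Cells flagged when a rate reaches `2 * alpha`.
#' @export
summarize_binomial_dominance <- function(rates, alpha = NULL) {
  if (inherits(rates, "acarp_rejection")) {
    if (is.null(alpha)) alpha <- rates$alpha
    rates <- rates$rates
  }
  if (is.null(alpha)) alpha <- 0.05
  rates |>
    dplyr::group_by(.data$test) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      dominated = {
        ks <- 0:max(.data$n_reps)
        emp <- vapply(ks, function(k) mean(.data$n_rejected <= k), 0)
        ref <- pbinom(ks, size = max(.data$n_reps), prob = alpha)
        all(emp >= ref - 1e-12)
      },
      max_cdf_violation = {
        ks <- 0:max(.data$n_reps)
        emp <- vapply(ks, function(k) mean(.data$n_rejected <= k), 0)
        ref <- pbinom(ks, size = max(.data$n_reps), prob = alpha)
        max(c(0, ref - emp))
      },
      max_rate = max(.data$rate),
      inflated_cells = sum(.data$rate >= 2 * alpha),
      .groups = "drop"
    )
}
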