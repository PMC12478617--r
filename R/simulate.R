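#' Describe a simulation scenario
#'
#' A design bundles everything needed to generate binary response matrices
#' from the compensatory two-dimensional 2PL model
#' `P(X_j = 1 | theta) = plogis(a_j1 theta1 + a_j2 theta2 + b_j)` with
#' `theta` bivariate standard normal, correlation 0 (no 1.7 scaling constant
#' in the parametrization). Three dimensionality scenarios are supported:
#'
#' * `dim0`: all discriminations 0 — items are i.i.d. Bernoulli(plogis(b)).
#' * `dim1`: every item loads on dimension 1 only (monotone homogeneity
#'   holds).
#' * `dim2`: items split evenly over the two dimensions (dimension 1 takes
#'   the extra item when `J` is odd); each item loads on exactly one
#'   dimension. Between-dimension pairs violate unidimensionality.
#'
#' Item parameters are either fixed constants (`a`, `b`) or drawn uniformly
#' per item from ranges (`a_range`, `b_range`).
#'
#' @param J Number of items (>= 3; `dim2` needs >= 4).
#' @param N Number of subjects.
#' @param scenario `"dim0"`, `"dim1"` or `"dim2"`.
#' @param a,b Fixed discrimination (on the loading dimension) and intercept.
#' @param a_range,b_range When non-NULL, per-item uniform sampling ranges
#'   that override the fixed values.
#' @param n_reps Replications (used by the experiment harness).
#' @param seed Master seed.
#' @param continuity,train_fraction,alpha Analysis settings carried along for
#'   the harness.
#' @return A list of class `acarp_design`.
#' @export
sim_design <- function(J, N, scenario = c("dim1", "dim0", "dim2"),
                       a = 1, b = 0, a_range = NULL, b_range = NULL,
                       n_reps = 1, seed = NULL, continuity = TRUE,
                       train_fraction = 0.3, alpha = 0.05) {
  scenario <- match.arg(scenario)
  if (J < 3) stop("`J` must be >= 3.", call. = FALSE)
  if (scenario == "dim2" && J < 4) {
    stop("invalid design: `dim2` needs J >= 4 so each dimension has two items.",
         call. = FALSE)
  }
  if (N < 10) stop("`N` must be >= 10.", call. = FALSE)
  if (!is.null(a_range) && min(a_range) < 0) {
    stop("discrimination range must be nonnegative (monotone regressions).",
         call. = FALSE)
  }
  structure(
    list(J = as.integer(J), N = as.integer(N), scenario = scenario,
         a = a, b = b, a_range = a_range, b_range = b_range,
         n_reps = as.integer(n_reps), seed = seed,
         continuity = continuity, train_fraction = train_fraction,
         alpha = alpha),
    class = "acarp_design"
  )
}

#' Loading pattern for a dimensionality scenario
#'
#' @param J Number of items.
#' @param scenario Scenario label.
#' @return A tibble with columns `item` and `dimension` (0 = no loading,
#'   1 or 2 = loading dimension). `J1 + J2 = J` always holds for `dim2`.
#' @export
scenario_loadings <- function(J, scenario = c("dim1", "dim0", "dim2")) {
  scenario <- match.arg(scenario)
  if (J < 3) stop("`J` must be >= 3.", call. = FALSE)
  dim <- switch(scenario,
    dim0 = rep(0L, J),
    dim1 = rep(1L, J),
    dim2 = {
      if (J < 4) stop("invalid design: `dim2` needs J >= 4.", call. = FALSE)
      c(rep(1L, ceiling(J / 2)), rep(2L, floor(J / 2)))
    })
  tibble::tibble(item = seq_len(J), dimension = dim)
}

#' Draw or fix the item parameters of a design
#'
#' In fixed mode every loading item gets discrimination `a` and intercept
#' `b`. In random mode (ranges supplied) each item's loading discrimination
#' and intercept are drawn independently and uniformly from the ranges.
#' Non-loading discriminations are always 0.
#'
#' @param design An [sim_design()] object.
#' @param seed Optional seed for random mode.
#' @return A tibble of class `acarp_params` with columns `item`, `a1`, `a2`,
#'   `b`.
#' @export
make_parameters <- function(design, seed = NULL) {
  J <- design$J
  load <- scenario_loadings(J, design$scenario)$dimension
  with_seed(seed, {
    av <- if (is.null(design$a_range)) rep_len(design$a, J) else
      runif(J, design$a_range[1], design$a_range[2])
    bv <- if (is.null(design$b_range)) rep_len(design$b, J) else
      runif(J, design$b_range[1], design$b_range[2])
    out <- tibble::tibble(
      item = seq_len(J),
      a1 = ifelse(load == 1L, av, 0),
      a2 = ifelse(load == 2L, av, 0),
      b = bv
    )
    class(out) <- c("acarp_params", class(out))
    out
  })
}

#' Item response probability under the 2PL model
#'
#' `P(X = 1 | theta) = plogis(a1 * theta1 + a2 * theta2 + b)`.
#'
#' @param theta1,theta2 Latent trait values.
#' @param a1,a2,b Item parameters.
#' @return Response probabilities.
#' @export
response_probability <- function(theta1, theta2, a1, a2, b) {
  plogis(a1 * theta1 + a2 * theta2 + b)
}

#' Generate a binary response matrix
#'
#' Draws `N` latent trait vectors from the uncorrelated bivariate standard
#' normal and, per item, independent Bernoulli responses at the 2PL
#' probabilities. Reproducible for a fixed seed.
#'
#' @param params An [make_parameters()] tibble (or any data frame with
#'   columns `a1`, `a2`, `b`).
#' @param N Number of subjects.
#' @param seed Optional seed.
#' @return An item-response matrix (`N` x `J`, 0/1).
#' @export
generate_responses <- function(params, N, seed = NULL) {
  J <- nrow(params)
  with_seed(seed, {
    theta <- matrix(rnorm(2 * N), N, 2)
    eta <- theta %*% rbind(params$a1, params$a2) +
      matrix(params$b, N, J, byrow = TRUE)
    X <- (matrix(runif(N * J), N, J) < plogis(eta)) + 0L
    colnames(X) <- paste0("V", seq_len(J))
    X
  })
}

#' Simulate one response matrix from a design
#'
#' Convenience wrapper: parameters (fixed or random) and responses in one
#' call, both driven by `seed`.
#'
#' @param design An [sim_design()] object.
#' @param seed Seed (defaults to the design's own).
#' @return An item-response matrix.
#' @export
simulate_irt <- function(design, seed = design$seed) {
  seeds <- if (is.null(seed)) c(NA, NA) else spawn_seeds(seed, 2)
  params <- make_parameters(design, seed = if (is.null(seed)) NULL else seeds[1])
  generate_responses(params, design$N, seed = if (is.null(seed)) NULL else seeds[2])
}
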