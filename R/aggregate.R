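#' Project a statistic vector onto the nonnegative cone
#'
#' Solves `min (x - theta)' Sigma^{-1} (x - theta)` subject to `theta >= 0`.
#' The minimized squared Mahalanobis distance is the chi-bar-square
#' statistic. Following the standard algorithm, the problem is whitened with
#' the Cholesky factor of `Sigma` and solved as a nonnegative least-squares
#' problem; with `Sigma = I` the solution is coordinatewise clipping
#' `theta* = pmax(x, 0)`.
#'
#' @param x Numeric vector of pairwise statistics (length K).
#' @param sigma An `acarp_cov` object or K x K positive-definite matrix
#'   (repair with [repair_psd()] first if needed).
#' @return A list of class `acarp_cone`: `theta_star`, `chibar_sq`,
#'   `n_active` (number of binding zero coordinates of `theta*`).
#' @export
#' @examples
#' project_nonneg_cone(c(-1, 2, -3), diag(3)) # chibar_sq = 10, n_active = 2
project_nonneg_cone <- function(x, sigma) {
  S <- cov_matrix(sigma)
  K <- length(x)
  stopifnot(nrow(S) == K)
  if (is_identity(S)) {
    theta <- pmax(x, 0)
    return(structure(
      list(theta_star = theta, chibar_sq = sum(pmin(x, 0)^2),
           n_active = sum(x < 0)),
      class = "acarp_cone"
    ))
  }
  R <- tryCatch(chol(S), error = function(e) {
    stop("`sigma` is not positive definite; apply repair_psd() first.", call. = FALSE)
  })
  L <- t(R)
  Linv <- forwardsolve(L, diag(K))
  fit <- pracma::lsqnonneg(Linv, drop(Linv %*% x))
  theta <- fit$x
  resid <- drop(Linv %*% (x - theta))
  chibar <- sum(resid^2)
  # Lagrange multipliers of the active constraints: Sigma^{-1} (theta - x)
  lambda <- drop(crossprod(Linv) %*% (theta - x))
  tol <- 1e-8 * max(1, max(abs(x)))
  structure(
    list(theta_star = theta, chibar_sq = chibar,
         n_active = sum(theta <= tol & lambda > tol)),
    class = "acarp_cone"
  )
}

cov_matrix <- function(sigma) {
  if (inherits(sigma, "acarp_cov")) sigma$matrix else as.matrix(sigma)
}

is_identity <- function(S, tol = 1e-12) {
  nrow(S) == ncol(S) && max(abs(S - diag(nrow(S)))) < tol
}

#' Monte-Carlo chi-bar-square mixture weights
#'
#' Under the least favorable null the chi-bar-square statistic is a mixture
#' of chi-square distributions; the mixture weight `w_k` is the probability
#' that exactly `k` coordinates of a `N(0, Sigma)` draw are negative. Weights
#' are estimated by Monte-Carlo counting over `n_draws` draws. For
#' `Sigma = I_K` the weights are exactly `Binomial(K, 1/2)`; see
#' [chibar_weights_identity()].
#'
#' @param sigma `acarp_cov` or positive-semidefinite matrix.
#' @param n_draws Number of Monte-Carlo draws (default 10000).
#' @param seed Optional seed.
#' @return Object of class `acarp_chibar_weights`: numeric `weights`
#'   (`w_0 ... w_K`, summing to 1), `n_draws`, `seed`.
#' @export
chibar_weights <- function(sigma, n_draws = 10000, seed = NULL) {
  S <- cov_matrix(repair_psd(sigma)$matrix)
  K <- nrow(S)
  R <- chol(S)
  n_neg <- with_seed(seed, {
    Z <- matrix(rnorm(n_draws * K), n_draws, K) %*% R
    rowSums(Z < 0)
  })
  w <- tabulate(n_neg + 1L, nbins = K + 1L) / n_draws
  structure(list(weights = stats::setNames(w, paste0("w", 0:K)),
                 n_draws = n_draws, seed = seed),
            class = "acarp_chibar_weights")
}

#' Exact chi-bar-square weights under the identity covariance
#'
#' With independent standard-normal coordinates the number of negative
#' coordinates is `Binomial(K, 1/2)`, so the mixture weights are known in
#' closed form and no Monte-Carlo is needed.
#'
#' @param K Number of coordinates.
#' @rdname chibar_weights
#' @export
chibar_weights_identity <- function(K) {
  structure(list(weights = stats::setNames(dbinom(0:K, K, 0.5), paste0("w", 0:K)),
                 n_draws = Inf, seed = NULL),
            class = "acarp_chibar_weights")
}

#' Chi-bar-square p-value for the LR test
#'
#' `p = sum_{k >= 1} w_k * SF_{chisq_k}(q)`; the `k = 0` component
#' contributes nothing for `q > 0`, and `p = 1` when `q = 0`.
#'
#' @param chibar_sq Observed chi-bar-square statistic (>= 0).
#' @param weights An [chibar_weights()] object or numeric vector `w_0..w_K`.
#' @return The p-value.
#' @export
lr_pvalue <- function(chibar_sq, weights) {
  w <- if (inherits(weights, "acarp_chibar_weights")) weights$weights else weights
  if (chibar_sq <= 0) return(1)
  K <- length(w) - 1L
  if (K < 1L) return(1)
  sum(w[-1L] * pchisq(chibar_sq, df = seq_len(K), lower.tail = FALSE))
}

#' Conditional (Wollan--Dykstra) chi-bar-square p-value
#'
#' Conditions on the number of binding nonnegativity constraints `D`: given
#' `D = d >= 1`, the chi-bar-square statistic is chi-square with `d` degrees
#' of freedom. With `D = 0` (all statistics nonnegative) the test never
#' rejects (`p = 1`); the correction factor for the probability of that
#' event is ignored, as it is negligible for five or more items.
#'
#' @param chibar_sq Observed statistic.
#' @param n_active Number of binding zero coordinates of the projection.
#' @return List with `p` and `reject_at(alpha)`, the decision rule
#'   `chibar_sq > qchisq(1 - alpha, df = n_active)`.
#' @export
cl_pvalue <- function(chibar_sq, n_active) {
  if (n_active < 1L) {
    return(list(p = 1, reject_at = function(alpha) FALSE))
  }
  list(
    p = pchisq(chibar_sq, df = n_active, lower.tail = FALSE),
    reject_at = function(alpha) chibar_sq > qchisq(1 - alpha, df = n_active)
  )
}

# ---- selections -------------------------------------------------------

#' Preselect item pairs on the training sample
#'
#' The preselected set S contains the pairs whose *training-sample* MCC is
#' negative. Because the training and test samples are independent, the
#' selection is independent of the test statistics, so test-sample p-values
#' over S can be combined as if S were fixed in advance.
#'
#' @param stats An [pair_stats()] tibble.
#' @return Object of class `acarp_selection` with `k` (canonical pair
#'   positions), `provenance = "preselected_train"`, `size`.
#' @export
preselect <- function(stats) {
  keep <- which(stats$train_mcc < 0 & !stats$degenerate)
  structure(list(k = stats$k[keep], provenance = "preselected_train",
                 threshold = NA_real_, size = length(keep)),
            class = "acarp_selection")
}

#' Conditionalized selection of test-sample p-values
#'
#' Selects the pairs with test p-value below `t` and carries the corrected
#' p-values `p / t`. With the default `t = 0.5` this keeps (up to the
#' continuity shift) the pairs with negative standardized statistics; if the
#' raw p-values are uniform, the corrected p-values are again uniform given
#' selection, so ordinary combiners apply to them unchanged.
#'
#' @param stats An [pair_stats()] tibble.
#' @param t Selection threshold in (0, 1].
#' @return Object of class `acarp_selection` with `k`, `corrected_p`,
#'   `provenance = "conditionalized_test"`, `threshold`, `size`.
#' @export
conditional_select <- function(stats, t = 0.5) {
  if (!(t > 0 && t <= 1)) stop("`t` must be in (0, 1].", call. = FALSE)
  keep <- which(!stats$degenerate & stats$p < t)
  structure(list(k = stats$k[keep], corrected_p = stats$p[keep] / t,
                 provenance = "conditionalized_test", threshold = t,
                 size = length(keep)),
            class = "acarp_selection")
}

clamp_p <- function(p, floor = 1e-300) {
  n0 <- sum(p < floor)
  if (n0 > 0) message(sprintf("%d p-value(s) clamped at %g before log.", n0, floor))
  pmax(p, floor)
}

new_omnibus <- function(test, statistic, reference, df_or_weights, p, reject,
                        alpha, selection = NULL, n_excluded = 0L) {
  structure(
    list(test = test, statistic = statistic, reference = reference,
         df_or_weights = df_or_weights, p = p, reject = reject, alpha = alpha,
         selection = selection,
         n_selected = if (is.null(selection)) NA_integer_ else selection$size,
         n_excluded = n_excluded),
    class = "acarp_omnibus"
  )
}

#' @export
print.acarp_omnibus <- function(x, ...) {
  cat(sprintf("ACARP omnibus test %s\n", x$test))
  cat(sprintf("  statistic = %.4f, reference = %s\n", x$statistic, x$reference))
  cat(sprintf("  p = %.4g; %s at alpha = %g\n", x$p,
              if (x$reject) "REJECT monotone homogeneity" else "no rejection",
              x$alpha))
  if (!is.na(x$n_selected)) cat(sprintf("  pairs selected: %d\n", x$n_selected))
  if (x$n_excluded > 0) cat(sprintf("  degenerate pairs excluded: %d\n", x$n_excluded))
  invisible(x)
}

# ---- elementary combiners --------------------------------------------

#' Preselected standardized partial sum (PS)
#'
#' Sums the selected test statistics and divides by the standard error of
#' the sum, `sqrt(sum of the selected submatrix of Sigma)`; the p-value is
#' the standard-normal left tail. With the identity covariance and Z
#' statistics this is `sum(Z_S) / sqrt(K_S)`.
#'
#' @param x Vector of pairwise statistics in canonical order (NA for
#'   degenerate pairs).
#' @param sigma `acarp_cov` or matrix over the same canonical order.
#' @param selection A [preselect()] selection.
#' @param alpha Significance level.
#' @export
ps_test <- function(x, sigma, selection, alpha = 0.05) {
  S <- cov_matrix(sigma)
  idx <- selection$k
  if (length(idx) == 0L) {
    return(new_omnibus("PS", NA_real_, "standard normal (left tail)", NA, 1,
                       FALSE, alpha, selection))
  }
  denom <- sqrt(sum(S[idx, idx]))
  stat <- sum(x[idx]) / denom
  new_omnibus("PS", stat, "standard normal (left tail)", NA, pnorm(stat),
              pnorm(stat) <= alpha, alpha, selection)
}

#' Conditionalized sum of normal scores (CS)
#'
#' Stouffer-type combiner on the corrected p-values:
#' `Z_CS = sum(qnorm(p~)) / sqrt(K')`, compared to the standard normal left
#' tail.
#'
#' @param selection A [conditional_select()] selection.
#' @param alpha Significance level.
#' @export
cs_test <- function(selection, alpha = 0.05) {
  Kp <- selection$size
  if (Kp == 0L) {
    return(new_omnibus("CS", NA_real_, "standard normal (left tail)", NA, 1,
                       FALSE, alpha, selection))
  }
  stat <- sum(qnorm(clamp_p(selection$corrected_p))) / sqrt(Kp)
  new_omnibus("CS", stat, "standard normal (left tail)", NA, pnorm(stat),
              pnorm(stat) <= alpha, alpha, selection)
}

#' Conditionalized Fisher product (CP)
#'
#' `X_CP = -2 * sum(log(p~))` compared to chi-square with `2 K'` degrees of
#' freedom.
#'
#' @inheritParams cs_test
#' @export
cp_test <- function(selection, alpha = 0.05) {
  Kp <- selection$size
  if (Kp == 0L) {
    return(new_omnibus("CP", NA_real_, "chi-square", NA, 1, FALSE, alpha, selection))
  }
  stat <- -2 * sum(log(clamp_p(selection$corrected_p)))
  p <- pchisq(stat, df = 2 * Kp, lower.tail = FALSE)
  new_omnibus("CP", stat, sprintf("chi-square(%d)", 2L * Kp), 2L * Kp, p,
              p <= alpha, alpha, selection)
}

#' Conditionalized Bonferroni (CB)
#'
#' `p_adj = min(1, K' * min(p~))`.
#'
#' @inheritParams cs_test
#' @export
cb_test <- function(selection, alpha = 0.05) {
  Kp <- selection$size
  if (Kp == 0L) {
    return(new_omnibus("CB", NA_real_, "Bonferroni", NA, 1, FALSE, alpha, selection))
  }
  p <- min(1, Kp * min(selection$corrected_p))
  new_omnibus("CB", min(selection$corrected_p), "Bonferroni", Kp, p,
              p <= alpha, alpha, selection)
}

#' Preselected Fisher product (PP)
#'
#' Fisher's product over the *raw* test p-values of the training-preselected
#' pairs: `X_PP = -2 * sum(log p_S)`, chi-square with `2 K_S` df.
#'
#' @param p Vector of raw test p-values in canonical order.
#' @param selection A [preselect()] selection.
#' @param alpha Significance level.
#' @export
pp_test <- function(p, selection, alpha = 0.05) {
  idx <- selection$k
  if (length(idx) == 0L) {
    return(new_omnibus("PP", NA_real_, "chi-square", NA, 1, FALSE, alpha, selection))
  }
  stat <- -2 * sum(log(clamp_p(p[idx])))
  df <- 2L * length(idx)
  pv <- pchisq(stat, df = df, lower.tail = FALSE)
  new_omnibus("PP", stat, sprintf("chi-square(%d)", df), df, pv, pv <= alpha,
              alpha, selection)
}

#' Preselected Bonferroni (PB)
#'
#' `p_adj = min(1, K_S * min(p_S))` over the raw test p-values of the
#' preselected pairs.
#'
#' @inheritParams pp_test
#' @export
pb_test <- function(p, selection, alpha = 0.05) {
  idx <- selection$k
  if (length(idx) == 0L) {
    return(new_omnibus("PB", NA_real_, "Bonferroni", NA, 1, FALSE, alpha, selection))
  }
  padj <- min(1, length(idx) * min(p[idx]))
  new_omnibus("PB", min(p[idx]), "Bonferroni", length(idx), padj,
              padj <= alpha, alpha, selection)
}

# ---- registry ---------------------------------------------------------

#' The 20 valid omnibus test codes
#'
#' Four-letter codes: first letter the pairwise statistic (M = MCC, Z =
#' standardized Z), second letter the covariance matrix (B = bootstrap, M =
#' moments, I = identity), last two the aggregation (LR, CL, PS, CS, CP, CB,
#' PP, PB). The identity matrix is only reasonable for the standardized Zs,
#' and the estimated covariance matrices only enter LR, CL, and PS; that
#' leaves 20 valid combinations.
#'
#' @return Character vector of the 20 codes.
#' @export
#' @examples
#' length(valid_test_names()) # 20
valid_test_names <- function() {
  c(as.vector(t(outer(c("MB", "MM", "ZB", "ZM"), c("LR", "CL", "PS"), paste0))),
    paste0("ZI", c("LR", "CL", "PS", "CS", "CP", "CB", "PP", "PB")))
}

parse_test_code <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% valid_test_names())) {
    stop(sprintf("invalid test code %s; valid codes are: %s",
                 deparse(name), paste(valid_test_names(), collapse = ", ")),
         call. = FALSE)
  }
  list(kind = if (substr(name, 1, 1) == "M") "MCC" else "Z",
       covmethod = c(B = "bootstrap", M = "moments", I = "identity")[substr(name, 2, 2)],
       agg = substr(name, 3, 4))
}

#' Run named omnibus tests on pairwise statistics
#'
#' Applies one or more of the 20 named aggregation tests to an existing
#' [pair_stats()] result. Degenerate pairs (zero MH variance) are excluded
#' from every aggregation and the effective K reduced accordingly.
#'
#' @param stats An [pair_stats()] result.
#' @param tests Character vector of test codes (see [valid_test_names()]).
#' @param alpha Significance level.
#' @param t Conditionalization threshold for CS/CP/CB.
#' @param B Bootstrap resamples for `*B**` tests.
#' @param n_draws Monte-Carlo draws for non-identity chi-bar weights.
#' @param seed Seed for bootstrap / chi-bar Monte-Carlo randomness.
#' @return A named list of `acarp_omnibus` objects.
#' @export
run_tests_on_stats <- function(stats, tests, alpha = 0.05, t = 0.5,
                               B = 1000, n_draws = 10000, seed = NULL) {
  specs <- lapply(tests, parse_test_code)
  nd <- which(!stats$degenerate)
  n_excl <- nrow(stats) - length(nd)
  sub <- stats[nd, , drop = FALSE]

  # covariance matrices, one per (method, kind) actually needed
  need_cov <- unique(vapply(
    specs[vapply(specs, function(s) s$agg %in% c("LR", "CL", "PS"), TRUE)],
    function(s) paste(s$covmethod, s$kind, sep = "."), ""))
  covs <- list()
  seeds <- if (is.null(seed)) list(boot = NULL, w = NULL) else {
    ss <- spawn_seeds(seed, 2)
    list(boot = ss[1], w = ss[2])
  }
  for (nm in need_cov) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    method <- parts[1]
    kind <- parts[2]
    covs[[nm]] <- switch(
      method,
      identity = cov_identity(length(nd)),
      moments = {
        cm <- cov_moments_mcc(stats)
        m <- cm$matrix[nd, nd, drop = FALSE]
        cm$matrix <- m
        if (kind == "Z") {
          cov_moments_z(cm, stats$variance[nd], attr(stats, "n_test"))
        } else cm
      },
      bootstrap = {
        cb <- cov_bootstrap(stats, kind = kind, B = B, seed = seeds$boot)
        keep <- setdiff(nd, cb$dropped)
        cb$matrix <- cb$matrix[keep, keep, drop = FALSE]
        cb$keep <- keep
        cb
      })
  }

  presel <- preselect(stats)
  condsel <- conditional_select(stats, t)

  out <- vector("list", length(tests))
  names(out) <- tests
  for (ti in seq_along(tests)) {
    sp <- specs[[ti]]
    name <- tests[[ti]]
    if (sp$agg %in% c("LR", "CL", "PS")) {
      cv <- covs[[paste(sp$covmethod, sp$kind, sep = ".")]]
      keep <- if (!is.null(cv$keep)) cv$keep else nd
      xk <- if (sp$kind == "MCC") stats$mcc[keep] else stats$z[keep]
      if (sp$agg == "PS") {
        sel <- presel
        sel$k <- intersect(sel$k, keep)
        sel$size <- length(sel$k)
        # map canonical k to positions within `keep`
        sel_pos <- sel
        sel_pos$k <- match(sel$k, keep)
        res <- ps_test(xk, cv, sel_pos, alpha)
        res$selection <- sel
        res$n_selected <- sel$size
      } else {
        cvr <- repair_psd(cv)
        proj <- project_nonneg_cone(xk, cvr)
        if (sp$agg == "LR") {
          w <- if (cvr$method == "identity") {
            chibar_weights_identity(length(xk))
          } else {
            chibar_weights(cvr, n_draws = n_draws, seed = seeds$w)
          }
          pv <- lr_pvalue(proj$chibar_sq, w)
          res <- new_omnibus(name, proj$chibar_sq,
                             "chi-bar-square (mixture of chi-squares)",
                             w$weights, pv, pv <= alpha, alpha)
        } else {
          cl <- cl_pvalue(proj$chibar_sq, proj$n_active)
          res <- new_omnibus(name, proj$chibar_sq,
                             sprintf("chi-square(D), D = %d binding constraints",
                                     proj$n_active),
                             proj$n_active, cl$p, cl$reject_at(alpha), alpha)
        }
      }
    } else {
      res <- switch(sp$agg,
                    CS = cs_test(condsel, alpha),
                    CP = cp_test(condsel, alpha),
                    CB = cb_test(condsel, alpha),
                    PP = pp_test(stats$p, presel, alpha),
                    PB = pb_test(stats$p, presel, alpha))
    }
    res$test <- name
    res$n_excluded <- n_excl
    out[[ti]] <- res
  }
  out
}

#' Run one ACARP omnibus test end to end
#'
#' Orchestrates the full pipeline on a raw item-response matrix: train/test
#' split, per-pair CARP statistics, covariance estimation as dictated by the
#' second letter of the test code, and aggregation as dictated by the last
#' two letters.
#'
#' @param data Item matrix or data frame of 0/1 scores.
#' @param test A single code from [valid_test_names()], e.g. `"ZICP"`.
#' @param alpha Significance level.
#' @param train_fraction,C,continuity,conditioning,split Passed to
#'   [pair_stats()].
#' @param t,B,n_draws Aggregation settings (see [run_tests_on_stats()]).
#' @param seed Seed controlling the split and any aggregation randomness.
#' @return An `acarp_omnibus` object.
#' @export
#' @examples
#' X <- simulate_irt(sim_design(J = 6, N = 400, scenario = "dim0", seed = 3))
#' run_acarp_test(X, "ZICP", seed = 4)
run_acarp_test <- function(data, test = "ZICP", alpha = 0.05,
                           train_fraction = 0.3, C = 10, continuity = TRUE,
                           conditioning = c("carp", "restscore"), t = 0.5,
                           B = 1000, n_draws = 10000, seed = NULL,
                           split = NULL) {
  parse_test_code(test)
  conditioning <- match.arg(conditioning)
  seeds <- if (is.null(seed)) c(NA, NA) else spawn_seeds(seed, 2)
  stats <- pair_stats(data, train_fraction = train_fraction, C = C,
                      continuity = continuity, conditioning = conditioning,
                      seed = if (is.null(seed)) NULL else seeds[1],
                      split = split)
  run_tests_on_stats(stats, test, alpha = alpha, t = t, B = B,
                     n_draws = n_draws,
                     seed = if (is.null(seed)) NULL else seeds[2])[[1]]
}

#' Run all 20 omnibus tests
#'
#' @inheritParams run_acarp_test
#' @param tests Codes to run (default: all 20).
#' @return A tibble with one row per test: `test`, `statistic`, `p`,
#'   `reject`, `n_selected`, `n_excluded`.
#' @export
run_acarp_tests <- function(data, tests = valid_test_names(), alpha = 0.05,
                            train_fraction = 0.3, C = 10, continuity = TRUE,
                            conditioning = c("carp", "restscore"), t = 0.5,
                            B = 1000, n_draws = 10000, seed = NULL,
                            split = NULL) {
  lapply(tests, parse_test_code)
  conditioning <- match.arg(conditioning)
  seeds <- if (is.null(seed)) c(NA, NA) else spawn_seeds(seed, 2)
  stats <- pair_stats(data, train_fraction = train_fraction, C = C,
                      continuity = continuity, conditioning = conditioning,
                      seed = if (is.null(seed)) NULL else seeds[1],
                      split = split)
  res <- run_tests_on_stats(stats, tests, alpha = alpha, t = t, B = B,
                            n_draws = n_draws,
                            seed = if (is.null(seed)) NULL else seeds[2])
  dplyr::bind_rows(lapply(res, tidy))
}
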