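#' Covariance-matrix estimators for the pairwise statistics
#'
#' The aggregation tests need an estimate of the K x K covariance matrix of
#' the vector of pairwise statistics (MCCs or Zs). Three estimators are
#' provided, mirroring the three strategies studied for the ACARP tests:
#'
#' * **identity** ([cov_identity()]): the asymptotic covariance of the
#'   standardized Zs is simply taken to be the identity. Only meaningful for
#'   Z statistics. Justified when conditioning groups pin the latent variable
#'   down well enough that pairs behave like independent Bernoulli tables.
#' * **moments** ([cov_moments()]): a delta-method plug-in using only
#'   within-group sample moments of the items and their products, treating
#'   group labels and sizes as fixed.
#' * **bootstrap** ([cov_bootstrap()]): resample the test rows with
#'   replacement, recompute the statistic per pair, and take the sample
#'   covariance across resamples. Training-fitted predictors (and, by
#'   default, the original decile cut-points) are held fixed: the
#'   conditioning rule is part of the statistic's definition.
#'
#' @name covariance-estimators
NULL

new_cov <- function(m, method, kind, repaired = FALSE) {
  structure(list(matrix = m, method = method, kind = kind, repaired = repaired),
            class = "acarp_cov")
}

#' @export
print.acarp_cov <- function(x, ...) {
  cat(sprintf("<acarp_cov> %dx%d, method = %s, kind = %s%s\n",
              nrow(x$matrix), ncol(x$matrix), x$method, x$kind,
              if (x$repaired) " (PSD-repaired)" else ""))
  invisible(x)
}

#' Identity covariance for standardized Z statistics
#'
#' @param K Number of item pairs.
#' @param kind Must be `"Z"`: the identity is only reasonable for the
#'   standardized statistics, never for raw MCCs.
#' @return An `acarp_cov` object wrapping the K x K identity.
#' @rdname covariance-estimators
#' @export
cov_identity <- function(K, kind = "Z") {
  if (!identical(kind, "Z")) {
    stop("the identity covariance is only valid for kind = \"Z\".", call. = FALSE)
  }
  if (K < 1) stop("`K` must be >= 1.", call. = FALSE)
  new_cov(diag(K), "identity", "Z")
}

#' Bootstrap covariance of the pairwise statistics
#'
#' @param stats An [pair_stats()] result.
#' @param kind `"MCC"` or `"Z"`.
#' @param B Number of resamples (>= 2; default 1000).
#' @param seed Optional seed for the resampling.
#' @param recompute_cuts Recompute decile cut-points within each resample
#'   (default `FALSE`: cut-points of the original test sample are part of the
#'   statistic and are held fixed).
#' @param max_degenerate Pairs degenerate in more than this fraction of
#'   resamples are dropped (their rows/columns are `NA`).
#' @rdname covariance-estimators
#' @export
cov_bootstrap <- function(stats, kind = c("MCC", "Z"), B = 1000, seed = NULL,
                          recompute_cuts = FALSE, max_degenerate = 0.1) {
  kind <- match.arg(kind)
  if (B < 2) stop("`B` must be at least 2.", call. = FALSE)
  ctx <- attr(stats, "context")
  Xte <- ctx$test_matrix
  n <- nrow(Xte)
  K <- nrow(stats)
  draws <- matrix(NA_real_, B, K)
  with_seed(seed, {
    for (b in seq_len(B)) {
      rows <- sample.int(n, n, replace = TRUE)
      rs <- recompute_test_stats(Xte[rows, , drop = FALSE], ctx,
                                 recompute_cuts = recompute_cuts)
      draws[b, ] <- if (kind == "MCC") rs$mcc else rs$z
    }
  })
  bad <- colMeans(is.na(draws)) > max_degenerate
  m <- stats::cov(draws, use = "pairwise.complete.obs")
  m[is.na(m)] <- 0
  if (any(bad)) {
    m[bad, ] <- NA_real_
    m[, bad] <- NA_real_
  }
  out <- new_cov(m, "bootstrap", kind)
  out$dropped <- which(bad)
  out
}

#' Moments (delta-method) covariance of the MCCs
#'
#' Treats the conditioning group labels and sizes as fixed and the subjects
#' as independent. Writing the MCC numerator as a sum over subjects of
#' within-group-centered cross products `u_n = (x_i - m_i,c)(x_j - m_j,c)`,
#' the covariance of two MCCs is estimated from sample moments only:
#' `Cov(MCC_p, MCC_q) = (sum_n u_n^p u_n^q - sum_n ubar^p_c(n) ubar^q_c(n)) / N^2`,
#' with `ubar` the within-group means of the centered cross products under
#' each pair's own grouping.
#'
#' @rdname covariance-estimators
#' @export
cov_moments_mcc <- function(stats) {
  ctx <- attr(stats, "context")
  Xte <- ctx$test_matrix
  n <- nrow(Xte)
  K <- nrow(stats)
  U <- matrix(0, n, K)   # centered cross products per subject
  Mbar <- matrix(0, n, K) # own-group mean of u, expanded to subjects
  for (k in seq_len(K)) {
    rest <- ctx$rests[[k]]
    cf <- ctx$coefs[[k]]
    s <- if (ctx$conditioning == "carp") {
      round(cf[1L] + drop(Xte[, rest, drop = FALSE] %*% cf[-1L]), 9)
    } else {
      rowSums(Xte[, rest, drop = FALSE])
    }
    g <- assign_bins(s, ctx$cuts[[k]])
    ij <- pair_from_k(k, ncol(Xte))
    xi <- Xte[, ij[1L]]
    xj <- Xte[, ij[2L]]
    u <- (xi - stats::ave(xi, g)) * (xj - stats::ave(xj, g))
    U[, k] <- u
    Mbar[, k] <- stats::ave(u, g)
  }
  m <- (crossprod(U) - crossprod(Mbar)) / n^2
  m <- (m + t(m)) / 2
  new_cov(m, "moments", "MCC")
}

#' Map an MCC covariance to a Z covariance
#'
#' Under the linear approximation `Z ~ N * MCC / sqrt(V)`, entry `(p, q)` of
#' the MCC covariance is rescaled by `N^2 / sqrt(V_p V_q)`. The congruence
#' transform preserves symmetry and positive semidefiniteness.
#'
#' @param mcc_cov An `acarp_cov` of kind `"MCC"`.
#' @param variances MH variances per pair (all > 0).
#' @param n_test Test-sample size.
#' @rdname covariance-estimators
#' @export
cov_moments_z <- function(mcc_cov, variances, n_test) {
  if (!identical(mcc_cov$kind, "MCC")) {
    stop("`mcc_cov` must have kind \"MCC\".", call. = FALSE)
  }
  if (any(variances <= 0, na.rm = TRUE)) {
    stop("all MH variances must be > 0; degenerate pairs must be excluded upstream.",
         call. = FALSE)
  }
  d <- n_test / sqrt(variances)
  new_cov(mcc_cov$matrix * outer(d, d), "moments", "Z")
}

#' Moments covariance for either statistic kind
#'
#' Convenience wrapper: the MCC moments covariance, rescaled to Z scale when
#' `kind = "Z"`. Degenerate pairs must be filtered out of `stats` first.
#'
#' @rdname covariance-estimators
#' @export
cov_moments <- function(stats, kind = c("MCC", "Z")) {
  kind <- match.arg(kind)
  m <- cov_moments_mcc(stats)
  if (kind == "MCC") return(m)
  cov_moments_z(m, stats$variance, attr(stats, "n_test"))
}

#' Repair a covariance matrix to positive definiteness
#'
#' The chi-bar-square projection whitens with a Cholesky factor, which needs
#' a positive-definite matrix. If the smallest eigenvalue is below `jitter`,
#' `(jitter - lambda_min) * I` is added and the `repaired` flag set.
#'
#' @param m An `acarp_cov` object or plain symmetric matrix.
#' @param jitter Target lower bound on the smallest eigenvalue.
#' @return An `acarp_cov` object that always admits a Cholesky factorization.
#' @rdname covariance-estimators
#' @export
repair_psd <- function(m, jitter = 1e-10) {
  if (!inherits(m, "acarp_cov")) m <- new_cov(m, "unknown", "Z")
  A <- (m$matrix + t(m$matrix)) / 2
  lmin <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin < jitter) {
    A <- A + (jitter - lmin) * diag(nrow(A))
    m$repaired <- TRUE
  }
  m$matrix <- A
  m
}
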