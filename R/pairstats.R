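#' Fit the CARP conditioning predictor for one item pair
#'
#' For the pair `(i, j)` the conditioning score is a weighted sum of the
#' remaining `J - 2` item scores, with weights estimated by ordinary least
#' squares in the training sample: the joint target `X_i + X_j` is regressed
#' on the remaining items. (For least squares this is identical to summing
#' separate predictions of `X_i` and of `X_j`.) A rank-deficient design
#' yields the minimum-norm solution, so a constant remaining item simply gets
#' a zero weight.
#'
#' @param train Training-sample item matrix (matrix/data frame of 0/1).
#' @param i,j Item column indices, `i < j`.
#' @return An object of class `acarp_predictor`: a list with `pair`,
#'   `intercept`, `weights` (length `J - 2`) and `rest` (the remaining item
#'   indices the weights refer to).
#' @export
#' @examples
#' X <- matrix(rbinom(60, 1, 0.5), 20, 3)
#' fit_pair_predictor(X, 1, 2)
fit_pair_predictor <- function(train, i, j) {
  X <- as_item_matrix(train)
  J <- ncol(X)
  check_pair(i, j, J)
  if (nrow(X) < 2L) stop("insufficient data: need at least 2 training rows.", call. = FALSE)
  G <- crossprod(cbind(1, X))
  cf <- pair_ols_coef(G, i, j, J)
  structure(
    list(pair = c(i = i, j = j), intercept = cf[1L], weights = cf[-1L],
         rest = seq_len(J)[-c(i, j)]),
    class = "acarp_predictor"
  )
}

check_pair <- function(i, j, J) {
  if (!(i >= 1 && j <= J && i < j)) {
    stop("invalid pair: need 1 <= i < j <= J.", call. = FALSE)
  }
}

# Normal-equations solve for the pair predictor from the (J+1)x(J+1)
# training Gram matrix G = crossprod(cbind(1, Xtr)). Target is X_i + X_j.
pair_ols_coef <- function(G, i, j, J) {
  idx <- c(1L, setdiff(seq_len(J), c(i, j)) + 1L)
  A <- G[idx, idx, drop = FALSE]
  b <- G[idx, i + 1L] + G[idx, j + 1L]
  unname(tryCatch(solve(A, b), error = function(e) pinv_solve(A, b)))
}

# Minimum-norm least-squares solve of A x = b via the pseudo-inverse.
pinv_solve <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d, tol)
  if (!any(pos)) return(rep(0, ncol(A)))
  drop(sv$v[, pos, drop = FALSE] %*%
         (crossprod(sv$u[, pos, drop = FALSE], b) / sv$d[pos]))
}

#' Assign test subjects to conditioning groups
#'
#' Subjects are binned into (at most) `C` quantile groups of the conditioning
#' score; the default `C = 10` gives deciles. Tied scores always share a bin
#' (quantile breaks are deduplicated), so the number of realized groups
#' `C_actual` can be smaller than `C`; with all scores tied there is a single
#' group, flagged degenerate. Group labels are a monotone function of the
#' score.
#'
#' @param test Test-sample item matrix.
#' @param predictor An [fit_pair_predictor()] object (fitted on disjoint
#'   training rows).
#' @param C Target number of groups (>= 2).
#' @return A list of class `acarp_groups`: `pair`, integer `labels` (one per
#'   test subject), `group_sizes`, `target_groups`, `C_actual`, `degenerate`.
#' @export
conditioning_groups <- function(test, predictor, C = 10) {
  X <- as_item_matrix(test)
  if (C < 2) stop("`C` must be at least 2.", call. = FALSE)
  s <- round(predictor$intercept +
    drop(X[, predictor$rest, drop = FALSE] %*% predictor$weights), 9)
  cuts <- score_cuts(s, C)
  g <- assign_bins(s, cuts)
  sizes <- tabulate(g)
  structure(
    list(pair = predictor$pair, labels = g, group_sizes = sizes,
         target_groups = C, C_actual = length(sizes),
         degenerate = length(sizes) == 1L),
    class = "acarp_groups"
  )
}

# Quantile binning of the conditioning score via midranks: subject n goes to
# bin ceiling(rank * C / n) with average ranks, so tied scores always share a
# bin and bins are near equal-sized when scores are distinct. Returns the upper
# score boundary of every bin except the last; bins are the intervals
# (cut_{b-1}, cut_b]. An empty cut vector means a single (degenerate) group.
score_cuts <- function(s, C) {
  n <- length(s)
  ss <- sort(s, method = "quick")
  chg <- which(ss[-1L] != ss[-n])       # ends of tie blocks (except last)
  ends <- c(chg, n)
  starts <- c(1L, chg + 1L)
  bin <- ceiling((starts + ends) / 2 * C / n)  # bin of each distinct value
  uv <- ss[ends]
  m <- length(uv)
  if (m == 1L) return(numeric(0))
  uv[which(bin[-m] != bin[-1L])]         # last value of each bin but the final
}

assign_bins <- function(s, cuts) {
  if (length(cuts) == 0L) return(rep(1L, length(s)))
  findInterval(s, cuts, left.open = TRUE) + 1L
}

#' Within-group sample covariance of two binary items
#'
#' Maximum-likelihood (divide-by-n) sample covariance
#' `mean(xi * xj) - mean(xi) * mean(xj)`. For binary items it is bounded by
#' \[-0.25, 0.25\]; a group of size 1 has covariance 0.
#'
#' @param xi,xj Equal-length binary vectors (one conditioning group).
#' @return The sample covariance.
#' @export
group_covariance <- function(xi, xj) {
  if (length(xi) != length(xj)) stop("`xi` and `xj` must have equal length.", call. = FALSE)
  if (length(xi) == 0L) stop("empty group: covariance undefined.", call. = FALSE)
  mean(xi * xj) - mean(xi) * mean(xj)
}

#' Mean conditional covariance (MCC) of an item pair
#'
#' The MCC is the group-size-weighted mean of the within-group covariances:
#' `T = sum_c n_c * cov_c` and `MCC = T / N_test`. Under monotone homogeneity
#' every conditional covariance is nonnegative in expectation, so a negative
#' MCC is evidence against the model. With a single group the MCC reduces to
#' the plain sample covariance of the pair.
#'
#' @param groups An [conditioning_groups()] object covering all test subjects.
#' @param xi,xj Binary score vectors of the pair on the test subjects.
#' @return A list with `numerator` (T) and `mcc` (T / N_test).
#' @export
mcc_statistic <- function(groups, xi, xj) {
  tl <- group_tallies(groups$labels, xi, xj)
  list(numerator = tl$num, mcc = tl$num / length(xi))
}

#' Mantel--Haenszel variance of the MCC numerator
#'
#' The stratified hypergeometric variance used to standardize the MCC
#' numerator:
#' `V = sum_c m_ic (n_c - m_ic) m_jc (n_c - m_jc) / (n_c^2 (n_c - 1))`,
#' where `m_ic`, `m_jc` count the ones on each item within group `c`. Groups
#' of size < 2 contribute 0, as does any group where either item is constant.
#'
#' @inheritParams mcc_statistic
#' @return The variance estimate (nonnegative).
#' @export
mh_variance <- function(groups, xi, xj) {
  group_tallies(groups$labels, xi, xj)$var
}

# One pass over the groups: numerator T = sum_c (m_ij - m_i m_j / n_c) and
# the MH variance. Size-1 groups contribute 0 to both automatically.
group_tallies <- function(g, xi, xj, nbins = max(g)) {
  # double precision: the variance products overflow 32-bit integers
  n <- as.numeric(tabulate(g, nbins))
  mi <- as.numeric(tabulate(g[xi == 1L], nbins))
  mj <- as.numeric(tabulate(g[xj == 1L], nbins))
  mij <- as.numeric(tabulate(g[xi == 1L & xj == 1L], nbins))
  ok <- n > 0L
  num <- sum(mij[ok] - mi[ok] * mj[ok] / n[ok])
  ok2 <- n >= 2L
  v <- if (any(ok2)) {
    n2 <- n[ok2]
    sum(mi[ok2] * (n2 - mi[ok2]) * mj[ok2] * (n2 - mj[ok2]) /
          (n2 * n2 * (n2 - 1)))
  } else 0
  list(num = num, var = v)
}

#' Standardized pairwise Z statistic
#'
#' `z = (T + 0.5 * continuity) / sqrt(V)` with the MH variance `V`; the 0.5
#' term is Rosenbaum's continuity correction (on by default). The p-value is
#' the left tail of the standard normal: small p means a markedly negative
#' conditional covariance, i.e. evidence against monotone homogeneity.
#'
#' @param numerator MCC numerator `T`.
#' @param variance MH variance `V` (> 0).
#' @param continuity Apply the 0.5 continuity correction?
#' @return A list with `z` and `p`. `variance = 0` is an undefined statistic
#'   and raises an error; such pairs must be excluded upstream.
#' @export
z_statistic <- function(numerator, variance, continuity = TRUE) {
  if (variance <= 0) {
    stop("undefined statistic: MH variance is zero; exclude this pair.", call. = FALSE)
  }
  z <- (numerator + 0.5 * isTRUE(continuity)) / sqrt(variance)
  list(z = z, p = pnorm(z))
}

#' Pairwise CARP statistics for every item pair
#'
#' The workhorse of the package. Splits the subjects into a training and a
#' test sample, fits the per-pair conditioning predictor on the training
#' rows, forms decile conditioning groups, and computes for every item pair
#' the MCC, its Mantel--Haenszel variance, the standardized Z statistic and
#' its left-tail p-value on the test sample. Training-sample MCCs (used for
#' preselection) are computed with groups built from the same training-fitted
#' predictor applied to the training rows.
#'
#' @param data Item-response matrix or data frame (0/1; rows = subjects).
#' @param train_fraction Proportion of subjects in the training sample.
#' @param C Target number of conditioning groups (deciles by default).
#' @param continuity Apply the 0.5 continuity correction to Z?
#' @param conditioning `"carp"` (regression-weighted rest score, the default)
#'   or `"restscore"` (Rosenbaum's unweighted pairwise rest score).
#' @param seed Optional seed for the random split.
#' @param split Optionally a precomputed [split_sample()] object; overrides
#'   `train_fraction`/`seed`.
#' @return A tibble of class `acarp_pairstats` with one row per pair in
#'   canonical order: `pair_i`, `pair_j`, `k`, `train_numerator`,
#'   `train_mcc`, `numerator`, `mcc`, `variance`, `z`, `p`, `degenerate`.
#'   Pairs with zero MH variance on the test sample are flagged degenerate
#'   (`z`, `p` are `NA`) and are excluded from every aggregation.
#' @export
#' @examples
#' X <- simulate_irt(sim_design(J = 5, N = 300, scenario = "dim0", seed = 1))
#' pair_stats(X, seed = 2)
pair_stats <- function(data, train_fraction = 0.3, C = 10, continuity = TRUE,
                       conditioning = c("carp", "restscore"),
                       seed = NULL, split = NULL) {
  conditioning <- match.arg(conditioning)
  X <- as_item_matrix(data)
  if (is.null(split)) split <- split_sample(nrow(X), train_fraction, seed)
  pairstats_engine(X, split, C = C, continuity = continuity,
                   conditioning = conditioning)
}

pairstats_engine <- function(X, split, C = 10, continuity = TRUE,
                             conditioning = "carp") {
  J <- ncol(X)
  pg <- pair_grid(J)
  K <- nrow(pg)
  Xtr <- X[split$train, , drop = FALSE]
  Xte <- X[split$test, , drop = FALSE]
  n_te <- nrow(Xte)
  n_tr <- nrow(Xtr)
  G <- if (conditioning == "carp") crossprod(cbind(1, Xtr)) else NULL

  train_num <- num <- vr <- numeric(K)
  coefs <- cuts <- rests <- vector("list", K)

  # all K conditioning scores in one matrix product: CF holds, per pair, the
  # intercept and the J-2 weights slotted into a (J+1)-row coefficient matrix
  CF <- matrix(0, J + 1L, K)
  for (k in seq_len(K)) {
    i <- pg$pair_i[k]
    j <- pg$pair_j[k]
    rest <- seq_len(J)[-c(i, j)]
    cf <- if (conditioning == "carp") pair_ols_coef(G, i, j, J) else
      c(0, rep(1, length(rest)))
    CF[c(1L, rest + 1L), k] <- cf
    coefs[[k]] <- cf
    rests[[k]] <- rest
  }
  # conditioning scores are rounded to 9 decimals before binning so that
  # scores equal up to floating-point noise always count as tied
  S_te <- round(cbind(1, Xte) %*% CF, 9)
  S_tr <- round(cbind(1, Xtr) %*% CF, 9)

  for (k in seq_len(K)) {
    i <- pg$pair_i[k]
    j <- pg$pair_j[k]
    ct <- score_cuts(S_te[, k], C)
    tl_te <- group_tallies(assign_bins(S_te[, k], ct), Xte[, i], Xte[, j],
                           length(ct) + 1L)
    ct_tr <- score_cuts(S_tr[, k], C)
    tl_tr <- group_tallies(assign_bins(S_tr[, k], ct_tr), Xtr[, i], Xtr[, j],
                           length(ct_tr) + 1L)
    train_num[k] <- tl_tr$num
    num[k] <- tl_te$num
    vr[k] <- tl_te$var
    cuts[[k]] <- ct
  }

  degenerate <- vr <= 0
  z <- p <- rep(NA_real_, K)
  z[!degenerate] <- (num[!degenerate] + 0.5 * isTRUE(continuity)) /
    sqrt(vr[!degenerate])
  p[!degenerate] <- pnorm(z[!degenerate])

  out <- tibble::tibble(
    pair_i = pg$pair_i, pair_j = pg$pair_j, k = pg$k,
    train_numerator = train_num, train_mcc = train_num / n_tr,
    numerator = num, mcc = num / n_te,
    variance = vr, z = z, p = p, degenerate = degenerate
  )
  structure(
    out,
    class = c("acarp_pairstats", class(out)),
    n_train = n_tr, n_test = n_te, C = C, continuity = isTRUE(continuity),
    conditioning = conditioning, split = split,
    context = list(coefs = coefs, cuts = cuts, rests = rests,
                   test_matrix = Xte, C = C,
                   continuity = isTRUE(continuity),
                   conditioning = conditioning)
  )
}

# Recompute test-sample statistics on (resampled) test rows, holding the
# training-fitted predictors fixed. Decile cut-points are held fixed unless
# recompute_cuts = TRUE. Returns list(mcc = , z = ) vectors with NA for
# degenerate pairs.
recompute_test_stats <- function(Xte, ctx, recompute_cuts = FALSE) {
  K <- length(ctx$coefs)
  n_te <- nrow(Xte)
  mcc <- z <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    rest <- ctx$rests[[k]]
    cf <- ctx$coefs[[k]]
    s <- if (ctx$conditioning == "carp") {
      round(cf[1L] + drop(Xte[, rest, drop = FALSE] %*% cf[-1L]), 9)
    } else {
      rowSums(Xte[, rest, drop = FALSE])
    }
    ct <- if (recompute_cuts) score_cuts(s, ctx$C) else ctx$cuts[[k]]
    ij <- pair_from_k(k, ncol(Xte))
    tl <- group_tallies(assign_bins(s, ct), Xte[, ij[1L]], Xte[, ij[2L]],
                        length(ct) + 1L)
    mcc[k] <- tl$num / n_te
    if (tl$var > 0) {
      z[k] <- (tl$num + 0.5 * ctx$continuity) / sqrt(tl$var)
    }
  }
  list(mcc = mcc, z = z)
}

# Inverse of the canonical lexicographic pair ordering.
pair_from_k <- function(k, J) {
  i <- 1L
  off <- 0L
  while (k > off + (J - i)) {
    off <- off + (J - i)
    i <- i + 1L
  }
  c(i, i + (k - off))
}
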