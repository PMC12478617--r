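# Fixtures are generated in code; nothing is stored on disk.

# A small deterministic 0/1 matrix with enough variation for regression fits.
toy_matrix <- function(n = 12, J = 4, seed = 7) {
  set.seed(seed)
  X <- matrix(rbinom(n * J, 1, 0.5), n, J)
  # ensure no constant column
  for (j in seq_len(J)) {
    if (length(unique(X[, j])) == 1L) X[1, j] <- 1L - X[1, j]
  }
  colnames(X) <- paste0("V", seq_len(J))
  X
}

# Independent naive recomputation of the pairwise statistics: explicit loops,
# lm() for the predictor, base rank() for decile bins.
naive_pair_stats <- function(X, split, C = 10, continuity = TRUE) {
  J <- ncol(X)
  Xtr <- X[split$train, , drop = FALSE]
  Xte <- X[split$test, , drop = FALSE]
  out <- NULL
  for (i in 1:(J - 1)) for (j in (i + 1):J) {
    rest <- setdiff(1:J, c(i, j))
    df_tr <- data.frame(y = Xtr[, i] + Xtr[, j], Xtr[, rest, drop = FALSE])
    fit <- lm(y ~ ., data = df_tr)
    cf <- coef(fit)
    cf[is.na(cf)] <- 0
    score <- function(M) round(cf[1] + as.vector(M[, rest, drop = FALSE] %*% cf[-1]), 9)
    bin <- function(s) {
      r <- rank(s, ties.method = "average")
      g0 <- ceiling(r * C / length(s))
      match(g0, sort(unique(g0)))
    }
    stat_on <- function(M) {
      s <- score(M)
      g <- bin(s)
      Tn <- 0
      V <- 0
      for (c in unique(g)) {
        xi <- M[g == c, i]
        xj <- M[g == c, j]
        nc <- length(xi)
        Tn <- Tn + nc * (mean(xi * xj) - mean(xi) * mean(xj))
        if (nc >= 2) {
          mi <- sum(xi); mj <- sum(xj)
          V <- V + mi * (nc - mi) * mj * (nc - mj) / (nc^2 * (nc - 1))
        }
      }
      c(Tn, V)
    }
    te <- stat_on(Xte)
    tr <- stat_on(Xtr)
    z <- if (te[2] > 0) (te[1] + 0.5 * continuity) / sqrt(te[2]) else NA_real_
    out <- rbind(out, data.frame(
      pair_i = i, pair_j = j,
      train_mcc = tr[1] / nrow(Xtr),
      numerator = te[1], mcc = te[1] / nrow(Xte),
      variance = te[2], z = z
    ))
  }
  out
}

# Exhaustive active-set oracle for the nonnegative-cone projection: for every
# subset A of zeroed coordinates, solve the stationarity system on the face
# and keep the feasible candidate with the smallest objective.
oracle_cone_projection <- function(x, S) {
  K <- length(x)
  Q <- solve(S)
  best <- list(obj = Inf, theta = NULL)
  for (m in 0:(2^K - 1)) {
    A <- which(bitwAnd(m, 2^(0:(K - 1))) > 0)
    FF <- setdiff(1:K, A)
    theta <- numeric(K)
    if (length(FF) > 0) {
      d_F <- if (length(A) > 0) {
        -solve(Q[FF, FF, drop = FALSE],
               Q[FF, A, drop = FALSE] %*% x[A])
      } else {
        rep(0, length(FF))
      }
      theta[FF] <- x[FF] - as.vector(d_F)
    }
    if (all(theta >= -1e-12)) {
      d <- x - theta
      obj <- as.numeric(t(d) %*% Q %*% d)
      if (obj < best$obj) best <- list(obj = obj, theta = theta)
    }
  }
  best
}

# Random positive-definite covariance matrix.
random_pd <- function(K) {
  A <- matrix(rnorm(K * K), K)
  S <- crossprod(A) + diag(K) * 0.1
  (S + t(S)) / 2
}
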