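test_that("pair counting and canonical ordering behave", {
  expect_identical(pair_count(10), 45L)
  expect_identical(pair_count(2), 1L)
  expect_identical(pair_count(30), 435L)
  expect_error(pair_count(1), ">= 2")

  pg <- pair_grid(4)
  expect_equal(pg$pair_i, c(1L, 1L, 1L, 2L, 2L, 3L))
  expect_equal(pg$pair_j, c(2L, 3L, 4L, 3L, 4L, 4L))
  expect_equal(pg$k, 1:6)
  # pair_from_k is the inverse of the ordering
  for (k in 1:6) {
    expect_equal(acarp:::pair_from_k(k, 4), c(pg$pair_i[k], pg$pair_j[k]))
  }
})

test_that("train/test splits are reproducible partitions of the right size", {
  s <- split_sample(10, fraction = 0.3, seed = 1)
  expect_length(s$train, 3)
  expect_length(s$test, 7)
  expect_setequal(c(s$train, s$test), 1:10)
  expect_length(intersect(s$train, s$test), 0)

  s2 <- split_sample(10, fraction = 0.3, seed = 1)
  expect_identical(s$train, s2$train)

  expect_length(split_sample(1000, 0.3, seed = 5)$train, 300)

  expect_error(split_sample(10, fraction = 1.2), "in \\(0, 1\\)")
  expect_error(split_sample(10, fraction = 0.01), "degenerate")
})

test_that("pair predictor is the least-squares fit of the joint target", {
  # constant target X_i + X_j = 1 -> intercept 1, zero weights
  X <- cbind(c(1, 0, 1, 0, 1, 0), c(0, 1, 0, 1, 0, 1),
             c(0, 1, 1, 0, 1, 0), c(1, 1, 0, 0, 1, 0))
  pr <- fit_pair_predictor(X, 1, 2)
  expect_equal(pr$intercept, 1, tolerance = 1e-10)
  expect_equal(unname(pr$weights), c(0, 0), tolerance = 1e-10)

  # J = 3 with the remaining item a perfect predictor: x3 = Xi + Xj - 1
  X2 <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1), c(0, 1, 0), c(1, 1, 1))
  pr2 <- fit_pair_predictor(X2, 1, 2)
  expect_equal(pr2$intercept, 1, tolerance = 1e-10)
  expect_equal(unname(pr2$weights), 1, tolerance = 1e-10)

  # toy matrix against an independent normal-equations solve via lm()
  X3 <- toy_matrix(n = 6, J = 5, seed = 11)
  pr3 <- fit_pair_predictor(X3, 2, 4)
  fit <- lm(y ~ ., data = data.frame(y = X3[, 2] + X3[, 4],
                                     X3[, c(1, 3, 5), drop = FALSE]))
  expect_equal(unname(c(pr3$intercept, pr3$weights)), unname(coef(fit)),
               tolerance = 1e-8)

  # J = 3 with a constant remaining item: zero-slope fallback, no error
  X4 <- cbind(c(1, 0, 1, 0), c(0, 1, 1, 0), c(0, 0, 0, 1))
  X4[, 3] <- 0L
  X4[1, 3] <- 0L
  expect_silent(pr4 <- fit_pair_predictor(rbind(X4, X4), 1, 2))
  expect_equal(unname(pr4$weights), 0, tolerance = 1e-8)

  expect_error(fit_pair_predictor(X[1, , drop = FALSE], 1, 2), "insufficient")
  expect_error(fit_pair_predictor(X, 3, 2), "invalid pair")
})

test_that("conditioning groups are quantile bins that respect ties", {
  # 20 distinct scores, C = 10 -> ten groups of two
  set.seed(3)
  n <- 20
  X <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
  pr <- structure(list(pair = c(i = 1, j = 2), intercept = 0,
                       weights = c(1, 0.1, 0.01), rest = 3:5),
                  class = "acarp_predictor")
  s <- pr$intercept + drop(X[, 3:5] %*% pr$weights)
  s <- s + seq_len(n) * 1e-6 # force all-distinct scores
  cuts <- acarp:::score_cuts(s, 10)
  g <- acarp:::assign_bins(s, cuts)
  expect_equal(unname(tabulate(g)), rep(2L, 10))

  # all scores equal -> one degenerate group
  pr0 <- structure(list(pair = c(i = 1, j = 2), intercept = 2,
                        weights = c(0, 0, 0), rest = 3:5),
                   class = "acarp_predictor")
  gr0 <- conditioning_groups(X, pr0, C = 10)
  expect_equal(gr0$C_actual, 1L)
  expect_true(gr0$degenerate)
  expect_equal(sum(gr0$group_sizes), n)

  # generated scores: C_actual <= C, labels monotone in score, ties share bins
  for (rep in 1:20) {
    s <- sample(seq(0, 20, by = 0.5), 35, replace = TRUE)
    C <- sample(2:10, 1)
    cuts <- acarp:::score_cuts(s, C)
    g <- acarp:::assign_bins(s, cuts)
    expect_lte(length(unique(g)), C)
    expect_false(is.unsorted(g[order(s)]))
    expect_true(all(tapply(g, s, function(v) length(unique(v))) == 1))
  }
})

test_that("group covariance matches enumeration on tiny groups", {
  expect_equal(group_covariance(c(1, 1, 1), c(0, 1, 0)), 0, tolerance = 1e-12)
  expect_equal(group_covariance(c(1, 0), c(1, 0)), 0.25)
  expect_equal(group_covariance(c(1, 0), c(0, 1)), -0.25)
  expect_error(group_covariance(numeric(0), numeric(0)), "empty group")
  expect_error(group_covariance(c(1, 0), c(1)), "equal length")
})

test_that("MCC is the group-size-weighted mean of conditional covariances", {
  # group 1 (n=4, cov 0.25), group 2 (n=6, cov -1/12)
  xi <- c(1, 1, 0, 0, 1, 1, 1, 0, 0, 0)
  xj <- c(1, 1, 0, 0, 0, 0, 1, 1, 1, 0)
  g <- structure(list(labels = rep(1:2, c(4, 6))), class = "acarp_groups")
  r <- mcc_statistic(g, xi, xj)
  expect_equal(r$numerator, 4 * 0.25 + 6 * (-1 / 12), tolerance = 1e-12)
  expect_equal(r$mcc, r$numerator / 10, tolerance = 1e-12)

  # single group reduces to the plain sample covariance
  g1 <- structure(list(labels = rep(1L, 10)), class = "acarp_groups")
  expect_equal(mcc_statistic(g1, xi, xj)$mcc,
               mean(xi * xj) - mean(xi) * mean(xj), tolerance = 1e-12)

  # all covariances zero -> (0, 0)
  xz <- rep(c(1, 0), 5)
  g2 <- structure(list(labels = rep(1:2, 5)), class = "acarp_groups")
  expect_equal(mcc_statistic(g2, xz, rep(1, 10))$numerator, 0)
})

test_that("MH variance matches the stratified hypergeometric form", {
  g4 <- structure(list(labels = rep(1L, 4)), class = "acarp_groups")
  expect_equal(mh_variance(g4, c(1, 1, 0, 0), c(1, 0, 1, 0)),
               2 * 2 * 2 * 2 / (16 * 3), tolerance = 1e-12)
  # constant item -> 0
  expect_equal(mh_variance(g4, c(1, 1, 1, 1), c(1, 0, 1, 0)), 0)
  # additive over groups: duplicated group doubles the variance
  g8 <- structure(list(labels = rep(1:2, each = 4)), class = "acarp_groups")
  expect_equal(mh_variance(g8, rep(c(1, 1, 0, 0), 2), rep(c(1, 0, 1, 0), 2)),
               2 / 3, tolerance = 1e-12)
})

test_that("Z statistic applies the continuity correction in the numerator", {
  expect_equal(z_statistic(-2, 4, continuity = TRUE)$z, -0.75)
  expect_equal(z_statistic(-2, 4, continuity = FALSE)$z, -1)
  expect_equal(z_statistic(-0.5, 1, continuity = TRUE)$p, 0.5)
  expect_error(z_statistic(1, 0), "undefined")
})

test_that("pair_stats agrees with a naive loop oracle and is well-behaved", {
  set.seed(21)
  for (rep in 1:3) {
    X <- matrix(rbinom(50 * 5, 1, runif(1, 0.3, 0.7)), 50, 5)
    for (j in 1:5) if (length(unique(X[, j])) == 1L) X[1, j] <- 1L - X[1, j]
    sp <- split_sample(50, 0.3, seed = rep)
    st <- pair_stats(X, split = sp)
    or <- naive_pair_stats(X, sp)
    expect_equal(st$train_mcc, or$train_mcc, tolerance = 1e-12)
    expect_equal(st$numerator, or$numerator, tolerance = 1e-12)
    expect_equal(st$variance, or$variance, tolerance = 1e-12)
    expect_equal(st$z[!st$degenerate], or$z[!st$degenerate], tolerance = 1e-12)
    expect_true(all(abs(st$mcc) <= 0.25 + 1e-12))
    expect_true(all(st$variance >= 0))
  }
})

test_that("pair_stats has the right shape and symmetries", {
  X <- simulate_irt(sim_design(J = 10, N = 200, scenario = "dim0", seed = 5))
  st <- pair_stats(X, seed = 6)
  expect_equal(nrow(st), 45L)

  # permuting rows within the train and test blocks leaves everything fixed
  X2 <- simulate_irt(sim_design(J = 5, N = 100, scenario = "dim1", seed = 7))
  sp <- list(train = 1:30, test = 31:100)
  set.seed(8)
  perm <- c(sample(1:30), sample(31:100))
  st1 <- pair_stats(X2, split = sp)
  st2 <- pair_stats(X2[perm, ], split = sp)
  expect_equal(tidy(st1), tidy(st2), tolerance = 1e-12)

  # recoding one item flips the sign of every numerator involving it
  # (exact under rest-score conditioning, whose groups are recode-invariant)
  X3 <- X2
  X3[, 2] <- 1L - X3[, 2]
  sa <- pair_stats(X2, split = sp, continuity = FALSE, conditioning = "restscore")
  sb <- pair_stats(X3, split = sp, continuity = FALSE, conditioning = "restscore")
  inv <- sa$pair_i == 2 | sa$pair_j == 2
  expect_equal(sb$numerator[inv], -sa$numerator[inv], tolerance = 1e-12)

  # continuity on shifts every z up by 0.5/sqrt(V)
  son <- pair_stats(X2, split = sp, continuity = TRUE)
  soff <- pair_stats(X2, split = sp, continuity = FALSE)
  ok <- !son$degenerate
  expect_equal(son$z[ok] - soff$z[ok], 0.5 / sqrt(son$variance[ok]),
               tolerance = 1e-12)
  expect_true(all(son$p[ok] >= soff$p[ok]))
})

test_that("pairwise p-values are near uniform for independent Bernoulli items", {
  # dimensionality 0, no continuity shift: left-tail p across replications
  ps <- numeric(0)
  des <- sim_design(J = 5, N = 400, scenario = "dim0", continuity = FALSE)
  for (r in 1:250) {
    X <- simulate_irt(des, seed = 1000 + r)
    st <- pair_stats(X, seed = r, continuity = FALSE)
    ps <- c(ps, st$p[!st$degenerate])
  }
  expect_gte(length(ps), 2000)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("item matrices round-trip through CSV and reject bad input", {
  X <- toy_matrix(n = 8, J = 4, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_item_matrix(X, f)
  expect_identical(read_item_matrix(f), as_item_matrix(X))
  unlink(f)

  expect_error(as_item_matrix(matrix(c(0, 1, 2, 1), 2)), "0 or 1")
  expect_error(as_item_matrix(matrix(c(0, 1, NA, 1), 2)), "missing")
  expect_error(as_item_matrix(matrix(0:1, 2, 2)), "3 items")
})
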