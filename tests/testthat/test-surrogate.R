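test_that("the GP interpolates noise-free data and vanishes on zeros", {
  set.seed(1)
  X <- matrix(runif(30 * 4), 30)
  y <- sin(3 * X[, 1]) + X[, 2]^2
  g <- gp_fit(X, y)
  pr <- predict(g, X)
  expect_lt(max(abs(pr$mean - y)), 0.05)
  # fitted to all-zero residuals the predictive correction is ~0
  g0 <- gp_fit(X, rep(0, 30))
  expect_lt(max(abs(predict(g0, X)$mean)), 1e-6)
})

test_that("the two-stage surrogate reproduces its training data", {
  set.seed(2)
  X <- matrix(rbinom(40 * 20, 1, 0.3), 40)
  y <- 1 + 2 * X[, 1] + X[, 2] * 0.5 + rnorm(40, 0, 0.01)
  m <- train_surrogate(X, y, seed = 1)
  pr <- predict(m, X)
  # stage 2 absorbs the forest's in-sample residuals (GP interpolation)
  expect_gt(cor(pr$mean, y), 0.99)
  expect_true(all(pr$sd >= 0))
  expect_error(train_surrogate(X[1:5, ], y[1:5]), ">= 8")
  expect_warning(train_surrogate(X, rep(1, 40)), "constant targets")
})

test_that("surrogate beats a label-shuffled control on a smooth landscape", {
  lib <- shared_library()
  set.seed(10)
  idx <- sample(nrow(lib$features), 240)
  X <- lib$features[idx, ]
  y <- lib$oracle(rownames(X))
  wins <- 0L
  for (s in 1:10) {
    set.seed(s)
    tr <- sample(240, 120)
    m <- train_surrogate(X[tr, ], y[tr], seed = s)
    rho <- cor(predict(m, X[-tr, ])$mean, y[-tr], method = "spearman")
    m0 <- train_surrogate(X[tr, ], sample(y[tr]), seed = s)
    rho0 <- cor(predict(m0, X[-tr, ])$mean, y[-tr], method = "spearman")
    if (rho > rho0) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("acquisition reduces to mean or sd ranking in the limits", {
  mu <- c(1.2, 0.8, 1.5, 1.1); sd <- c(0.1, 0.5, 0.05, 0.3)
  expect_identical(order(acquisition_score(mu, sd, 0)), order(mu))
  expect_identical(order(acquisition_score(rep(1, 4), sd, 1)), order(sd))
  expect_error(acquisition_score(mu, sd, -1), "non-negative")
  expect_error(acquisition_score(mu, c(-0.1, sd[-1]), 1), ">= 0")
})

test_that("larger beta never makes the top pick less novel", {
  lib <- shared_library()
  set.seed(20)
  tested <- sample(nrow(lib$features), 60)
  X <- lib$features
  y <- lib$oracle(rownames(X)[tested])
  m <- train_surrogate(X[tested, ], y, seed = 3)
  pool <- setdiff(seq_len(nrow(X)), tested)
  pr <- predict(m, X[pool, ])
  novelty <- vapply(c(0, 0.5, 1, 2, 4), function(b) {
    top <- pool[which.max(acquisition_score(pr$mean, pr$sd, b))]
    1 - max(tanimoto_matrix(X[top, , drop = FALSE],
                            X[tested, , drop = FALSE]))
  }, numeric(1))
  expect_true(all(diff(novelty) >= -1e-12))
})

test_that("batch selection is greedy top-k with deterministic tie-breaks", {
  sc <- c(b = 1, a = 1, d = 3, c = 2)
  expect_identical(select_batch(sc, 4), c("d", "c", "a", "b"))
  expect_identical(select_batch(sc, 2), c("d", "c"))
  expect_error(select_batch(sc, 5), "smaller than batch")
  # diversity cutoff 1 equals pure greedy even with fingerprints given
  lib <- shared_library()
  fp <- lib$features[1:4, ]
  sc2 <- stats::setNames(c(4, 3, 2, 1), rownames(fp))
  expect_identical(select_batch(sc2, 2, fp = fp, diversity_cutoff = 1),
                   select_batch(sc2, 2))
})
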