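test_that("degenerate posterior: elpd_loo is the in-sample log-likelihood, p_loo 0", {
  ll <- matrix(rep(c(-1.2, -0.4, -2.2), each = 200), nrow = 200)
  res <- compute_loo(ll)
  expect_equal(res$elpd_loo, sum(ll[1, ]))
  expect_equal(res$p_loo, 0, tolerance = 1e-10)
  expect_equal(res$se, sqrt(3 * var(ll[1, ])))
})

test_that("PSIS-LOO matches exact leave-one-out in a conjugate normal model", {
  # y_i ~ N(theta, 1), theta ~ N(0, 1): closed-form LOO predictives
  set.seed(41)
  n <- 20
  y <- rnorm(n, 0.7, 1)
  post_par <- function(yy) {
    v <- 1 / (1 + length(yy))
    list(m = v * sum(yy), v = v)
  }
  full <- post_par(y)
  S <- 4000
  theta <- rnorm(S, full$m, sqrt(full$v))
  ll <- sapply(y, function(yi) dnorm(yi, theta, 1, log = TRUE))
  res <- compute_loo(ll)
  exact <- sum(vapply(seq_len(n), function(i) {
    p <- post_par(y[-i])
    dnorm(y[i], p$m, sqrt(1 + p$v), log = TRUE)
  }, numeric(1)))
  expect_lt(abs(res$elpd_loo - exact), 0.25)
  expect_true(all(res$pointwise$k < 0.7))
  # effective parameter count of a one-parameter model is about one
  expect_gt(res$p_loo, 0.2)
  expect_lt(res$p_loo, 3)
})

test_that("elpd_loo penalizes relative to the in-sample lpd", {
  set.seed(42)
  theta <- rnorm(500, 0, 0.4)
  y <- rnorm(10)
  ll <- sapply(y, function(yi) dnorm(yi, theta, 1, log = TRUE))
  res <- compute_loo(ll)
  lpd <- sum(apply(ll, 2, function(v) log(mean(exp(v)))))
  expect_lte(res$elpd_loo, lpd + 1e-10)
  expect_gte(res$p_loo, 0)
})

test_that("the generalized Pareto fit recovers known shapes approximately", {
  set.seed(43)
  rgpd <- function(n, k, sigma) sigma * (runif(n)^(-k) - 1) / k
  for (k_true in c(0.2, 0.5)) {
    x <- rgpd(3000, k_true, 1)
    fit <- drsirt:::.gpd_fit(x)
    expect_lt(abs(fit["k"] - k_true), 0.1)
    expect_lt(abs(fit["sigma"] - 1), 0.15)
  }
})

test_that("elpd_diff uses the pointwise difference vector", {
  set.seed(44)
  ll1 <- matrix(rnorm(200 * 15, -1), 200, 15)
  ll2 <- ll1 + matrix(rnorm(200 * 15, 0, 0.01), 200, 15)
  a <- compute_loo(ll1); b <- compute_loo(ll2)
  d <- elpd_diff(a, b)
  expect_equal(d$delta_elpd, a$elpd_loo - b$elpd_loo)
  dd <- a$pointwise$elpd_i - b$pointwise$elpd_i
  expect_equal(d$se, sqrt(length(dd) * var(dd)))
  # self comparison: exactly zero with zero SE
  self <- elpd_diff(a, a)
  expect_equal(self$delta_elpd, 0)
  expect_equal(self$se, 0)
  expect_error(elpd_diff(a, compute_loo(ll1[, 1:3])), "different observation")
})
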