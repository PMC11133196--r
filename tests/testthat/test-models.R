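test_that("brm_mean follows the logistic link", {
  it <- brm_item_params(alpha = 2, delta = 0.5, tau = 4)
  expect_equal(brm_mean(0.5, it), 0.5)
  expect_equal(brm_mean(1.5, it), plogis(2), tolerance = 1e-12)
  expect_equal(plogis(2), 0.8807971, tolerance = 1e-6)
  expect_gt(brm_mean(30, it), 1 - 1e-10)
  # strictly increasing in theta
  th <- seq(-3, 3, length.out = 50)
  expect_true(all(diff(brm_mean(th, it)) > 0))
})

test_that("brm_logpdf equals the generic beta density under the reparameterization", {
  it <- brm_item_params(alpha = 1, delta = 0, tau = 2)
  expect_equal(brm_logpdf(0.5, 0, it), 0)   # Beta(1, 1)
  it4 <- brm_item_params(alpha = 1, delta = 0, tau = 4)
  expect_equal(brm_logpdf(0.25, 0, it4), log(6 * 0.25 * 0.75))  # Beta(2, 2)
  expect_equal(log(6 * 0.25 * 0.75), 0.1177830, tolerance = 1e-6)
  set.seed(1)
  for (i in 1:1000) {
    x <- runif(1, 0.01, 0.99); theta <- rnorm(1)
    it <- brm_item_params(alpha = rlnorm(1, 0, 0.5), delta = rnorm(1),
                          tau = rlnorm(1, log(10), 0.7))
    mu <- plogis(it$alpha * (theta - it$delta))
    oracle <- dbeta(x, mu * it$tau, (1 - mu) * it$tau, log = TRUE)
    expect_equal(brm_logpdf(x, theta, it), oracle, tolerance = 1e-12)
  }
  expect_error(brm_logpdf(0, 0, it), "compress")
  expect_error(brm_logpdf(1, 0, it), "compress")
})

test_that("ddrm_mean reproduces the location-width coupling", {
  it <- ddrm_item_params(1, 0, 1, 0, tau = 3)
  expect_equal(unname(ddrm_mean(0, 0, it)[1, ]), c(0.25, 0.5, 0.25))
  # eta -> -Inf: zero width, components (mu, 0, 1 - mu)
  m <- ddrm_mean(1, -50, it)
  expect_equal(unname(m[1, ]), c(plogis(1), 0, 1 - plogis(1)), tolerance = 1e-12)
  # mu = 0.5, omega = 1/3: uniform simplex
  it2 <- ddrm_item_params(1, 0, 1, qlogis(2/3), tau = 3)
  expect_equal(unname(ddrm_mean(0, 0, it2)[1, ]), rep(1/3, 3), tolerance = 1e-12)
  # monotonicity: expected width in eta, expected midpoint in theta
  et <- seq(-3, 3, length.out = 40)
  expect_true(all(diff(ddrm_mean(0, et, it)[, "width"]) > 0))
  th <- seq(-3, 3, length.out = 40)
  mid <- ddrm_mean(th, 0.3, it)
  expect_true(all(diff(mid[, "lower"] + mid[, "width"] / 2) > 0))
  # omega -> 1 squeezes the expected midpoint to the scale center
  m1 <- ddrm_mean(2, 50, it)
  expect_equal(unname(m1[1, "lower"] + m1[1, "width"] / 2), 0.5, tolerance = 1e-6)
  expect_simplex(ddrm_mean(rnorm(50), rnorm(50), it))
})

test_that("ddrm_logpdf equals a hand-rolled Dirichlet density", {
  it <- ddrm_item_params(1, 0, 1, qlogis(2/3), tau = 3)
  # shapes (1,1,1): flat Dirichlet, density Gamma(3) = 2
  expect_equal(ddrm_logpdf(c(1, 1, 1) / 3, 0, 0, it), log(2), tolerance = 1e-12)
  ddirich <- function(x, a) {
    lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(x))
  }
  set.seed(2)
  for (i in 1:1000) {
    g <- rgamma(3, shape = 1); x <- g / sum(g)
    theta <- rnorm(1); eta <- rnorm(1)
    it <- ddrm_item_params(rlnorm(1, 0, 0.5), rnorm(1), rlnorm(1, 0, 0.5),
                           rnorm(1), rlnorm(1, log(10), 0.7))
    a <- as.vector(ddrm_mean(theta, eta, it)) * it$tau
    expect_equal(ddrm_logpdf(x, theta, eta, it), ddirich(x, a),
                 tolerance = 1e-12)
  }
  expect_error(ddrm_logpdf(c(0, 0.5, 0.5), 0, 0, it), "compress")
})

test_that("ddrm_logpdf integrates to one over the simplex (Monte Carlo)", {
  it <- ddrm_item_params(1.2, -0.3, 0.8, 0.5, tau = 6)
  set.seed(3)
  n <- 40000
  # uniform points on the simplex; Lebesgue measure of {x1, x2 > 0, x1+x2 < 1}
  # is 1/2, and the density is defined w.r.t. (x1, x2)
  g <- matrix(rgamma(3 * n, 1), ncol = 3)
  x <- g / rowSums(g)
  vals <- exp(ddrm_logpdf(x, theta = 0.4, eta = -0.2, it))
  est <- mean(vals) * 0.5
  se <- sd(vals) * 0.5 / sqrt(n)
  expect_lt(abs(est - 1), 3 * se + 1e-3)
})

test_that("compressed boundary responses never produce non-finite densities", {
  it_b <- brm_item_params(1, 0, 5)
  it_d <- ddrm_item_params(1, 0, 1, 0, 5)
  v <- compress(vas_components(c(0, 50, 100)), n = 100)
  expect_true(all(is.finite(brm_logpdf(v[, 1], 0.3, it_b))))
  d <- compress(drs_components(c(0, 50, 0), c(100, 50, 0)), n = 100)
  expect_true(all(is.finite(ddrm_logpdf(d, 0.1, -0.4, it_d))))
})
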