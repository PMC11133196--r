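# exhaustive-window oracle for the HDI
hdi_oracle <- function(s, mass = 0.95) {
  s <- sort(s)
  n <- length(s)
  m <- min(n, ceiling(mass * n))
  best <- c(s[1], s[m]); bw <- s[m] - s[1]
  for (i in seq_len(n - m + 1)) {
    w <- s[i + m - 1] - s[i]
    if (w < bw) { bw <- w; best <- c(s[i], s[i + m - 1]) }
  }
  best
}

test_that("hdi equals the exhaustive shortest-window oracle", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(5:400, 1)
    s <- switch(sample(3, 1),
                rnorm(n), rexp(n), c(rnorm(n %/% 2), rnorm(n - n %/% 2, 6)))
    mass <- sample(c(0.5, 0.8, 0.9, 0.95), 1)
    expect_equal(unname(hdi(s, mass)), hdi_oracle(s, mass))
  }
})

test_that("hdi handles edge cases", {
  expect_equal(unname(hdi(rep(3, 10))), c(3, 3))
  s <- rnorm(100)
  expect_equal(hdi(s), hdi(sample(s)))  # permutation invariance
  expect_equal(unname(hdi(1:100, 0.95)), c(1, 95))
  expect_error(hdi(numeric(0)), "at least two")
})

test_that("clpm closed form: orthogonal and null cases", {
  mk <- function(rx, ry1, ry2, ryy) {
    R <- diag(4)
    R[1, 2] <- R[2, 1] <- rx
    R[1, 3] <- R[3, 1] <- ry1[1]; R[2, 3] <- R[3, 2] <- ry1[2]
    R[1, 4] <- R[4, 1] <- ry2[1]; R[2, 4] <- R[4, 2] <- ry2[2]
    R[3, 4] <- R[4, 3] <- ryy
    R
  }
  # identity predictors, r(x1, y1) = 0.5
  R <- mk(0, c(0.5, 0), c(0, 0), 0)
  arr <- array(R, c(4, 4, 2))
  arr <- aperm(arr, c(3, 1, 2))
  res <- clpm_from_correlation(arr)
  sm <- res$summary
  expect_equal(sm$median[sm$parameter == "beta11"], 0.5)
  expect_equal(sm$median[sm$parameter == "beta21"], 0)
  expect_equal(sm$median[sm$parameter == "r2_full_E"], 0.25)
  expect_equal(sm$median[sm$parameter == "delta_r2_E"], 0.25)
  # all-zero off-diagonals except the outcome block
  R0 <- mk(0, c(0, 0), c(0, 0), 0.4)
  arr0 <- aperm(array(R0, c(4, 4, 2)), c(3, 1, 2))
  sm0 <- clpm_from_correlation(arr0)$summary
  expect_true(all(sm0$median[grepl("beta", sm0$parameter)] == 0))
  expect_equal(sm0$median[sm0$parameter == "rho_residual"], 0.4)
})

test_that("clpm closed form matches Monte-Carlo OLS on a fixed matrix", {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.8
  R[2, 3] <- R[3, 2] <- 0.75
  R[1, 4] <- R[4, 1] <- 0.7
  R[2, 4] <- R[4, 2] <- 0.78
  R[3, 4] <- R[4, 3] <- 0.85
  expect_gt(min(eigen(R, only.values = TRUE)$values), 0)
  arr <- aperm(array(R, c(4, 4, 2)), c(3, 1, 2))
  sm <- clpm_from_correlation(arr)$summary
  set.seed(99)
  n <- 2e5
  X <- matrix(rnorm(n * 4), n, 4) %*% chol(R)
  f1 <- lm(X[, 3] ~ X[, 1] + X[, 2])
  f2 <- lm(X[, 4] ~ X[, 1] + X[, 2])
  expect_lt(abs(sm$median[sm$parameter == "beta11"] - coef(f1)[2]), 0.01)
  expect_lt(abs(sm$median[sm$parameter == "beta21"] - coef(f1)[3]), 0.01)
  expect_lt(abs(sm$median[sm$parameter == "beta12"] - coef(f2)[2]), 0.01)
  expect_lt(abs(sm$median[sm$parameter == "r2_full_E"] -
                  summary(f1)$r.squared), 0.01)
  expect_lt(abs(sm$median[sm$parameter == "rho_residual"] -
                  cor(resid(f1), resid(f2))), 0.01)
})

test_that("descriptive_table averages within persons first", {
  df <- rbind(
    data.frame(person_id = "a", item_id = c("E01", "E02", "E03"), trait = "E",
               occasion = 1L, format = c("VAS", "DRS", "DRS"),
               value_low = c(60, 40, 20), value_high = c(60, 90, 40),
               reverse_coded = FALSE, block_order = "VAS_first",
               response_time_s = NA, serious = NA),
    data.frame(person_id = "b", item_id = c("E01", "E02", "E03"), trait = "E",
               occasion = 1L, format = c("VAS", "DRS", "DRS"),
               value_low = c(30, 10, 50), value_high = c(30, 20, 80),
               reverse_coded = FALSE, block_order = "VAS_first",
               response_time_s = NA, serious = NA))
  out <- descriptive_table(response_table(df))
  # person a: DRS midpoints (65, 30) -> 47.5; widths (50, 20) -> 35
  # person b: midpoints (15, 65) -> 40;    widths (10, 30) -> 20
  expect_equal(out$vas_m, mean(c(60, 30)))
  expect_equal(out$drs_loc_m, mean(c(47.5, 40)))
  expect_equal(out$drs_wid_m, mean(c(35, 20)))
  expect_equal(out$drs_lb_m, mean(c(mean(c(40, 20)), mean(c(10, 50)))))
  expect_equal(out$drs_ub_m, mean(c(mean(c(90, 40)), mean(c(20, 80)))))
  expect_equal(out$vas_sd, sd(c(60, 30)))
  # identical persons give zero SDs
  df2 <- df; df2$person_id <- rep(c("a", "b"), each = 3)
  df2$value_low <- rep(df$value_low[1:3], 2)
  df2$value_high <- rep(df$value_high[1:3], 2)
  out2 <- descriptive_table(response_table(df2))
  expect_equal(out2$vas_sd, 0)
  expect_equal(out2$drs_wid_sd, 0)
})

test_that("single DRS interval (40, 90): width 50, location 65", {
  df <- data.frame(person_id = "a", item_id = "E01", trait = "E",
                   occasion = 1L, format = "DRS", value_low = 40,
                   value_high = 90, reverse_coded = FALSE,
                   block_order = "DRS_first", response_time_s = NA,
                   serious = NA)
  out <- descriptive_table(response_table(df))
  expect_equal(out$drs_loc_m, 65)
  expect_equal(out$drs_wid_m, 50)
  expect_equal(out$drs_lb_m, 40)
  expect_equal(out$drs_ub_m, 90)
})

test_that("cumulative interval density counts containment and conserves mass", {
  r <- cumulative_interval_density(c(0, 25), c(50, 75), grid_step = 1)
  dens_at <- function(x) r$density[match(x, r$grid)]
  expect_equal(dens_at(30), 2)
  expect_equal(dens_at(60), 1)
  expect_equal(dens_at(80), 0)
  expect_equal(r$total_mass, 100)
  # integral of the density trace equals summed widths (up to grid resolution)
  expect_equal(sum(r$density) * 1, 100, tolerance = 3)
  expect_equal(r$median, 37.5)
  # fine-grid numeric oracle for the median
  g <- seq(0, 100, by = 0.001)
  cnt <- vapply(g, function(x) sum(c(0, 25) <= x & x <= c(50, 75)), numeric(1))
  cm <- cumsum(cnt) * 0.001
  expect_equal(g[which.min(abs(cm - 0.5 * max(cm)))], r$median, tolerance = 0.01)
  # single interval: median at the midpoint
  one <- cumulative_interval_density(20, 60)
  expect_equal(one$median, 40)
  expect_equal(one$q025, 20 + 0.025 * 40)
  expect_error(cumulative_interval_density(numeric(0), numeric(0)),
               "at least one interval")
})

test_that("order-effect analysis fits both block-order subgroups", {
  sim <- small_simulation(n_persons = 36, items_per_trait = 4, seed = 81)
  res <- order_effect_analysis(sim$table, test_config(iter = 80, warmup = 120))
  expect_setequal(names(res), c("VAS_first", "DRS_first"))
  # subgroup sizes partition the sample
  n1 <- sum(vapply(res, `[[`, numeric(1), "n_persons"))
  expect_equal(n1, 36)
  for (r in res) {
    expect_equal(nrow(r$summary), 2L)  # one convergent pair per trait
    expect_true(all(r$summary$hdi_low <= r$summary$median &
                      r$summary$median <= r$summary$hdi_high))
  }
  # identical generating process: subgroup estimates agree loosely
  meds <- vapply(res, function(r) r$summary$median[1], numeric(1))
  expect_lt(abs(diff(meds)), 0.35)
  # single block order present -> error
  df <- as.data.frame(sim$table)
  df$block_order <- "VAS_first"
  expect_error(order_effect_analysis(response_table(df), test_config()),
               "both block orders")
})

test_that("rq_correlation_pairs covers the three research-question families", {
  p <- rq_correlation_pairs()
  expect_equal(sum(p$family == "test_retest"), 6L)
  expect_equal(sum(p$family == "convergent"), 4L)
  expect_equal(sum(p$family == "discriminant"), 6L)
  expect_true(all(c(p$a, p$b) %in% person_dims()))
})
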