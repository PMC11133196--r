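test_that("C++ log-posterior gradient matches numerical differentiation", {
  sim <- small_simulation(n_persons = 6, items_per_trait = 4, seed = 51)
  cfg <- model_config()
  data <- drsirt:::.build_model_data(sim$table, unique(sim$table$trait),
                                     "strict", cfg$priors)
  lay <- drsirt:::.par_layout(data)
  set.seed(52)
  par <- rnorm(lay$npar, 0, 0.4)
  res <- drsirt:::.lp_grad_cpp(par, data, TRUE)
  expect_length(res$loglik, nrow(sim$table))
  expect_true(is.finite(res$lp))
  h <- 1e-5
  idx <- sort(sample(lay$npar, 80))
  num <- vapply(idx, function(k) {
    pp <- par; pp[k] <- pp[k] + h
    up <- drsirt:::.lp_grad_cpp(pp, data, FALSE)$lp
    pp[k] <- pp[k] - 2 * h
    dn <- drsirt:::.lp_grad_cpp(pp, data, FALSE)$lp
    (up - dn) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num - res$grad[idx]) / pmax(1, abs(num))), 1e-5)
})

test_that("log-posterior equals an independent R-side computation", {
  # the C++ likelihood must match the exported density functions plus priors
  sim <- small_simulation(n_persons = 5, items_per_trait = 2, seed = 53)
  tab <- sim$table
  cfg <- model_config()
  data <- drsirt:::.build_model_data(tab, unique(tab$trait), "strict",
                                     cfg$priors)
  lay <- drsirt:::.par_layout(data)
  set.seed(54)
  par <- rnorm(lay$npar, 0, 0.3)
  res <- drsirt:::.lp_grad_cpp(par, data, TRUE)
  # reconstruct pointwise log-likelihoods in R from the draw
  o <- lay$offsets; s <- lay$sizes
  L <- drsirt:::.corr_chol_from_y(par[o["y"] + seq_len(s["y"])], data$D)
  mu <- rep(0, data$D); sg <- rep(1, data$D)
  mu[data$free_mu + 1] <- par[o["mu"] + seq_len(s["mu"])]
  sg[data$free_sig + 1] <- exp(par[o["sig"] + seq_len(s["sig"])])
  P <- t(sapply(seq_len(data$N), function(p) {
    z <- par[(p - 1) * data$D + seq_len(data$D)]
    mu + sg * as.vector(L %*% z)
  }))
  meta <- attr(data, "meta")
  ll <- numeric(length(res$loglik))
  nv <- length(data$v_p)
  for (r in seq_len(nv)) {
    it <- list(alpha = exp(par[o["ba"] + data$v_ia[r] + 1]),
               delta = par[o["bd"] + data$v_id[r] + 1],
               tau = exp(par[o["bt"] + data$v_it[r] + 1]))
    x <- exp(data$v_lx[r])
    ll[r] <- brm_logpdf(x, P[data$v_p[r] + 1, data$v_dim[r] + 1], it)
  }
  for (r in seq_along(data$d_p)) {
    it <- list(alpha_loc = exp(par[o["dal"] + data$d_ial[r] + 1]),
               delta_loc = par[o["dl"] + data$d_idl[r] + 1],
               alpha_wid = exp(par[o["daw"] + data$d_iaw[r] + 1]),
               delta_wid = par[o["dw"] + data$d_idw[r] + 1],
               tau = exp(par[o["dt"] + data$d_it[r] + 1]))
    x <- exp(c(data$d_lx1[r], data$d_lx2[r], data$d_lx3[r]))
    ll[nv + r] <- ddrm_logpdf(x, P[data$d_p[r] + 1, data$d_diml[r] + 1],
                              P[data$d_p[r] + 1, data$d_dimw[r] + 1], it)
  }
  expect_equal(res$loglik, ll, tolerance = 1e-9)
})

test_that("identification constraints hold exactly in the posterior draws", {
  sim <- small_simulation(n_persons = 12, items_per_trait = 2, seed = 55)
  fit <- fit_joint(sim$table, test_config(iter = 50, warmup = 100))
  t1 <- grep("_t1$", fit$dims)
  t2 <- grep("_t2$", fit$dims)
  expect_true(all(fit$pop$mu[, t1] == 0))
  expect_true(all(fit$pop$sigma[, t1] == 1))
  expect_true(any(fit$pop$mu[, t2] != 0))
  # every correlation draw is symmetric with unit diagonal
  S <- dim(fit$pop$corr)[1]
  for (sdx in sample(S, 5)) {
    R <- fit$pop$corr[sdx, , ]
    expect_equal(R, t(R), tolerance = 1e-12)
    expect_equal(diag(R), setNames(rep(1, 12), fit$dims), tolerance = 1e-12)
  }
})

test_that("fixed seed and data reproduce draws exactly; seeds differ otherwise", {
  sim <- small_simulation(n_persons = 8, items_per_trait = 2, seed = 56)
  cfg <- test_config(iter = 40, warmup = 80, chains = 2)
  f1 <- fit_joint(sim$table, cfg)
  f2 <- fit_joint(sim$table, cfg)
  expect_identical(f1$draws, f2$draws)
  cfg$seed <- 43
  f3 <- fit_joint(sim$table, cfg)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("pointwise log-likelihood bookkeeping matches the table", {
  sim <- small_simulation(n_persons = 8, items_per_trait = 2, seed = 57)
  fit <- fit_joint(sim$table, test_config(iter = 30, warmup = 80))
  ll <- pointwise_loglik(fit)
  expect_equal(ncol(ll), nrow(sim$table))
  expect_equal(nrow(ll), 30 * 2)
  expect_true(all(is.finite(ll)))
  fit2 <- fit_joint(sim$table, test_config(iter = 30, warmup = 80,
                                           store_loglik = FALSE))
  expect_error(pointwise_loglik(fit2), "store_loglik")
})

test_that("degenerate inputs are rejected with informative errors", {
  sim <- small_simulation(n_persons = 5, items_per_trait = 2, seed = 58)
  one <- sim$table[sim$table$person_id == "P001", ]
  one <- response_table(as.data.frame(one))
  expect_error(fit_joint(one, test_config()), "two persons")
  # person missing at occasion 2
  df <- as.data.frame(sim$table)
  df <- df[!(df$person_id == "P002" & df$occasion == 2), ]
  expect_error(fit_joint(response_table(df), test_config()),
               "without records at every occasion.*P002")
  # un-recoded reverse-coded rows are refused
  df2 <- as.data.frame(sim$table)
  df2$reverse_coded[1] <- TRUE
  expect_error(fit_joint(response_table(df2), test_config()), "reverse_code")
})

test_that("strict fits expose one parameter set per item; configural two", {
  sim <- small_simulation(n_persons = 10, items_per_trait = 4, seed = 59)
  cfg <- test_config(iter = 20, warmup = 60, chains = 1, store_loglik = FALSE)
  strict <- fit_submodel(sim$table, "E", "DRS", "strict", cfg)
  conf <- fit_submodel(sim$table, "E", "DRS", "configural", cfg)
  n_items <- 4  # items of trait E seen in DRS format across persons
  expect_equal(unname(n_item_parameters(strict)[c("ddrm_alpha_loc",
                                                  "ddrm_delta_loc",
                                                  "ddrm_tau")]),
               rep(n_items, 3))
  expect_equal(unname(n_item_parameters(conf)[c("ddrm_alpha_loc",
                                                "ddrm_delta_loc",
                                                "ddrm_tau")]),
               rep(2 * n_items, 3))
  # metric: alpha shared (expanded draws identical across occasions),
  # delta occasion-specific
  metric <- fit_submodel(sim$table, "E", "DRS", "metric", cfg)
  al <- item_parameter_draws(metric, "ddrm", "alpha_loc")
  expect_identical(al[, "E01@t1"], al[, "E01@t2"])
  dl <- item_parameter_draws(metric, "ddrm", "delta_loc")
  expect_false(identical(dl[, "E01@t1"], dl[, "E01@t2"]))
})

test_that("correlation extraction agrees between R and C++ transforms", {
  set.seed(61)
  for (d in c(2, 4, 12)) {
    y <- rnorm(d * (d - 1) / 2, 0, 0.8)
    L <- drsirt:::.corr_chol_from_y(y, d)
    R <- tcrossprod(L)
    expect_equal(diag(R), rep(1, d), tolerance = 1e-12)
    expect_gt(min(eigen(R, only.values = TRUE)$values), 0)
  }
})
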