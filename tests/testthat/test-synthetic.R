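test_that("draw_persons respects the population and the seed", {
  pop <- population_config(R = diag(12))
  X1 <- draw_persons(500, pop, seed = 5)
  X2 <- draw_persons(500, pop, seed = 5)
  expect_identical(X1, X2)
  expect_false(identical(X1, draw_persons(500, pop, seed = 6)))
  expect_equal(dim(X1), c(500L, 12L))
  # identity R: sample correlations concentrate around zero at large n
  X <- draw_persons(50000, pop, seed = 1)
  C <- cor(X)
  expect_lt(max(abs(C[upper.tri(C)])), 0.02)
  expect_lt(max(abs(colMeans(X[, 1:6]))), 0.02)
  expect_lt(max(abs(apply(X[, 1:6], 2, sd) - 1)), 0.02)
})

test_that("draw_persons reports non-positive-definite correlation input", {
  R <- diag(12); R[1, 2] <- R[2, 1] <- 1.2
  expect_error(population_config(R = R), "not positive definite.*eigenvalue")
})

test_that("population_config enforces the identification constraints", {
  expect_error(population_config(R = diag(12), mu = c(0.5, rep(0, 11))),
               "occasion-1 means")
  expect_error(population_config(R = diag(12), sigma = c(2, rep(1, 11))),
               "occasion-1 SDs")
})

test_that("draw_items: support, determinism, degenerate priors, prior mean", {
  pr <- item_prior_defaults()
  it <- draw_items(2000, prior = pr, seed = 2)
  expect_true(all(it$brm$alpha > 0) && all(it$brm$tau > 0))
  expect_true(all(it$ddrm$alpha_loc > 0) && all(it$ddrm$alpha_wid > 0))
  # sample mean of delta within CLT bound of the prior mean
  se <- pr$delta_sd / sqrt(2000)
  expect_lt(abs(mean(it$brm$delta) - pr$delta_mean), 4 * se)
  # point-mass prior: every item identical
  pr0 <- lapply(pr, function(x) x)
  pr0$alpha_sdlog <- pr0$delta_sd <- pr0$delta_wid_sd <- pr0$tau_sdlog <- 0
  it0 <- draw_items(10, prior = pr0, seed = 3)
  expect_equal(length(unique(it0$brm$alpha)), 1L)
  expect_equal(length(unique(it0$ddrm$delta_wid)), 1L)
})

test_that("simulate_study emits one valid record per design slot", {
  sim <- small_simulation(n_persons = 15, items_per_trait = 6, seed = 4)
  tab <- sim$table
  expect_equal(nrow(tab), n_response_slots(sim$design))  # 15 * 12 * 2
  expect_true(all(tab$value_low <= tab$value_high))
  expect_true(all(tab$value_low >= 0 & tab$value_high <= 100))
  expect_true(all(tab$value_low[tab$format == "VAS"] ==
                    tab$value_high[tab$format == "VAS"]))
  # identical format assignment across occasions comes from the design
  key <- paste(tab$person_id, tab$item_id)
  expect_true(all(tapply(tab$format, key, function(f) length(unique(f))) == 1))
})

test_that("generator hits the paper-scale record count", {
  d <- make_design(224, 42, 2, seed = 1)
  expect_equal(n_response_slots(d), 37632L)
})

test_that("high precision concentrates responses at the model mean", {
  pop <- reference_population()
  pr <- pop$item_prior
  pr$tau_meanlog <- log(5000); pr$tau_sdlog <- 0
  pop$item_prior <- pr
  design <- make_design(10, 4, 1, seed = 2)
  truth <- draw_truth(design, pop, seed = 3)
  tab <- simulate_study(design, truth, pop, seed = 4)
  drs <- tab[tab$format == "DRS", ]
  idx <- match(drs$item_id, truth$items$ddrm$item_id)
  th <- truth$persons[cbind(match(drs$person_id, rownames(truth$persons)),
                            match(paste0("thetaD_", drs$trait, "_t1"),
                                  colnames(truth$persons)))]
  et <- truth$persons[cbind(match(drs$person_id, rownames(truth$persons)),
                            match(paste0("etaD_", drs$trait, "_t1"),
                                  colnames(truth$persons)))]
  m <- ddrm_mean(th, et, truth$items$ddrm[idx, ])
  expect_lt(mean(abs(drs$value_low / 100 - m[, "lower"])), 0.01)
})

test_that("empirical DRS component means match ddrm_mean (Monte Carlo)", {
  pop <- reference_population()
  design <- make_design(20000, 2, 1, traits = "E", seed = 5)
  truth <- draw_truth(design, pop, seed = 6)
  tab <- simulate_study(design, truth, pop, seed = 7)
  drs <- tab[tab$format == "DRS", ]
  item <- drs$item_id[1]
  drs <- drs[drs$item_id == item, ]
  comp <- drs_components(drs$value_low, drs$value_high)
  ip <- truth$items$ddrm[truth$items$ddrm$item_id == item, ]
  pid <- match(drs$person_id, rownames(truth$persons))
  m <- ddrm_mean(truth$persons[pid, "thetaD_E_t1"],
                 truth$persons[pid, "etaD_E_t1"], ip)
  for (k in 1:3) {
    diff <- mean(comp[, k]) - mean(m[, k])
    se <- sd(comp[, k]) / sqrt(nrow(comp))
    expect_lt(abs(diff), 4 * se)
  }
})

test_that("strict invariance: occasion-2 regeneration with shared items is a no-op", {
  sim <- small_simulation(n_persons = 8, items_per_trait = 4, seed = 9)
  truth2 <- sim$truth
  truth2$items_t2 <- truth2$items   # explicit override equals the shared set
  tab2 <- simulate_study(sim$design, truth2, reference_population(), seed = 11)
  tab1 <- simulate_study(sim$design, sim$truth, reference_population(), seed = 11)
  expect_equal(as.data.frame(tab1), as.data.frame(tab2))
})

test_that("reference population reproduces its specified cells and is PD", {
  pop <- reference_population()
  R <- pop$R
  expect_equal(R["etaD_E_t1", "etaD_C_t1"], 0.94, tolerance = 1e-8)
  expect_equal(R["thetaV_E_t1", "thetaD_E_t1"], 0.93, tolerance = 1e-8)
  expect_equal(R["etaD_E_t1", "etaD_E_t2"], 0.81, tolerance = 1e-8)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  sp <- attr(R, "specified")
  expect_equal(sp$value, sp$target, tolerance = 1e-6)
  # zero fill is also positive definite after projection, but distorts cells
  pz <- reference_population(fill = "zero")
  expect_gt(min(eigen(pz$R, symmetric = TRUE, only.values = TRUE)$values), 0)
  spz <- attr(pz$R, "specified")
  expect_gt(max(abs(spz$value - spz$target)), 0.05)
})

test_that("nearest_correlation clips eigenvalues and keeps valid matrices fixed", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9; R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9  # indefinite
  P <- nearest_correlation(R)
  expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(diag(P), rep(1, 3))
  good <- reference_population()$R
  expect_equal(nearest_correlation(good), good, tolerance = 1e-6,
               ignore_attr = TRUE)
})
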