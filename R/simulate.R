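#' Draw person parameters from the population distribution
#'
#' Draws `n` independent 12-vectors (or whatever dimension the population
#' carries) from `MVN(mu, D R D)` with `D = diag(sigma)`.
#'
#' @param n Number of persons.
#' @param pop A [population_config()].
#' @param seed Integer seed.
#' @return `n x d` matrix with dimension labels as column names.
#' @export
draw_persons <- function(n, pop, seed = 1) {
  stopifnot(inherits(pop, "population_config"))
  d <- length(pop$mu)
  ev <- eigen(pop$R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("correlation matrix not positive definite (smallest eigenvalue %.3e)",
                 min(ev)))
  }
  set.seed(seed)
  Z <- matrix(rnorm(n * d), n, d)
  Sig_chol <- chol(diag(pop$sigma) %*% pop$R %*% diag(pop$sigma))
  X <- Z %*% Sig_chol + matrix(pop$mu, n, d, byrow = TRUE)
  colnames(X) <- names(pop$mu)
  X
}

#' Draw item parameters from the generator prior
#'
#' One parameter set per item (strict measurement invariance across
#' occasions, by construction). Every item receives both a BRM set (for the
#' persons answering it with the single slider) and a DDRM set (for the
#' persons answering it with the dual-range slider).
#'
#' @param item_ids Character vector of item ids (or a single integer, taken
#'   as a count).
#' @param prior Hyperparameter list, see [item_prior_defaults()]. Point-mass
#'   priors (zero SDs) give identical items.
#' @param seed Integer seed.
#' @return List with elements `brm` and `ddrm`: data frames of item
#'   parameters keyed by `item_id`.
#' @export
draw_items <- function(item_ids, prior = item_prior_defaults(), seed = 1) {
  if (is.numeric(item_ids) && length(item_ids) == 1L) {
    item_ids <- sprintf("I%02d", seq_len(item_ids))
  }
  m <- length(item_ids)
  set.seed(seed)
  brm <- data.frame(
    item_id = item_ids,
    alpha = rlnorm(m, prior$alpha_meanlog, prior$alpha_sdlog),
    delta = rnorm(m, prior$delta_mean, prior$delta_sd),
    tau = rlnorm(m, prior$tau_meanlog, prior$tau_sdlog),
    stringsAsFactors = FALSE)
  ddrm <- data.frame(
    item_id = item_ids,
    alpha_loc = rlnorm(m, prior$alpha_meanlog, prior$alpha_sdlog),
    delta_loc = rnorm(m, prior$delta_mean, prior$delta_sd),
    alpha_wid = rlnorm(m, prior$alpha_meanlog, prior$alpha_sdlog),
    delta_wid = rnorm(m, prior$delta_wid_mean, prior$delta_wid_sd),
    tau = rlnorm(m, prior$tau_meanlog, prior$tau_sdlog),
    stringsAsFactors = FALSE)
  list(brm = brm, ddrm = ddrm)
}

#' Draw complete ground truth (persons + items) for a design
#'
#' @param design A [make_design()] object.
#' @param pop A [population_config()].
#' @param seed Integer seed.
#' @return List with `persons` (matrix, rownames = person ids) and `items`
#'   (list `brm`/`ddrm` as in [draw_items()]).
#' @export
draw_truth <- function(design, pop, seed = 1) {
  persons <- draw_persons(design$n_persons, pop, seed = seed)
  rownames(persons) <- design$persons
  items <- draw_items(design$items$item_id, prior = pop$item_prior,
                      seed = seed + 1L)
  list(persons = persons, items = items)
}

#' Simulate a complete multitrait-multimethod response table
#'
#' Generates one response per person x item x occasion slot of the design.
#' Items assigned to a person's VAS half produce beta-distributed single
#' responses; items in the DRS half produce Dirichlet-distributed interval
#' responses, using the trait- and occasion-specific person parameters and
#' the shared item parameters (strict invariance). Raw values are returned on
#' the 0-`scale_max` scale; items listed in `design$reverse_coded_items` are
#' emitted reflected with the `reverse_coded` flag set, so preprocessing has
#' real work to do.
#'
#' @param design A [make_design()] object.
#' @param truth Ground truth as from [draw_truth()]. An optional element
#'   `items_t2` (same shape as `items`) replaces the item parameters at
#'   occasions > 1, for generating invariance violations.
#' @param pop A [population_config()]; supplies `rounding` and `scale_max`
#'   conventions.
#' @param seed Integer seed for the response noise.
#' @param scale_max Response-scale maximum (default 100).
#' @param rt_meanlog,rt_sdlog Log-normal parameters for simulated per-record
#'   response times.
#' @return A `response_table` with `nrow = n_response_slots(design)`.
#' @export
simulate_study <- function(design, truth, pop, seed = 1, scale_max = 100,
                           rt_meanlog = log(6), rt_sdlog = 0.5) {
  persons <- truth$persons
  if (is.null(rownames(persons))) rownames(persons) <- design$persons
  if (!all(design$persons %in% rownames(persons))) {
    stop("truth$persons does not cover all design persons")
  }
  set.seed(seed)
  fa <- design$format_assignment
  items <- design$items
  fa$trait <- items$trait[match(fa$item_id, items$item_id)]
  grid <- do.call(rbind, lapply(seq_len(design$n_occasions), function(o) {
    g <- fa; g$occasion <- o; g
  }))
  n <- nrow(grid)
  occ_items <- function(kind, occ_vec) {
    # item-parameter table effective at each record's occasion
    base <- truth$items[[kind]]
    out <- base[match(grid$item_id, base$item_id), , drop = FALSE]
    if (!is.null(truth$items_t2)) {
      alt <- truth$items_t2[[kind]]
      late <- occ_vec > 1L
      out[late, ] <- alt[match(grid$item_id[late], alt$item_id), , drop = FALSE]
    }
    out
  }
  dim_of <- function(par) paste0(par, "_", grid$trait, "_t", grid$occasion)
  pidx <- match(grid$person_id, rownames(persons))

  value_low <- value_high <- numeric(n)
  is_vas <- grid$format == "VAS"

  if (any(is_vas)) {
    ib <- occ_items("brm", grid$occasion)[is_vas, ]
    theta <- persons[cbind(pidx[is_vas],
                           match(dim_of("thetaV")[is_vas], colnames(persons)))]
    mu <- plogis(ib$alpha * (theta - ib$delta))
    x <- rbeta(sum(is_vas), mu * ib$tau, (1 - mu) * ib$tau)
    value_low[is_vas] <- value_high[is_vas] <- x * scale_max
  }
  if (any(!is_vas)) {
    idr <- which(!is_vas)
    id_ <- occ_items("ddrm", grid$occasion)[idr, ]
    theta <- persons[cbind(pidx[idr],
                           match(dim_of("thetaD")[idr], colnames(persons)))]
    eta <- persons[cbind(pidx[idr],
                         match(dim_of("etaD")[idr], colnames(persons)))]
    m <- ddrm_mean(theta, eta,
                   list(alpha_loc = id_$alpha_loc, delta_loc = id_$delta_loc,
                        alpha_wid = id_$alpha_wid, delta_wid = id_$delta_wid))
    a <- m * id_$tau
    g1 <- rgamma(length(idr), a[, 1]); g2 <- rgamma(length(idr), a[, 2])
    g3 <- rgamma(length(idr), a[, 3])
    tot <- g1 + g2 + g3
    value_low[idr] <- g1 / tot * scale_max
    value_high[idr] <- (g1 + g2) / tot * scale_max
  }
  if (isTRUE(pop$rounding)) {
    value_low <- round(value_low); value_high <- round(value_high)
  }
  # emit reverse-coded items reflected, flag set
  rev <- grid$item_id %in% design$reverse_coded_items
  if (any(rev)) {
    lo <- value_low[rev]; hi <- value_high[rev]
    value_low[rev] <- scale_max - hi
    value_high[rev] <- scale_max - lo
  }
  bo <- design$block_order
  bkey <- match(paste(grid$person_id, grid$occasion),
                paste(bo$person_id, bo$occasion))
  df <- data.frame(
    person_id = grid$person_id, item_id = grid$item_id, trait = grid$trait,
    occasion = grid$occasion, format = grid$format,
    value_low = value_low, value_high = value_high,
    reverse_coded = rev, block_order = bo$block_order[bkey],
    response_time_s = rlnorm(n, rt_meanlog, rt_sdlog),
    serious = TRUE, stringsAsFactors = FALSE)
  response_table(df, scale_max = scale_max, allow_duplicates = FALSE)
}

#' One-call synthetic data set
#'
#' Convenience wrapper: design, truth, and responses from three seeds derived
#' from one.
#'
#' @inheritParams make_design
#' @param pop A [population_config()]; default [reference_population()].
#' @param seed Master seed.
#' @return List with `design`, `truth`, `table`.
#' @export
simulate_dataset <- function(n_persons = 224, items_per_trait = 42,
                             n_occasions = 2, traits = c("E", "C"),
                             pop = reference_population(), seed = 1,
                             reverse_coded_items = character()) {
  design <- make_design(n_persons, items_per_trait, n_occasions, traits,
                        seed = seed, reverse_coded_items = reverse_coded_items)
  truth <- draw_truth(design, pop, seed = seed + 1L)
  table <- simulate_study(design, truth, pop, seed = seed + 2L)
  list(design = design, truth = truth, table = table)
}
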