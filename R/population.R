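#' Labels for the joint person-parameter vector
#'
#' The joint model stacks, per measurement occasion and per trait, the three
#' person parameters: VAS location `thetaV`, DRS location `thetaD`, and DRS
#' width `etaD`. With two traits and two occasions this yields the
#' 12-dimensional vector
#' `(thetaV_E_t1, thetaD_E_t1, etaD_E_t1, thetaV_C_t1, ..., etaD_C_t2)`.
#'
#' @param traits Character vector of trait labels.
#' @param n_occasions Number of occasions.
#' @param params Which person parameters each trait/occasion contributes
#'   (default all three).
#' @return Character vector of dimension labels, occasion-major.
#' @export
person_dims <- function(traits = c("E", "C"), n_occasions = 2,
                        params = c("thetaV", "thetaD", "etaD")) {
  as.vector(vapply(seq_len(n_occasions), function(o)
    vapply(traits, function(tr) paste0(params, "_", tr, "_t", o),
           character(length(params))),
    character(length(params) * length(traits))))
}

#' Population configuration for the synthetic-data generator
#'
#' Describes the multivariate normal distribution of the stacked person
#' parameters: means `mu` (first-occasion entries fixed at 0 for
#' identification), standard deviations `sigma` (first-occasion entries fixed
#' at 1), and a correlation matrix `R`. Also carries the item-parameter prior
#' used by [draw_items()] and a rounding flag for discretized sliders.
#'
#' @param R Correlation matrix (symmetric, unit diagonal, positive definite);
#'   dimension must match `length(mu)`.
#' @param mu,sigma Mean and SD vectors; entries for occasion 1 must be 0
#'   and 1.
#' @param traits,n_occasions Design labels used to name dimensions.
#' @param item_prior Named list of item-prior hyperparameters (see
#'   [item_prior_defaults()]).
#' @param rounding Round simulated raw values to integers (default `FALSE`;
#'   the measurement models are continuous).
#' @return A `population_config` list.
#' @export
population_config <- function(R, mu = NULL, sigma = NULL,
                              traits = c("E", "C"), n_occasions = 2,
                              item_prior = item_prior_defaults(),
                              rounding = FALSE) {
  dims <- person_dims(traits, n_occasions)
  d <- length(dims)
  stopifnot(is.matrix(R), nrow(R) == d, ncol(R) == d)
  if (max(abs(R - t(R))) > 1e-10) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10) stop("R must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("R is not positive definite (smallest eigenvalue %.3e)", min(ev)))
  }
  if (is.null(mu)) mu <- rep(0, d)
  if (is.null(sigma)) sigma <- rep(1, d)
  first <- seq_len(d / n_occasions)   # occasion-1 block
  if (any(mu[first] != 0)) stop("occasion-1 means must be fixed at 0")
  if (any(sigma[first] != 1)) stop("occasion-1 SDs must be fixed at 1")
  if (any(sigma <= 0)) stop("sigma must be positive")
  dimnames(R) <- list(dims, dims)
  names(mu) <- names(sigma) <- dims
  structure(list(mu = mu, sigma = sigma, R = R, traits = traits,
                 n_occasions = n_occasions, item_prior = item_prior,
                 rounding = rounding),
            class = "population_config")
}

#' Default item-parameter prior for the generator
#'
#' Scalings are log-normal around 1; difficulties are normal, centered so
#' that average responses land in the realistic upper-middle part of the
#' scale (VAS/DRS-location means around 55-67 of 100) and average interval
#' widths around 30 of 100; precisions are log-normal around 10, giving
#' slider noise of realistic magnitude.
#'
#' @return Named list of hyperparameters.
#' @export
item_prior_defaults <- function() {
  list(alpha_meanlog = 0, alpha_sdlog = 0.3,
       delta_mean = -0.4, delta_sd = 0.75,
       delta_wid_mean = 0.8, delta_wid_sd = 0.75,
       tau_meanlog = log(10), tau_sdlog = 0.3)
}

# fill unspecified correlation cells by transitive closure: repeatedly set
# r_ij to the largest-|.| available product r_ik * r_kj. Keeps a matrix with
# strong specified cells (e.g. cross-trait width .94 plus test-retest .81)
# nearly consistent, unlike a zero fill.
.fill_correlations <- function(R) {
  d <- nrow(R)
  for (pass in 1:d) {
    na_idx <- which(is.na(R) & upper.tri(R), arr.ind = TRUE)
    if (!nrow(na_idx)) break
    for (r in seq_len(nrow(na_idx))) {
      i <- na_idx[r, 1]; j <- na_idx[r, 2]
      cand <- R[i, ] * R[, j]
      cand[c(i, j)] <- NA
      if (all(is.na(cand))) next
      best <- which.max(abs(cand))
      R[i, j] <- R[j, i] <- cand[best]
    }
  }
  R[is.na(R)] <- 0
  R
}

#' Project a symmetric matrix to the nearest positive-definite correlation matrix
#'
#' Eigenvalue clipping: eigenvalues below `tol` are raised to `tol`, the
#' matrix is reassembled and rescaled to unit diagonal. Deterministic and
#' idempotent on matrices that are already valid.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param tol Smallest admissible eigenvalue (default 1e-8).
#' @return A positive-definite correlation matrix.
#' @export
nearest_correlation <- function(R, tol = 1e-8) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, tol)
  S <- e$vectors %*% diag(lam) %*% t(e$vectors)
  D <- 1 / sqrt(diag(S))
  out <- S * tcrossprod(D)
  diag(out) <- 1
  dimnames(out) <- dimnames(R)
  (out + t(out)) / 2
}

#' Reference population with published-magnitude correlations
#'
#' Builds a 12 x 12 correlation matrix whose specified cells reproduce the
#' posterior-median correlations reported for the two-trait (Extraversion,
#' Conscientiousness), two-format, two-occasion slider study: test-retest
#' correlations (`thetaV` .89/.90, `thetaD` .92/.87, `etaD` .81/.73),
#' convergent VAS-DRS location correlations (.93/.96/.88/.90), DRS
#' location-width correlations (.00/-.01/-.11/-.05), and cross-trait
#' correlations (`thetaV` .38/.34, `thetaD` .30/.31, `etaD` .94/.96).
#' Unspecified cells are completed either by transitive path products
#' (default) or with zeros, and the result is projected to the nearest
#' positive-definite correlation matrix.
#'
#' @param fill `"path"` (default) or `"zero"`; see Details. With `"zero"` the
#'   projection must repair severe indefiniteness and the specified cells are
#'   no longer reproduced closely, which is why `"path"` is the default.
#' @param tol Eigenvalue floor for the projection.
#' @return A `population_config` whose `R` carries attribute `specified`, a
#'   data frame of the specified cells (row, col, target value) for use as
#'   exact truths in recovery studies.
#' @export
reference_population <- function(fill = c("path", "zero"), tol = 1e-8) {
  fill <- match.arg(fill)
  dims <- person_dims()
  d <- length(dims)
  R <- matrix(NA_real_, d, d, dimnames = list(dims, dims))
  diag(R) <- 1
  set_cell <- function(a, b, v) R[a, b] <<- R[b, a] <<- v
  # test-retest (same parameter, T1-T2)
  set_cell("thetaV_E_t1", "thetaV_E_t2", .89)
  set_cell("thetaV_C_t1", "thetaV_C_t2", .90)
  set_cell("thetaD_E_t1", "thetaD_E_t2", .92)
  set_cell("thetaD_C_t1", "thetaD_C_t2", .87)
  set_cell("etaD_E_t1",   "etaD_E_t2",   .81)
  set_cell("etaD_C_t1",   "etaD_C_t2",   .73)
  # convergent validity (VAS vs DRS location, same trait and occasion)
  set_cell("thetaV_E_t1", "thetaD_E_t1", .93)
  set_cell("thetaV_E_t2", "thetaD_E_t2", .96)
  set_cell("thetaV_C_t1", "thetaD_C_t1", .88)
  set_cell("thetaV_C_t2", "thetaD_C_t2", .90)
  # DRS location vs width, same trait and occasion
  set_cell("thetaD_E_t1", "etaD_E_t1",  .00)
  set_cell("thetaD_E_t2", "etaD_E_t2", -.01)
  set_cell("thetaD_C_t1", "etaD_C_t1", -.11)
  set_cell("thetaD_C_t2", "etaD_C_t2", -.05)
  # cross-trait (same parameter and occasion)
  set_cell("thetaV_E_t1", "thetaV_C_t1", .38)
  set_cell("thetaV_E_t2", "thetaV_C_t2", .34)
  set_cell("thetaD_E_t1", "thetaD_C_t1", .30)
  set_cell("thetaD_E_t2", "thetaD_C_t2", .31)
  set_cell("etaD_E_t1",   "etaD_C_t1",   .94)
  set_cell("etaD_E_t2",   "etaD_C_t2",   .96)

  spec_idx <- which(!is.na(R) & upper.tri(R), arr.ind = TRUE)
  specified <- data.frame(row = dims[spec_idx[, 1]], col = dims[spec_idx[, 2]],
                          target = R[spec_idx], stringsAsFactors = FALSE)
  filled <- if (fill == "zero") { R0 <- R; R0[is.na(R0)] <- 0; R0 } else .fill_correlations(R)
  Rpd <- nearest_correlation(filled, tol = tol)
  specified$value <- Rpd[cbind(specified$row, specified$col)]
  attr(Rpd, "specified") <- specified
  population_config(R = Rpd)
}
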