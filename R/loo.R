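#' @name psis-loo
#' @title Pareto-smoothed importance-sampling leave-one-out cross-validation
#' @description
#' Implements PSIS-LOO (Vehtari, Gelman & Gabry, 2017): for each observation
#' the importance ratios `1 / p(y_i | theta_s)` are stabilized by fitting a
#' generalized Pareto distribution (Zhang & Stephens, 2009, with the usual
#' weakly informative shape regularization) to the largest ratios and
#' replacing them with expected order statistics, truncated at the raw
#' maximum. Reported are the expected log pointwise predictive density
#' `elpd_loo` with its standard error, the effective number of parameters
#' `p_loo`, and the per-observation Pareto shape diagnostics `k`.
NULL

# Zhang & Stephens (2009) profile-posterior fit of the generalized Pareto
# distribution to exceedances x > 0; returns shape k and scale sigma.
.gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5 || x[n] <= 0) return(c(k = NA_real_, sigma = NA_real_))
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  jhalf <- seq_len(m) - 0.5
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / jhalf)) / (prior_bs * xstar)
  # profile log-likelihood in theta = -shape/scale; k(theta) is the
  # conditional MLE of the shape
  k_j <- vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(-theta / k_j) - k_j - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l_j - l_j[j])), numeric(1))
  th_hat <- sum(theta * w)
  k_hat <- mean(log1p(-th_hat * x))
  c(k = k_hat, sigma = -k_hat / th_hat)
}

.qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# smooth one vector of log importance weights; returns list(lw, k)
.psis_smooth <- function(lw) {
  S <- length(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || diff(range(lw)) < sqrt(.Machine$double.eps)) {
    return(list(lw = lw - .logsumexp(lw), k = -Inf))
  }
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exc <- exp(lw[tail_ids] - cutoff) - 1  # exceedances on the ratio scale
  fit <- .gpd_fit(exc)
  k <- unname(fit["k"])
  if (is.finite(k)) {
    # regularize the shape towards 0.5 (weak prior, as in standard practice)
    k <- (M * k + 5 * 0.5) / (M + 10)
    sigma <- unname(fit["sigma"])
    if (is.finite(sigma) && sigma > 0) {
      p <- (seq_len(M) - 0.5) / M
      smoothed <- cutoff + log1p(.qgpd(p, k, sigma))
      smoothed <- pmin(smoothed, max(lw))
      lw[tail_ids[order(lw[tail_ids])]] <- smoothed
    }
  } else {
    k <- Inf
  }
  list(lw = lw - .logsumexp(lw), k = k)
}

#' Compute PSIS-LOO for a fitted model
#'
#' @param x A `drs_fit` fitted with `store_loglik = TRUE`, or an
#'   `S x n_obs` matrix of pointwise log-likelihood draws.
#' @return A `loo_result` list: `elpd_loo`, `se`, `p_loo`, `pointwise` (data
#'   frame with `elpd_i`, `lpd_i`, `k`), `n_obs`, `n_draws`, and
#'   `n_bad_k` (shape estimates above 0.7).
#' @export
compute_loo <- function(x) {
  ll <- if (inherits(x, "drs_fit")) pointwise_loglik(x) else as.matrix(x)
  S <- nrow(ll); n <- ncol(ll)
  if (!S || !n) stop("empty log-likelihood matrix")
  elpd_i <- lpd_i <- kv <- numeric(n)
  for (i in seq_len(n)) {
    lli <- ll[, i]
    sm <- .psis_smooth(-lli)
    elpd_i[i] <- .logsumexp(sm$lw + lli)
    lpd_i[i] <- .logsumexp(lli) - log(S)
    kv[i] <- sm$k
  }
  structure(list(elpd_loo = sum(elpd_i),
                 se = sqrt(n * var(elpd_i)),
                 p_loo = sum(lpd_i - elpd_i),
                 pointwise = data.frame(elpd_i = elpd_i, lpd_i = lpd_i, k = kv),
                 n_obs = n, n_draws = S,
                 n_bad_k = sum(is.finite(kv) & kv > 0.7)),
            class = "loo_result")
}

#' Difference in elpd_loo between two models on the same observations
#'
#' The standard error is computed from the pointwise elpd difference vector,
#' not from the marginal standard errors.
#'
#' @param a,b `loo_result` objects for the same data (same observations in
#'   the same order).
#' @return List with `delta_elpd` (`a` minus `b`) and `se`.
#' @export
elpd_diff <- function(a, b) {
  stopifnot(inherits(a, "loo_result"), inherits(b, "loo_result"))
  if (a$n_obs != b$n_obs) stop("models were scored on different observation counts")
  d <- a$pointwise$elpd_i - b$pointwise$elpd_i
  list(delta_elpd = sum(d), se = sqrt(length(d) * var(d)))
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("elpd_loo %.2f (SE %.2f), p_loo %.1f, %d observations, %d draws\n",
              x$elpd_loo, x$se, x$p_loo, x$n_obs, x$n_draws))
  if (x$n_bad_k > 0) {
    cat("  warning:", x$n_bad_k, "observation(s) with Pareto k > 0.7\n")
  }
  invisible(x)
}
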