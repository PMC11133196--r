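#' @name convergence-diagnostics
#' @title Rank-normalized split-R-hat and effective sample sizes
#' @description
#' Implementations of the rank-normalized split-\eqn{\hat R} and bulk/tail
#' effective sample size diagnostics of Vehtari, Gelman, Simpson, Carpenter &
#' Bürkner (2021). Draws are supplied as an `iterations x chains` matrix;
#' each chain is split in half, draws are rank-normalized via the inverse
#' normal transform, and the classic between/within variance ratio is
#' computed. `rhat()` reports the maximum of the bulk and the folded
#' (median-absolute-deviation) statistic; `ess_bulk()` uses Geyer's initial
#' monotone sequence on rank-normalized draws; `ess_tail()` is the smaller of
#' the effective sample sizes of the 5% and 95% quantile indicators.
NULL

.split_chains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

.rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  array(z, dim = dim(x))
}

.rhat_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (n < 2L) return(NA_real_)
  means <- colMeans(x)
  vars <- apply(x, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W == 0) {
    # constant chains: identical -> converged; different -> blown up
    return(if (B == 0 || !is.finite(B)) 1 else Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @rdname convergence-diagnostics
#' @param x Numeric matrix of posterior draws, `iterations x chains`
#'   (>= 2 chains).
#' @return `rhat()`: scalar potential-scale-reduction estimate;
#'   `ess_bulk()`/`ess_tail()`: scalar effective sample sizes.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("rhat requires at least two chains")
  xs <- .split_chains(x)
  if (all(!is.finite(xs)) || diff(range(xs)) == 0) return(1)
  bulk <- .rhat_basic(.rank_normalize(xs))
  folded <- .rhat_basic(.rank_normalize(abs(xs - median(xs))))
  max(bulk, folded)
}

.acov_fft <- function(v) {
  n <- length(v)
  v <- v - mean(v)
  m <- 2^ceiling(log2(2 * n))
  f <- fft(c(v, rep(0, m - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (m)
  ac / n  # biased autocovariance (divides by n)
}

.ess_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) return(NA_real_)
  if (diff(range(x)) == 0) return(NA_real_)
  acov <- vapply(seq_len(m), function(j) .acov_fft(x[, j]), numeric(n))
  chain_var <- acov[1, ] * n / (n - 1)
  W <- mean(chain_var)
  var_plus <- W * (n - 1) / n
  if (m > 1L) var_plus <- var_plus + var(colMeans(x))
  if (var_plus == 0) return(NA_real_)
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # Geyer initial positive + monotone sequence over pairs
  max_t <- floor((n - 2) / 2)
  tau <- 0; prev <- Inf
  for (t in 0:max_t) {
    p <- rho[2 * t + 1] + rho[2 * t + 2]
    if (p <= 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + p
  }
  tau <- max(2 * tau - 1, 1 / log10(n * m + 10))
  min(n * m / tau, n * m * log10(n * m))
}

#' @rdname convergence-diagnostics
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  xs <- .split_chains(x)
  .ess_basic(.rank_normalize(xs))
}

#' @rdname convergence-diagnostics
#' @export
ess_tail <- function(x) {
  x <- as.matrix(x)
  xs <- .split_chains(x)
  ess_q <- function(p) {
    ind <- (xs <= quantile(xs, p)) + 0
    .ess_basic(.rank_normalize(ind))
  }
  min(ess_q(0.05), ess_q(0.95))
}

#' Convergence diagnostics for a fitted model
#'
#' Computes rank-normalized split-\eqn{\hat R}, bulk ESS, and tail ESS for
#' every scalar parameter of a `drs_fit` (population means/SDs, all
#' correlations, item parameters, and person parameters on the unconstrained
#' scale), and checks them against the conventional thresholds
#' \eqn{\hat R < 1.01} and ESS \eqn{\ge 400}.
#'
#' @param fit A `drs_fit` with at least two chains.
#' @param rhat_max,ess_min Pass thresholds.
#' @param include_persons Include per-person latent parameters (the bulk of
#'   the parameter count).
#' @return A `fit_diagnostics` list: `summary` (per-parameter data frame),
#'   `pass`, `n_divergent`, thresholds.
#' @export
diagnose <- function(fit, rhat_max = 1.01, ess_min = 400,
                     include_persons = TRUE) {
  if (dim(fit$draws)[2] < 2L) {
    stop("diagnostics require at least two chains")
  }
  lay <- fit$layout; o <- lay$offsets; s <- lay$sizes
  sel <- unlist(lapply(names(s)[s > 0], function(nm) {
    if (nm == "z" && !include_persons) return(integer())
    o[nm] + seq_len(s[nm])
  }))
  labels <- .par_labels(lay)[sel]
  stats <- vapply(sel, function(k) {
    m <- fit$draws[, , k]
    c(rhat(m), ess_bulk(m), ess_tail(m))
  }, numeric(3))
  summ <- data.frame(parameter = labels, rhat = stats[1, ],
                     ess_bulk = stats[2, ], ess_tail = stats[3, ],
                     stringsAsFactors = FALSE)
  ok <- is.finite(summ$rhat) & summ$rhat < rhat_max &
    summ$ess_bulk >= ess_min & summ$ess_tail >= ess_min
  structure(list(summary = summ, pass = all(ok),
                 n_failing = sum(!ok), n_divergent = sum(fit$sampler$divergences),
                 rhat_max = rhat_max, ess_min = ess_min,
                 worst_rhat = max(summ$rhat, na.rm = TRUE),
                 min_ess_bulk = min(summ$ess_bulk, na.rm = TRUE),
                 min_ess_tail = min(summ$ess_tail, na.rm = TRUE)),
            class = "fit_diagnostics")
}

.par_labels <- function(lay) {
  meta <- lay$meta
  z_lab <- as.vector(outer(meta$dims, meta$persons,
                           function(d, p) paste0("z[", p, ",", d, "]")))
  y_lab <- paste0("corr_y[", seq_len(lay$M), "]")
  free_dims <- meta$dims[meta$free + 1L]
  c(z_lab, y_lab,
    if (lay$sizes["mu"] > 0) paste0("mu[", free_dims, "]"),
    if (lay$sizes["sig"] > 0) paste0("log_sigma[", free_dims, "]"),
    paste0("brm_log_alpha[", meta$brm_keys$alpha, "]"),
    paste0("brm_delta[", meta$brm_keys$delta, "]"),
    paste0("brm_log_tau[", meta$brm_keys$tau, "]"),
    paste0("ddrm_log_alpha_loc[", meta$ddrm_keys$alpha_loc, "]"),
    paste0("ddrm_delta_loc[", meta$ddrm_keys$delta_loc, "]"),
    paste0("ddrm_log_alpha_wid[", meta$ddrm_keys$alpha_wid, "]"),
    paste0("ddrm_delta_wid[", meta$ddrm_keys$delta_wid, "]"),
    paste0("ddrm_log_tau[", meta$ddrm_keys$tau, "]"))
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat("Convergence diagnostics over", nrow(x$summary), "parameters\n")
  cat(sprintf("  worst R-hat %.4f (threshold %.3f)\n", x$worst_rhat, x$rhat_max))
  cat(sprintf("  min bulk ESS %.0f, min tail ESS %.0f (floor %d)\n",
              x$min_ess_bulk, x$min_ess_tail, x$ess_min))
  cat("  divergences:", x$n_divergent, "\n")
  cat("  overall:", if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}
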