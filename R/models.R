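#' Item parameters for the beta response model (BRM)
#'
#' The BRM describes a single-slider composition `(x, 1 - x)` with a beta
#' distribution whose mean is a logistic function of the person's location
#' parameter: `mu = plogis(alpha * (theta - delta))`. `alpha > 0` is the
#' item's scaling (discrimination, akin to a loading), `delta` its difficulty
#' (akin to an intercept), and `tau > 0` its precision (inverse residual
#' dispersion): the response follows `Beta(mu * tau, (1 - mu) * tau)`.
#'
#' @param alpha,delta,tau Numeric scalars (or equal-length vectors for several
#'   items); `alpha > 0`, `tau > 0`.
#' @return A `brm_items` data frame with columns `alpha`, `delta`, `tau`.
#' @export
brm_item_params <- function(alpha, delta, tau) {
  stopifnot(all(alpha > 0), all(tau > 0),
            length(delta) == length(alpha), length(tau) == length(alpha))
  structure(data.frame(alpha = alpha, delta = delta, tau = tau),
            class = c("brm_items", "data.frame"))
}

#' Item parameters for the Dirichlet dual-response model (DDRM)
#'
#' The DDRM has two logistic submodels: location
#' `mu = plogis(alpha_loc * (theta - delta_loc))` and width
#' `omega = plogis(alpha_wid * (eta - delta_wid))`, combined into expected
#' composition `(mu * (1 - omega), omega, (1 - mu) * (1 - omega))` and scaled
#' by a single item precision `tau` into Dirichlet shape parameters.
#'
#' @param alpha_loc,delta_loc Scaling and difficulty of the location submodel.
#' @param alpha_wid,delta_wid Scaling and difficulty of the width submodel.
#' @param tau Item precision, shared across the three components.
#' @return A `ddrm_items` data frame.
#' @export
ddrm_item_params <- function(alpha_loc, delta_loc, alpha_wid, delta_wid, tau) {
  stopifnot(all(alpha_loc > 0), all(alpha_wid > 0), all(tau > 0))
  structure(data.frame(alpha_loc = alpha_loc, delta_loc = delta_loc,
                       alpha_wid = alpha_wid, delta_wid = delta_wid, tau = tau),
            class = c("ddrm_items", "data.frame"))
}

#' Expected VAS response proportion under the BRM
#'
#' @param theta Person location parameter(s).
#' @param item A single-row [brm_item_params()] object or list with `alpha`,
#'   `delta`.
#' @return `plogis(alpha * (theta - delta))`, strictly increasing in `theta`.
#' @export
brm_mean <- function(theta, item) {
  plogis(item$alpha * (theta - item$delta))
}

#' BRM log-density of a compressed VAS proportion
#'
#' Log of the `Beta(mu * tau, (1 - mu) * tau)` density at `x`, with
#' `mu = brm_mean(theta, item)`, so that `E[x] = mu`.
#'
#' @param x Response proportion strictly in (0, 1); boundary values must be
#'   compressed first (see [compress()]).
#' @inheritParams brm_mean
#' @return Log-density value(s).
#' @export
brm_logpdf <- function(x, theta, item) {
  if (any(x <= 0 | x >= 1)) {
    stop("x must be strictly inside (0, 1); compress() boundary responses first")
  }
  mu <- brm_mean(theta, item)
  dbeta(x, mu * item$tau, (1 - mu) * item$tau, log = TRUE)
}

#' Expected DRS composition under the DDRM
#'
#' With location `mu = plogis(alpha_loc * (theta - delta_loc))` and width
#' `omega = plogis(alpha_wid * (eta - delta_wid))`, the expected composition
#' is `(mu * (1 - omega), omega, (1 - mu) * (1 - omega))`. The expected
#' interval midpoint `mu * (1 - omega) + omega / 2` increases in `theta`, the
#' expected width `omega` increases in `eta`, and as `omega` grows the
#' expected midpoint is squeezed towards the scale center — the structural
#' negative location-width dependency of interval responses.
#'
#' @param theta Person location parameter(s).
#' @param eta Person width (intra-individual variability) parameter(s).
#' @param item A single-row [ddrm_item_params()] object.
#' @return Matrix with columns `lower`, `width`, `upper`, rows summing to 1.
#' @export
ddrm_mean <- function(theta, eta, item) {
  mu    <- plogis(item$alpha_loc * (theta - item$delta_loc))
  omega <- plogis(item$alpha_wid * (eta - item$delta_wid))
  cbind(lower = mu * (1 - omega), width = omega, upper = (1 - mu) * (1 - omega))
}

#' DDRM log-density of a compressed DRS composition
#'
#' Log Dirichlet density at `x` with shape vector
#' `ddrm_mean(theta, eta, item) * tau`, so `E[x]` equals the model mean.
#'
#' @param x Numeric length-3 vector or 3-column matrix, strictly interior,
#'   rows summing to 1.
#' @inheritParams ddrm_mean
#' @return Log-density value(s).
#' @export
ddrm_logpdf <- function(x, theta, eta, item) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 3L)
  if (any(x <= 0)) {
    stop("all components must be strictly positive; compress() boundary responses first")
  }
  a <- ddrm_mean(theta, eta, item) * item$tau
  if (nrow(a) == 1L && nrow(x) > 1L) a <- a[rep(1L, nrow(x)), , drop = FALSE]
  rowSums((a - 1) * log(x)) + lgamma(rowSums(a)) - rowSums(lgamma(a))
}
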