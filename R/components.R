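#' Decompose a single-slider (VAS) response into a two-part composition
#'
#' A VAS response at `value` on a scale from 0 to `scale_max` splits the
#' response line into a lower segment (left of the slider) and an upper
#' segment (right of the slider). Expressed as proportions of the scale the
#' two segments are non-negative and sum to one. Boundary responses (0 or
#' `scale_max`) yield zero components and must be pushed into the interior
#' with [compress()] before a density is evaluated.
#'
#' @param value Numeric vector of slider values in `[0, scale_max]`.
#' @param scale_max Upper end of the response scale (default 100).
#' @return A matrix with columns `lower`, `upper`; rows sum to 1.
#' @seealso [drs_components()], [compress()]
#' @examples
#' vas_components(65)            # 0.65, 0.35
#' @export
vas_components <- function(value, scale_max = 100) {
  stopifnot(is.numeric(value), length(scale_max) == 1L, scale_max > 0)
  if (any(value < 0 | value > scale_max, na.rm = TRUE)) {
    stop("VAS value outside [0, ", scale_max, "]")
  }
  p <- value / scale_max
  cbind(lower = p, upper = 1 - p)
}

#' Decompose a dual-range-slider (DRS) response into a three-part composition
#'
#' An interval response `[low, high]` splits the response line into a lower
#' segment (left of the lower bound), a middle segment (the interval width),
#' and an upper segment (right of the upper bound). The interval midpoint
#' `(low + high) / 2` (the "DRS location") and the width `high - low` are
#' recoverable from the composition. Zero components (bounds touching the
#' scale ends, or zero-width intervals) require [compress()] before density
#' evaluation.
#'
#' @param low,high Numeric vectors of interval bounds, `0 <= low <= high <=
#'   scale_max`.
#' @inheritParams vas_components
#' @return A matrix with columns `lower`, `width`, `upper`; rows sum to 1.
#' @examples
#' drs_components(40, 90)        # 0.40, 0.50, 0.10
#' @export
drs_components <- function(low, high, scale_max = 100) {
  stopifnot(is.numeric(low), is.numeric(high), scale_max > 0)
  if (any(low > high, na.rm = TRUE)) stop("DRS lower bound exceeds upper bound")
  if (any(low < 0 | high > scale_max, na.rm = TRUE)) {
    stop("DRS bounds outside [0, ", scale_max, "]")
  }
  cbind(lower = low / scale_max,
        width = (high - low) / scale_max,
        upper = (scale_max - high) / scale_max)
}

#' Compress a composition away from the boundary of the simplex
#'
#' Slider responses at the scale ends (or zero-width intervals) produce
#' compositions with zero components, where beta/Dirichlet densities are not
#' defined. The standard remedy shrinks every composition towards the
#' barycenter: `x' = (x * (n - 1) + 1/K) / n`, with `n` the number of
#' observations in the data set and `K` the number of components. The output
#' is strictly inside the simplex and still sums to one.
#'
#' @param components Numeric vector or matrix (rows are compositions) summing
#'   to 1.
#' @param n Compression sample size, `n >= 2`; conventionally the total
#'   number of response records in the data set.
#' @param K Number of components; defaults to the composition length.
#' @return Object of the same shape, strictly in (0, 1).
#' @examples
#' compress(c(0, 1), n = 100)    # 0.005, 0.995
#' @export
compress <- function(components, n, K = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 2) stop("compression requires n >= 2")
  if (is.matrix(components)) {
    if (is.null(K)) K <- ncol(components)
  } else if (is.null(K)) K <- length(components)
  (components * (n - 1) + 1 / K) / n
}
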