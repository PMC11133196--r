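#' Highest density interval of a sample
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' samples; ties are broken in favor of the leftmost window.
#'
#' @param samples Numeric vector (>= 2 values).
#' @param mass Probability mass to cover (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2L) stop("hdi requires at least two samples")
  stopifnot(mass > 0, mass < 1)
  s <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = s[1], upper = s[n]))
  widths <- s[m:n] - s[seq_len(n - m + 1)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + m - 1])
}

#' Canonical research-question correlation pairs
#'
#' The three families of correlations of the multitrait-multimethod design:
#' test-retest reliability (same parameter across occasions), convergent
#' validity (VAS vs DRS location, plus DRS location vs width, within trait
#' and occasion), and discriminant validity (same parameter across traits,
#' within occasion).
#'
#' @param traits Pair of trait labels.
#' @param occasions Occasion numbers.
#' @return Data frame with columns `family`, `a`, `b`.
#' @export
rq_correlation_pairs <- function(traits = c("E", "C"), occasions = 1:2) {
  lab <- function(p, tr, o) paste0(p, "_", tr, "_t", o)
  out <- list()
  for (tr in traits) for (p in c("thetaV", "thetaD", "etaD")) {
    out[[length(out) + 1L]] <- data.frame(
      family = "test_retest", a = lab(p, tr, occasions[1]),
      b = lab(p, tr, occasions[2]))
  }
  for (tr in traits) for (o in occasions) {
    out[[length(out) + 1L]] <- data.frame(
      family = "convergent", a = lab("thetaV", tr, o), b = lab("thetaD", tr, o))
    out[[length(out) + 1L]] <- data.frame(
      family = "location_width", a = lab("thetaD", tr, o), b = lab("etaD", tr, o))
  }
  for (p in c("thetaV", "thetaD", "etaD")) for (o in occasions) {
    out[[length(out) + 1L]] <- data.frame(
      family = "discriminant", a = lab(p, traits[1], o), b = lab(p, traits[2], o))
  }
  do.call(rbind, out)
}

#' Posterior summaries of person-parameter correlations
#'
#' For each requested pair: posterior median, highest-density interval, and
#' the fraction of posterior mass below a reliability threshold (default
#' 0.70).
#'
#' @param fit A `drs_fit`.
#' @param pairs Data frame with columns `a`, `b` (dimension labels; see
#'   `fit$dims`), optionally `family`; defaults to [rq_correlation_pairs()]
#'   restricted to pairs available in the fit.
#' @param threshold Reliability threshold for `prob_below`.
#' @param mass HDI mass.
#' @return Data frame with `median`, `hdi_low`, `hdi_high`, `prob_below`.
#' @export
summarize_correlations <- function(fit, pairs = NULL, threshold = 0.70,
                                   mass = 0.95) {
  if (is.null(pairs)) {
    pairs <- rq_correlation_pairs(fit$traits,
                                  fit$layout$meta$occasions)
    pairs <- pairs[pairs$a %in% fit$dims & pairs$b %in% fit$dims, ]
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    d <- correlation_pair_draws(fit, pairs$a[i], pairs$b[i])
    h <- hdi(d, mass)
    data.frame(a = pairs$a[i], b = pairs$b[i],
               family = if ("family" %in% names(pairs)) pairs$family[i] else NA,
               median = median(d), hdi_low = h[["lower"]],
               hdi_high = h[["upper"]], prob_below = mean(d < threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cross-lagged panel model from posterior correlation draws
#'
#' Given posterior draws of the 4 x 4 correlation matrix of the
#' intra-individual variability scores (trait 1 and trait 2 at occasions 1
#' and 2, in the order T1-trait1, T1-trait2, T2-trait1, T2-trait2), computes
#' for every draw the closed-form standardized regressions of each T2 score
#' on both T1 scores: coefficients `beta = Rxx^{-1} rxy`, full explained
#' variance `R2_full = rxy' Rxx^{-1} rxy`, the simple variance explained by
#' the *other* trait alone (`r2_other`), the increment
#' `delta_r2 = R2_full - r2_other` attributable to the same trait, and the
#' correlation of the two T2 residuals. Summaries are posterior medians with
#' HDIs. Singular predictor blocks are skipped and counted.
#'
#' @param R4_draws Array `S x 4 x 4` of correlation-matrix draws (e.g.
#'   `correlation_draws(fit)` subset to the four `etaD` dimensions).
#' @param labels Length-2 labels for the traits (for output naming).
#' @param mass HDI mass.
#' @return A `clpm_result`: `summary` data frame (rows `beta11`, `beta21`,
#'   `beta22`, `beta12`, `rho_residual`, `r2_*`, `r2_other_*`,
#'   `delta_r2_*`), `draws` matrix, `n_skipped`.
#' @export
clpm_from_correlation <- function(R4_draws, labels = c("E", "C"), mass = 0.95) {
  S <- dim(R4_draws)[1]
  stopifnot(dim(R4_draws)[2] == 4, dim(R4_draws)[3] == 4)
  cols <- c("beta11", "beta21", "beta22", "beta12", "rho_residual",
            paste0("r2_full_", labels), paste0("r2_other_", labels),
            paste0("delta_r2_", labels))
  draws <- matrix(NA_real_, S, length(cols), dimnames = list(NULL, cols))
  skipped <- 0L
  for (s in seq_len(S)) {
    R <- R4_draws[s, , ]
    if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8) {
      stop("draw ", s, " is not a correlation matrix")
    }
    Rxx <- R[1:2, 1:2]; Rxy <- R[1:2, 3:4]; Ryy <- R[3:4, 3:4]
    det_xx <- Rxx[1, 1] * Rxx[2, 2] - Rxx[1, 2]^2
    if (abs(det_xx) < 1e-12) { skipped <- skipped + 1L; next }
    B <- solve(Rxx, Rxy)                    # column j: coefs for outcome j
    r2_full <- diag(t(Rxy) %*% B)
    r2_other <- c(R[2, 3]^2, R[1, 4]^2)     # other-trait simple regressions
    res_cov <- Ryy - t(B) %*% Rxx %*% B
    dr <- sqrt(diag(res_cov))
    rho_res <- if (all(dr > 0)) res_cov[1, 2] / (dr[1] * dr[2]) else NA_real_
    draws[s, ] <- c(B[1, 1], B[2, 1], B[2, 2], B[1, 2], rho_res,
                    r2_full, r2_other, r2_full - r2_other)
  }
  ok <- stats::complete.cases(draws)
  summ <- do.call(rbind, lapply(cols, function(cc) {
    v <- draws[ok, cc]
    h <- hdi(v, mass)
    data.frame(parameter = cc, median = median(v),
               hdi_low = h[["lower"]], hdi_high = h[["upper"]],
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, draws = draws, n_skipped = skipped,
                 labels = labels),
            class = "clpm_result")
}

#' @export
print.clpm_result <- function(x, ...) {
  cat("Cross-lagged panel model (computed per posterior draw)\n")
  print(transform(x$summary, median = round(median, 3),
                  hdi_low = round(hdi_low, 3), hdi_high = round(hdi_high, 3)))
  if (x$n_skipped) cat("skipped", x$n_skipped, "singular draw(s)\n")
  invisible(x)
}

#' Descriptive statistics of slider responses
#'
#' Per trait and occasion: responses are first averaged within each
#' respondent, then the mean and SD across respondents are reported, for the
#' VAS value, the DRS location (interval midpoint), the DRS width, and the
#' DRS lower/upper bounds. Reverse coding must already be applied.
#'
#' @param table A `response_table`.
#' @return Data frame with one row per trait x occasion.
#' @export
descriptive_table <- function(table) {
  df <- as.data.frame(table)
  groups <- unique(df[, c("trait", "occasion")])
  groups <- groups[order(groups$trait, groups$occasion), ]
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    sub <- df[df$trait == groups$trait[g] & df$occasion == groups$occasion[g], ]
    vas <- sub[sub$format == "VAS", ]
    drs <- sub[sub$format == "DRS", ]
    pmean <- function(d, v) if (nrow(d)) tapply(v, d$person_id, mean) else numeric()
    ms <- function(x) c(mean = if (length(x)) mean(x) else NA_real_,
                        sd = if (length(x) > 1) sd(x) else if (length(x)) 0 else NA_real_)
    v <- ms(pmean(vas, vas$value_low))
    loc <- ms(pmean(drs, (drs$value_low + drs$value_high) / 2))
    wid <- ms(pmean(drs, drs$value_high - drs$value_low))
    lb <- ms(pmean(drs, drs$value_low))
    ub <- ms(pmean(drs, drs$value_high))
    data.frame(trait = groups$trait[g], occasion = groups$occasion[g],
               vas_m = v[1], vas_sd = v[2], drs_loc_m = loc[1],
               drs_loc_sd = loc[2], drs_wid_m = wid[1], drs_wid_sd = wid[2],
               drs_lb_m = lb[1], drs_lb_sd = lb[2], drs_ub_m = ub[1],
               drs_ub_sd = ub[2], stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Cumulative interval density of one respondent's DRS responses
#'
#' For a set of response intervals, the density at a scale value `x` is the
#' number of intervals containing `x`. Quantiles are computed over the
#' cumulated value mass, i.e. treating each interval as a uniform block of
#' mass proportional to its width, so the integral of the density equals the
#' summed interval widths. Zero-width intervals count for the density but
#' carry no mass; if *all* intervals have zero width, quantiles fall back to
#' the weighted quantiles of the point responses.
#'
#' @param low,high Numeric vectors of interval bounds (one respondent's DRS
#'   records for one trait and occasion).
#' @param scale_max Response-scale maximum.
#' @param grid_step Grid resolution for the returned density trace.
#' @return List with `grid`, `density` (counts), `median`, `q025`, `q975`,
#'   `total_mass`.
#' @export
cumulative_interval_density <- function(low, high, scale_max = 100,
                                        grid_step = 0.1) {
  if (!length(low)) stop("at least one interval is required")
  stopifnot(length(low) == length(high), all(low <= high),
            all(low >= 0), all(high <= scale_max))
  grid <- seq(0, scale_max, by = grid_step)
  density <- vapply(grid, function(x) sum(low <= x & x <= high), numeric(1))
  widths <- high - low
  total <- sum(widths)
  qfun <- if (total > 0) {
    # piecewise-linear cumulative mass over the union of breakpoints
    bp <- sort(unique(c(0, low, high, scale_max)))
    segmass <- vapply(seq_len(length(bp) - 1), function(k) {
      cnt <- sum(low <= bp[k] & bp[k + 1] <= high)
      cnt * (bp[k + 1] - bp[k])
    }, numeric(1))
    cum <- c(0, cumsum(segmass))
    function(p) {
      target <- p * total
      k <- max(which(cum <= target + 1e-12))
      if (k >= length(bp)) return(bp[length(bp)])
      need <- target - cum[k]
      cnt <- (cum[k + 1] - cum[k]) / (bp[k + 1] - bp[k])
      if (cnt <= 0) bp[k + 1] else bp[k] + need / cnt
    }
  } else {
    function(p) unname(quantile(low, p, type = 1))
  }
  list(grid = grid, density = density,
       median = qfun(0.5), q025 = qfun(0.025), q975 = qfun(0.975),
       total_mass = total)
}

#' Block-order (carry-over) subgroup analysis
#'
#' Splits the first-occasion data by the order in which the two format
#' blocks were administered and fits the joint model independently in each
#' subgroup, summarizing the VAS-DRS location correlation per trait. Closely
#' matching subgroup estimates argue against carry-over effects between
#' formats.
#'
#' @param table A preprocessed `response_table`; only the first occasion is
#'   used. Both block orders must be present.
#' @param cfg A [model_config()].
#' @return A list with one element per block order: `n_persons` and
#'   `summary` (the convergent-validity correlation summaries).
#' @export
order_effect_analysis <- function(table, cfg = model_config()) {
  df <- as.data.frame(table)
  df <- df[df$occasion == min(df$occasion), ]
  orders <- sort(unique(df$block_order))
  if (length(orders) < 2L) {
    stop("both block orders must be present; found: ",
         paste(orders, collapse = ", "))
  }
  cfg$store_loglik <- FALSE
  out <- lapply(orders, function(bo) {
    sub <- df[df$block_order == bo, ]
    if (!nrow(sub)) stop("empty subgroup for block order ", bo)
    tab <- response_table(sub, scale_max = scale_max(table),
                          allow_duplicates = FALSE)
    fit <- fit_joint(tab, cfg = cfg)
    pairs <- rq_correlation_pairs(fit$traits, occasions = unique(sub$occasion))
    pairs <- pairs[pairs$family == "convergent" &
                     pairs$a %in% fit$dims & pairs$b %in% fit$dims, ]
    list(n_persons = length(unique(sub$person_id)),
         summary = summarize_correlations(fit, pairs))
  })
  names(out) <- orders
  out
}
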