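#' Model configuration for the Bayesian hierarchical fit
#'
#' @param invariance_level One of `"strict"` (default; one item-parameter set
#'   shared across occasions), `"scalar"` (scaling and difficulty shared,
#'   precision occasion-specific), `"metric"` (scaling shared), or
#'   `"configural"` (all item parameters occasion-specific).
#' @param chains Number of MCMC chains (>= 2 for diagnostics; default 4).
#' @param iter Post-warmup draws per chain.
#' @param warmup Warmup (adaptation) iterations per chain.
#' @param thin Thinning factor applied post-warmup.
#' @param max_treedepth Cap on the no-U-turn trajectory doubling depth (a
#'   trajectory uses at most `2^max_treedepth` leapfrog steps).
#' @param target_accept Dual-averaging acceptance target.
#' @param seed Integer seed; chain `c` uses `seed * 1000 + c`, so a fixed
#'   seed with fixed data yields identical draws.
#' @param store_loglik Store pointwise log-likelihoods (needed for LOO).
#' @param store_persons Keep posterior draws of the person parameters.
#' @param priors Named list overriding prior hyperparameters:
#'   `alpha_meanlog` (0), `alpha_sdlog` (0.5), `delta_mean` (0), `delta_sd`
#'   (1), `tau_meanlog` (log 10), `tau_sdlog` (1), `delta_wid_mean` (0),
#'   `delta_wid_sd` (1), `mu_sd` (1), `sigma_scale` (1), `lkj_eta` (1).
#' @return A `model_config` list.
#' @export
model_config <- function(invariance_level = c("strict", "scalar", "metric",
                                              "configural"),
                         chains = 4, iter = 500, warmup = 500, thin = 1,
                         max_treedepth = 9, target_accept = 0.95, seed = 1,
                         store_loglik = TRUE, store_persons = TRUE,
                         priors = list()) {
  stopifnot(chains >= 1, iter > 0, warmup >= 50, thin >= 1)
  pr <- list(alpha_meanlog = 0, alpha_sdlog = 0.5, delta_mean = 0,
             delta_sd = 1, tau_meanlog = log(10), tau_sdlog = 1,
             delta_wid_mean = 0, delta_wid_sd = 1,
             mu_sd = 1, sigma_scale = 1, lkj_eta = 1)
  pr[names(priors)] <- priors
  structure(list(invariance_level = match.arg(invariance_level),
                 chains = chains, iter = iter, warmup = warmup, thin = thin,
                 max_treedepth = max_treedepth, target_accept = target_accept,
                 seed = seed, store_loglik = store_loglik,
                 store_persons = store_persons, priors = pr),
            class = "model_config")
}

# level -> which of (alpha, delta, tau) are shared across occasions
.shared_flags <- function(level) {
  switch(level,
         strict     = c(alpha = TRUE,  delta = TRUE,  tau = TRUE),
         scalar     = c(alpha = TRUE,  delta = TRUE,  tau = FALSE),
         metric     = c(alpha = TRUE,  delta = FALSE, tau = FALSE),
         configural = c(alpha = FALSE, delta = FALSE, tau = FALSE),
         stop("unknown invariance level: ", level))
}

.param_keys <- function(item_ids, occasions, shared) {
  key <- if (shared) item_ids else paste0(item_ids, "@t", occasions)
  u <- sort(unique(key))
  list(idx = match(key, u) - 1L, keys = u, n = length(u))
}

# R mirror of the C++ correlation-Cholesky transform (used to extract
# correlation draws, and in tests as an independent check)
.corr_chol_from_y <- function(y, d) {
  L <- matrix(0, d, d)
  L[1, 1] <- 1
  k <- 0L
  for (i in 2:d) {
    acc <- 1
    for (j in 1:(i - 1)) {
      k <- k + 1L
      L[i, j] <- tanh(y[k]) * sqrt(acc)
      acc <- acc - L[i, j]^2
      acc <- max(acc, 1e-16)
    }
    L[i, i] <- sqrt(acc)
  }
  L
}

# Assemble the C++ data list from a cleaned, reverse-coded response table.
.build_model_data <- function(table, traits, level, priors) {
  df <- as.data.frame(table)
  sm <- scale_max(table)
  occasions <- sort(unique(df$occasion))
  persons <- sort(unique(df$person_id))
  if (length(persons) < 2L) {
    stop("at least two persons are required; the correlation matrix is not identified")
  }
  po <- table(df$person_id, df$occasion)
  missing_po <- which(po == 0, arr.ind = TRUE)
  if (nrow(missing_po)) {
    stop("person(s) without records at every occasion: ",
         paste(head(rownames(po)[missing_po[, 1]], 5L), collapse = ", "))
  }
  params <- c("thetaV", "thetaD", "etaD")[c("VAS", "DRS", "DRS") %in% df$format]
  params <- unique(params)
  dims <- as.vector(vapply(occasions, function(o)
    vapply(traits, function(tr) paste0(params, "_", tr, "_t", o),
           character(length(params))),
    character(length(params) * length(traits))))
  D <- length(dims)
  free <- which(rep(occasions, each = length(params) * length(traits)) >
                occasions[1]) - 1L

  sh <- .shared_flags(level)
  n_total <- nrow(df)

  vas <- df[df$format == "VAS", ]
  drs <- df[df$format == "DRS", ]
  dim_idx <- function(par, sub) {
    match(paste0(par, "_", sub$trait, "_t", sub$occasion), dims) - 1L
  }
  out <- list(N = length(persons), D = D,
              free_mu = free, free_sig = free,
              priors = unname(unlist(priors[c(
                "alpha_meanlog", "alpha_sdlog", "delta_mean", "delta_sd",
                "tau_meanlog", "tau_sdlog", "delta_wid_mean", "delta_wid_sd",
                "mu_sd", "sigma_scale", "lkj_eta")])))

  ka <- .param_keys(vas$item_id, vas$occasion, sh["alpha"])
  kd <- .param_keys(vas$item_id, vas$occasion, sh["delta"])
  kt <- .param_keys(vas$item_id, vas$occasion, sh["tau"])
  cv <- compress(vas_components(vas$value_low, sm), n = n_total, K = 2)
  out$v_p <- match(vas$person_id, persons) - 1L
  out$v_dim <- dim_idx("thetaV", vas)
  out$v_ia <- ka$idx; out$v_id <- kd$idx; out$v_it <- kt$idx
  out$v_lx <- log(cv[, 1]); out$v_l1x <- log(cv[, 2])
  out$nba <- ka$n; out$nbd <- kd$n; out$nbt <- kt$n

  kal <- .param_keys(drs$item_id, drs$occasion, sh["alpha"])
  kdl <- .param_keys(drs$item_id, drs$occasion, sh["delta"])
  kt2 <- .param_keys(drs$item_id, drs$occasion, sh["tau"])
  cd <- compress(drs_components(drs$value_low, drs$value_high, sm),
                 n = n_total, K = 3)
  out$d_p <- match(drs$person_id, persons) - 1L
  out$d_diml <- dim_idx("thetaD", drs)
  out$d_dimw <- dim_idx("etaD", drs)
  out$d_ial <- kal$idx; out$d_idl <- kdl$idx
  out$d_iaw <- kal$idx; out$d_idw <- kdl$idx
  out$d_it <- kt2$idx
  out$d_lx1 <- log(cd[, 1]); out$d_lx2 <- log(cd[, 2]); out$d_lx3 <- log(cd[, 3])
  out$ndal <- kal$n; out$ndl <- kdl$n; out$ndaw <- kal$n; out$ndw <- kdl$n
  out$ndt <- kt2$n

  attr(out, "meta") <- list(
    persons = persons, dims = dims, occasions = occasions, traits = traits,
    params = params, level = level, free = free,
    brm_keys = list(alpha = ka$keys, delta = kd$keys, tau = kt$keys),
    ddrm_keys = list(alpha_loc = kal$keys, delta_loc = kdl$keys,
                     alpha_wid = kal$keys, delta_wid = kdl$keys,
                     tau = kt2$keys),
    record_rows = c(which(df$format == "VAS"), which(df$format == "DRS")),
    n_obs = n_total)
  out
}

# offsets into the unconstrained parameter vector, mirroring the C++ layout
.par_layout <- function(data) {
  meta <- attr(data, "meta")
  D <- data$D; N <- data$N; M <- D * (D - 1) / 2
  sizes <- c(z = N * D, y = M, mu = length(data$free_mu),
             sig = length(data$free_sig),
             ba = data$nba, bd = data$nbd, bt = data$nbt,
             dal = data$ndal, dl = data$ndl, daw = data$ndaw,
             dw = data$ndw, dt = data$ndt)
  off <- cumsum(c(0, sizes))[seq_along(sizes)]
  names(off) <- names(sizes)
  list(sizes = sizes, offsets = off, npar = sum(sizes), D = D, N = N, M = M,
       meta = meta)
}

.init_par <- function(layout, data, priors, chain_seed) {
  set.seed(chain_seed)
  p <- rnorm(layout$npar, 0, 0.05)
  o <- layout$offsets; s <- layout$sizes
  idx <- function(nm) if (s[nm] > 0) o[nm] + seq_len(s[nm]) else integer()
  p[idx("bt")] <- priors$tau_meanlog + rnorm(s["bt"], 0, 0.05)
  p[idx("dt")] <- priors$tau_meanlog + rnorm(s["dt"], 0, 0.05)
  p
}

.fit_model <- function(table, traits = NULL, cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  if (is.null(traits)) traits <- unique(table$trait)
  if (any(table$reverse_coded %in% TRUE)) {
    stop("apply reverse_code() before fitting")
  }
  data <- .build_model_data(table, traits, cfg$invariance_level, cfg$priors)
  layout <- .par_layout(data)
  draws <- array(NA_real_, c(cfg$iter, cfg$chains, layout$npar))
  loglik <- if (cfg$store_loglik) {
    array(NA_real_, c(cfg$iter, cfg$chains, layout$meta$n_obs))
  }
  info <- list(stepsize = numeric(cfg$chains), accept = numeric(cfg$chains),
               divergences = integer(cfg$chains))
  for (ch in seq_len(cfg$chains)) {
    chain_seed <- (cfg$seed %% 1000000L) * 1000L + ch
    init <- .init_par(layout, data, cfg$priors, chain_seed)
    res <- .hmc_cpp(data, init, cfg$warmup, cfg$iter, cfg$thin,
                    cfg$max_treedepth, cfg$target_accept, chain_seed,
                    cfg$store_loglik)
    draws[, ch, ] <- res$draws
    if (cfg$store_loglik) {
      # C++ emits VAS records then DRS records; restore table row order
      ll <- res$loglik
      ll[, layout$meta$record_rows] <- res$loglik
      loglik[, ch, ] <- ll
    }
    info$stepsize[ch] <- res$stepsize
    info$accept[ch] <- res$accept_rate
    info$divergences[ch] <- res$divergences
  }
  fit <- structure(list(draws = draws, loglik = loglik, layout = layout,
                        data = data, cfg = cfg, traits = traits,
                        dims = layout$meta$dims, sampler = info),
                   class = "drs_fit")
  fit$pop <- .extract_population(fit)
  fit
}

# posterior draws of population-level quantities on the natural scale
.extract_population <- function(fit) {
  lay <- fit$layout; D <- lay$D
  S <- dim(fit$draws)[1] * dim(fit$draws)[2]
  flat <- matrix(aperm(fit$draws, c(1, 2, 3)), nrow = S)  # iter-major within chain
  o <- lay$offsets; s <- lay$sizes
  corr <- array(NA_real_, c(S, D, D), dimnames = list(NULL, fit$dims, fit$dims))
  for (sdx in seq_len(S)) {
    L <- .corr_chol_from_y(flat[sdx, o["y"] + seq_len(s["y"])], D)
    corr[sdx, , ] <- tcrossprod(L)
  }
  mu <- matrix(0, S, D, dimnames = list(NULL, fit$dims))
  sig <- matrix(1, S, D, dimnames = list(NULL, fit$dims))
  if (s["mu"] > 0) mu[, fit$data$free_mu + 1L] <- flat[, o["mu"] + seq_len(s["mu"])]
  if (s["sig"] > 0) {
    sig[, fit$data$free_sig + 1L] <- exp(flat[, o["sig"] + seq_len(s["sig"])])
  }
  keys <- lay$meta
  items <- list(
    brm = list(alpha = exp(flat[, o["ba"] + seq_len(s["ba"]), drop = FALSE]),
               delta = flat[, o["bd"] + seq_len(s["bd"]), drop = FALSE],
               tau = exp(flat[, o["bt"] + seq_len(s["bt"]), drop = FALSE])),
    ddrm = list(alpha_loc = exp(flat[, o["dal"] + seq_len(s["dal"]), drop = FALSE]),
                delta_loc = flat[, o["dl"] + seq_len(s["dl"]), drop = FALSE],
                alpha_wid = exp(flat[, o["daw"] + seq_len(s["daw"]), drop = FALSE]),
                delta_wid = flat[, o["dw"] + seq_len(s["dw"]), drop = FALSE],
                tau = exp(flat[, o["dt"] + seq_len(s["dt"]), drop = FALSE])))
  for (blk in names(items)) {
    for (pp in names(items[[blk]])) {
      kn <- keys[[paste0(blk, "_keys")]][[pp]]
      if (length(kn)) colnames(items[[blk]][[pp]]) <- kn
    }
  }
  list(corr = corr, mu = mu, sigma = sig, items = items)
}

#' Fit the joint hierarchical measurement model
#'
#' Combines a beta response model for every VAS record and a Dirichlet
#' dual-response model for every DRS record into one joint Bayesian
#' hierarchical model: person parameters (`thetaV`, `thetaD`, `etaD` per
#' trait and occasion) follow a multivariate normal with means fixed at 0 and
#' SDs fixed at 1 for the first occasion (identification), free means/SDs for
#' later occasions, and a full correlation matrix (LKJ prior). Under strict
#' invariance (the default) one item-parameter set per item and format is
#' shared across occasions. Items a person answered in the other format are
#' simply absent from that person's likelihood (missing by design).
#'
#' Estimation is Hamiltonian Monte Carlo on the unconstrained scale with a
#' non-centered person parameterization (see the methods vignette).
#'
#' @param table A preprocessed `response_table` (reverse coding already
#'   applied); every person must have records at every occasion.
#' @param cfg A [model_config()].
#' @param traits Trait ordering for the person-parameter vector; defaults to
#'   order of first appearance in the table.
#' @return A `drs_fit` object; see [correlation_draws()], [diagnose()],
#'   [compute_loo()], [summarize_correlations()].
#' @export
fit_joint <- function(table, cfg = model_config(), traits = NULL) {
  .fit_model(table, traits = traits, cfg = cfg)
}

#' Fit a single-trait, single-format sub-model
#'
#' Restricts the table to one trait and one response format and fits the
#' corresponding measurement model (BRM for VAS, DDRM for DRS) with the
#' requested invariance level. The person structure is the multivariate
#' normal over that sub-model's person parameters across occasions, with the
#' same first-occasion identification constraints as the joint model.
#'
#' @param table A preprocessed `response_table` spanning both occasions.
#' @param trait Trait label to keep.
#' @param format `"VAS"` or `"DRS"`.
#' @param level Invariance level; overrides `cfg$invariance_level`.
#' @param cfg A [model_config()].
#' @return A `drs_fit`.
#' @export
fit_submodel <- function(table, trait, format = c("VAS", "DRS"),
                         level = c("configural", "metric", "scalar", "strict"),
                         cfg = model_config()) {
  format <- match.arg(format); level <- match.arg(level)
  sub <- table[table$trait == trait & table$format == format, ]
  if (!nrow(sub)) stop("no records for trait ", trait, " in format ", format)
  if (length(unique(sub$occasion)) < 2L) {
    stop("sub-model requires records at more than one occasion")
  }
  sub <- response_table(as.data.frame(sub), scale_max = scale_max(table),
                        allow_duplicates = FALSE)
  cfg$invariance_level <- level
  .fit_model(sub, traits = trait, cfg = cfg)
}

#' Posterior draws of the person-parameter correlation matrix
#'
#' @param fit A `drs_fit`.
#' @return Array `S x d x d` (draws by dimension by dimension) with
#'   dimension labels; every slice is symmetric with unit diagonal.
#' @export
correlation_draws <- function(fit) fit$pop$corr

#' Posterior draws of the correlation between two person parameters
#' @param fit A `drs_fit`.
#' @param a,b Dimension labels (see `fit$dims`).
#' @return Numeric vector of posterior draws.
#' @export
correlation_pair_draws <- function(fit, a, b) {
  if (!a %in% fit$dims || !b %in% fit$dims) {
    stop("unknown parameter pair: ", a, " / ", b,
         " (available: ", paste(fit$dims, collapse = ", "), ")")
  }
  fit$pop$corr[, a, b]
}

#' Posterior draws of person parameters (factor scores)
#'
#' Reassembles each person's parameter vector from the non-centered draws:
#' `P = mu + sigma * (L z)` with `L` the correlation Cholesky factor.
#'
#' @param fit A `drs_fit`.
#' @param thin Keep every `thin`-th draw (person draws are bulky).
#' @return Array `S x N x d` with person ids and dimension labels.
#' @export
person_draws <- function(fit, thin = 1) {
  lay <- fit$layout; D <- lay$D; N <- lay$N
  S <- dim(fit$draws)[1] * dim(fit$draws)[2]
  flat <- matrix(fit$draws, nrow = S)
  keep <- seq(1, S, by = thin)
  o <- lay$offsets; s <- lay$sizes
  out <- array(NA_real_, c(length(keep), N, D),
               dimnames = list(NULL, lay$meta$persons, fit$dims))
  for (ii in seq_along(keep)) {
    sdx <- keep[ii]
    L <- .corr_chol_from_y(flat[sdx, o["y"] + seq_len(s["y"])], D)
    Z <- matrix(flat[sdx, seq_len(N * D)], nrow = D)
    mu <- fit$pop$mu[sdx, ]; sg <- fit$pop$sigma[sdx, ]
    out[ii, , ] <- t((L %*% Z) * sg + mu)
  }
  out
}

#' Pointwise log-likelihood matrix
#' @param fit A `drs_fit` fitted with `store_loglik = TRUE`.
#' @return `S x n_obs` matrix, columns in the order of the fitted table rows.
#' @export
pointwise_loglik <- function(fit) {
  if (is.null(fit$loglik)) {
    stop("fit was run with store_loglik = FALSE; pointwise log-likelihood unavailable")
  }
  ll <- fit$loglik
  matrix(ll, nrow = dim(ll)[1] * dim(ll)[2], ncol = dim(ll)[3])
}

#' Expand item-parameter draws to one column per item and occasion
#'
#' Under shared (invariant) parameters the per-occasion columns of a
#' constrained parameter are identical by construction, which makes the
#' constraint pattern of each invariance level directly inspectable.
#'
#' @param fit A `drs_fit`.
#' @param block `"brm"` or `"ddrm"`.
#' @param param Parameter name within the block.
#' @return `S x (items x occasions)` matrix with `item@t<occ>` column names.
#' @export
item_parameter_draws <- function(fit, block = c("brm", "ddrm"), param) {
  block <- match.arg(block)
  draws <- fit$pop$items[[block]][[param]]
  keys <- colnames(draws)
  occs <- fit$layout$meta$occasions
  if (any(grepl("@t", keys, fixed = TRUE))) return(draws)
  expanded <- draws[, rep(seq_along(keys), each = length(occs)), drop = FALSE]
  colnames(expanded) <- paste0(rep(keys, each = length(occs)), "@t",
                               rep(occs, length(keys)))
  expanded
}

#' Number of distinct item parameters in a fit
#' @param fit A `drs_fit`.
#' @return Named integer vector of parameter-set sizes.
#' @export
n_item_parameters <- function(fit) {
  with(fit$data, c(brm_alpha = nba, brm_delta = nbd, brm_tau = nbt,
                   ddrm_alpha_loc = ndal, ddrm_delta_loc = ndl,
                   ddrm_alpha_wid = ndaw, ddrm_delta_wid = ndw,
                   ddrm_tau = ndt))
}

#' @export
print.drs_fit <- function(x, ...) {
  cat("Joint slider-response fit (", x$layout$meta$level, " invariance)\n", sep = "")
  cat("  persons:", x$data$N, " dims:", x$data$D,
      " observations:", x$layout$meta$n_obs, "\n")
  cat("  draws:", dim(x$draws)[1], "x", dim(x$draws)[2], "chains;",
      "mean acceptance", round(mean(x$sampler$accept), 2),
      "; divergences", sum(x$sampler$divergences), "\n")
  invisible(x)
}
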