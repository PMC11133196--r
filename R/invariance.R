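#' Longitudinal measurement-invariance ladder
#'
#' Fits, for one trait and one response format, the four nested invariance
#' levels — configural (all item parameters occasion-specific), metric
#' (scaling shared across occasions), scalar (scaling and difficulty shared),
#' strict (scaling, difficulty, and precision shared) — and compares adjacent
#' levels by their difference in `elpd_loo`, with the standard error taken
#' from the pointwise elpd differences.
#'
#' @param table A preprocessed `response_table` spanning two (or more)
#'   occasions.
#' @param trait Trait label.
#' @param format `"VAS"` or `"DRS"`.
#' @param cfg A [model_config()]; its `invariance_level` is ignored (all four
#'   are fitted). `store_loglik` is forced on.
#' @param check_convergence Run [diagnose()] on each fit and flag the ladder
#'   if any fit fails (adds some run time).
#' @return An `invariance_ladder` object: `table` (per level: `elpd_loo`,
#'   `se`, `delta_elpd` vs the previous level, `delta_se`), `winner` (level
#'   with the highest `elpd_loo`), `practically_equivalent` (`TRUE` when the
#'   winner's lead over the runner-up is below twice its SE), `fits`
#'   (optional), `flagged`.
#' @export
invariance_ladder <- function(table, trait, format = c("VAS", "DRS"),
                              cfg = model_config(), check_convergence = FALSE,
                              keep_fits = FALSE) {
  format <- match.arg(format)
  levels <- c("configural", "metric", "scalar", "strict")
  cfg$store_loglik <- TRUE
  fits <- list(); loos <- list(); flagged <- FALSE
  for (lev in levels) {
    f <- fit_submodel(table, trait, format, level = lev, cfg = cfg)
    if (check_convergence) {
      dg <- diagnose(f)
      if (!dg$pass) flagged <- TRUE
    }
    loos[[lev]] <- compute_loo(f)
    if (keep_fits) fits[[lev]] <- f else fits[lev] <- list(NULL)
  }
  elpd <- vapply(loos, `[[`, numeric(1), "elpd_loo")
  se <- vapply(loos, `[[`, numeric(1), "se")
  delta <- delta_se <- rep(NA_real_, length(levels))
  for (k in 2:length(levels)) {
    d <- elpd_diff(loos[[k]], loos[[k - 1]])
    delta[k] <- d$delta_elpd
    delta_se[k] <- d$se
  }
  tab <- data.frame(level = levels, elpd_loo = elpd, se = se,
                    delta_elpd = delta, delta_se = delta_se,
                    row.names = NULL, stringsAsFactors = FALSE)
  winner <- levels[which.max(elpd)]
  runner <- sort(elpd, decreasing = TRUE)[2]
  lead <- max(elpd) - runner
  lead_se <- {
    iw <- which.max(elpd)
    ir <- order(elpd, decreasing = TRUE)[2]
    elpd_diff(loos[[iw]], loos[[ir]])$se
  }
  structure(list(table = tab, winner = winner,
                 practically_equivalent = lead < 2 * lead_se,
                 loos = loos, fits = if (keep_fits) fits else NULL,
                 flagged = flagged, trait = trait, format = format),
            class = "invariance_ladder")
}

#' @export
print.invariance_ladder <- function(x, ...) {
  cat("Measurement-invariance ladder:", x$trait, "/", x$format, "\n")
  print(transform(x$table,
                  elpd_loo = round(elpd_loo, 2), se = round(se, 2),
                  delta_elpd = round(delta_elpd, 2),
                  delta_se = round(delta_se, 2)))
  cat("winner:", x$winner,
      if (x$practically_equivalent) "(within 2 SE of runner-up)" else "", "\n")
  if (x$flagged) cat("NOTE: at least one fit failed convergence checks\n")
  invisible(x)
}
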