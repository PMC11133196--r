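#' Construct a multitrait-multimethod study design
#'
#' For each person and trait, the trait's items are randomly split into two
#' halves; one half is answered with the single slider (VAS), the other with
#' the dual-range slider (DRS). The assignment is drawn once and held fixed
#' across all measurement occasions, while the order of the two format blocks
#' is re-randomized per person and occasion.
#'
#' @param n_persons Number of respondents (>= 1).
#' @param items_per_trait Number of items per trait; must be even so the
#'   format split is exact.
#' @param n_occasions Number of measurement occasions (default 2).
#' @param traits Character vector of trait labels (default `c("E", "C")`).
#' @param seed Integer seed; the whole design is reproducible from it.
#' @param reverse_coded_items Character vector of item ids flagged for
#'   reverse coding (default none).
#' @return A `design_spec` list with elements `n_persons`, `traits`,
#'   `items_per_trait`, `n_occasions`, `persons`, `items` (data frame with
#'   `item_id`, `trait`), `format_assignment` (data frame `person_id`,
#'   `item_id`, `format`), `block_order` (data frame `person_id`, `occasion`,
#'   `block_order`), `reverse_coded_items`, `seed`.
#' @examples
#' d <- make_design(n_persons = 4, items_per_trait = 6, seed = 1)
#' @export
make_design <- function(n_persons, items_per_trait, n_occasions = 2,
                        traits = c("E", "C"), seed = 1,
                        reverse_coded_items = character()) {
  stopifnot(n_persons >= 1, n_occasions >= 1, length(traits) >= 1)
  if (items_per_trait %% 2 != 0) {
    stop("items_per_trait must be even to split formats evenly")
  }
  set.seed(seed)
  persons <- sprintf("P%03d", seq_len(n_persons))
  items <- do.call(rbind, lapply(traits, function(tr) {
    data.frame(item_id = sprintf("%s%02d", tr, seq_len(items_per_trait)),
               trait = tr, stringsAsFactors = FALSE)
  }))
  half <- items_per_trait / 2
  fa <- do.call(rbind, lapply(persons, function(p) {
    do.call(rbind, lapply(traits, function(tr) {
      ids <- items$item_id[items$trait == tr]
      vas <- sample(ids, half)
      data.frame(person_id = p, item_id = ids,
                 format = ifelse(ids %in% vas, "VAS", "DRS"),
                 stringsAsFactors = FALSE)
    }))
  }))
  bo <- expand.grid(person_id = persons, occasion = seq_len(n_occasions),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bo <- bo[order(bo$person_id, bo$occasion), ]
  bo$block_order <- sample(c("VAS_first", "DRS_first"), nrow(bo), replace = TRUE)
  rownames(bo) <- NULL
  structure(list(n_persons = n_persons, traits = traits,
                 items_per_trait = items_per_trait, n_occasions = n_occasions,
                 persons = persons, items = items, format_assignment = fa,
                 block_order = bo,
                 reverse_coded_items = as.character(reverse_coded_items),
                 seed = seed),
            class = "design_spec")
}

#' Number of response slots implied by a design
#' @param design A [make_design()] object.
#' @return `n_persons * total_items * n_occasions`.
#' @export
n_response_slots <- function(design) {
  design$n_persons * nrow(design$items) * design$n_occasions
}

#' Preprocessing exclusion configuration
#'
#' Encodes the preprocessing ladder applied to raw response tables, in order:
#' duplicate submissions, self-reported non-serious participation,
#' exceptionally fast/slow completion times (quantile thresholds on
#' per-person-occasion total response time), and robust outliers in
#' per-person response means/SDs (z-scores via median/MAD). The exact
#' thresholds are configurable; the defaults (1%/99% quantiles, |z| > 3.5)
#' are conventions, not transcriptions.
#'
#' @param drop_duplicates Remove duplicate (person, item, occasion) rows,
#'   keeping the first in file order.
#' @param drop_non_serious Remove persons flagged non-serious at any
#'   occasion.
#' @param fast_quantile,slow_quantile Completion-time quantile cutoffs in
#'   (0, 1), or `NULL` to disable; `fast_quantile < slow_quantile`.
#' @param time_guard_z Robust z threshold (on log completion times) an entry
#'   must additionally exceed to count as exceptionally fast/slow. Rank-based
#'   trimming alone removes its tail fraction on *every* pass; requiring
#'   genuine separation from the bulk makes the operation a fixed point on
#'   clean data. `NULL` disables the guard (pure quantile rule).
#' @param outlier_z Robust z threshold on per-person response means and SDs,
#'   or `NULL` to disable.
#' @param require_both_occasions Keep only persons observed at every
#'   occasion present in the table.
#' @return An `exclusion_config` list.
#' @export
exclusion_config <- function(drop_duplicates = TRUE, drop_non_serious = TRUE,
                             fast_quantile = 0.01, slow_quantile = 0.99,
                             time_guard_z = 3.5, outlier_z = 3.5,
                             require_both_occasions = TRUE) {
  if (!is.null(fast_quantile) && !is.null(slow_quantile) &&
      fast_quantile >= slow_quantile) {
    stop("fast_quantile must be below slow_quantile")
  }
  structure(list(drop_duplicates = drop_duplicates,
                 drop_non_serious = drop_non_serious,
                 fast_quantile = fast_quantile, slow_quantile = slow_quantile,
                 time_guard_z = time_guard_z, outlier_z = outlier_z,
                 require_both_occasions = require_both_occasions),
            class = "exclusion_config")
}

#' Apply preprocessing exclusions
#'
#' Applies the rules of an [exclusion_config()] in their documented order and
#' tallies, per rule, how many respondents and person-occasion entries were
#' removed. The operation is idempotent: re-running it on its own output with
#' the same configuration removes nothing.
#'
#' @param table A `response_table` (duplicates permitted).
#' @param cfg An [exclusion_config()].
#' @return A list with elements `table` (the cleaned `response_table`,
#'   duplicate-free) and `report` (class `exclusion_report`): per-rule counts,
#'   `n_retained_both`, `n_retained_t1_only`, and `attrition_pct` computed as
#'   `100 * t1_only / (t1_only + both)`.
#' @export
apply_exclusions <- function(table, cfg = exclusion_config()) {
  sm <- scale_max(table)
  df <- as.data.frame(table)
  rules <- list()
  note_rule <- function(name, persons_removed, entries_removed) {
    rules[[name]] <<- c(respondents = length(persons_removed),
                        entries = entries_removed)
  }
  entry_key <- function(d) paste(d$person_id, d$occasion, sep = "\r")

  # 1. duplicated (person, item, occasion) rows: keep first in file order
  if (isTRUE(cfg$drop_duplicates)) {
    key <- paste(df$person_id, df$item_id, df$occasion, sep = "\r")
    dup <- duplicated(key)
    affected <- unique(entry_key(df)[dup])
    note_rule("duplicates", character(), length(affected))
    df <- df[!dup, ]
  }

  # 2. persons ever flagged non-serious
  if (isTRUE(cfg$drop_non_serious)) {
    bad <- unique(df$person_id[df$serious %in% FALSE])
    ents <- length(unique(entry_key(df)[df$person_id %in% bad]))
    note_rule("non_serious", bad, ents)
    df <- df[!df$person_id %in% bad, ]
  }

  # 3. completion-time quantile rules (per person-occasion total time),
  #    guarded by robust separation on the log scale
  thresholds <- list()
  if (!is.null(cfg$fast_quantile) || !is.null(cfg$slow_quantile)) {
    if (all(is.na(df$response_time_s))) {
      stop("time-based exclusion enabled but response_time_s is missing everywhere")
    }
    ek <- entry_key(df)
    tt <- tapply(df$response_time_s, ek, function(v) sum(v, na.rm = TRUE))
    lt <- log(pmax(tt, .Machine$double.eps))
    rz <- if (is.null(cfg$time_guard_z)) {
      rep(c(-Inf, Inf), length.out = length(tt))  # unused
    } else {
      s <- mad(lt)
      if (!is.finite(s) || s == 0) rep(0, length(tt)) else (lt - median(lt)) / s
    }
    for (rule in c("fast", "slow")) {
      q <- cfg[[paste0(rule, "_quantile")]]
      if (is.null(q)) { note_rule(rule, character(), 0L); next }
      thr <- quantile(tt, probs = q, na.rm = TRUE, names = FALSE)
      thresholds[[rule]] <- thr
      flagged <- if (rule == "fast") {
        tt <= thr & (is.null(cfg$time_guard_z) | rz < -cfg$time_guard_z)
      } else {
        tt >= thr & (is.null(cfg$time_guard_z) | rz > cfg$time_guard_z)
      }
      bad <- unique(sub("\r.*$", "", names(tt)[flagged]))
      ents <- length(unique(entry_key(df)[df$person_id %in% bad]))
      note_rule(rule, bad, ents)
      df <- df[!df$person_id %in% bad, ]
      keep <- !sub("\r.*$", "", names(tt)) %in% bad
      tt <- tt[keep]; rz <- rz[keep]
    }
  }

  # 4. robust outliers of per-person response mean/SD (interval midpoints)
  if (!is.null(cfg$outlier_z)) {
    mid <- (df$value_low + df$value_high) / 2
    pm <- tapply(mid, df$person_id, mean)
    ps <- tapply(mid, df$person_id, sd)
    rz <- function(v) {
      m <- median(v, na.rm = TRUE); s <- mad(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) return(rep(0, length(v)))
      (v - m) / s
    }
    bad <- union(names(pm)[abs(rz(pm)) > cfg$outlier_z],
                 names(ps)[!is.na(ps) & abs(rz(ps)) > cfg$outlier_z])
    ents <- length(unique(entry_key(df)[df$person_id %in% bad]))
    note_rule("outlier", bad, ents)
    df <- df[!df$person_id %in% bad, ]
  }

  # occupancy across occasions (before optionally enforcing completeness)
  occs <- sort(unique(df$occasion))
  per_person_occ <- tapply(df$occasion, df$person_id, function(o) length(unique(o)))
  n_both <- sum(per_person_occ == length(occs))
  n_t1_only <- sum(per_person_occ < length(occs))

  if (isTRUE(cfg$require_both_occasions) && length(occs) > 1L) {
    keep <- names(per_person_occ)[per_person_occ == length(occs)]
    ents <- length(unique(entry_key(df)[!df$person_id %in% keep]))
    note_rule("incomplete", setdiff(names(per_person_occ), keep), ents)
    df <- df[df$person_id %in% keep, ]
  } else {
    note_rule("incomplete", character(), 0L)
  }

  attr_pct <- if (n_both + n_t1_only > 0) 100 * n_t1_only / (n_t1_only + n_both) else 0
  report <- structure(list(n_removed_by_rule = rules,
                           n_retained_both = n_both,
                           n_retained_t1_only = n_t1_only,
                           attrition_pct = attr_pct,
                           time_thresholds = thresholds),
                      class = "exclusion_report")
  clean <- response_table(df, scale_max = sm, allow_duplicates = FALSE)
  list(table = clean, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report\n")
  for (nm in names(x$n_removed_by_rule)) {
    cat(sprintf("  %-12s respondents removed: %3d  entries: %3d\n", nm,
                x$n_removed_by_rule[[nm]]["respondents"],
                x$n_removed_by_rule[[nm]]["entries"]))
  }
  cat(sprintf("  retained: %d complete, %d first-occasion-only (attrition %.1f%%)\n",
              x$n_retained_both, x$n_retained_t1_only, x$attrition_pct))
  invisible(x)
}
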