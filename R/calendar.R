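#' Calendar-conversion configuration
#'
#' @param mean_birth_year Average birth year of the sampled individuals, `D`
#'   (default 1968).
#' @param generation_years Generation time in years (default 28).
#' @return A list of class `calendar_config`.
#' @export
calendar_config <- function(mean_birth_year = 1968, generation_years = 28) {
  stopifnot_scalar_number(generation_years, "generation_years", min = 1e-9)
  structure(list(mean_birth_year = mean_birth_year,
                 generation_years = generation_years),
            class = "calendar_config")
}

#' Convert an admixture date in generations to a calendar year
#'
#' `Y = D - generation_years * (g + 1)`: the dated event happened `g`
#' generations before the sampled individuals' parents, with `D` the mean
#' sampling birth year. Years use astronomical numbering internally (year 0
#' exists); [format_year()] renders years at or below zero as BCE.
#'
#' @param g Admixture date(s) in generations ago; must be nonnegative.
#' @param config A [calendar_config()].
#' @return Numeric vector of calendar years (astronomical numbering).
#' @examples
#' generations_to_year(44)  # 708
#' @export
generations_to_year <- function(g, config = calendar_config()) {
  if (any(g < 0, na.rm = TRUE)) abort("generations must be nonnegative")
  config$mean_birth_year - config$generation_years * (g + 1)
}

#' Invert the calendar conversion
#'
#' @param year Calendar year(s), astronomical numbering.
#' @inheritParams generations_to_year
#' @return Generations ago.
#' @export
year_to_generations <- function(year, config = calendar_config()) {
  (config$mean_birth_year - year) / config$generation_years - 1
}

#' Render an astronomical year as a BCE/CE label
#'
#' @param year Numeric year(s); values at or below zero become BCE (year 0 is
#'   1 BCE).
#' @param digits Rounding for the displayed number (default 0).
#' @return Character vector like `"708 CE"` or `"861 BCE"`.
#' @export
format_year <- function(year, digits = 0) {
  y <- round(year, digits)
  ifelse(y <= 0, paste0(1 - y, " BCE"), paste0(y, " CE"))
}

#' Normal-approximation confidence interval from a standard error
#'
#' Builds the 95% CI `g +/- 1.96 * se`, truncated below at zero generations,
#' and converts both bounds to calendar years (note the year interval runs
#' from the older bound, `ci_high` generations, to the younger).
#'
#' @param g Point estimate in generations.
#' @param se Standard error in generations (nonnegative).
#' @param config A [calendar_config()].
#' @param z Quantile multiplier (default 1.96 for 95%).
#' @return A tibble: `g`, `ci_low`, `ci_high` (generations), `year`,
#'   `year_low` (older), `year_high` (younger).
#' @export
ci_from_se <- function(g, se, config = calendar_config(), z = 1.96) {
  if (any(se < 0, na.rm = TRUE)) abort("`se` must be nonnegative")
  lo <- pmax(0, g - z * se)
  hi <- g + z * se
  tibble(g = g, ci_low = lo, ci_high = hi,
         year = generations_to_year(g, config),
         year_low = generations_to_year(hi, config),
         year_high = generations_to_year(lo, config))
}

#' Method-specific quality filters for admixture-date results
#'
#' Applies each dating method's published retention rule:
#' * fastGLOBETROTTER: keep only `max_r2fit_1date > 0.5` (the one-date model
#'   must fit the observed ancestry-LD decay well);
#' * MOSAIC: reject expected genome-wide `r2 < 0.5` and reject source
#'   differentiation `rst < 0.01`;
#' * MALDER: keep `p_value < 0.01` and reject dates older than 200
#'   generations (too old to retain admixture-LD signal).
#' Rows lacking a statistic their method requires are rejected with reason
#' `"incomplete"`.
#'
#' @param results Tibble with columns `method`, `target`, `g` and the
#'   method-specific statistic columns `max_r2fit_1date`, `r2`, `rst`,
#'   `p_value` (see [generate_admixture_table()] for the layout).
#' @param skip_rules Character vector of rule names to disable, from
#'   `c("gt_fit", "mosaic_r2", "mosaic_rst", "malder_p", "malder_age")`.
#' @param max_generations MALDER age cutoff (default 200).
#' @return A list with `retained` (tibble) and `rejected` (tibble with a
#'   `reason` column naming the violated rule).
#' @export
apply_quality_filters <- function(results, skip_rules = character(),
                                  max_generations = 200) {
  need <- c("method", "g")
  if (!all(need %in% names(results))) abort("results need `method` and `g`")
  col <- function(nm) {
    if (nm %in% names(results)) results[[nm]] else rep(NA_real_, nrow(results))
  }
  reason <- rep(NA_character_, nrow(results))
  active <- function(rule) !(rule %in% skip_rules)
  is_gt <- results$method == "fastGLOBETROTTER"
  is_mo <- results$method == "MOSAIC"
  is_ma <- results$method == "MALDER"
  fit <- col("max_r2fit_1date"); r2 <- col("r2"); rst <- col("rst")
  pv <- col("p_value")
  mark <- function(reason_vec, idx, label) {
    ifelse(idx & is.na(reason_vec), label, reason_vec)
  }
  if (active("gt_fit")) {
    reason <- mark(reason, is_gt & is.na(fit), "incomplete")
    reason <- mark(reason, is_gt & !is.na(fit) & fit <= 0.5, "gt_fit")
  }
  if (active("mosaic_r2")) {
    reason <- mark(reason, is_mo & is.na(r2), "incomplete")
    reason <- mark(reason, is_mo & !is.na(r2) & r2 < 0.5, "mosaic_r2")
  }
  if (active("mosaic_rst")) {
    reason <- mark(reason, is_mo & is.na(rst), "incomplete")
    reason <- mark(reason, is_mo & !is.na(rst) & rst < 0.01, "mosaic_rst")
  }
  if (active("malder_p")) {
    reason <- mark(reason, is_ma & is.na(pv), "incomplete")
    reason <- mark(reason, is_ma & !is.na(pv) & pv >= 0.01, "malder_p")
  }
  if (active("malder_age")) {
    reason <- mark(reason, is_ma & results$g > max_generations, "malder_age")
  }
  rejected <- results[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  list(retained = as_tibble(results[is.na(reason), , drop = FALSE]),
       rejected = as_tibble(rejected))
}

#' Decide between one and two admixture events from MALDER output
#'
#' Two distinct events are concluded only when two inferred events have
#' disjoint date confidence intervals AND disjoint two-reference-curve
#' amplitude confidence intervals; otherwise the result is a single event.
#'
#' @param events Tibble of MALDER events for one target group with columns
#'   `ci_low`, `ci_high` (date CI, generations) and `amp_ci_low`,
#'   `amp_ci_high`.
#' @return A list: `classification` (`"one-event"` or `"two-events"`) and
#'   `evidence` (for two events, the indices of the supporting pair).
#' @export
detect_two_events <- function(events) {
  if (nrow(events) < 2) return(list(classification = "one-event", evidence = NULL))
  disjoint <- function(l1, h1, l2, h2) h1 < l2 | h2 < l1
  for (i in seq_len(nrow(events) - 1)) {
    for (j in seq(i + 1, nrow(events))) {
      date_dj <- disjoint(events$ci_low[i], events$ci_high[i],
                          events$ci_low[j], events$ci_high[j])
      amp_dj <- disjoint(events$amp_ci_low[i], events$amp_ci_high[i],
                         events$amp_ci_low[j], events$amp_ci_high[j])
      if (isTRUE(date_dj) && isTRUE(amp_dj)) {
        return(list(classification = "two-events", evidence = c(i, j)))
      }
    }
  }
  list(classification = "one-event", evidence = NULL)
}

#' Union of confidence intervals across methods
#'
#' Merges overlapping (or touching) intervals into a set of disjoint
#' intervals and also reports the convex hull (minimum lower bound to
#' maximum upper bound), the rendering used when a single combined interval
#' is displayed.
#'
#' @param intervals Tibble (or data frame) with columns `lower`, `upper`.
#' @return A list: `intervals` (tibble of merged disjoint intervals) and
#'   `hull` (length-2 numeric).
#' @export
union_ci <- function(intervals) {
  if (!nrow(intervals)) abort("need at least one interval")
  if (any(intervals$lower > intervals$upper)) abort("lower must be <= upper")
  o <- order(intervals$lower, intervals$upper)
  lo <- intervals$lower[o]; hi <- intervals$upper[o]
  out_lo <- lo[1]; out_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= out_hi[length(out_hi)]) {
      out_hi[length(out_hi)] <- max(out_hi[length(out_hi)], hi[i])
    } else {
      out_lo <- c(out_lo, lo[i]); out_hi <- c(out_hi, hi[i])
    }
  }
  list(intervals = tibble(lower = out_lo, upper = out_hi),
       hull = c(min(lo), max(hi)))
}

#' Cross-method agreement of dated events
#'
#' An event is a single-method outlier when the gap between its confidence
#' interval and every other method's interval exceeds the tolerance
#' (3 generations by default); the gap between intervals I and J is
#' `max(0, J.lower - I.upper, I.lower - J.upper)` (0 when they overlap).
#'
#' @param events Tibble with columns `method`, `ci_low`, `ci_high`
#'   (generations).
#' @param tolerance Maximum gap in generations (default 3).
#' @return The input tibble with added columns `min_gap` (smallest gap to
#'   another method's event; `NA` with a single method) and `agreement`
#'   (`"concordant"` or `"single-method-outlier"`).
#' @export
classify_agreement <- function(events, tolerance = 3) {
  n <- nrow(events)
  min_gap <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    others <- which(events$method != events$method[i])
    if (!length(others)) next
    gaps <- vapply(others, function(j) {
      max(0, events$ci_low[j] - events$ci_high[i],
          events$ci_low[i] - events$ci_high[j])
    }, numeric(1))
    min_gap[i] <- min(gaps)
  }
  dplyr::mutate(as_tibble(events), min_gap = min_gap,
                agreement = dplyr::case_when(
                  is.na(min_gap) ~ "concordant",
                  min_gap > tolerance ~ "single-method-outlier",
                  TRUE ~ "concordant"))
}

#' Harmonise a multi-method admixture-date table
#'
#' Applies the quality filters, builds the SE-based CI for MALDER rows,
#' converts all dates and CI bounds to calendar years, merges CIs per target
#' group, and classifies cross-method agreement.
#'
#' @inheritParams apply_quality_filters
#' @param config A [calendar_config()].
#' @return A list: `events` (retained rows with year columns and agreement),
#'   `rejected`, and `by_target` (tibble: `target`, union interval(s) and
#'   hull in generations and years).
#' @export
harmonize_admixture_dates <- function(results, config = calendar_config(),
                                      skip_rules = character()) {
  filt <- apply_quality_filters(results, skip_rules)
  ev <- filt$retained
  if (nrow(ev)) {
    is_ma <- ev$method == "MALDER" & !is.na(ev$se)
    if (any(is_ma)) {
      ci <- ci_from_se(ev$g[is_ma], ev$se[is_ma], config)
      ev$ci_low[is_ma] <- ci$ci_low
      ev$ci_high[is_ma] <- ci$ci_high
    }
    ev$year <- generations_to_year(ev$g, config)
    ev$year_low <- generations_to_year(ev$ci_high, config)
    ev$year_high <- generations_to_year(ev$ci_low, config)
    ev <- ev |>
      dplyr::group_by(.data$target) |>
      dplyr::group_modify(~ classify_agreement(.x)) |>
      dplyr::ungroup()
    by_target <- ev |>
      dplyr::group_by(.data$target) |>
      dplyr::group_modify(function(d, key) {
        u <- union_ci(tibble(lower = d$ci_low, upper = d$ci_high))
        tibble(hull_low_gen = u$hull[1], hull_high_gen = u$hull[2],
               n_intervals = nrow(u$intervals),
               hull_year_low = generations_to_year(u$hull[2], config),
               hull_year_high = generations_to_year(u$hull[1], config))
      }) |>
      dplyr::ungroup()
  } else {
    by_target <- tibble(target = character())
  }
  list(events = ev, rejected = filt$rejected, by_target = by_target)
}
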