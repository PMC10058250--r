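#' Relatedness-pruning configuration
#'
#' Constants of the population-relative PI_HAT outlier rule: a pair is
#' flagged when its PI_HAT exceeds `base_threshold` AND exceeds
#' `min(X_i + m*max(floor, S_i), Y_i + m*max(floor, D_i),
#'      X_k + m*max(floor, S_k), Y_k + m*max(floor, D_k))`
#' where {X, Y, S, D} are the mean, median, standard deviation and median
#' absolute deviation of within-population PI_HAT for the pair's two
#' populations, and `m` is `multiplier`.
#'
#' @param base_threshold Absolute floor below which pairs are never flagged
#'   (default 0.15).
#' @param floor Lower bound applied to S and D inside the formula
#'   (default 0.02).
#' @param multiplier Spread multiplier (default 3).
#' @param second_pass_threshold Absolute PI_HAT threshold applied to pairs
#'   surviving the formula pass (default 0.18); `NULL` disables the pass.
#' @param duplicate_threshold PI_HAT at or above which a pair is treated as a
#'   duplicated sample (default 0.9).
#' @param mad_scale Scale constant for the MAD; 1 gives the raw MAD
#'   (default), 1.4826 the normal-consistent estimate.
#' @return A list of class `pruning_config`.
#' @export
pruning_config <- function(base_threshold = 0.15, floor = 0.02,
                           multiplier = 3, second_pass_threshold = 0.18,
                           duplicate_threshold = 0.9, mad_scale = 1) {
  for (v in c("base_threshold", "floor", "duplicate_threshold")) {
    stopifnot_scalar_number(get(v), v, min = 0, max = 1)
  }
  if (!is.null(second_pass_threshold)) {
    stopifnot_scalar_number(second_pass_threshold, "second_pass_threshold", 0, 1)
  }
  stopifnot_scalar_number(multiplier, "multiplier", min = 0)
  stopifnot_scalar_number(mad_scale, "mad_scale", min = 1e-9)
  structure(list(base_threshold = base_threshold, floor = floor,
                 multiplier = multiplier,
                 second_pass_threshold = second_pass_threshold,
                 duplicate_threshold = duplicate_threshold,
                 mad_scale = mad_scale),
            class = "pruning_config")
}

check_kinship_table <- function(kinship) {
  need <- c("ID1", "ID2", "PI_HAT")
  if (!all(need %in% names(kinship))) {
    abort("kinship table needs columns ID1, ID2, PI_HAT")
  }
  if (any(kinship$ID1 == kinship$ID2)) abort("self-pairs are not allowed")
  if (anyDuplicated(pair_key(kinship$ID1, kinship$ID2))) {
    abort("each unordered pair may appear only once")
  }
  if (any(kinship$PI_HAT < 0 | kinship$PI_HAT > 1)) {
    abort("PI_HAT must lie in [0, 1]")
  }
  invisible(kinship)
}

#' Within-population PI_HAT summary statistics
#'
#' Computes, per population, the mean, median, standard deviation and median
#' absolute deviation of pairwise PI_HAT among its members. Populations with
#' fewer than three sampled individuals have undefined spread statistics and
#' are flagged (`defined = FALSE`) rather than silently zeroed; the outlier
#' rule treats their pairs with the small-population branch.
#'
#' @param kinship Tibble with columns `ID1`, `ID2`, `PI_HAT`.
#' @param populations Mapping from id to population: named character vector
#'   or a data frame with columns `id` and `population` (a metadata table
#'   with `ethnic_group` is also accepted).
#' @param config A [pruning_config()] (supplies `mad_scale`).
#' @return A tibble with columns `population`, `n_individuals`, `n_pairs`,
#'   `mean`, `median`, `sd`, `mad`, `defined`.
#' @export
kinship_stats <- function(kinship, populations, config = pruning_config()) {
  check_kinship_table(kinship)
  pop <- as_population_vector(populations)
  ids <- unique(c(kinship$ID1, kinship$ID2))
  missing_ids <- setdiff(ids, names(pop))
  if (length(missing_ids)) {
    abort(paste0("ids without population labels: ",
                 paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  p1 <- pop[kinship$ID1]; p2 <- pop[kinship$ID2]
  within <- kinship[p1 == p2, ]
  within$population <- pop[within$ID1]
  stats_tbl <- within |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean = mean(.data$PI_HAT),
      median = stats::median(.data$PI_HAT),
      sd = stats::sd(.data$PI_HAT),
      mad = stats::mad(.data$PI_HAT, constant = config$mad_scale),
      .groups = "drop")
  all_pops <- unique(unname(pop))
  out <- tibble(population = all_pops,
                n_individuals = as.integer(table(factor(unname(pop),
                                                        levels = all_pops)))) |>
    dplyr::left_join(stats_tbl, by = "population") |>
    dplyr::mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L),
                  defined = .data$n_individuals >= 3)
  out$mean[!out$defined] <- NA_real_
  out$median[!out$defined] <- NA_real_
  out$sd[!out$defined] <- NA_real_
  out$mad[!out$defined] <- NA_real_
  # >=3 members but constant PI_HAT: sd/mad are 0, which the floor handles
  out$sd[out$defined & is.na(out$sd)] <- 0
  out$mad[out$defined & is.na(out$mad)] <- 0
  out
}

as_population_vector <- function(populations) {
  if (is.data.frame(populations)) {
    col <- if ("population" %in% names(populations)) "population" else "ethnic_group"
    if (!all(c("id", col) %in% names(populations))) {
      abort("population table needs columns id and population (or ethnic_group)")
    }
    stats::setNames(as.character(populations[[col]]), as.character(populations$id))
  } else {
    stats::setNames(as.character(populations), names(populations))
  }
}

#' Flag outlying related pairs with the population-relative rule
#'
#' A pair from populations (i, k) is flagged when `PI_HAT > base_threshold`
#' and `PI_HAT` exceeds the four-way minimum of the mean/median plus
#' `multiplier` times the floored spread of either population. Any pair
#' touching a population with at most two sampled individuals (where spread
#' is undefined) is flagged on `PI_HAT > base_threshold` alone.
#'
#' @inheritParams kinship_stats
#' @param stats Output of [kinship_stats()]; computed if `NULL`.
#' @return A tibble of flagged pairs: `ID1`, `ID2`, `PI_HAT`, `threshold`
#'   (`NA` for the small-population branch), `rule` (`"formula"` or
#'   `"small_population"`).
#' @export
flag_outlier_pairs <- function(kinship, populations, config = pruning_config(),
                               stats = NULL) {
  check_kinship_table(kinship)
  pop <- as_population_vector(populations)
  if (is.null(stats)) stats <- kinship_stats(kinship, populations, config)
  p1 <- pop[kinship$ID1]; p2 <- pop[kinship$ID2]
  if (anyNA(p1) || anyNA(p2)) abort("ids without population labels")
  srow <- function(p) stats[match(p, stats$population), ]
  s1 <- srow(p1); s2 <- srow(p2)
  small <- !s1$defined | !s2$defined
  term <- function(center, spread) {
    center + config$multiplier * pmax(config$floor, spread)
  }
  thr <- pmin(term(s1$mean, s1$sd), term(s1$median, s1$mad),
              term(s2$mean, s2$sd), term(s2$median, s2$mad))
  flag_formula <- !small & kinship$PI_HAT > config$base_threshold &
    kinship$PI_HAT > thr
  flag_small <- small & kinship$PI_HAT > config$base_threshold
  out <- kinship[flag_formula | flag_small,
                 c("ID1", "ID2", "PI_HAT"), drop = FALSE]
  out$threshold <- ifelse(flag_small[flag_formula | flag_small],
                          NA_real_, thr[flag_formula | flag_small])
  out$rule <- ifelse(flag_small[flag_formula | flag_small],
                     "small_population", "formula")
  as_tibble(out)
}

#' Stepwise greedy removal of related individuals
#'
#' Repeatedly removes the individual appearing in the most unresolved flagged
#' pairs (ties broken by lexicographically smallest id, for determinism)
#' until every flagged pair has lost at least one member.
#'
#' @param flagged Tibble with columns `ID1`, `ID2` (e.g. from
#'   [flag_outlier_pairs()]).
#' @return A list with `removed` (character vector) and `log` (tibble:
#'   `step`, `id`, `n_pairs_resolved`).
#' @export
greedy_prune <- function(flagged) {
  pairs <- unique(tibble(a = pmin(flagged$ID1, flagged$ID2),
                         b = pmax(flagged$ID1, flagged$ID2)))
  removed <- character()
  log <- list()
  step <- 0L
  while (nrow(pairs)) {
    counts <- sort(table(c(pairs$a, pairs$b)), decreasing = TRUE)
    top <- counts[counts == counts[1]]
    victim <- sort(names(top))[1]
    hit <- pairs$a == victim | pairs$b == victim
    step <- step + 1L
    log[[step]] <- tibble(step = step, id = victim,
                          n_pairs_resolved = sum(hit))
    removed <- c(removed, victim)
    pairs <- pairs[!hit, , drop = FALSE]
  }
  list(removed = removed,
       log = if (step) dplyr::bind_rows(log) else
         tibble(step = integer(), id = character(), n_pairs_resolved = integer()))
}

#' Resolve duplicated samples
#'
#' Pairs with `PI_HAT >= duplicate_threshold` are treated as the same person
#' genotyped twice: one member of each pair is removed (a seeded random
#' choice). When the pair's metadata disagree on ethnic group or self
#' birthplace, the surviving individual is additionally marked for exclusion
#' from analyses that use that metadata.
#'
#' @inheritParams kinship_stats
#' @param metadata Cohort metadata with columns `id`, `ethnic_group` and
#'   (optionally) `self_lat`, `self_lon`.
#' @param seed Integer seed for the coin flips.
#' @return A list: `removed` (character), `report` (tibble with `ID1`, `ID2`,
#'   `PI_HAT`, `removed`, `kept`, `metadata_discordant`), and
#'   `metadata_excluded` (ids of survivors with discordant records).
#' @export
resolve_duplicates <- function(kinship, metadata, config = pruning_config(),
                               seed = 1L) {
  check_kinship_table(kinship)
  dup <- kinship[kinship$PI_HAT >= config$duplicate_threshold, , drop = FALSE]
  if (!nrow(dup)) {
    return(list(removed = character(),
                report = tibble(ID1 = character(), ID2 = character(),
                                PI_HAT = double(), removed = character(),
                                kept = character(),
                                metadata_discordant = logical()),
                metadata_excluded = character()))
  }
  meta <- metadata[match(c(dup$ID1, dup$ID2), metadata$id), , drop = FALSE]
  m1 <- meta[seq_len(nrow(dup)), ]; m2 <- meta[nrow(dup) + seq_len(nrow(dup)), ]
  discord <- m1$ethnic_group != m2$ethnic_group
  if (all(c("self_lat", "self_lon") %in% names(metadata))) {
    discord <- discord | (abs(m1$self_lat - m2$self_lat) > 1e-9) |
      (abs(m1$self_lon - m2$self_lon) > 1e-9)
  }
  discord[is.na(discord)] <- TRUE
  with_seed(substream_seed(seed, "duplicates"), {
    drop_first <- stats::runif(nrow(dup)) < 0.5
    removed <- ifelse(drop_first, dup$ID1, dup$ID2)
    kept <- ifelse(drop_first, dup$ID2, dup$ID1)
    list(removed = unique(removed),
         report = tibble(ID1 = dup$ID1, ID2 = dup$ID2, PI_HAT = dup$PI_HAT,
                         removed = removed, kept = kept,
                         metadata_discordant = discord),
         metadata_excluded = unique(kept[discord]))
  })
}

#' Full relatedness-pruning chain
#'
#' Composes the pruning steps: duplicate resolution (with the metadata
#' discordance report), the population-relative formula pass with greedy
#' removal, and — when `second_pass_threshold` is set — a final absolute
#' threshold pass on the surviving pairs.
#'
#' @inheritParams resolve_duplicates
#' @return A list with `removed` (tibble: `id`, `reason` in
#'   `{"duplicate", "kinship_formula", "absolute_threshold"}`),
#'   `metadata_excluded`, `flagged` (the formula-pass flags), `stats` and
#'   `duplicate_report`.
#' @export
prune_related <- function(kinship, metadata, config = pruning_config(),
                          seed = 1L) {
  check_kinship_table(kinship)
  dup <- resolve_duplicates(kinship, metadata, config, seed)
  keep <- !(kinship$ID1 %in% dup$removed | kinship$ID2 %in% dup$removed)
  kin2 <- kinship[keep, , drop = FALSE]
  stats <- kinship_stats(kin2, metadata, config)
  flagged <- flag_outlier_pairs(kin2, metadata, config, stats)
  pass1 <- greedy_prune(flagged)
  removed <- tibble(id = dup$removed,
                    reason = rep("duplicate", length(dup$removed))) |>
    dplyr::bind_rows(tibble(id = pass1$removed,
                            reason = rep("kinship_formula", length(pass1$removed))))
  kin3 <- kin2[!(kin2$ID1 %in% removed$id | kin2$ID2 %in% removed$id), ,
               drop = FALSE]
  if (!is.null(config$second_pass_threshold)) {
    above <- kin3[kin3$PI_HAT > config$second_pass_threshold, , drop = FALSE]
    pass2 <- greedy_prune(above)
    removed <- dplyr::bind_rows(removed,
      tibble(id = pass2$removed,
             reason = rep("absolute_threshold", length(pass2$removed))))
  }
  list(removed = removed, metadata_excluded = dup$metadata_excluded,
       flagged = flagged, stats = stats, duplicate_report = dup$report)
}
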