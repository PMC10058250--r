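#' Isolation-by-distance configuration
#'
#' @param bin_width_km Width of the distance bins, km (default 25).
#' @param min_pairs Named minimum pair counts per bin (strict: a bin is kept
#'   when it has *more* than this many pairs): default 100 for the
#'   inter-ethnic variant and 20 for the intra-ethnic and river-corridor
#'   variants.
#' @param corridor_halfwidth_km Maximum distance from the river polyline for
#'   the corridor variant, km (default 20).
#' @param exclude Character vector of individual ids dropped from every pair
#'   (manual exclusions).
#' @return A list of class `decay_config`.
#' @export
decay_config <- function(bin_width_km = 25,
                         min_pairs = c(inter_ethnic = 100, intra_ethnic = 20,
                                       corridor = 20),
                         corridor_halfwidth_km = 20, exclude = character()) {
  stopifnot_scalar_number(bin_width_km, "bin_width_km", min = 1e-9)
  stopifnot_scalar_number(corridor_halfwidth_km, "corridor_halfwidth_km",
                          min = 1e-9)
  if (any(min_pairs < 0)) abort("min_pairs must be nonnegative")
  structure(list(bin_width_km = bin_width_km, min_pairs = min_pairs,
                 corridor_halfwidth_km = corridor_halfwidth_km,
                 exclude = exclude),
            class = "decay_config")
}

#' Assemble individual pairs for an isolation-by-distance analysis
#'
#' Builds the (distance, similarity) pair table for one analysis variant:
#' `inter_ethnic` keeps pairs whose members report different ethnic groups,
#' `intra_ethnic` pairs from the same ethnic group, and `corridor` pairs of
#' different ethnic groups in which both members live within
#' `corridor_halfwidth_km` of a supplied river polyline. Individuals whose
#' assigned birthplace is flagged as excluded (see [assign_birthplaces()]),
#' and ids on the config's exclusion list, appear in no pair.
#'
#' @param locations Tibble from [assign_birthplaces()] (`id`, `lat`, `lon`,
#'   `included`).
#' @param sim Similarity matrix with individual ids as dimnames.
#' @param metadata Tibble with columns `id`, `ethnic_group`.
#' @param variant One of `"inter_ethnic"`, `"intra_ethnic"`, `"corridor"`.
#' @param config A [decay_config()].
#' @param polyline River polyline (`lat`, `lon` tibble); required for the
#'   corridor variant.
#' @return A tibble: `id1`, `id2`, `distance_km`, `similarity`.
#' @export
assemble_pairs <- function(locations, sim, metadata,
                           variant = c("inter_ethnic", "intra_ethnic",
                                       "corridor"),
                           config = decay_config(), polyline = NULL) {
  variant <- match.arg(variant)
  if (variant == "corridor" && is.null(polyline)) {
    abort("corridor variant needs a river `polyline`")
  }
  loc <- locations[locations$included & !(locations$id %in% config$exclude), ,
                   drop = FALSE]
  loc <- loc[loc$id %in% rownames(sim), , drop = FALSE]
  eth <- stats::setNames(as.character(metadata$ethnic_group),
                         as.character(metadata$id))
  if (variant == "corridor") {
    near <- dist_to_polyline_km(loc$lat, loc$lon, polyline) <=
      config$corridor_halfwidth_km
    loc <- loc[near, , drop = FALSE]
  }
  if (nrow(loc) < 2) {
    return(tibble(id1 = character(), id2 = character(),
                  distance_km = double(), similarity = double()))
  }
  pr <- utils::combn(nrow(loc), 2)
  i1 <- pr[1, ]; i2 <- pr[2, ]
  e1 <- eth[loc$id[i1]]; e2 <- eth[loc$id[i2]]
  keep <- if (variant == "intra_ethnic") e1 == e2 else e1 != e2
  i1 <- i1[keep]; i2 <- i2[keep]
  tibble(id1 = loc$id[i1], id2 = loc$id[i2],
         distance_km = haversine_km(loc$lat[i1], loc$lon[i1],
                                    loc$lat[i2], loc$lon[i2]),
         similarity = sim[cbind(match(loc$id[i1], rownames(sim)),
                                match(loc$id[i2], rownames(sim)))])
}

#' Bin pair distances and fit the isolation-by-distance line
#'
#' Groups pair distances into bins of `bin_width_km`, computes the mean
#' similarity per bin, drops bins that fail the minimum-comparison rule
#' (strictly more pairs than the variant's minimum) or in which every pair
#' involves one same individual, and fits an ordinary least squares line of
#' bin mean similarity on bin midpoint. R squared is reported; when the
#' retained bin means have zero variance it is defined as 0.
#'
#' @param pairs Pair table from [assemble_pairs()].
#' @param config A [decay_config()].
#' @param variant Variant name selecting the minimum pair count.
#' @return An object of class `decay_fit`: list with `bins` (tibble:
#'   `midpoint_km`, `mean_similarity`, `n_pairs`, `retained`), `slope`,
#'   `intercept`, `r_squared`, `n_bins`, `model` (the `lm` fit).
#' @export
bin_and_fit <- function(pairs, config = decay_config(),
                        variant = "inter_ethnic") {
  min_pairs <- config$min_pairs[[variant]]
  if (is.null(min_pairs)) abort(paste0("no min_pairs entry for ", variant))
  w <- config$bin_width_km
  bin_idx <- floor(pairs$distance_km / w)
  bins <- tibble(bin = bin_idx, id1 = pairs$id1, id2 = pairs$id2,
                 similarity = pairs$similarity) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      midpoint_km = (.data$bin[1] + 0.5) * w,
      mean_similarity = mean(.data$similarity),
      n_pairs = dplyr::n(),
      # a bin where one individual takes part in every pair measures that
      # individual, not the bin's distance class
      single_individual = max(table(c(.data$id1, .data$id2))) == dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(retained = .data$n_pairs > min_pairs &
                    !.data$single_individual) |>
    dplyr::arrange(.data$midpoint_km)
  kept <- bins[bins$retained, , drop = FALSE]
  if (nrow(kept) < 2) {
    abort("fewer than two retained distance bins")
  }
  fit <- stats::lm(mean_similarity ~ midpoint_km, data = kept)
  ss_tot <- sum((kept$mean_similarity - mean(kept$mean_similarity))^2)
  r2 <- if (ss_tot <= 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(bins = dplyr::select(bins, -"single_individual", -"bin"),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_bins = nrow(kept), variant = variant,
                 model = fit),
            class = "decay_fit")
}

#' One-call isolation-by-distance analysis
#'
#' [assemble_pairs()] followed by [bin_and_fit()].
#'
#' @inheritParams assemble_pairs
#' @return A `decay_fit` object.
#' @export
distance_decay <- function(locations, sim, metadata,
                           variant = c("inter_ethnic", "intra_ethnic",
                                       "corridor"),
                           config = decay_config(), polyline = NULL) {
  variant <- match.arg(variant)
  pairs <- assemble_pairs(locations, sim, metadata, variant, config, polyline)
  bin_and_fit(pairs, config, variant)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Isolation-by-distance fit (", x$variant, ")\n", sep = "")
  cat(sprintf("  %d retained bins; slope = %.3g per km; intercept = %.4f; R^2 = %.3f\n",
              x$n_bins, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  co <- summary(x$model)$coefficients
  tibble(term = c("intercept", "slope_per_km"),
         estimate = co[, 1], std_error = co[, 2],
         statistic = co[, 3], p_value = co[, 4])
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         n_bins = as.integer(x$n_bins), variant = x$variant)
}
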