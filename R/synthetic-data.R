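#' Describe one synthetic sampling group
#'
#' A group is a named population with an ethnic label, a language
#' classification, a country, a geographic centre, and a Dirichlet
#' distribution over donor groups from which its members' copying profiles
#' are drawn.
#'
#' @param name Group name (also the default ethnic label).
#' @param n Number of sampled individuals.
#' @param center_lat,center_lon Geographic centre of the group (degrees).
#' @param profile_mean Numeric vector over the K donor groups; must sum to 1.
#' @param ethnic,language,country Labels; default to `name` / `"CountryA"`.
#' @param dispersion_km Standard deviation of birthplace scatter around the
#'   centre, km (default 30).
#' @param concentration Dirichlet concentration (precision) of the copying
#'   profiles; larger means tighter profiles (default 50).
#' @return A one-row tibble.
#' @export
synth_group <- function(name, n, center_lat, center_lon, profile_mean,
                        ethnic = name, language = name, country = "CountryA",
                        dispersion_km = 30, concentration = 50) {
  stopifnot_scalar_number(n, "n", min = 0)
  stopifnot_scalar_number(concentration, "concentration", min = 1e-12)
  stopifnot_scalar_number(dispersion_km, "dispersion_km", min = 0)
  check_coords(center_lat, center_lon)
  if (any(profile_mean < 0) || abs(sum(profile_mean) - 1) > 1e-8) {
    abort("`profile_mean` must be nonnegative and sum to 1")
  }
  tibble(name = name, n = as.integer(n), ethnic = ethnic, language = language,
         country = country, center_lat = center_lat, center_lon = center_lon,
         dispersion_km = dispersion_km, concentration = concentration,
         profile_mean = list(as.numeric(profile_mean)))
}

#' Configuration for the synthetic study-input generator
#'
#' Bundles the group layout with the parameters of each generator: copying
#' matrix (total genome length in cM), kinship table (background relatedness,
#' noise), IBD segments (distance-decaying sharing) and the record-level
#' missingness that exercises the birthplace rules.
#'
#' @param groups A tibble of [synth_group()] rows (may be zero rows).
#' @param seed Root integer seed; every generator derives a named substream
#'   from it, so generators are individually reproducible.
#' @param genome_length Total genome-wide matched chunk length per recipient,
#'   cM (default 3545, roughly a human autosomal map).
#' @param relative_pairs Tibble with columns `relationship` (one of
#'   `"duplicate"`, `"parent-offspring"`, `"full-sib"`, `"half-sib"`) and
#'   `count`: pairs of close relatives planted into the kinship table.
#' @param kinship_background Mean background PI_HAT between unrelated
#'   individuals (default 0.005).
#' @param kinship_within_inflation Additional mean PI_HAT between members of
#'   the same group (default 0.01), mimicking within-population endogamy.
#' @param kinship_noise_sd Standard deviation of the truncated-normal noise on
#'   PI_HAT (default 0.01).
#' @param ibd_baseline_cm Expected total IBD sharing at distance zero, cM
#'   (default 30).
#' @param ibd_slope_cm_per_km Linear decay of expected sharing with
#'   geographic distance (default 0.05 cM/km).
#' @param ibd_segment_mean_cm Mean segment length, cM; lengths are
#'   2 + Exponential(mean - 2) so every segment is at least 2 cM (default 4).
#' @param missing_fraction Fraction of individuals whose grandparent
#'   coordinates are blanked (default 0.05).
#' @param far_grandparent_fraction Fraction whose paternal grandfather is
#'   displaced >150 km from the maternal grandmother (default 0.05), to
#'   exercise the exclusion rule.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(groups, seed = 1L, genome_length = 3545,
                         relative_pairs = NULL,
                         kinship_background = 0.005,
                         kinship_within_inflation = 0.01,
                         kinship_noise_sd = 0.01,
                         ibd_baseline_cm = 30, ibd_slope_cm_per_km = 0.05,
                         ibd_segment_mean_cm = 4,
                         missing_fraction = 0.05,
                         far_grandparent_fraction = 0.05) {
  if (!is.data.frame(groups)) abort("`groups` must be a tibble of synth_group() rows")
  stopifnot_scalar_number(genome_length, "genome_length", min = 1e-12)
  stopifnot_scalar_number(kinship_background, "kinship_background", 0, 1)
  stopifnot_scalar_number(kinship_noise_sd, "kinship_noise_sd", min = 0)
  stopifnot_scalar_number(ibd_baseline_cm, "ibd_baseline_cm", min = 0)
  stopifnot_scalar_number(ibd_slope_cm_per_km, "ibd_slope_cm_per_km", min = 0)
  if (ibd_segment_mean_cm < 2) abort("`ibd_segment_mean_cm` must be >= 2")
  stopifnot_scalar_number(missing_fraction, "missing_fraction", 0, 1)
  stopifnot_scalar_number(far_grandparent_fraction, "far_grandparent_fraction", 0, 1)
  if (nrow(groups)) {
    if (any(groups$n < 0)) abort("group sizes must be >= 0")
    k <- lengths(groups$profile_mean)
    if (length(unique(k)) > 1) abort("all profile_mean vectors must share length K")
  }
  if (is.null(relative_pairs)) {
    relative_pairs <- tibble(relationship = character(), count = integer())
  }
  ok <- c("duplicate", "parent-offspring", "full-sib", "half-sib")
  if (!all(relative_pairs$relationship %in% ok)) {
    abort(paste0("relationship must be one of: ", paste(ok, collapse = ", ")))
  }
  structure(list(groups = groups, seed = as.integer(seed),
                 genome_length = genome_length,
                 relative_pairs = relative_pairs,
                 kinship_background = kinship_background,
                 kinship_within_inflation = kinship_within_inflation,
                 kinship_noise_sd = kinship_noise_sd,
                 ibd_baseline_cm = ibd_baseline_cm,
                 ibd_slope_cm_per_km = ibd_slope_cm_per_km,
                 ibd_segment_mean_cm = ibd_segment_mean_cm,
                 missing_fraction = missing_fraction,
                 far_grandparent_fraction = far_grandparent_fraction),
            class = "synth_config")
}

#' Generate a synthetic cohort metadata table
#'
#' Draws individuals for every configured group: self, parent and grandparent
#' birthplaces scattered around the group centre with the configured
#' dispersion, plus a configurable fraction of records with missing
#' grandparent fields or a grandfather displaced by more than 150 km (so the
#' birthplace rule chain has work to do).
#'
#' @param config A [synth_config()].
#' @return A tibble with one row per individual: `id`, `group`,
#'   `ethnic_group`, `language`, `country`, and `self`/`mother`/`father`/
#'   `mgm`/`pgf` `_lat`/`_lon` coordinate columns.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  g <- config$groups
  if (!nrow(g) || sum(g$n) == 0) {
    return(tibble(id = character(), group = character(),
                  ethnic_group = character(), language = character(),
                  country = character(),
                  self_lat = double(), self_lon = double(),
                  mother_lat = double(), mother_lon = double(),
                  father_lat = double(), father_lon = double(),
                  mgm_lat = double(), mgm_lon = double(),
                  pgf_lat = double(), pgf_lon = double()))
  }
  with_seed(substream_seed(config$seed, "cohort"), {
    rows <- purrr::pmap(g, function(name, n, ethnic, language, country,
                                    center_lat, center_lon, dispersion_km,
                                    concentration, profile_mean) {
      if (n == 0) return(NULL)
      scatter <- function() {
        # km-scale isotropic Gaussian scatter converted to degrees locally
        dlat <- stats::rnorm(n, 0, dispersion_km) / 111.32
        dlon <- stats::rnorm(n, 0, dispersion_km) /
          (111.32 * cos(center_lat * pi / 180))
        tibble(lat = pmin(pmax(center_lat + dlat, -90), 90),
               lon = center_lon + dlon)
      }
      self <- scatter(); mo <- scatter(); fa <- scatter()
      mgm <- scatter(); pgf <- scatter()
      tibble(id = sprintf("%s_%03d", name, seq_len(n)), group = name,
             ethnic_group = ethnic, language = language, country = country,
             self_lat = self$lat, self_lon = self$lon,
             mother_lat = mo$lat, mother_lon = mo$lon,
             father_lat = fa$lat, father_lon = fa$lon,
             mgm_lat = mgm$lat, mgm_lon = mgm$lon,
             pgf_lat = pgf$lat, pgf_lon = pgf$lon)
    })
    cohort <- dplyr::bind_rows(rows)
    n_all <- nrow(cohort)
    n_miss <- round(config$missing_fraction * n_all)
    n_far <- round(config$far_grandparent_fraction * n_all)
    pick <- sample.int(n_all, min(n_all, n_miss + n_far))
    miss_idx <- pick[seq_len(min(n_miss, length(pick)))]
    far_idx <- setdiff(pick, miss_idx)
    cohort$mgm_lat[miss_idx] <- NA_real_
    cohort$mgm_lon[miss_idx] <- NA_real_
    if (length(far_idx)) {
      # relocate the paternal grandfather 2-4 degrees of latitude away from
      # the maternal grandmother (>222 km, so the 150 km rule always trips)
      shift <- stats::runif(length(far_idx), 2, 4) *
        sample(c(-1, 1), length(far_idx), replace = TRUE)
      cohort$pgf_lat[far_idx] <- pmin(pmax(cohort$mgm_lat[far_idx] + shift, -90), 90)
      cohort$pgf_lon[far_idx] <- cohort$mgm_lon[far_idx]
    }
    cohort
  })
}

#' Generate a synthetic ChromoPainter-style copying matrix
#'
#' Each recipient's row is `genome_length` times a Dirichlet draw with the
#' recipient's group-specific mean profile and concentration, emulating
#' genome-wide matched chunk lengths summed over donor groups. In
#' `donor_mode = "individual"` the per-group mass is further split across
#' pseudo-donor individuals (uniform Dirichlet within group) and the
#' donor-to-group map is attached as attribute `"donor_map"`, for exercising
#' [aggregate_to_groups()].
#'
#' @param cohort A tibble from [generate_cohort()].
#' @param config The matching [synth_config()].
#' @param donor_mode `"group"` (default) or `"individual"`.
#' @param donors_per_group Pseudo-donors per donor group in individual mode
#'   (default 3).
#' @return A tibble: first column `id`, then one numeric column per donor;
#'   every row sums to `genome_length`.
#' @export
generate_copying_matrix <- function(cohort, config,
                                    donor_mode = c("group", "individual"),
                                    donors_per_group = 3) {
  stopifnot(inherits(config, "synth_config"))
  donor_mode <- match.arg(donor_mode)
  if (!nrow(cohort)) abort("cohort is empty")
  g <- config$groups
  k <- length(g$profile_mean[[1]])
  if (!all(cohort$group %in% g$name)) abort("cohort group not in config")
  with_seed(substream_seed(config$seed, "copying", donor_mode), {
    mean_by_group <- stats::setNames(g$profile_mean, g$name)
    conc_by_group <- stats::setNames(g$concentration, g$name)
    draws <- t(vapply(seq_len(nrow(cohort)), function(i) {
      gm <- mean_by_group[[cohort$group[i]]]
      alpha <- pmax(gm * conc_by_group[[cohort$group[i]]], 1e-12)
      # structural zeros in the mean stay exactly zero
      out <- numeric(k)
      nz <- gm > 0
      out[nz] <- rdirichlet(1, alpha[nz])[1, ]
      out
    }, numeric(k)))
    if (k == 1) draws <- matrix(as.numeric(draws), ncol = 1)
    donor_labels <- sprintf("D%02d", seq_len(k))
    if (donor_mode == "individual") {
      split_w <- lapply(seq_len(k), function(j) {
        w <- rdirichlet(nrow(cohort), rep(1, donors_per_group))
        draws[, j] * w
      })
      draws <- do.call(cbind, split_w)
      donor_ind <- unlist(lapply(donor_labels, function(d)
        sprintf("%s_ind%d", d, seq_len(donors_per_group))))
      colnames(draws) <- donor_ind
      map <- tibble(donor = donor_ind,
                    group = rep(donor_labels, each = donors_per_group))
    } else {
      colnames(draws) <- donor_labels
      map <- NULL
    }
    out <- dplyr::bind_cols(tibble(id = cohort$id),
                            as_tibble(draws * config$genome_length))
    if (!is.null(map)) attr(out, "donor_map") <- map
    out
  })
}

#' Generate a synthetic pairwise kinship (PI_HAT) table
#'
#' All unordered pairs of cohort individuals receive a background PI_HAT
#' (inflated within groups), and the configured relative pairs are planted at
#' the expected values for their relationship: duplicate 1.0,
#' parent-offspring 0.5, full-sib 0.5, half-sib 0.25. Normal noise is added
#' and values truncated to [0, 1]. The planted pairs are attached as
#' attribute `"planted"`.
#'
#' @inheritParams generate_copying_matrix
#' @return A tibble with columns `ID1`, `ID2`, `PI_HAT`.
#' @export
generate_kinship_table <- function(cohort, config) {
  stopifnot(inherits(config, "synth_config"))
  n <- nrow(cohort)
  if (n < 2) abort("need at least two individuals for a kinship table")
  n_planted <- sum(config$relative_pairs$count)
  if (2 * n_planted > n) abort("requested relative pairs exceed cohort size")
  with_seed(substream_seed(config$seed, "kinship"), {
    idx <- utils::combn(n, 2)
    id1 <- cohort$id[idx[1, ]]
    id2 <- cohort$id[idx[2, ]]
    same_group <- cohort$group[idx[1, ]] == cohort$group[idx[2, ]]
    mu <- config$kinship_background +
      ifelse(same_group, config$kinship_within_inflation, 0)
    # plant relatives on disjoint individuals
    expected <- c("duplicate" = 1.0, "parent-offspring" = 0.5,
                  "full-sib" = 0.5, "half-sib" = 0.25)
    pool <- sample.int(n)
    planted <- NULL
    used <- 0
    for (r in seq_len(nrow(config$relative_pairs))) {
      rel <- config$relative_pairs$relationship[r]
      cnt <- config$relative_pairs$count[r]
      if (cnt == 0) next
      take <- pool[used + seq_len(2 * cnt)]
      used <- used + 2 * cnt
      a <- take[seq_len(cnt)]; b <- take[cnt + seq_len(cnt)]
      planted <- dplyr::bind_rows(planted,
        tibble(ID1 = pmin(cohort$id[a], cohort$id[b]),
               ID2 = pmax(cohort$id[a], cohort$id[b]),
               relationship = rel, expected = expected[[rel]]))
    }
    key <- pair_key(id1, id2)
    if (!is.null(planted)) {
      hit <- match(pair_key(planted$ID1, planted$ID2), key)
      mu[hit] <- planted$expected
    }
    pi_hat <- mu
    if (config$kinship_noise_sd > 0) {
      pi_hat <- pi_hat + stats::rnorm(length(mu), 0, config$kinship_noise_sd)
    }
    pi_hat <- pmin(pmax(pi_hat, 0), 1)
    out <- tibble(ID1 = pmin(id1, id2), ID2 = pmax(id1, id2), PI_HAT = pi_hat)
    attr(out, "planted") <- planted %||%
      tibble(ID1 = character(), ID2 = character(),
             relationship = character(), expected = double())
    out
  })
}

#' Generate synthetic IBD segments with distance-decaying sharing
#'
#' For each unordered pair, the expected total shared length is
#' `max(0, baseline - slope * d)` where `d` is the haversine distance between
#' the two self birthplaces. Segment counts are Poisson with that expectation
#' divided by the mean segment length; lengths are 2 + Exponential(mean - 2)
#' cM, so the minimum emitted length is 2 cM (the usual detection floor).
#'
#' @inheritParams generate_copying_matrix
#' @return A tibble in hap-ibd dialect: `ID1`, `HAP1`, `ID2`, `HAP2`,
#'   `CHROM`, `START_BP`, `END_BP`, `LENGTH_CM`.
#' @export
generate_ibd_segments <- function(cohort, config) {
  stopifnot(inherits(config, "synth_config"))
  n <- nrow(cohort)
  empty <- tibble(ID1 = character(), HAP1 = integer(), ID2 = character(),
                  HAP2 = integer(), CHROM = integer(), START_BP = integer(),
                  END_BP = integer(), LENGTH_CM = double())
  if (n < 2 || config$ibd_baseline_cm == 0) return(empty)
  with_seed(substream_seed(config$seed, "ibd"), {
    idx <- utils::combn(n, 2)
    d <- haversine_km(cohort$self_lat[idx[1, ]], cohort$self_lon[idx[1, ]],
                      cohort$self_lat[idx[2, ]], cohort$self_lon[idx[2, ]])
    expected <- pmax(0, config$ibd_baseline_cm - config$ibd_slope_cm_per_km * d)
    counts <- stats::rpois(length(expected),
                           expected / config$ibd_segment_mean_cm)
    total <- sum(counts)
    if (total == 0) return(empty)
    pair_i <- rep(idx[1, ], counts)
    pair_j <- rep(idx[2, ], counts)
    len <- 2 + stats::rexp(total, 1 / max(config$ibd_segment_mean_cm - 2, 1e-9))
    start <- as.integer(stats::runif(total, 1, 9e7))
    tibble(ID1 = cohort$id[pair_i],
           HAP1 = sample(1:2, total, replace = TRUE),
           ID2 = cohort$id[pair_j],
           HAP2 = sample(1:2, total, replace = TRUE),
           CHROM = sample(1:22, total, replace = TRUE),
           START_BP = start,
           END_BP = start + as.integer(len * 1e6),
           LENGTH_CM = len)
  })
}

#' Generate a synthetic admixture-dating results table
#'
#' Synthetic stand-in for the merged output of the three admixture-dating
#' methods, with per-method point estimates scattered around a true date per
#' target group, CIs (bootstrap-style for fastGLOBETROTTER/MOSAIC, SE-based
#' for MALDER) and the fit statistics the quality filters consume. A
#' configurable fraction of rows is generated to fail each filter.
#'
#' @param targets Character vector of target group names.
#' @param true_g Numeric vector of true admixture dates (generations),
#'   recycled to `length(targets)`.
#' @param seed Integer seed.
#' @param fail_fraction Fraction of rows planted to fail a quality filter
#'   (default 0.2).
#' @return A tibble with columns `method`, `target`, `g`, `ci_low`, `ci_high`,
#'   `se`, `max_r2fit_1date`, `max_score_2events`, `r2`, `rst`, `p_value`,
#'   `amplitude`, `amp_ci_low`, `amp_ci_high`.
#' @export
generate_admixture_table <- function(targets, true_g, seed = 1L,
                                     fail_fraction = 0.2) {
  true_g <- rep_len(true_g, length(targets))
  with_seed(substream_seed(seed, "admixture"), {
    rows <- purrr::map2(targets, true_g, function(tg, g0) {
      purrr::map(c("fastGLOBETROTTER", "MOSAIC", "MALDER"), function(m) {
        g <- max(1, stats::rnorm(1, g0, 0.08 * g0))
        half <- abs(stats::rnorm(1, 0.25 * g0, 0.05 * g0))
        fail <- stats::runif(1) < fail_fraction
        tibble(
          method = m, target = tg, g = g,
          ci_low = if (m != "MALDER") max(0, g - half) else NA_real_,
          ci_high = if (m != "MALDER") g + half else NA_real_,
          se = if (m == "MALDER") half / 1.96 else NA_real_,
          max_r2fit_1date = if (m == "fastGLOBETROTTER") {
            if (fail) stats::runif(1, 0.1, 0.5) else stats::runif(1, 0.55, 0.95)
          } else NA_real_,
          max_score_2events = if (m == "fastGLOBETROTTER")
            stats::runif(1, 0, 0.4) else NA_real_,
          r2 = if (m == "MOSAIC") {
            if (fail) stats::runif(1, 0.1, 0.5) else stats::runif(1, 0.55, 0.95)
          } else NA_real_,
          rst = if (m == "MOSAIC") stats::runif(1, 0.02, 0.3) else NA_real_,
          p_value = if (m == "MALDER") {
            if (fail) stats::runif(1, 0.02, 0.5) else stats::runif(1, 0, 0.009)
          } else NA_real_,
          amplitude = if (m == "MALDER") stats::runif(1, 0.001, 0.02) else NA_real_,
          amp_ci_low = NA_real_, amp_ci_high = NA_real_)
      }) |> dplyr::bind_rows()
    })
    out <- dplyr::bind_rows(rows)
    amp_half <- abs(stats::rnorm(nrow(out), 0.002, 5e-4))
    is_malder <- out$method == "MALDER"
    out$amp_ci_low[is_malder] <- pmax(0, out$amplitude[is_malder] - amp_half[is_malder])
    out$amp_ci_high[is_malder] <- out$amplitude[is_malder] + amp_half[is_malder]
    out
  })
}

#' Write the synthetic study inputs to disk
#'
#' Writes the standard file dialects consumed by the readers in this package:
#' metadata CSV, copying-matrix TSV (first column the recipient id), kinship
#' TSV (`ID1`, `ID2`, `PI_HAT`) and hap-ibd-style IBD TSV.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_synthetic_inputs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  cm <- generate_copying_matrix(cohort, config)
  kin <- generate_kinship_table(cohort, config)
  ibd <- generate_ibd_segments(cohort, config)
  files <- c(metadata = file.path(dir, "metadata.csv"),
             copying = file.path(dir, "copying_matrix.tsv"),
             kinship = file.path(dir, "kinship.tsv"),
             ibd = file.path(dir, "ibd_segments.tsv"))
  readr::write_csv(cohort, files[["metadata"]])
  readr::write_tsv(cm, files[["copying"]])
  readr::write_tsv(kin, files[["kinship"]])
  readr::write_tsv(ibd, files[["ibd"]])
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
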