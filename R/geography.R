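#' Great-circle distance between points, in kilometres
#'
#' Haversine distance on a sphere, computed with the `atan2` form of the
#' formula, which stays accurate all the way to antipodal separations. The
#' default radius is the IUGG mean Earth radius.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees. Vectors are
#'   recycled to a common length.
#' @param radius_km Sphere radius in km (default 6371.0088, the IUGG mean).
#' @return Numeric vector of distances in km. Symmetric and nonnegative.
#' @examples
#' haversine_km(0, 0, 0, 90)   # quarter circumference, ~10007.5 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0088) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dlat <- (lat2 - lat1) * pi / 180
  dlon <- (lon2 - lon1) * pi / 180
  a <- sin(dlat / 2)^2 + cos(p1) * cos(p2) * sin(dlon / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * radius_km * atan2(sqrt(a), sqrt(1 - a))
}

check_coords <- function(lat, lon) {
  bad_lat <- !is.na(lat) & (lat < -90 | lat > 90)
  bad_lon <- !is.na(lon) & (lon <= -180 | lon > 180)
  if (any(bad_lat)) abort("latitude out of range [-90, 90]")
  if (any(bad_lon)) abort("longitude out of range (-180, 180]")
  invisible(NULL)
}

#' Spherical midpoint of two points
#'
#' The midpoint is the renormalised mean of the two positions as 3-D unit
#' vectors: the point on the great circle through both that is equidistant
#' from each. Undefined (and an error) for antipodal inputs.
#'
#' @inheritParams haversine_km
#' @return A tibble with columns `lat`, `lon` (degrees).
#' @export
spherical_midpoint <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  v1 <- latlon_to_xyz(lat1, lon1)
  v2 <- latlon_to_xyz(lat2, lon2)
  m <- v1 + v2
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < 1e-12)) abort("midpoint undefined for antipodal points")
  m <- m / nrm
  tibble(lat = asin(pmin(pmax(m[, 3], -1), 1)) * 180 / pi,
         lon = atan2(m[, 2], m[, 1]) * 180 / pi)
}

latlon_to_xyz <- function(lat, lon) {
  la <- lat * pi / 180; lo <- lon * pi / 180
  cbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
}

#' Birthplace assignment rules
#'
#' Controls [assign_birthplaces()]: the maximum allowed separation between
#' the two recorded grandparents (maternal grandmother and paternal
#' grandfather) before the individual falls back to their own birthplace and
#' is excluded from birthplace analyses.
#'
#' @param max_separation_km Maximum grandparent (and parent) birthplace
#'   separation in km; default 150.
#' @param apply_to_parents Apply the same separation rule to the parental
#'   fallback (default `TRUE`).
#' @return A list of class `birthplace_rules`.
#' @export
birthplace_rules <- function(max_separation_km = 150, apply_to_parents = TRUE) {
  stopifnot_scalar_number(max_separation_km, "max_separation_km", min = 1e-9)
  structure(list(max_separation_km = max_separation_km,
                 apply_to_parents = isTRUE(apply_to_parents)),
            class = "birthplace_rules")
}

#' Assign one geographic location per individual from multi-generation records
#'
#' Implements the mean-birthplace rule chain: when both grandparent
#' birthplaces (maternal grandmother, paternal grandfather) are recorded and
#' lie within `max_separation_km` of each other, the individual's location is
#' their spherical midpoint. When grandparent information is missing, the
#' parents' midpoint is used instead. When no relative information is
#' available, or the grandparents lived further apart than the threshold, the
#' individual's own birthplace is used and the individual is flagged as
#' excluded from downstream birthplace analyses.
#'
#' @param data A data frame with columns `id`, `self_lat`, `self_lon`,
#'   `mother_lat`, `mother_lon`, `father_lat`, `father_lon`, `mgm_lat`,
#'   `mgm_lon`, `pgf_lat`, `pgf_lon` (grandparent columns: maternal
#'   grandmother, paternal grandfather). Missing locations are `NA`.
#' @param rules A [birthplace_rules()] object.
#' @return A tibble with columns `id`, `lat`, `lon`,
#'   `provenance` (`"grandparents"`, `"parents"` or `"self"`) and `included`
#'   (logical; `FALSE` when the self fallback was used).
#' @export
assign_birthplaces <- function(data, rules = birthplace_rules()) {
  stopifnot(inherits(rules, "birthplace_rules"))
  need <- c("id", "self_lat", "self_lon", "mother_lat", "mother_lon",
            "father_lat", "father_lon", "mgm_lat", "mgm_lon",
            "pgf_lat", "pgf_lon")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  all_missing <- apply(
    is.na(data[c("self_lat", "mother_lat", "father_lat", "mgm_lat", "pgf_lat")]),
    1, all)
  if (any(all_missing)) {
    abort(sprintf("all birthplaces missing for: %s",
                  paste(data$id[all_missing], collapse = ", ")))
  }
  rows <- purrr::pmap(data[need], assign_one, rules = rules)
  dplyr::bind_cols(tibble(id = data$id), dplyr::bind_rows(rows))
}

assign_one <- function(id, self_lat, self_lon, mother_lat, mother_lon,
                       father_lat, father_lon, mgm_lat, mgm_lon,
                       pgf_lat, pgf_lon, rules) {
  pair_location <- function(la1, lo1, la2, lo2) {
    if (anyNA(c(la1, lo1, la2, lo2))) return(NULL)
    sep <- haversine_km(la1, lo1, la2, lo2)
    if (sep > rules$max_separation_km) return("too_far")
    mid <- spherical_midpoint(la1, lo1, la2, lo2)
    c(lat = mid$lat, lon = mid$lon)
  }
  gp <- pair_location(mgm_lat, mgm_lon, pgf_lat, pgf_lon)
  if (is.numeric(gp)) {
    return(tibble(lat = gp[["lat"]], lon = gp[["lon"]],
                  provenance = "grandparents", included = TRUE))
  }
  if (!identical(gp, "too_far")) {
    # grandparents missing: parental fallback
    pa <- pair_location(mother_lat, mother_lon, father_lat, father_lon)
    if (is.numeric(pa)) {
      return(tibble(lat = pa[["lat"]], lon = pa[["lon"]],
                    provenance = "parents", included = TRUE))
    }
    if (identical(pa, "too_far") && !rules$apply_to_parents) {
      mid <- spherical_midpoint(mother_lat, mother_lon, father_lat, father_lon)
      return(tibble(lat = mid$lat, lon = mid$lon,
                    provenance = "parents", included = TRUE))
    }
  }
  # rule failed (relatives too far apart) or no relative information: self,
  # excluded from birthplace analyses
  if (anyNA(c(self_lat, self_lon))) {
    abort(sprintf("individual %s: fallback reached but own birthplace missing", id))
  }
  tibble(lat = self_lat, lon = self_lon, provenance = "self", included = FALSE)
}

#' Minimum distance from points to a polyline, in km
#'
#' Spherical point-to-segment distance (cross-track distance clamped to the
#' segment ends), minimised over all segments of the polyline. Used by the
#' river-corridor variant of the isolation-by-distance analysis.
#'
#' @param lat,lon Point coordinates (degrees), recycled to a common length.
#' @param polyline Data frame with columns `lat`, `lon`: the ordered vertices.
#' @inheritParams haversine_km
#' @return Numeric vector of distances in km.
#' @export
dist_to_polyline_km <- function(lat, lon, polyline, radius_km = 6371.0088) {
  if (!all(c("lat", "lon") %in% names(polyline)) || nrow(polyline) < 1) {
    abort("`polyline` needs columns lat, lon and at least one vertex")
  }
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  p <- latlon_to_xyz(lat, lon)
  v <- latlon_to_xyz(polyline$lat, polyline$lon)
  out <- rep(Inf, n)
  if (nrow(polyline) == 1) {
    return(haversine_km(lat, lon, polyline$lat, polyline$lon, radius_km))
  }
  for (s in seq_len(nrow(polyline) - 1)) {
    a <- v[s, ]; b <- v[s + 1, ]
    out <- pmin(out, point_segment_dist(p, a, b, radius_km))
  }
  out
}

# Distance from unit vectors p (rows) to great-circle arc a-b on a sphere.
point_segment_dist <- function(p, a, b, radius_km) {
  axb <- c(a[2] * b[3] - a[3] * b[2],
           a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
  nn <- sqrt(sum(axb^2))
  ang_pa <- acos(pmin(pmax(p %*% a, -1), 1))
  ang_pb <- acos(pmin(pmax(p %*% b, -1), 1))
  if (nn < 1e-12) return(radius_km * pmin(ang_pa, ang_pb))  # degenerate segment
  nvec <- axb / nn
  # cross-track angular distance to the great circle
  xt <- abs(asin(pmin(pmax(p %*% nvec, -1), 1)))
  # foot of perpendicular lies within the arc iff both along-track angles
  # are no longer than the arc itself
  arc <- acos(pmin(pmax(sum(a * b), -1), 1))
  along_a <- acos(pmin(pmax(cos(ang_pa) / pmax(cos(xt), 1e-15), -1), 1))
  along_b <- acos(pmin(pmax(cos(ang_pb) / pmax(cos(xt), 1e-15), -1), 1))
  inside <- (along_a <= arc) & (along_b <= arc)
  radius_km * ifelse(inside, xt, pmin(ang_pa, ang_pb))
}
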