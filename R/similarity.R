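#' Coerce a copying table to a numeric matrix
#'
#' Accepts either a numeric matrix with row names, or a data frame whose
#' first column holds recipient ids and whose remaining columns are donors.
#'
#' @param x Copying matrix in either representation.
#' @return Numeric matrix with recipient ids as row names.
#' @export
as_copying_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("matrix must have recipient row names")
    return(x)
  }
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    return(m)
  }
  abort("`x` must be a matrix or a data frame with an id column first")
}

#' Aggregate a copying matrix into normalised copying profiles
#'
#' Sums donor columns within donor groups and normalises each recipient's
#' row to 1, producing the copying profile `f` whose entry `f[k]` is the
#' proportion of genome-wide DNA the recipient matches to donor group `k`.
#' When recipients are themselves among the donors, the self-column (a
#' structural zero: no one is painted by themselves) is excluded from the
#' recipient's own sums.
#'
#' @param x Copying matrix (see [as_copying_matrix()]).
#' @param donor_groups `NULL` for identity grouping (donors are already
#'   groups), or a donor-to-group map: a data frame with columns `donor` and
#'   `group`, or a named character vector `c(donor = group)`.
#' @return Numeric matrix of profiles: recipients in rows, donor groups in
#'   columns, rows summing to 1.
#' @export
aggregate_to_groups <- function(x, donor_groups = NULL) {
  m <- as_copying_matrix(x)
  if (is.null(donor_groups)) {
    groups <- colnames(m)
    if (is.null(groups)) abort("donor columns must be named")
    gmap <- stats::setNames(groups, groups)
  } else if (is.data.frame(donor_groups)) {
    gmap <- stats::setNames(as.character(donor_groups$group),
                            as.character(donor_groups$donor))
  } else {
    gmap <- donor_groups
  }
  unmapped <- setdiff(colnames(m), names(gmap))
  if (length(unmapped)) {
    abort(paste0("unmapped donors: ", paste(unmapped, collapse = ", ")))
  }
  self <- intersect(rownames(m), colnames(m))
  if (length(self)) {
    for (s in self) m[s, s] <- 0
  }
  glev <- unique(unname(gmap[colnames(m)]))
  agg <- vapply(glev, function(g) {
    cols <- colnames(m)[gmap[colnames(m)] == g]
    rowSums(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  if (nrow(m) == 1) agg <- matrix(agg, nrow = 1, dimnames = list(rownames(m), glev))
  tot <- rowSums(agg)
  zero <- tot <= 0
  if (any(zero)) {
    abort(paste0("recipient(s) with all-zero copying row: ",
                 paste(rownames(m)[zero], collapse = ", ")))
  }
  sweep(agg, 1, tot, "/")
}

#' Total variation distance between two copying profiles
#'
#' Half the L1 distance between two probability vectors over the K donor
#' groups: `0.5 * sum(|f_i - f_j|)`, a metric on the simplex taking values
#' in [0, 1]. `1 - tvd` is used throughout as genetic similarity.
#'
#' @param fi,fj Numeric vectors of equal length (copying profiles).
#' @return A single number in [0, 1].
#' @examples
#' tvd(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5))  # 0.3
#' @export
tvd <- function(fi, fj) {
  if (length(fi) != length(fj)) abort("profiles must have equal length")
  0.5 * sum(abs(fi - fj))
}

#' Pairwise 1 - TVD similarity matrix
#'
#' @param profiles Matrix of copying profiles (individuals in rows, rows
#'   summing to 1) as produced by [aggregate_to_groups()].
#' @return Symmetric numeric matrix of `1 - TVD` similarities with unit
#'   diagonal and the profile row names as dimnames.
#' @export
similarity_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n)) {
    di <- 0.5 * colSums(abs(t(profiles) - profiles[i, ]))
    d[i, ] <- di
  }
  1 - d
}

#' Mean within- and between-group similarity
#'
#' The similarity within a group is the mean `1 - TVD` across all unordered
#' pairings of distinct individuals from that group; the similarity between
#' two groups is the mean across all pairings of individuals from different
#' groups. An optional exclusion predicate drops pairs from both kinds of
#' mean (used by the language-level tests to discard same-ethnic-group
#' pairs).
#'
#' @param sim Similarity matrix from [similarity_matrix()].
#' @param groups Named character vector or factor mapping individual id to
#'   group, or a data frame with columns `id` and `group`.
#' @param exclude_pairs Optional function `(id1, id2) -> logical` (vectorised)
#'   returning `TRUE` for pairs to exclude.
#' @return A tibble with columns `group_a`, `group_b` (`group_a == group_b`
#'   for within-group rows), `similarity`, `n_pairs`.
#' @export
group_similarity <- function(sim, groups, exclude_pairs = NULL) {
  groups <- as_group_vector(groups, rownames(sim))
  ids <- rownames(sim)
  glev <- unique(groups[ids])
  pairs <- t(utils::combn(length(ids), 2))
  i1 <- ids[pairs[, 1]]; i2 <- ids[pairs[, 2]]
  keep <- if (is.null(exclude_pairs)) rep(TRUE, nrow(pairs)) else !exclude_pairs(i1, i2)
  s <- sim[cbind(pairs[, 1], pairs[, 2])]
  g1 <- groups[i1]; g2 <- groups[i2]
  ga <- pmin(g1, g2); gb <- pmax(g1, g2)
  tibble(group_a = ga[keep], group_b = gb[keep], s = s[keep]) |>
    dplyr::group_by(.data$group_a, .data$group_b) |>
    dplyr::summarise(similarity = mean(.data$s), n_pairs = dplyr::n(),
                     .groups = "drop")
}

as_group_vector <- function(groups, ids) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), as.character(groups$id))
  } else {
    groups <- stats::setNames(as.character(groups), names(groups))
  }
  missing_ids <- setdiff(ids, names(groups))
  if (length(missing_ids)) {
    abort(paste0("no group for: ", paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  groups
}

#' Normalise a square painting matrix for principal component analysis
#'
#' The raw painting matrix has a structural zero diagonal (no individual is
#' painted by themselves). Each diagonal entry is replaced by the mean of
#' the row (by default the mean of its off-diagonal entries), then row means
#' are subtracted.
#'
#' @param x Square copying matrix (see [as_copying_matrix()]).
#' @param include_zero_diagonal Include the structural zero itself when
#'   averaging the row to fill the diagonal (default `FALSE`: the mean is
#'   over the off-diagonal entries).
#' @return Row-centred numeric matrix of the same dimensions.
#' @export
prepare_pca_matrix <- function(x, include_zero_diagonal = FALSE) {
  m <- as_copying_matrix(x)
  if (nrow(m) != ncol(m)) abort("painting matrix must be square")
  n <- nrow(m)
  off_sum <- rowSums(m) - diag(m)
  fill <- if (include_zero_diagonal) rowSums(m) / n else off_sum / (n - 1)
  diag(m) <- fill
  m - rowMeans(m)
}

#' Principal components of a normalised painting matrix
#'
#' Runs [prepare_pca_matrix()] then an uncentred PCA (the matrix is already
#' row-centred).
#'
#' @inheritParams prepare_pca_matrix
#' @param n_pcs Number of components to retain (default 10, capped at the
#'   matrix rank).
#' @return A tibble: `id`, then `PC1 ... PCn`.
#' @export
painting_pca <- function(x, n_pcs = 10, include_zero_diagonal = FALSE) {
  m <- prepare_pca_matrix(x, include_zero_diagonal)
  pc <- stats::prcomp(m, center = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  dplyr::bind_cols(tibble(id = rownames(m)),
                   as_tibble(pc$x[, seq_len(k), drop = FALSE]))
}

#' Read a copying matrix TSV
#'
#' First column: recipient id; header row: donor labels.
#'
#' @param path File path.
#' @return A tibble (see [generate_copying_matrix()] for the layout).
#' @export
read_copying_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
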