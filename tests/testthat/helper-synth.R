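# Shared fixture builders for the test suite.

three_group_config <- function(seed = 1, n = 10, concentration = 50,
                               means = list(c(0.6, 0.3, 0.1),
                                            c(0.3, 0.4, 0.3),
                                            c(0.1, 0.3, 0.6)),
                               ...) {
  groups <- dplyr::bind_rows(
    synth_group("A", n, 5.0, 10.0, means[[1]], concentration = concentration),
    synth_group("B", n, 6.0, 12.0, means[[2]], concentration = concentration),
    synth_group("C", n, 7.0, 14.0, means[[3]], concentration = concentration))
  synth_config(groups, seed = seed, ...)
}

# Similarity matrix straight from a profile matrix with given row ids.
sim_from_profiles <- function(profiles, ids) {
  rownames(profiles) <- ids
  similarity_matrix(profiles)
}

# Random point on the probability simplex (independent of rdirichlet in the
# package: plain normalised exponentials).
random_simplex <- function(k) {
  x <- -log(runif(k))
  x / sum(x)
}

# Exhaustive minimum vertex cover size on a small pair list (oracle).
brute_force_vertex_cover <- function(pairs) {
  ids <- sort(unique(c(pairs$ID1, pairs$ID2)))
  n <- length(ids)
  if (!nrow(pairs)) return(0L)
  for (k in 0:n) {
    if (k == 0) next
    combs <- utils::combn(ids, k)
    for (j in seq_len(ncol(combs))) {
      cover <- combs[, j]
      if (all(pairs$ID1 %in% cover | pairs$ID2 %in% cover)) return(k)
    }
  }
  n
}

# Validity of a vertex cover: every pair loses at least one member.
is_vertex_cover <- function(pairs, removed) {
  all(pairs$ID1 %in% removed | pairs$ID2 %in% removed)
}

# Endogamy confound: two language groups of four ethnic groups each;
# cross-ethnic pair similarities are iid (exchangeable across languages)
# while same-ethnic pairs get a constant boost. Language-level structure is
# therefore pure ethnic-group endogamy.
make_endogamy_confound <- function(seed, n_eth_per_lang = 4, n_per_eth = 5,
                                   cross_lo = 0.6, cross_hi = 0.7,
                                   boost = 0.25) {
  set.seed(seed)
  n_eth <- 2 * n_eth_per_lang
  n <- n_eth * n_per_eth
  ids <- sprintf("p%03d", seq_len(n))
  eth <- stats::setNames(rep(sprintf("E%d", seq_len(n_eth)), each = n_per_eth),
                         ids)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    v <- stats::runif(1, cross_lo, cross_hi)
    if (eth[i] == eth[j]) v <- v + boost
    S[i, j] <- S[j, i] <- v
  }
  diag(S) <- 1
  half <- n / 2
  list(S = S, eth = eth, langA = ids[seq_len(half)],
       langB = ids[seq(half + 1, n)])
}

# Minimal metadata table for kinship tests.
meta_for <- function(ids, populations) {
  tibble::tibble(id = ids, ethnic_group = populations)
}
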