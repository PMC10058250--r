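#' Permutation-test configuration
#'
#' @param n_perm Number of permutations (default 100000, the convention for
#'   published runs; reduce for exploratory work).
#' @param alpha Significance conventions reported alongside p-values
#'   (default `c(0.01, 0.001)`).
#' @param seed Root seed; each comparison derives a substream from the seed
#'   and the two member sets, so results do not depend on the order in which
#'   comparisons are run. `NULL` uses the current RNG state.
#' @param strict_gt Use the literal strict "greater than" counting rule with
#'   no correction, i.e. `p = #\{mean(C) > mean(ref)\} / n_perm`. The default
#'   (`FALSE`) counts ties and applies the +1 correction,
#'   `p = (1 + #\{mean(C) >= mean(ref)\}) / (n_perm + 1)`, which keeps
#'   p-values valid when similarities are degenerate.
#' @param reference `"full"` (default): each permutation's test-group mean is
#'   compared against the intragroup mean of the full group A (the reported
#'   G); `"downsampled"`: against the mean of the per-permutation downsampled
#'   group.
#' @param min_ethnic_groups Minimum distinct ethnic groups a language group
#'   (and each permuted test group) must contain in language mode (default 2).
#' @param max_redraw_factor In language mode, permutations violating the
#'   ethnic-diversity requirement are redrawn; after
#'   `max_redraw_factor * n_perm` total attempts the test aborts (default
#'   100).
#' @return A list of class `perm_config`.
#' @export
perm_config <- function(n_perm = 100000, alpha = c(0.01, 0.001), seed = NULL,
                        strict_gt = FALSE,
                        reference = c("full", "downsampled"),
                        min_ethnic_groups = 2, max_redraw_factor = 100) {
  stopifnot_scalar_number(n_perm, "n_perm", min = 1)
  structure(list(n_perm = as.integer(n_perm), alpha = alpha, seed = seed,
                 strict_gt = isTRUE(strict_gt),
                 reference = match.arg(reference),
                 min_ethnic_groups = as.integer(min_ethnic_groups),
                 max_redraw_factor = max_redraw_factor),
            class = "perm_config")
}

# Mean pairwise similarity over the members idx, honouring a pair mask W
# (W[i,j] = 1 for pairs that count; diag always 0). Returns NaN when no
# valid pairs exist.
masked_mean_sim <- function(S0, W, idx) {
  sum(S0[idx, idx]) / sum(W[idx, idx])
}

#' Permutation test of genetic distinguishability between two groups
#'
#' Tests, asymmetrically, whether individuals of group A (and separately of
#' group B) are on average more similar to members of their own group than
#' to a mixed group. Per permutation the larger group is downsampled so both
#' have `n = min(n_a, n_b)` members, and a test group C is assembled with
#' `n/2` members sampled without replacement from each (for odd `n`,
#' `(n-1)/2` from each plus one extra from a randomly chosen side). The
#' p-value for A is the proportion of permutations in which the mean
#' pairwise similarity within C reaches the mean within A (see `strict_gt`
#' in [perm_config()] for the tie convention). A small p-value for A means A
#' is genetically distinguishable from B; because the two intragroup means
#' differ, significance can be asymmetric.
#'
#' @param sim Similarity matrix from [similarity_matrix()].
#' @param members_a,members_b Character vectors of member ids (disjointness
#'   is not required; shared ids make the test conservative).
#' @param config A [perm_config()].
#' @param ethnic Optional named vector mapping id to ethnic group; when
#'   supplied the language-mode correction is applied (see [language_test()]).
#' @return An object of class `distinguishability_test`: a list with
#'   `p_a`, `p_b`, `g_a`, `g_b` (mean intragroup similarities), `inter`
#'   (mean intergroup similarity), `n` (per-group size used), `n_perm`,
#'   `mode`, `testable`.
#' @export
distinguishability_test <- function(sim, members_a, members_b,
                                    config = perm_config(), ethnic = NULL) {
  mode <- if (is.null(ethnic)) "ethnic" else "language"
  members_a <- as.character(members_a); members_b <- as.character(members_b)
  if (length(members_a) < 2 || length(members_b) < 2) {
    abort("both groups need at least two members")
  }
  bad <- setdiff(c(members_a, members_b), rownames(sim))
  if (length(bad)) {
    abort(paste0("ids missing from similarity matrix: ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  ids <- unique(c(members_a, members_b))
  S <- sim[ids, ids, drop = FALSE]
  n_tot <- length(ids)
  W <- matrix(1, n_tot, n_tot, dimnames = dimnames(S))
  diag(W) <- 0
  if (mode == "language") {
    eth <- ethnic[ids]
    if (anyNA(eth)) abort("ethnic labels missing for some members")
    if (length(unique(ethnic[members_a])) < config$min_ethnic_groups ||
        length(unique(ethnic[members_b])) < config$min_ethnic_groups) {
      return(structure(list(p_a = NA_real_, p_b = NA_real_, g_a = NA_real_,
                            g_b = NA_real_, inter = NA_real_,
                            n = min(length(members_a), length(members_b)),
                            n_perm = config$n_perm, mode = mode,
                            testable = FALSE,
                            reason = "fewer than two ethnic groups"),
                       class = "distinguishability_test"))
    }
    same_eth <- outer(eth, eth, "==")
    W[same_eth] <- 0
  }
  S0 <- S * W
  ia <- match(members_a, ids); ib <- match(members_b, ids)
  g_a <- masked_mean_sim(S0, W, ia)
  g_b <- masked_mean_sim(S0, W, ib)
  cross <- S[members_a, members_b, drop = FALSE] *
    W[members_a, members_b, drop = FALSE]
  wcross <- W[members_a, members_b, drop = FALSE]
  inter <- sum(cross) / sum(wcross)
  n <- min(length(ia), length(ib))
  k <- n %/% 2
  odd <- n %% 2 == 1
  seed <- if (is.null(config$seed)) NULL else
    substream_seed(config$seed, "permtest", mode,
                   paste(sort(members_a), collapse = ","),
                   paste(sort(members_b), collapse = ","))
  with_seed(seed, {
    ref_full <- config$reference == "full"
    need_valid <- mode == "language"
    max_attempts <- config$max_redraw_factor * config$n_perm
    count_a <- 0L; count_b <- 0L
    attempts <- 0L; done <- 0L
    while (done < config$n_perm) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort("redraw cap reached: valid permutations too rare")
      }
      sub_a <- if (length(ia) > n) ia[sample.int(length(ia), n)] else ia
      sub_b <- if (length(ib) > n) ib[sample.int(length(ib), n)] else ib
      pick_a <- sub_a[sample.int(n, k)]
      pick_b <- sub_b[sample.int(n, k)]
      cidx <- c(pick_a, pick_b)
      if (odd) {
        extra_from_a <- stats::runif(1) < 0.5
        rest <- if (extra_from_a) setdiff(sub_a, pick_a) else setdiff(sub_b, pick_b)
        cidx <- c(cidx, rest[sample.int(length(rest), 1)])
      }
      wsum <- sum(W[cidx, cidx])
      if (need_valid && wsum == 0) next
      m_c <- sum(S0[cidx, cidx]) / wsum
      ref_a <- if (ref_full) g_a else masked_mean_sim(S0, W, sub_a)
      ref_b <- if (ref_full) g_b else masked_mean_sim(S0, W, sub_b)
      if (config$strict_gt) {
        count_a <- count_a + (m_c > ref_a)
        count_b <- count_b + (m_c > ref_b)
      } else {
        count_a <- count_a + (m_c >= ref_a)
        count_b <- count_b + (m_c >= ref_b)
      }
      done <- done + 1L
    }
    p <- function(count) {
      if (config$strict_gt) count / config$n_perm
      else (1 + count) / (config$n_perm + 1)
    }
    structure(list(p_a = p(count_a), p_b = p(count_b), g_a = g_a, g_b = g_b,
                   inter = inter, n = n, n_perm = config$n_perm, mode = mode,
                   testable = TRUE, reason = NA_character_),
              class = "distinguishability_test")
  })
}

#' @export
print.distinguishability_test <- function(x, ...) {
  cat("Group distinguishability permutation test (", x$mode, " mode)\n", sep = "")
  if (!x$testable) {
    cat("  not testable:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  n per group: %d, permutations: %d\n", x$n, x$n_perm))
  cat(sprintf("  G_A = %.4f  G_B = %.4f  inter = %.4f\n", x$g_a, x$g_b, x$inter))
  cat(sprintf("  p_A = %.4g  p_B = %.4g\n", x$p_a, x$p_b))
  invisible(x)
}

#' Language-level distinguishability test with ethnic-group correction
#'
#' As [distinguishability_test()], but pairs of individuals from the same
#' ethnic group are excluded from every similarity mean (within the language
#' groups, between them, and inside each permuted test group), so that
#' ethnic-group endogamy cannot masquerade as language-level structure.
#' Permutations whose test group contains fewer than two ethnic groups (so
#' no cross-ethnic pair exists) are redrawn. A language group containing a
#' single ethnic group is not testable and is returned as such.
#'
#' @inheritParams distinguishability_test
#' @param ethnic Named character vector (or data frame with `id`,
#'   `ethnic_group`) giving each individual's ethnic group.
#' @return A `distinguishability_test` object (`testable = FALSE` when the
#'   correction cannot be applied).
#' @export
language_test <- function(sim, members_a, members_b, ethnic,
                          config = perm_config()) {
  if (is.data.frame(ethnic)) {
    ethnic <- stats::setNames(as.character(ethnic$ethnic_group),
                              as.character(ethnic$id))
  }
  distinguishability_test(sim, members_a, members_b, config, ethnic = ethnic)
}

#' Run distinguishability tests for every pair of groups
#'
#' @param sim Similarity matrix.
#' @param grouping Named vector or data frame (`id`, `group`) assigning each
#'   individual to a group (ethnic group, or language classification in
#'   language mode).
#' @param config A [perm_config()].
#' @param mode `"ethnic"` (default) or `"language"`.
#' @param ethnic Required in language mode: id-to-ethnic-group mapping.
#' @return A tibble with one row per unordered group pair: `group_a`,
#'   `group_b`, `p_a`, `p_b`, `g_a`, `g_b`, `inter`, `n`, `mode`,
#'   `testable`. P-values are raw (no multiple-testing correction), reported
#'   for both conventional levels in `config$alpha`.
#' @export
all_pairs_tests <- function(sim, grouping, config = perm_config(),
                            mode = c("ethnic", "language"), ethnic = NULL) {
  mode <- match.arg(mode)
  groups <- as_group_vector(grouping, rownames(sim))
  if (mode == "language" && is.null(ethnic)) {
    abort("language mode needs an `ethnic` mapping")
  }
  if (is.data.frame(ethnic)) {
    ethnic <- stats::setNames(as.character(ethnic$ethnic_group),
                              as.character(ethnic$id))
  }
  glev <- sort(unique(unname(groups)))
  if (length(glev) < 2) {
    return(tibble(group_a = character(), group_b = character(),
                  p_a = double(), p_b = double(), g_a = double(),
                  g_b = double(), inter = double(), n = integer(),
                  mode = character(), testable = logical()))
  }
  combos <- utils::combn(glev, 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(j) {
    a <- combos[1, j]; b <- combos[2, j]
    ma <- names(groups)[groups == a & names(groups) %in% rownames(sim)]
    mb <- names(groups)[groups == b & names(groups) %in% rownames(sim)]
    res <- distinguishability_test(sim, ma, mb, config,
                                   ethnic = if (mode == "language") ethnic)
    tibble(group_a = a, group_b = b, p_a = res$p_a, p_b = res$p_b,
           g_a = res$g_a, g_b = res$g_b, inter = res$inter,
           n = as.integer(res$n), mode = res$mode, testable = res$testable)
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.distinguishability_test <- function(x, ...) {
  tibble(p_a = x$p_a, p_b = x$p_b, g_a = x$g_a, g_b = x$g_b,
         inter = x$inter, n = as.integer(x$n), n_perm = as.integer(x$n_perm),
         mode = x$mode, testable = x$testable)
}
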