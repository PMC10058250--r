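test_that("degenerate identical profiles give p = 1 under the tie rule", {
  prof <- matrix(rep(c(0.5, 0.5), 10), ncol = 2, byrow = TRUE)
  S <- sim_from_profiles(prof, paste0("i", 1:10))
  res <- distinguishability_test(S, paste0("i", 1:5), paste0("i", 6:10),
                                 perm_config(n_perm = 200, seed = 1))
  expect_equal(res$p_a, 1)
  expect_equal(res$p_b, 1)
  expect_equal(res$g_a, 1)
  expect_equal(res$inter, 1)
  # the literal strict-> rule gives 0 on the same degenerate data
  strict <- distinguishability_test(S, paste0("i", 1:5), paste0("i", 6:10),
                                    perm_config(n_perm = 200, seed = 1,
                                                strict_gt = TRUE))
  expect_equal(strict$p_a, 0)
})

test_that("well-separated groups are distinguishable in both directions", {
  cfg <- synth_config(dplyr::bind_rows(
    synth_group("A", 20, 0, 0, c(0.7, 0.2, 0.1), concentration = 200),
    synth_group("B", 20, 0, 5, c(0.2, 0.2, 0.6), concentration = 200)),
    seed = 21)
  co <- generate_cohort(cfg)
  S <- similarity_matrix(aggregate_to_groups(generate_copying_matrix(co, cfg)))
  res <- distinguishability_test(S, co$id[co$group == "A"],
                                 co$id[co$group == "B"],
                                 perm_config(n_perm = 2000, seed = 9))
  expect_lt(res$p_a, 0.001)
  expect_lt(res$p_b, 0.001)
  expect_equal(res$n, 20)
})

test_that("comparing a group against itself is never significant", {
  cfg <- three_group_config(seed = 31, n = 12)
  co <- generate_cohort(cfg)
  S <- similarity_matrix(aggregate_to_groups(generate_copying_matrix(co, cfg)))
  ids <- co$id[co$group == "A"]
  res <- distinguishability_test(S, ids, ids,
                                 perm_config(n_perm = 500, seed = 5))
  expect_gt(res$p_a, 0.01)
  expect_gt(res$p_b, 0.01)
})

test_that("results are reproducible and order-independent via substreams", {
  cfg <- three_group_config(seed = 41, n = 8)
  co <- generate_cohort(cfg)
  S <- similarity_matrix(aggregate_to_groups(generate_copying_matrix(co, cfg)))
  a <- co$id[co$group == "A"]; b <- co$id[co$group == "B"]
  pc <- perm_config(n_perm = 300, seed = 99)
  r1 <- distinguishability_test(S, a, b, pc)
  # run an unrelated comparison in between; substreams make this a no-op
  distinguishability_test(S, a, co$id[co$group == "C"], pc)
  r2 <- distinguishability_test(S, a, b, pc)
  expect_identical(tidy(r1), tidy(r2))
})

test_that("unequal group sizes are downsampled to n = min(na, nb)", {
  cfg <- synth_config(dplyr::bind_rows(
    synth_group("A", 9, 0, 0, c(0.5, 0.5), concentration = 40),
    synth_group("B", 21, 0, 1, c(0.5, 0.5), concentration = 40)),
    seed = 3)
  co <- generate_cohort(cfg)
  S <- similarity_matrix(aggregate_to_groups(generate_copying_matrix(co, cfg)))
  res <- distinguishability_test(S, co$id[co$group == "A"],
                                 co$id[co$group == "B"],
                                 perm_config(n_perm = 300, seed = 2))
  expect_equal(res$n, 9)  # odd n exercises the (n-1)/2 + 1 rule
  expect_true(res$p_a > 0 && res$p_a <= 1)
})

test_that("language test refuses single-ethnic-group languages", {
  prof <- matrix(rep(c(0.5, 0.5), 8), ncol = 2, byrow = TRUE)
  S <- sim_from_profiles(prof, paste0("i", 1:8))
  eth <- stats::setNames(rep(c("E1", "E1", "E2", "E2"), 2), paste0("i", 1:8))
  # language A = all E1 -> not testable
  res <- language_test(S, paste0("i", c(1, 2, 5)), paste0("i", c(3, 4, 7)),
                       stats::setNames(rep("E1", 8), paste0("i", 1:8)),
                       perm_config(n_perm = 100, seed = 1))
  expect_false(res$testable)
  expect_true(is.na(res$p_a))
  # two languages x two ethnic groups with identical profiles: p = 1
  langA <- paste0("i", 1:4); langB <- paste0("i", 5:8)
  res2 <- language_test(S, langA, langB, eth,
                        perm_config(n_perm = 200, seed = 1))
  expect_true(res2$testable)
  expect_equal(res2$p_a, 1)
})

test_that("ethnic-group correction removes an endogamy confound", {
  cc <- make_endogamy_confound(7)
  corrected <- language_test(cc$S, cc$langA, cc$langB, cc$eth,
                             perm_config(n_perm = 400, seed = 11))
  uncorrected <- distinguishability_test(cc$S, cc$langA, cc$langB,
                                         perm_config(n_perm = 400, seed = 11))
  expect_gt(corrected$p_a, 0.01)
  expect_lt(uncorrected$p_a, 0.01)
})

test_that("asymmetric design: homogeneous A significant, heterogeneous B not", {
  set.seed(13)
  # A: tight cluster; B: very diverse. Mixing B into C lowers mean similarity
  # below G_A (A significant); mixing A into C raises it above G_B.
  k <- 4
  profA <- t(replicate(12, {
    x <- c(100, 1, 1, 1) + stats::rgamma(k, 2); x / sum(x)
  }))
  profB <- t(replicate(12, random_simplex(k)))
  ids <- sprintf("x%02d", 1:24)
  S <- sim_from_profiles(rbind(profA, profB), ids)
  res <- distinguishability_test(S, ids[1:12], ids[13:24],
                                 perm_config(n_perm = 1000, seed = 17))
  expect_lt(res$p_a, 0.01)
  expect_gt(res$p_b, 0.05)
})

test_that("all_pairs_tests runs every unordered pair and empty cases", {
  cfg <- three_group_config(seed = 61, n = 6)
  co <- generate_cohort(cfg)
  S <- similarity_matrix(aggregate_to_groups(generate_copying_matrix(co, cfg)))
  res <- all_pairs_tests(S, tibble::tibble(id = co$id, group = co$group),
                         perm_config(n_perm = 100, seed = 1))
  expect_equal(nrow(res), 3)
  expect_setequal(paste(res$group_a, res$group_b),
                  c("A B", "A C", "B C"))
  one <- all_pairs_tests(S[co$group == "A", co$group == "A"],
                         tibble::tibble(id = co$id[co$group == "A"],
                                        group = co$group[co$group == "A"]),
                         perm_config(n_perm = 50, seed = 1))
  expect_equal(nrow(one), 0)
})
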