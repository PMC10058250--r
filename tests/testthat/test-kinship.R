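make_kinship <- function(ids, values) {
  pr <- t(utils::combn(ids, 2))
  tibble::tibble(ID1 = pmin(pr[, 1], pr[, 2]), ID2 = pmax(pr[, 1], pr[, 2]),
                 PI_HAT = values)
}

test_that("within-population statistics match direct formula evaluation", {
  # 5 within-population pairs -> 4 individuals in one population
  ids <- paste0("i", 1:4)
  kin <- make_kinship(ids, c(0.01, 0.02, 0.03, 0.04, 0.05, 0.03))
  # use only the first five pairs' values for the worked check
  kin5 <- kin[1:5, ]
  vals <- kin5$PI_HAT
  pops <- meta_for(ids, rep("P", 4))
  st <- kinship_stats(kin5, pops, pruning_config(mad_scale = 1))
  expect_equal(st$mean, mean(vals))
  expect_equal(st$median, stats::median(vals))
  expect_equal(st$sd, stats::sd(vals))
  expect_equal(st$mad, stats::mad(vals, constant = 1))
  # the spec's worked numbers for {0.01 ... 0.05}
  st2 <- kinship_stats(make_kinship(paste0("j", 1:4), rep(0.03, 6))[1:5, ] |>
                         dplyr::mutate(PI_HAT = c(0.01, 0.02, 0.03, 0.04, 0.05)),
                       meta_for(paste0("j", 1:4), rep("Q", 4)),
                       pruning_config(mad_scale = 1))
  expect_equal(st2$mean, 0.03)
  expect_equal(st2$median, 0.03)
  expect_equal(st2$sd, sqrt(sum((c(0.01, 0.02, 0.03, 0.04, 0.05) - 0.03)^2) / 4))
  expect_equal(st2$mad, 0.01)
})

test_that("constant PI_HAT gives zero spread; tiny populations are undefined", {
  ids <- paste0("c", 1:4)
  kin <- make_kinship(ids, rep(0.05, 6))
  st <- kinship_stats(kin, meta_for(ids, rep("P", 4)))
  expect_equal(st$sd, 0)
  expect_equal(st$mad, 0)
  expect_true(st$defined)

  two <- make_kinship(c("a1", "a2"), 0.2)
  st2 <- kinship_stats(two, meta_for(c("a1", "a2"), c("T", "T")))
  expect_false(st2$defined)
  expect_true(is.na(st2$sd))
})

test_that("outlier flagging reproduces the hand-computed threshold", {
  # two populations engineered to X = Y = 0.02 and S, D <= 0.02 so the
  # four-way minimum is 0.02 + 3 * 0.02 = 0.08
  idsP <- paste0("p", 1:4); idsQ <- paste0("q", 1:4)
  pops <- meta_for(c(idsP, idsQ), rep(c("P", "Q"), each = 4))
  within_vals <- c(0.01, 0.015, 0.02, 0.02, 0.025, 0.03)  # mean=median=0.02
  pr <- rbind(t(utils::combn(idsP, 2)), t(utils::combn(idsQ, 2)))
  kin <- tibble::tibble(ID1 = pr[, 1], ID2 = pr[, 2],
                        PI_HAT = rep(within_vals, 2))
  cross <- tibble::tibble(ID1 = c("p1", "p2", "p3"), ID2 = c("q1", "q2", "q3"),
                          PI_HAT = c(0.20, 0.14, 0.16))
  kin <- dplyr::bind_rows(kin, cross)
  st <- kinship_stats(kin, pops)
  expect_equal(st$mean, c(0.02, 0.02))
  expect_true(all(st$sd <= 0.02 & st$mad <= 0.02))
  flagged <- flag_outlier_pairs(kin, pops)
  expect_equal(flagged$threshold, c(0.08, 0.08))
  # 0.20 and 0.16 exceed both 0.15 and 0.08; 0.14 is below the base threshold
  expect_setequal(flagged$PI_HAT, c(0.20, 0.16))
  expect_true(all(flagged$rule == "formula"))
})

test_that("pairs below the base threshold are never flagged", {
  ids <- paste0("x", 1:6)
  set.seed(1)
  kin <- make_kinship(ids, runif(15, 0, 0.14))
  flagged <- flag_outlier_pairs(kin, meta_for(ids, rep("P", 6)))
  expect_equal(nrow(flagged), 0)
})

test_that("small populations use the absolute rule", {
  ids <- c("s1", paste0("big", 1:5))
  pops <- meta_for(ids, c("Solo", rep("Big", 5)))
  kin <- make_kinship(ids, c(0.16, rep(0.01, 4), rep(0.02, 10)))
  flagged <- flag_outlier_pairs(kin, pops)
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$rule, "small_population")
  expect_equal(flagged$PI_HAT, 0.16)
})

test_that("greedy pruning follows the stepwise most-pairs rule", {
  f1 <- tibble::tibble(ID1 = c("a", "a", "d"), ID2 = c("b", "c", "e"))
  r1 <- greedy_prune(f1)
  expect_equal(r1$removed, c("a", "d"))
  f2 <- tibble::tibble(ID1 = c("a", "b"), ID2 = c("b", "c"))
  r2 <- greedy_prune(f2)
  expect_equal(r2$removed, "b")
  r3 <- greedy_prune(tibble::tibble(ID1 = character(), ID2 = character()))
  expect_equal(r3$removed, character())
})

test_that("greedy removal is a valid cover, bounded by the exact optimum", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    ids <- sprintf("v%02d", 1:n)
    m <- sample(2:min(12, n * (n - 1) / 2), 1)
    pr <- t(utils::combn(ids, 2))
    pick <- sample(nrow(pr), m)
    pairs <- tibble::tibble(ID1 = pr[pick, 1], ID2 = pr[pick, 2])
    res <- greedy_prune(pairs)
    expect_true(is_vertex_cover(pairs, res$removed))
    opt <- brute_force_vertex_cover(pairs)
    expect_gte(length(res$removed), opt)
    expect_lte(length(res$removed), nrow(pairs))
  }
})

test_that("duplicate resolution removes one member and reports discordance", {
  ids <- c("d1", "d2", "d3", "d4")
  meta <- tibble::tibble(id = ids,
                         ethnic_group = c("E1", "E1", "E2", "E3"),
                         self_lat = c(0, 0, 5, 5), self_lon = c(0, 0, 8, 8))
  kin <- tibble::tibble(ID1 = c("d1", "d3", "d1"), ID2 = c("d2", "d4", "d3"),
                        PI_HAT = c(0.99, 0.99, 0.05))
  res <- resolve_duplicates(kin, meta, pruning_config(), seed = 3)
  expect_equal(nrow(res$report), 2)
  expect_equal(res$report$metadata_discordant, c(FALSE, TRUE))
  expect_length(res$removed, 2)
  # discordant pair's survivor is excluded from metadata analyses
  expect_equal(res$metadata_excluded,
               res$report$kept[res$report$metadata_discordant])
  # seeded: same seed, same choice
  res2 <- resolve_duplicates(kin, meta, pruning_config(), seed = 3)
  expect_identical(res$removed, res2$removed)
  none <- resolve_duplicates(kin[3, ], meta, pruning_config(), seed = 3)
  expect_length(none$removed, 0)
})

test_that("full chain leaves no flagged pair intact and honours the 0.18 pass", {
  set.seed(11)
  for (rep in 1:20) {
    cfg <- three_group_config(
      seed = rep, n = 8,
      relative_pairs = tibble::tibble(
        relationship = c("duplicate", "parent-offspring", "half-sib"),
        count = c(1L, 2L, 1L)))
    co <- generate_cohort(cfg)
    kin <- generate_kinship_table(co, cfg)
    pr <- prune_related(kin, co, pruning_config(), seed = rep)
    kept <- kin[!(kin$ID1 %in% pr$removed$id | kin$ID2 %in% pr$removed$id), ]
    refl <- flag_outlier_pairs(kept, co,
                               stats = kinship_stats(kin, co))
    # re-scan with the original population statistics: no flagged pair intact
    expect_equal(nrow(refl), 0)
    expect_true(all(kept$PI_HAT <= 0.18))
  }
})

test_that("kinship table validation rejects malformed input", {
  expect_error(check_kinship_table(
    tibble::tibble(ID1 = "a", ID2 = "a", PI_HAT = 0.1)), "self")
  expect_error(check_kinship_table(
    tibble::tibble(ID1 = c("a", "b"), ID2 = c("b", "a"), PI_HAT = c(0.1, 0.1))),
    "once")
  expect_error(check_kinship_table(
    tibble::tibble(ID1 = "a", ID2 = "b", PI_HAT = 1.2)), "PI_HAT")
})
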