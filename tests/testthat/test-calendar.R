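test_that("generations-to-year conversion matches the worked cases", {
  expect_equal(generations_to_year(0), 1940)
  expect_equal(generations_to_year(44), 708)
  expect_equal(generations_to_year(100), -860)
  expect_equal(format_year(-860), "861 BCE")
  expect_equal(format_year(708), "708 CE")
  expect_equal(format_year(0), "1 BCE")
  expect_error(generations_to_year(-1), "nonnegative")
  # strictly decreasing and invertible
  g <- seq(0, 250, by = 0.5)
  y <- generations_to_year(g)
  expect_true(all(diff(y) < 0))
  expect_equal(year_to_generations(y), g, tolerance = 1e-12)
})

test_that("SE-based confidence intervals are built and truncated", {
  ci <- ci_from_se(50, 10)
  expect_equal(c(ci$ci_low, ci$ci_high), c(30.4, 69.6))
  expect_equal(ci$year_low, generations_to_year(69.6))
  zero <- ci_from_se(12, 0)
  expect_equal(c(zero$ci_low, zero$ci_high), c(12, 12))
  trunc <- ci_from_se(5, 10)
  expect_equal(trunc$ci_low, 0)
  expect_error(ci_from_se(5, -1), "nonnegative")
})

quality_fixture <- function() {
  tibble::tibble(
    method = c("fastGLOBETROTTER", "fastGLOBETROTTER", "MOSAIC", "MOSAIC",
               "MALDER", "MALDER", "MALDER", "MOSAIC"),
    target = "T",
    g = c(20, 25, 30, 35, 40, 203, 45, 50),
    ci_low = c(15, 20, 25, 30, NA, NA, NA, 45),
    ci_high = c(25, 30, 35, 40, NA, NA, NA, 55),
    se = c(NA, NA, NA, NA, 5, 5, 5, NA),
    max_r2fit_1date = c(0.7, 0.4, NA, NA, NA, NA, NA, NA),
    r2 = c(NA, NA, 0.6, 0.6, NA, NA, NA, NA),
    rst = c(NA, NA, 0.05, 0.005, NA, NA, NA, 0.05),
    p_value = c(NA, NA, NA, NA, 0.001, 0.001, 0.05, NA))
}

test_that("method-specific quality filters reject the documented cases", {
  res <- apply_quality_filters(quality_fixture())
  expect_equal(res$rejected$g, c(25, 35, 203, 45, 50))
  expect_equal(res$rejected$reason,
               c("gt_fit", "mosaic_rst", "malder_age", "malder_p",
                 "incomplete"))
  expect_equal(res$retained$g, c(20, 30, 40))
})

test_that("disabling one filter rule retains exactly its rejections", {
  fx <- quality_fixture()
  base <- apply_quality_filters(fx)
  for (rule in c("gt_fit", "mosaic_rst", "malder_p", "malder_age")) {
    relaxed <- apply_quality_filters(fx, skip_rules = rule)
    gained <- setdiff(relaxed$retained$g, base$retained$g)
    only_this <- base$rejected$g[base$rejected$reason == rule]
    expect_setequal(gained, only_this)
  }
})

test_that("two-event calls need disjoint date AND amplitude intervals", {
  mk <- function(d1, d2, a1, a2) {
    tibble::tibble(ci_low = c(d1[1], d2[1]), ci_high = c(d1[2], d2[2]),
                   amp_ci_low = c(a1[1], a2[1]), amp_ci_high = c(a1[2], a2[2]))
  }
  both <- mk(c(5, 15), c(40, 60), c(0.01, 0.02), c(0.05, 0.08))
  expect_equal(detect_two_events(both)$classification, "two-events")
  amp_overlap <- mk(c(5, 15), c(40, 60), c(0.01, 0.05), c(0.04, 0.08))
  expect_equal(detect_two_events(amp_overlap)$classification, "one-event")
  date_overlap <- mk(c(5, 45), c(40, 60), c(0.01, 0.02), c(0.05, 0.08))
  expect_equal(detect_two_events(date_overlap)$classification, "one-event")
  single <- both[1, ]
  expect_equal(detect_two_events(single)$classification, "one-event")
})

test_that("interval unions merge overlaps and report the hull", {
  u <- union_ci(tibble::tibble(lower = c(-10, 200), upper = c(840, 900)))
  expect_equal(nrow(u$intervals), 1)
  expect_equal(c(u$intervals$lower, u$intervals$upper), c(-10, 900))
  u2 <- union_ci(tibble::tibble(lower = c(0, 20), upper = c(10, 30)))
  expect_equal(nrow(u2$intervals), 2)
  expect_equal(u2$hull, c(0, 30))
  u3 <- union_ci(tibble::tibble(lower = 5, upper = 9))
  expect_equal(c(u3$intervals$lower, u3$intervals$upper), c(5, 9))
  expect_error(union_ci(tibble::tibble(lower = 3, upper = 1)), "lower")
})

test_that("interval union matches a rasterised oracle on integer grids", {
  set.seed(808)
  for (rep in 1:50) {
    k <- sample(1:6, 1)
    lo <- sample(0:50, k, replace = TRUE)
    hi <- lo + sample(0:15, k, replace = TRUE)
    u <- union_ci(tibble::tibble(lower = lo, upper = hi))
    grid <- 0:70
    covered_in <- vapply(grid, function(x) any(x >= lo & x <= hi), logical(1))
    covered_out <- vapply(grid, function(x)
      any(x >= u$intervals$lower & x <= u$intervals$upper), logical(1))
    expect_identical(covered_out, covered_in)
    # merged intervals are pairwise disjoint
    if (nrow(u$intervals) > 1) {
      expect_true(all(u$intervals$lower[-1] >
                        u$intervals$upper[-nrow(u$intervals)]))
    }
  }
})

test_that("cross-method agreement uses the 3-generation gap rule", {
  ev <- tibble::tibble(method = c("fastGLOBETROTTER", "MALDER"),
                       ci_low = c(10, 42), ci_high = c(40, 60))
  out <- classify_agreement(ev)
  expect_equal(out$min_gap, c(2, 2))
  expect_equal(out$agreement, rep("concordant", 2))
  ev2 <- tibble::tibble(method = c("fastGLOBETROTTER", "MALDER"),
                        ci_low = c(10, 50), ci_high = c(40, 60))
  out2 <- classify_agreement(ev2)
  expect_equal(out2$min_gap, c(10, 10))
  expect_equal(out2$agreement, rep("single-method-outlier", 2))
  ev3 <- tibble::tibble(method = c("fastGLOBETROTTER", "MALDER"),
                        ci_low = c(10, 30), ci_high = c(40, 60))
  expect_equal(classify_agreement(ev3)$agreement, rep("concordant", 2))
})

test_that("harmonisation builds MALDER CIs, years and per-target unions", {
  fx <- quality_fixture()
  h <- harmonize_admixture_dates(fx)
  expect_equal(nrow(h$events), 3)
  ma <- h$events[h$events$method == "MALDER", ]
  expect_equal(c(ma$ci_low, ma$ci_high), c(40 - 1.96 * 5, 40 + 1.96 * 5))
  expect_equal(h$events$year, generations_to_year(h$events$g))
  expect_equal(nrow(h$by_target), 1)
  expect_equal(h$by_target$hull_low_gen, 15)
  expect_equal(h$by_target$hull_high_gen, 40 + 1.96 * 5)
})
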