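test_that("schedules encode the expansion-bottleneck-expansion structure", {
  s <- ne_schedule(ancestral = 5000, expansion1 = 20000,
                   bottleneck = 2000, expansion2 = 30000)
  expect_equal(s$start_gen_ago, c(0, 25, 50, 100))
  expect_equal(s$ne, c(30000, 2000, 20000, 5000))
  # epoch lookup: generation 10 ago is in the second expansion, 30 in the
  # bottleneck, 60 in the first expansion, 150 ancestral
  expect_equal(paintpop:::ne_at_generation(s, c(10, 30, 60, 150)),
               c(30000, 2000, 20000, 5000))
  flat <- ne_schedule(1000, 1000, 1000, 1000)
  expect_equal(unique(flat$ne), 1000)
  expect_error(ne_schedule(5000, 2, 2, 2, times = c(25, 25, 100)), "increasing")
  expect_error(ne_schedule(5000, 1, 2000, 30000), ">= 2")
  expect_error(build_schedule(tibble::tibble(start_gen_ago = c(5, 10),
                                             ne = c(10, 10))), "begin at 0")
})

test_that("drift is negligible at huge Ne and absorption is permanent", {
  s <- build_schedule(tibble::tibble(start_gen_ago = 0, ne = 1e6))
  sim <- simulate_frequencies(s, 1000, init = rep(0.3, 1000),
                              n_generations = 10, seed = 5)
  expect_lt(mean(abs(sim$freq - 0.3)), 0.01)
  zero <- simulate_frequencies(s, 50, init = rep(0, 50), n_generations = 5,
                               seed = 6)
  expect_true(all(zero$freq == 0))
})

test_that("fixation probability approximates the initial frequency", {
  s <- build_schedule(tibble::tibble(start_gen_ago = 0, ne = 25))
  sim <- simulate_frequencies(s, 4000, init = rep(0.1, 4000),
                              n_generations = 600, seed = 7)
  fixed <- mean(sim$freq == 1)
  lost <- mean(sim$freq == 0)
  expect_gt(fixed + lost, 0.999)  # essentially everything absorbed
  se <- sqrt(0.1 * 0.9 / 4000)
  expect_lt(abs(fixed - 0.1), 4 * se)
})

test_that("frequency trajectories are martingales under any schedule", {
  s <- ne_schedule(500, 2000, 100, 3000)
  sim <- simulate_frequencies(s, 10000, seed = 8)
  mc_se <- stats::sd(sim$freq) / sqrt(length(sim$freq))
  expect_lt(abs(mean(sim$freq) - mean(sim$init)), 3 * mc_se)
  # genotype sample has the right shape and support
  sim2 <- simulate_frequencies(s, 100, n_sample = 20, seed = 9)
  expect_equal(dim(sim2$genotypes), c(100, 20))
  expect_true(all(sim2$genotypes %in% 0:2))
})

test_that("MAF histogram folds, bins and flags monomorphic sites", {
  h <- maf_histogram(c(0.01, 0.07, 0.49))
  expect_equal(h$count[1:2], c(1L, 1L))
  expect_equal(h$count[10], 1L)
  expect_equal(sum(h$count), 3L)
  # folding symmetry
  set.seed(12)
  p <- runif(500)
  expect_equal(maf_histogram(p)$count, maf_histogram(1 - p)$count)
  # top bin closed at 0.5
  expect_equal(maf_histogram(0.5)$count[10], 1L)
  # empty input and monomorphic flags
  empty <- maf_histogram(numeric(0))
  expect_equal(sum(empty$count), 0L)
  mono <- maf_histogram(c(0, 1, 0.2))
  expect_equal(attr(mono, "n_monomorphic"), 2L)
  expect_equal(mono$count[1], 2L)
  expect_error(maf_histogram(1.2), "0, 1")
})

test_that("downsampling matches the target histogram exactly when feasible", {
  set.seed(21)
  p <- runif(2000)
  target <- maf_histogram(runif(300))
  keep <- downsample_to_match(p, target, seed = 3)
  expect_true(all(keep %in% seq_along(p)))      # subset property
  expect_false(any(duplicated(keep)))
  got <- maf_histogram(p[keep])
  expect_identical(got$count, target$count)
  # exact example: five variants, two bins requested
  p5 <- c(0.01, 0.02, 0.03, 0.07, 0.08)
  tgt <- maf_histogram(c(0.01, 0.02, 0.06))
  k5 <- downsample_to_match(p5, tgt, seed = 1)
  expect_equal(sum(p5[k5] < 0.05), 2)
  expect_equal(sum(p5[k5] >= 0.05), 1)
})

test_that("infeasible targets are scaled by the largest common factor", {
  p <- c(0.01, 0.02, 0.26, 0.27, 0.28, 0.29)  # 2 in bin 1, 4 in bin 6
  tgt <- maf_histogram(c(rep(0.01, 4), rep(0.26, 4)))  # wants 4 + 4
  expect_warning(keep <- downsample_to_match(p, tgt, seed = 2), "scaled")
  got <- maf_histogram(p[keep])
  # scale = min(2/4, 4/4) = 0.5 -> targets floor to 2 and 2
  expect_equal(got$count[c(1, 6)], c(2L, 2L))
  expect_error(downsample_to_match(p, maf_histogram(numeric(0))), "all zero")
})

test_that("stronger bottlenecks lose more heterozygosity", {
  het <- vapply(c(2000, 200, 20), function(ne_b) {
    s <- ne_schedule(5000, 5000, ne_b, 5000)
    sim <- simulate_frequencies(s, 4000, init = rep(0.2, 4000), seed = 31)
    expected_heterozygosity(sim$freq)
  }, numeric(1))
  expect_true(all(diff(het) < 0))
})

test_that("VCF round trip: frequencies, histogram match, downsampling", {
  # write a small VCF by hand
  tmp <- tempfile(fileext = ".vcf")
  n_ind <- 20; n_var <- 120
  set.seed(41)
  p <- runif(n_var, 0.05, 0.95)
  gt <- vapply(seq_len(n_ind), function(i) {
    g <- rbinom(n_var, 2, p)
    c("0/0", "0/1", "1/1")[g + 1]
  }, character(n_var))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sprintf("s%02d", 1:n_ind)),
                    collapse = "\t"))
  body <- vapply(seq_len(n_var), function(v) {
    paste(c("1", v * 100, sprintf("rs%d", v), "A", "G", ".", "PASS", ".",
            "GT", gt[v, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), tmp)

  freqs <- maf_from_vcf(tmp)
  expect_length(freqs, n_var)
  expect_true(all(freqs >= 0 & freqs <= 1))
  tgt <- maf_histogram(freqs)
  tgt$count <- pmax(0L, tgt$count - 2L)  # ask for a feasible sub-histogram
  out <- tempfile(fileext = ".vcf.gz")
  keep <- downsample_vcf(tmp, out, tgt, seed = 5)
  expect_equal(length(keep), sum(tgt$count))
  back <- maf_from_vcf(out)
  expect_identical(maf_histogram(back)$count, tgt$count)
  unlink(c(tmp, out))
})
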