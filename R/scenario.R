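#' Piecewise-constant effective population size schedule
#'
#' Encodes the expansion-bottleneck-expansion scenario: a first expansion
#' beginning 100 generations ago, a bottleneck beginning 50 generations ago
#' and a second expansion beginning 25 generations ago, each with its own
#' diploid effective size. Epochs are stored most recent first as
#' (start generations-ago, Ne) pairs; the epoch starting at the largest time
#' extends indefinitely into the past.
#'
#' @param ancestral Ne before the first expansion.
#' @param expansion1 Ne from 100 to 50 generations ago.
#' @param bottleneck Ne from 50 to 25 generations ago.
#' @param expansion2 Ne from 25 generations ago to the present.
#' @param times Epoch change times in generations ago, most recent first
#'   (default `c(25, 50, 100)`); must be strictly increasing and distinct.
#' @return A tibble of class `ne_schedule` with columns `start_gen_ago`,
#'   `ne`, rows ordered most recent first (start 0 = present epoch).
#' @export
ne_schedule <- function(ancestral, expansion1, bottleneck, expansion2,
                        times = c(25, 50, 100)) {
  ne <- c(expansion2, bottleneck, expansion1, ancestral)
  if (any(ne < 2)) abort("every Ne must be >= 2")
  if (length(times) != 3 || anyDuplicated(times) || any(diff(times) <= 0)) {
    abort("`times` must be three strictly increasing change points")
  }
  structure(tibble(start_gen_ago = c(0, times), ne = as.numeric(ne)),
            class = c("ne_schedule", "tbl_df", "tbl", "data.frame"))
}

#' Build a schedule from explicit epochs
#'
#' @param epochs Tibble with columns `start_gen_ago` (first value 0,
#'   strictly increasing) and `ne`.
#' @return An `ne_schedule`.
#' @export
build_schedule <- function(epochs) {
  if (!all(c("start_gen_ago", "ne") %in% names(epochs))) {
    abort("epochs need columns start_gen_ago and ne")
  }
  if (epochs$start_gen_ago[1] != 0 || any(diff(epochs$start_gen_ago) <= 0)) {
    abort("epoch start times must begin at 0 and increase strictly")
  }
  if (any(epochs$ne < 2)) abort("every Ne must be >= 2")
  structure(as_tibble(epochs[c("start_gen_ago", "ne")]),
            class = c("ne_schedule", "tbl_df", "tbl", "data.frame"))
}

ne_at_generation <- function(schedule, gen_ago) {
  idx <- findInterval(gen_ago, schedule$start_gen_ago)
  schedule$ne[idx]
}

#' Simulate allele-frequency drift under a piecewise-Ne Wright-Fisher model
#'
#' Each variant's frequency is resampled binomially every generation with
#' the epoch's 2Ne gene copies, from `n_generations` ago forward to the
#' present. Frequencies absorbed at 0 or 1 stay absorbed. Optionally draws a
#' diploid genotype sample from the final frequencies.
#'
#' @param schedule An [ne_schedule()].
#' @param n_variants Number of independent variants.
#' @param init Initial frequencies: a numeric vector (recycled), or a
#'   function of `n` returning one (default `runif(n, 0.05, 0.95)`).
#' @param n_generations Generations simulated (default: the oldest epoch
#'   start time).
#' @param n_sample Diploid individuals to draw at the end (default 0: none).
#' @param seed Integer seed (optional).
#' @return A list: `freq` (final frequencies), `init` (initial frequencies),
#'   `genotypes` (`n_variants x n_sample` matrix of 0/1/2, or `NULL`).
#' @export
simulate_frequencies <- function(schedule, n_variants,
                                 init = function(n) stats::runif(n, 0.05, 0.95),
                                 n_generations = NULL, n_sample = 0,
                                 seed = NULL) {
  stopifnot(inherits(schedule, "ne_schedule"))
  if (is.null(n_generations)) n_generations <- max(schedule$start_gen_ago)
  with_seed(seed, {
    p0 <- if (is.function(init)) init(n_variants) else rep_len(init, n_variants)
    if (any(p0 < 0 | p0 > 1)) abort("initial frequencies must lie in [0, 1]")
    p <- p0
    if (n_generations >= 1) {
      for (t in seq(n_generations, 1)) {
        two_ne <- round(2 * ne_at_generation(schedule, t - 1))
        p <- stats::rbinom(n_variants, two_ne, p) / two_ne
      }
    }
    genotypes <- NULL
    if (n_sample > 0) {
      genotypes <- matrix(stats::rbinom(n_variants * n_sample, 2, rep(p, n_sample)),
                          nrow = n_variants)
    }
    list(freq = p, init = p0, genotypes = genotypes)
  })
}

#' Minor-allele-frequency histogram with 0.05-wide bins
#'
#' Folds frequencies to `MAF = min(p, 1 - p)` and counts variants in the
#' bins [0, 0.05), [0.05, 0.10), ..., [0.45, 0.5]; the final bin is closed
#' so MAF exactly 0.5 is counted. Monomorphic sites (MAF 0) land in the
#' first bin and their count is reported separately.
#'
#' @param p Allele frequencies in [0, 1] (may be empty).
#' @param bin_width Bin width (default 0.05).
#' @return An object of class `maf_histogram`: tibble with columns
#'   `bin_low`, `bin_high`, `count`, plus attribute `n_monomorphic`.
#' @export
maf_histogram <- function(p, bin_width = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("frequencies must lie in [0, 1]")
  maf <- pmin(p, 1 - p)
  breaks <- seq(0, 0.5, by = bin_width)
  idx <- pmin(findInterval(maf, breaks), length(breaks) - 1)  # close top bin
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  out <- tibble(bin_low = utils::head(breaks, -1),
                bin_high = utils::tail(breaks, -1),
                count = as.integer(counts))
  attr(out, "n_monomorphic") <- sum(maf == 0, na.rm = TRUE)
  class(out) <- c("maf_histogram", class(out))
  out
}

maf_bin_index <- function(maf, bin_width = 0.05) {
  breaks <- seq(0, 0.5, by = bin_width)
  pmin(findInterval(maf, breaks), length(breaks) - 1)
}

#' Downsample variants to match a target MAF histogram
#'
#' Within each minor-allele-frequency bin, retains a uniform random subset
#' of exactly the target count. When some bin has fewer variants than its
#' target, all bin targets are scaled by the largest feasible common factor
#' (so relative bin proportions are preserved) and a warning is raised.
#'
#' @param p Allele frequencies of the candidate variants.
#' @param target A [maf_histogram()] (or tibble with `count` per bin).
#' @param seed Integer seed (optional).
#' @param bin_width Bin width matching the target (default 0.05).
#' @return Integer vector of retained variant indices (sorted).
#' @export
downsample_to_match <- function(p, target, seed = NULL, bin_width = 0.05) {
  counts <- target$count
  if (sum(counts) == 0) abort("target histogram is all zero")
  idx <- maf_bin_index(pmin(p, 1 - p), bin_width)
  avail <- tabulate(idx, nbins = length(counts))
  scale <- 1
  short <- counts > avail
  if (any(short)) {
    scale <- min(avail[counts > 0] / counts[counts > 0])
    counts <- floor(counts * scale)
    warn(sprintf(
      "target infeasible in %d bin(s); all bin targets scaled by %.3f",
      sum(short), scale))
  }
  with_seed(seed, {
    keep <- unlist(lapply(which(counts > 0), function(b) {
      cand <- which(idx == b)
      cand[sample.int(length(cand), counts[b])]
    }))
    sort(as.integer(keep))
  })
}

#' Allele frequencies from a VCF
#'
#' Reads a (biallelic, GT-field) VCF and returns alternate-allele
#' frequencies, for feeding [maf_histogram()] and [downsample_to_match()]
#' with output from an external simulation engine.
#'
#' @param path VCF file path.
#' @return Numeric vector of ALT allele frequencies, one per site.
#' @export
maf_from_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- apply(gt, 1, function(row) {
    alleles <- unlist(strsplit(row[!is.na(row)], "[/|]"))
    alleles <- alleles[alleles %in% c("0", "1")]
    if (!length(alleles)) return(NA_real_)
    mean(alleles == "1")
  })
  unname(alt)
}

#' Downsample a VCF to match a target MAF histogram
#'
#' @param path_in,path_out Input and output VCF paths (output is written
#'   gzipped by `vcfR`).
#' @inheritParams downsample_to_match
#' @return Invisibly, the retained row indices.
#' @export
downsample_vcf <- function(path_in, path_out, target, seed = NULL,
                           bin_width = 0.05) {
  v <- vcfR::read.vcfR(path_in, verbose = FALSE)
  p <- maf_from_vcf(path_in)
  keep <- downsample_to_match(p, target, seed = seed, bin_width = bin_width)
  out <- v[keep, ]
  vcfR::write.vcf(out, file = path_out)
  invisible(keep)
}

#' Expected heterozygosity of a frequency set
#'
#' `mean(2 p (1 - p))`; drops `NA`s. Convenience summary for comparing drift
#' severity across schedules.
#'
#' @param p Allele frequencies.
#' @return A single number.
#' @export
expected_heterozygosity <- function(p) {
  mean(2 * p * (1 - p), na.rm = TRUE)
}
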