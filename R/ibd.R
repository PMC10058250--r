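#' Validate an IBD segment table
#'
#' Checks the hap-ibd dialect columns and the row-level invariants
#' (`START_BP < END_BP`, no self-pairs, nonnegative lengths); malformed rows
#' are reported by row number.
#'
#' @param segments Tibble with columns `ID1`, `ID2`, `LENGTH_CM` and
#'   optionally `HAP1`, `HAP2`, `CHROM`, `START_BP`, `END_BP`.
#' @return The validated tibble, invisibly.
#' @export
check_ibd_segments <- function(segments) {
  need <- c("ID1", "ID2", "LENGTH_CM")
  if (!all(need %in% names(segments))) {
    abort("IBD table needs columns ID1, ID2, LENGTH_CM")
  }
  bad <- segments$LENGTH_CM < 0 | segments$ID1 == segments$ID2
  if (all(c("START_BP", "END_BP") %in% names(segments))) {
    bad <- bad | segments$START_BP >= segments$END_BP
  }
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    rows <- which(bad | is.na(bad))
    abort(sprintf("malformed IBD rows: %s",
                  paste(utils::head(rows, 10), collapse = ", ")))
  }
  invisible(segments)
}

#' Total IBD sharing per pair of individuals
#'
#' Sums segment lengths at or above the detection floor over all segments of
#' each unordered individual pair (haplotype pairs are aggregated).
#'
#' @param segments IBD segment tibble (see [check_ibd_segments()]).
#' @param min_cm Minimum segment length retained, cM (default 2).
#' @return A tibble with columns `ID1`, `ID2` (`ID1 < ID2`), `total_cm`.
#' @export
ibd_pair_totals <- function(segments, min_cm = 2) {
  check_ibd_segments(segments)
  seg <- segments[segments$LENGTH_CM >= min_cm, , drop = FALSE]
  if (!nrow(seg)) {
    return(tibble(ID1 = character(), ID2 = character(), total_cm = double()))
  }
  tibble(ID1 = pmin(seg$ID1, seg$ID2), ID2 = pmax(seg$ID1, seg$ID2),
         LENGTH_CM = seg$LENGTH_CM) |>
    dplyr::group_by(.data$ID1, .data$ID2) |>
    dplyr::summarise(total_cm = sum(.data$LENGTH_CM), .groups = "drop")
}

#' Bin specification for IBD length decomposition
#'
#' @param breaks Increasing breakpoints in cM starting at the detection
#'   floor; the default `c(2, 6, Inf)` gives the bins [2, 6) and [6, Inf).
#'   Every bin is half-open on the right except that infinity closes the
#'   last, so a segment of exactly 6 cM falls in the upper bin.
#' @return Numeric vector of validated breakpoints.
#' @export
ibd_bins <- function(breaks = c(2, 6, Inf)) {
  if (length(breaks) < 2 || any(diff(breaks) <= 0)) {
    abort("breaks must be strictly increasing with at least two values")
  }
  breaks
}

#' Decompose pairwise IBD sharing into length bins
#'
#' Each segment is assigned to exactly one bin by its length; bin totals per
#' pair therefore sum exactly to [ibd_pair_totals()] computed with
#' `min_cm = breaks[1]`.
#'
#' @inheritParams ibd_pair_totals
#' @param breaks See [ibd_bins()].
#' @return A tibble with columns `ID1`, `ID2`, `bin` (label like `"[2,6)"`),
#'   `total_cm`.
#' @export
ibd_bin_decompose <- function(segments, breaks = ibd_bins()) {
  check_ibd_segments(segments)
  breaks <- ibd_bins(breaks)
  seg <- segments[segments$LENGTH_CM >= breaks[1], , drop = FALSE]
  labels <- sprintf("[%s,%s)", utils::head(breaks, -1), utils::tail(breaks, -1))
  if (!nrow(seg)) {
    return(tibble(ID1 = character(), ID2 = character(), bin = character(),
                  total_cm = double()))
  }
  bin <- labels[findInterval(seg$LENGTH_CM, breaks)]
  tibble(ID1 = pmin(seg$ID1, seg$ID2), ID2 = pmax(seg$ID1, seg$ID2),
         bin = bin, LENGTH_CM = seg$LENGTH_CM) |>
    dplyr::group_by(.data$ID1, .data$ID2, .data$bin) |>
    dplyr::summarise(total_cm = sum(.data$LENGTH_CM), .groups = "drop")
}

#' Mean within-cluster IBD sharing
#'
#' Mean of pairwise total sharing over all unordered within-cluster pairs;
#' pairs with no detected segments count as zero (so the mean is not
#' conditional on detection). Clusters need at least two members.
#'
#' @param pair_totals Output of [ibd_pair_totals()].
#' @param clusters Named vector or data frame (`id`, `cluster`) assigning
#'   individuals to clusters.
#' @return A tibble: `cluster`, `n_individuals`, `n_pairs`, `mean_cm`.
#' @export
ibd_cluster_means <- function(pair_totals, clusters) {
  if (is.data.frame(clusters)) {
    clusters <- stats::setNames(as.character(clusters$cluster),
                                as.character(clusters$id))
  }
  sizes <- table(unname(clusters))
  if (any(sizes < 2)) {
    abort(paste0("singleton cluster(s): ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  key <- pair_key(pair_totals$ID1, pair_totals$ID2)
  totals <- stats::setNames(pair_totals$total_cm, key)
  purrr::map_dfr(names(sizes), function(cl) {
    ids <- names(clusters)[clusters == cl]
    pr <- utils::combn(sort(ids), 2)
    k <- pair_key(pr[1, ], pr[2, ])
    v <- totals[k]
    v[is.na(v)] <- 0
    tibble(cluster = cl, n_individuals = length(ids),
           n_pairs = ncol(pr), mean_cm = mean(v))
  })
}

#' Read a hap-ibd-style IBD segment TSV
#'
#' Accepts either a file with the header `ID1 HAP1 ID2 HAP2 CHROM START_BP
#' END_BP LENGTH_CM` or a headerless 8-column file in that order.
#'
#' @param path File path.
#' @return An IBD segment tibble.
#' @export
read_ibd_segments <- function(path) {
  first <- readLines(path, n = 1)
  cols <- c("ID1", "HAP1", "ID2", "HAP2", "CHROM", "START_BP", "END_BP",
            "LENGTH_CM")
  if (grepl("ID1", first)) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    readr::read_tsv(path, col_names = cols, show_col_types = FALSE)
  }
}
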