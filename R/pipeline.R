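#' End-to-end pipeline configuration
#'
#' Describes one run of the whole downstream-analysis chain on synthetic
#' inputs (or inputs previously written to disk in the same dialects):
#' generate -> assign birthplaces -> prune relatives -> copying similarity ->
#' distinguishability tests -> isolation by distance -> IBD summaries ->
#' admixture calendar -> summary report.
#'
#' @param synth A [synth_config()] describing the synthetic inputs.
#' @param out_dir Output directory.
#' @param seed Root seed for every stage's randomness (default: the synth
#'   config's seed).
#' @param stages Character vector of stages to run, in dependency order;
#'   subset of the default.
#' @param n_perm Permutations per distinguishability comparison in the
#'   pipeline run (default 1000; raise towards 1e5 for publication-grade
#'   p-values).
#' @param decay_variant Isolation-by-distance variant (default
#'   `"inter_ethnic"`).
#' @param decay A [decay_config()].
#' @param pruning A [pruning_config()].
#' @param calendar A [calendar_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth, out_dir, seed = NULL,
                            stages = c("synth", "birthplaces", "prune",
                                       "similarity", "permtests", "decay",
                                       "ibd", "calendar", "report"),
                            n_perm = 1000,
                            decay_variant = "inter_ethnic",
                            decay = decay_config(),
                            pruning = pruning_config(),
                            calendar = calendar_config()) {
  stopifnot(inherits(synth, "synth_config"))
  known <- c("synth", "birthplaces", "prune", "similarity", "permtests",
             "decay", "ibd", "calendar", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  structure(list(synth = synth, out_dir = out_dir,
                 seed = as.integer(seed %||% synth$seed),
                 stages = stages, n_perm = n_perm,
                 decay_variant = decay_variant, decay = decay,
                 pruning = pruning, calendar = calendar),
            class = "pipeline_config")
}

#' Run the full downstream-analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' outputs under `out_dir` and recording every file in a manifest with its
#' MD5 content hash; a rerun with the same configuration and seed reproduces
#' the hashes. A stage failure halts downstream stages and the partial
#' manifest (with the error recorded) is still written.
#'
#' @param config A [pipeline_config()].
#' @return A tibble manifest: `stage`, `file`, `md5`, plus attribute
#'   `"errors"` (named list of stage failures, empty on success). The
#'   manifest is also written to `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  errors <- list()
  halted <- FALSE
  state <- new.env(parent = emptyenv())

  record <- function(stage, files) {
    manifest[[stage]] <<- tibble(stage = stage, file = unname(files),
                                 md5 = unname(tools::md5sum(unname(files))))
  }
  run_stage <- function(stage, fun) {
    if (halted || !(stage %in% config$stages)) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[stage]] <<- conditionMessage(res)
      halted <<- TRUE
    } else {
      record(stage, res)
    }
    invisible(NULL)
  }
  out <- function(name) file.path(config$out_dir, name)

  run_stage("synth", function() {
    files <- write_synthetic_inputs(config$synth, config$out_dir)
    state$cohort <- generate_cohort(config$synth)
    state$copying <- generate_copying_matrix(state$cohort, config$synth)
    state$kinship <- generate_kinship_table(state$cohort, config$synth)
    state$ibd <- generate_ibd_segments(state$cohort, config$synth)
    files
  })
  run_stage("birthplaces", function() {
    state$locations <- assign_birthplaces(state$cohort)
    f <- out("assigned_birthplaces.csv")
    readr::write_csv(state$locations, f)
    f
  })
  run_stage("prune", function() {
    if (is.null(state$kinship)) abort("prune stage needs the kinship table")
    pr <- prune_related(state$kinship, state$cohort, config$pruning,
                        seed = substream_seed(config$seed, "prune"))
    state$removed <- pr$removed$id
    f <- out("removed_individuals.tsv")
    readr::write_tsv(pr$removed, f)
    f
  })
  run_stage("similarity", function() {
    keep <- !(state$cohort$id %in% (state$removed %||% character()))
    state$kept_cohort <- state$cohort[keep, , drop = FALSE]
    cm <- state$copying[state$copying$id %in% state$kept_cohort$id, ,
                        drop = FALSE]
    profiles <- aggregate_to_groups(cm)
    state$sim <- similarity_matrix(profiles)
    gs <- group_similarity(state$sim,
                           tibble(id = state$kept_cohort$id,
                                  group = state$kept_cohort$ethnic_group))
    f1 <- out("similarity_matrix.tsv")
    f2 <- out("group_similarity.tsv")
    readr::write_tsv(dplyr::bind_cols(tibble(id = rownames(state$sim)),
                                      as_tibble(state$sim)), f1)
    readr::write_tsv(gs, f2)
    c(f1, f2)
  })
  run_stage("permtests", function() {
    cfg <- perm_config(n_perm = config$n_perm,
                       seed = substream_seed(config$seed, "permtests"))
    res <- all_pairs_tests(state$sim,
                           tibble(id = state$kept_cohort$id,
                                  group = state$kept_cohort$ethnic_group),
                           cfg)
    f <- out("distinguishability.tsv")
    readr::write_tsv(res, f)
    f
  })
  run_stage("decay", function() {
    meta <- state$kept_cohort
    locs <- state$locations[state$locations$id %in% meta$id, , drop = FALSE]
    fit <- distance_decay(locs, state$sim, meta,
                          variant = config$decay_variant,
                          config = config$decay)
    f1 <- out("decay_bins.tsv")
    f2 <- out("decay_fit.json")
    readr::write_tsv(fit$bins, f1)
    jsonlite::write_json(glance(fit), f2, auto_unbox = TRUE, digits = NA)
    c(f1, f2)
  })
  run_stage("ibd", function() {
    totals <- ibd_pair_totals(state$ibd)
    cl <- tibble(id = state$cohort$id, cluster = state$cohort$ethnic_group)
    means <- ibd_cluster_means(totals, cl)
    f1 <- out("ibd_pair_totals.tsv")
    f2 <- out("ibd_cluster_means.tsv")
    readr::write_tsv(totals, f1)
    readr::write_tsv(means, f2)
    c(f1, f2)
  })
  run_stage("calendar", function() {
    adm <- generate_admixture_table(
      targets = unique(state$cohort$ethnic_group),
      true_g = seq(10, 60, length.out = length(unique(state$cohort$ethnic_group))),
      seed = substream_seed(config$seed, "calendar"))
    harm <- harmonize_admixture_dates(adm, config$calendar)
    f1 <- out("admixture_events.tsv")
    f2 <- out("admixture_by_target.json")
    readr::write_tsv(harm$events, f1)
    jsonlite::write_json(harm$by_target, f2, auto_unbox = TRUE, digits = NA)
    c(f1, f2)
  })
  run_stage("report", function() {
    f <- out("summary.json")
    jsonlite::write_json(list(
      n_individuals = nrow(state$cohort),
      n_removed = length(state$removed %||% character()),
      stages_run = intersect(config$stages, names(manifest)),
      seed = config$seed), f, auto_unbox = TRUE)
    f
  })

  man <- if (length(manifest)) dplyr::bind_rows(manifest) else
    tibble(stage = character(), file = character(), md5 = character())
  jsonlite::write_json(list(manifest = man, errors = errors),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  attr(man, "errors") <- errors
  if (length(errors)) {
    warn(paste0("pipeline halted at stage '", names(errors)[1], "': ",
                errors[[1]]))
  }
  man
}
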