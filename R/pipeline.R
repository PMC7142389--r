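#' Pipeline configuration
#'
#' Bundles every stage's parameters for an end-to-end run: a synthetic
#' [cohort_spec()] (or paths to an existing cohort), the screening and RFE
#' configurations, the evaluation mode, and one master seed from which all
#' randomness flows (the cohort spec's seed is overridden by it).
#'
#' @param cohort a [cohort_spec()], or a path to a phenotype TSV readable by
#'   [read_cohort()].
#' @param screening a [screening_config()].
#' @param rfe an [rfe_config()].
#' @param mode LOO protocol, `"nested"` or `"pooled"`.
#' @param seed master integer seed.
#' @param atlas optional [volume3d] atlas, or `"synthetic"` to build one
#'   with [make_synthetic_atlas()] (`n_regions` regions) on the cohort grid.
#' @param n_regions regions for the synthetic atlas.
#' @param mask optional binary mask volume, or `"all"`.
#' @param write_volumes also write the per-subject NIfTI volumes (off by
#'   default; they are reproducible from the spec and seed).
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            screening = screening_config(),
                            rfe = rfe_config(),
                            mode = c("nested", "pooled"),
                            seed = 1L, atlas = "synthetic",
                            n_regions = 32L, mask = "all",
                            write_volumes = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(screening, "screening_config"),
            inherits(rfe, "rfe_config"))
  if (!(inherits(cohort, "cohort_spec") ||
        (is.character(cohort) && length(cohort) == 1L)))
    stop("'cohort' must be a cohort_spec or a phenotype TSV path",
         call. = FALSE)
  structure(list(cohort = cohort, screening = screening, rfe = rfe,
                 mode = mode, seed = as.integer(seed), atlas = atlas,
                 n_regions = as.integer(n_regions), mask = mask,
                 write_volumes = isTRUE(write_volumes)),
            class = "pipeline_config")
}

# plain-list view of a config, for JSON provenance
config_as_list <- function(config) {
  co <- config$cohort
  list(
    cohort = if (inherits(co, "cohort_spec")) {
      sp <- unclass(co); sp$blobs <- lapply(sp$blobs, unclass); sp
    } else co,
    screening = unclass(config$screening),
    rfe = unclass(config$rfe),
    mode = config$mode, seed = config$seed,
    atlas = if (is.character(config$atlas)) config$atlas
            else "user-supplied",
    n_regions = config$n_regions,
    write_volumes = config$write_volumes)
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> screen -> select -> evaluate -> report,
#' writing every stage's artifacts under `out_dir` and a `summary.json`
#' with the evaluation metrics, retained-feature count, region count, the
#' full configuration, its MD5 hash and the seed. Rerunning with an
#' identical config and seed reproduces the summary byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; stage subdirectories
#'   `cohort/`, `screening/`, `selection/`, `evaluation/`, `regions/`).
#' @param quiet suppress progress messages.
#' @return list with `fit` (the [ctf_svm()] on the full cohort),
#'   `evaluation`, `regions`, `summary` (the summary list), `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[vbmrfe] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # provenance first: config JSON + hash
  cfg_list <- config_as_list(config)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg_list, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  # --- stage 1: cohort -------------------------------------------------
  say("stage 1/5: cohort")
  if (inherits(config$cohort, "cohort_spec")) {
    spec <- config$cohort
    spec$seed <- config$seed   # all randomness flows from the master seed
    gen <- stage("simulate", generate_cohort(spec))
    volumes <- gen$volumes; labels <- gen$labels
    truth_dir <- file.path(out_dir, "cohort")
    dir.create(truth_dir, showWarnings = FALSE)
    write_ground_truth(gen$truth, spec, truth_dir)
    if (config$write_volumes) write_cohort(volumes, labels, truth_dir)
  } else {
    co <- stage("load", read_cohort(config$cohort))
    volumes <- co$volumes; labels <- co$labels
  }
  cohort <- stage("to_matrix", to_matrix(volumes, labels, config$mask))

  # --- stages 2-3: fit (screen + select + SVM) -------------------------
  say("stage 2/5: screening; stage 3/5: RFE selection")
  fit <- stage("fit", ctf_svm(cohort, screening = config$screening,
                              rfe = config$rfe))
  write_screening(fit$screening, file.path(out_dir, "screening"))
  write_selection(fit$selection, cohort, file.path(out_dir, "selection"))

  # --- stage 4: evaluation ---------------------------------------------
  say("stage 4/5: leave-one-out evaluation (", config$mode, ")")
  eres <- stage("evaluate",
                loo_evaluate(cohort, config$screening, config$rfe,
                             config$mode))
  write_evaluation(eres, file.path(out_dir, "evaluation"))

  # --- stage 5: region report ------------------------------------------
  say("stage 5/5: region report")
  atlas <- config$atlas
  if (identical(atlas, "synthetic"))
    atlas <- make_synthetic_atlas(cohort$dim, config$n_regions,
                                  seed = config$seed)
  retained <- array(0, dim = cohort$dim)
  retained[cohort$mask_linear[fit$selection$cols]] <- 1
  retained <- volume3d(retained, cohort$affine)
  regions <- stage("report",
                   report_regions(retained, fit$screening$t_map, atlas,
                                  min_cluster = config$screening$min_cluster,
                                  connectivity = config$screening$connectivity,
                                  p_threshold = config$screening$alpha))
  write_regions(regions, retained, file.path(out_dir, "regions"),
                config$screening$connectivity)

  summary <- list(
    seed = config$seed, config_md5 = cfg_hash, mode = config$mode,
    n_subjects = nrow(cohort$X), n_voxels = ncol(cohort$X),
    n_screened = length(fit$screening$selected_cols),
    n_retained = length(fit$selection$cols),
    n_regions = nrow(regions),
    metrics = unclass(eres$metrics),
    confusion = eres$confusion,
    package_version = as.character(utils::packageVersion("vbmrfe")))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", out_dir)
  list(fit = fit, evaluation = eres, regions = regions, summary = summary,
       out_dir = out_dir)
}
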