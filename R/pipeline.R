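#' Read a stack of subject NIfTI maps into a subject x voxel matrix
#'
#' All files must share grid dimensions and affine; a mask restricts the
#' columns to the masked voxels. Voxel order is the array linearization
#' with the first axis fastest-varying.
#'
#' @param paths character vector of NIfTI file paths, one per subject.
#' @param mask optional logical vector/array over the full grid.
#' @return object of class `pk_map_stack`.
#' @export
read_nifti_stack <- function(paths, mask = NULL) {
  stopifnot(length(paths) >= 1L)
  imgs <- lapply(paths, RNifti::readNifti)
  dims <- dim(imgs[[1]])
  aff <- RNifti::xform(imgs[[1]])
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), dims))
      stop("grid mismatch in file: ", paths[i])
    if (max(abs(RNifti::xform(imgs[[i]]) - aff)) > 1e-4)
      stop("affine mismatch in file: ", paths[i])
  }
  nv <- prod(dims)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  mask <- as.logical(as.vector(mask))
  stopifnot(length(mask) == nv)
  maps <- t(vapply(imgs, function(im) as.vector(im)[mask], numeric(sum(mask))))
  structure(list(maps = maps, mask = mask,
                 grid_meta = list(dims = dims,
                                  voxel_size = RNifti::pixdim(imgs[[1]]),
                                  affine = unclass(aff)),
                 subject_ids = sub("\\.nii(\\.gz)?$", "", basename(paths)),
                 group = NULL),
            class = "pk_map_stack")
}

# Write one masked component/source map back onto the full grid as NIfTI.
write_source_nifti <- function(values, mask, grid_meta, path) {
  vol <- array(0, dim = grid_meta$dims)
  vol[as.logical(mask)] <- values
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "float"), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Stage-keyed parameter blocks with validation: unknown keys are rejected.
#' All randomness is derived from the master seed via [substream_seed()].
#'
#' @param seed master seed.
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param simulate named list of [sim_config()] overrides.
#' @param connectivity list: `passband` (Hz).
#' @param sbi list: `n_components` (NULL = MDL), `n_perm`, `alpha`,
#'   `mask_threshold`.
#' @param crossmodal list: `k_folds`, `n_repeats`, `n_perm`, `alpha`,
#'   `shrinkage`, `covariate_placement` ("first_level", "second_level" or
#'   "none").
#' @param secondlevel list: `robust`.
#' @param verbose logical.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("inflammetry_run_"),
                            simulate = list(), connectivity = list(),
                            sbi = list(), crossmodal = list(),
                            secondlevel = list(), verbose = FALSE) {
  defaults <- list(
    connectivity = list(passband = c(0.0078, 0.1)),
    sbi = list(n_components = NULL, n_perm = 10000L, alpha = 0.05,
               mask_threshold = 0.3),
    crossmodal = list(k_folds = 5L, n_repeats = 1000L, n_perm = 5000L,
                      alpha = 0.05, shrinkage = "analytic",
                      covariate_placement = "second_level"),
    secondlevel = list(robust = TRUE)
  )
  check_keys <- function(user, allowed, block) {
    bad <- setdiff(names(user), allowed)
    if (length(bad)) stop("unknown key(s) in '", block, "' block: ",
                          paste(bad, collapse = ", "))
  }
  check_keys(simulate, setdiff(names(formals(sim_config)), "seed"),
             "simulate")
  for (blk in names(defaults)) {
    user <- get(blk)
    check_keys(user, names(defaults[[blk]]), blk)
    defaults[[blk]] <- utils::modifyList(defaults[[blk]], user)
  }
  cm <- defaults$crossmodal
  stopifnot(cm$covariate_placement %in% c("first_level", "second_level",
                                          "none"))
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, connectivity = defaults$connectivity,
                 sbi = defaults$sbi, crossmodal = cm,
                 secondlevel = defaults$secondlevel, verbose = verbose),
            class = "pipeline_config")
}

stage_error <- function(stage, cond) {
  errorCondition(paste0("stage '", stage, "' failed: ",
                        conditionMessage(cond)),
                 class = c("pipeline_stage_error",
                           class(cond)[class(cond) != "condition" &
                                         class(cond) != "error"],
                           "error", "condition"),
                 stage = stage, parent = cond)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Stages in order: simulate -> connectivity -> sbi -> crossmodal ->
#' secondlevel. Every stage writes plain CSV/NIfTI/JSON artifacts under the
#' configured output directory, and a run manifest records the config hash,
#' seed and per-file MD5 digests; re-running with an identical config and
#' seed reproduces the digests. A stage failure writes the manifest with
#' the error recorded, then signals a stage-tagged error.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list), invisibly also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE))
    stop("cannot create output directory: ", out)
  say <- function(...) if (config$verbose) message(...)
  files <- character(0)
  manifest <- list(seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("inflammetry")),
                   stages = character(0), status = "running",
                   files = list())
  cfg_file <- file.path(out, "config.yaml")
  yaml::write_yaml(config_to_list(config), cfg_file)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  state <- new.env(parent = emptyenv())

  finish <- function(status, error = NULL) {
    manifest$status <<- status
    if (!is.null(error)) manifest$error <<- error
    manifest$files <<- as.list(tools::md5sum(sort(files)))
    names(manifest$files) <<- basename(sort(files))
    manifest$timestamp <<- format(Sys.time(), tz = "UTC")
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }

  run_stage <- function(stage, fun) {
    say("running stage: ", stage)
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      err <- stage_error(stage, res)
      finish("failed", error = list(stage = stage,
                                    message = conditionMessage(res)))
      stop(err)
    }
    manifest$stages <<- c(manifest$stages, stage)
    res
  }

  run_stage("simulate", function() {
    scfg <- do.call(sim_config, c(config$simulate, list(
      seed = substream_seed(config$seed, "simulate"))))
    state$cohort <- simulate_cohort(scfg)
    files <<- c(files, write_cohort(state$cohort, file.path(out, "cohort")))
  })

  run_stage("connectivity", function() {
    co <- state$cohort
    design <- suppressMessages(build_nuisance_design(
      co$config$n_timepoints, co$config$tr_seconds,
      passband = config$connectivity$passband))
    vectors <- lapply(co$series, function(ts)
      connectivity_vector(clean_timeseries(ts, design)))
    state$fc <- connectivity_matrix(vectors)
    stats_tab <- group_connectivity_stats(vectors, co$stack$group)
    f1 <- file.path(out, "connectivity_matrix.csv")
    utils::write.csv(data.frame(subject_id = co$stack$subject_ids,
                                state$fc, check.names = FALSE), f1,
                     row.names = FALSE)
    f2 <- file.path(out, "connectivity_group_stats.csv")
    utils::write.csv(stats_tab, f2, row.names = FALSE)
    files <<- c(files, f1, f2)
  })

  run_stage("sbi", function() {
    co <- state$cohort
    k <- config$sbi$n_components
    if (is.null(k)) k <- as.integer(estimate_n_components(co$stack))
    decomp <- sbi_decompose(co$stack, n_components = k,
                            seed = substream_seed(config$seed, "sbi"))
    gtests <- test_loading_group_difference(
      decomp, co$stack$group, n_perm = config$sbi$n_perm,
      seed = substream_seed(config$seed, "sbi_perm"))
    gm <- test_loading_gm_association(decomp, co$cohort$total_gm,
                                      co$stack$group)
    tests <- merge(gtests, gm, by = "component")
    decomp$selected <- select_component(tests, alpha = config$sbi$alpha)
    state$decomp <- decomp
    state$component_tests <- tests
    f1 <- file.path(out, "sbi_loadings.csv")
    utils::write.csv(data.frame(subject_id = co$stack$subject_ids,
                                decomp$loadings), f1, row.names = FALSE)
    f2 <- file.path(out, "sbi_component_tests.csv")
    utils::write.csv(cbind(tests, selected =
                             tests$component == decomp$selected), f2,
                     row.names = FALSE)
    src_files <- vapply(seq_len(k), function(s) {
      write_source_nifti(decomp$sources[s, ], co$stack$mask,
                         co$stack$grid_meta,
                         file.path(out, sprintf("sbi_source_%02d.nii", s)))
    }, character(1))
    files <<- c(files, f1, f2, src_files)
  })

  run_stage("crossmodal", function() {
    co <- state$cohort
    covars <- data.frame(age = co$cohort$age,
                         sex = as.numeric(co$cohort$sex == "F"),
                         motion_rms = co$cohort$motion_rms,
                         total_gm = co$cohort$total_gm)
    placement <- config$crossmodal$covariate_placement
    cvc <- cv_config(k_folds = config$crossmodal$k_folds,
                     n_repeats = config$crossmodal$n_repeats,
                     seed = substream_seed(config$seed, "crossmodal_cv"),
                     shrinkage = config$crossmodal$shrinkage)
    res <- crossmodal_analysis(
      state$fc, state$decomp$loadings[, state$decomp$selected],
      covariates = if (placement == "first_level") covars else NULL,
      config = cvc, n_perm = config$crossmodal$n_perm,
      alpha = config$crossmodal$alpha,
      seed = substream_seed(config$seed, "crossmodal_perm"))
    state$crossmodal <- res
    state$covars <- covars
    f1 <- file.path(out, "crossmodal_connections.csv")
    utils::write.csv(data.frame(
      label = names(res$structure_coefficients),
      coefficient = res$coefficients,
      structure_coefficient = res$structure_coefficients,
      p_perm = res$structure_p, p_fdr = res$structure_p_fdr,
      significant = seq_along(res$structure_coefficients) %in%
        res$significant_connections), f1, row.names = FALSE)
    f2 <- file.path(out, "brain_scores.csv")
    utils::write.csv(data.frame(
      subject_id = co$stack$subject_ids[res$included],
      brain_score = res$brain_scores), f2, row.names = FALSE)
    f3 <- file.path(out, "crossmodal_summary.json")
    jsonlite::write_json(list(
      insample_r = res$insample_r, cv_r_median = res$cv_r_median,
      model_p = res$model_p, shrinkage_rho = res$rho,
      n_significant_connections = length(res$significant_connections),
      excluded_subjects = res$excluded_subjects), f3,
      auto_unbox = TRUE, digits = NA)
    files <<- c(files, f1, f2, f3)
  })

  run_stage("secondlevel", function() {
    co <- state$cohort
    res <- state$crossmodal
    inc <- res$included
    comp <- cognitive_pca(co$cohort[inc, c("MMSE", "ACER", "RAVLT")])
    # the second-level model always carries the covariates of no interest;
    # `covariate_placement` controls the first-level residualization only
    covars2 <- state$covars[inc, , drop = FALSE]
    model <- fit_interaction_model(comp$pc1_scores, res$brain_scores,
                                   co$stack$group[inc],
                                   covariates = covars2,
                                   robust = config$secondlevel$robust)
    wg <- within_group_correlations(comp$pc1_scores, res$brain_scores,
                                    co$stack$group[inc])
    summ <- cohort_summary(co$cohort)
    state$secondlevel <- list(composite = comp, model = model,
                              within_group = wg)
    f1 <- file.path(out, "second_level_terms.csv")
    utils::write.csv(model$terms, f1, row.names = FALSE)
    f2 <- file.path(out, "within_group_correlations.csv")
    utils::write.csv(wg, f2, row.names = FALSE)
    f3 <- file.path(out, "cohort_summary.csv")
    utils::write.csv(summ, f3, row.names = FALSE)
    f4 <- file.path(out, "second_level_summary.json")
    jsonlite::write_json(list(
      pc1_variance_explained = comp$variance_explained,
      pc1_loadings = as.numeric(comp$loadings),
      interaction_t = model$terms$t[model$terms$term == "brain_score:group"],
      interaction_p = model$terms$p[model$terms$term == "brain_score:group"]),
      f4, auto_unbox = TRUE, digits = NA)
    files <<- c(files, f1, f2, f3, f4)
  })

  manifest <- finish("ok")
  out_state <- as.list(state)
  attr(manifest, "state") <- out_state
  invisible(manifest)
}

# plain-list view of a pipeline_config for hashing / YAML
config_to_list <- function(config) {
  l <- unclass(config)
  l$out_dir <- NULL  # location must not affect the config hash
  l$verbose <- NULL
  rapply(l, function(x) x, how = "replace")
}
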