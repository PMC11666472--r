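#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end synthetic pipeline. Defaults are
#' the study constants: a 288-sentence balanced design over six runs (42
#' production trials of interest per run), 38 participants, 8 mm FWHM map
#' smoothing, 100 permutations per participant, 10,000 bootstrap draws,
#' voxelwise P < 0.005 with FDR cluster correction at q < 0.05, and ROI
#' voxel-selection thresholds t > 2.4 falling back to t > 1.68.
#'
#' @param n_target,n_runs Stimulus design size.
#' @param n_participants Number of simulated participants.
#' @param grid_dims,voxel_size_mm Voxel grid geometry.
#' @param n_blobs,blob_radius,blob_models,signal_amplitude,noise_sd Planted
#'   ground truth (`n_blobs = 0` gives pure-null data).
#' @param attrition_rate,substitution_rate Production imperfection rates.
#' @param models Encoding models to fit.
#' @param fwhm_mm Map smoothing FWHM in millimetres.
#' @param analysis An [analysis_config()].
#' @param selection A [selection_config()].
#' @param run_group,run_roi Toggle the group and ROI stages.
#' @param seed Global seed; per-stage seeds derive from it deterministically.
#' @return A list of class `run_config`, serializable to JSON.
#' @export
pipeline_config <- function(n_target = 288, n_runs = 6, n_participants = 38,
                            grid_dims = c(20, 20, 20), voxel_size_mm = 2.5,
                            n_blobs = 4, blob_radius = 3,
                            blob_models = "narrow_roles",
                            signal_amplitude = 1, noise_sd = 1,
                            attrition_rate = 0.05, substitution_rate = 0.23,
                            models = c("bag_of_nouns_cat", "broad_roles",
                                       "narrow_roles"),
                            fwhm_mm = 8,
                            analysis = analysis_config(),
                            selection = selection_config(),
                            run_group = TRUE, run_roi = TRUE, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

config_to_json <- function(config, path) {
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file written by the pipeline or by hand; missing fields
#'   take their defaults.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$analysis <- do.call(analysis_config,
                          raw$analysis[names(raw$analysis) %in%
                                       names(formals(analysis_config))] %||% list())
  raw$selection <- do.call(selection_config,
                           raw$selection[names(raw$selection) %in%
                                         names(formals(selection_config))] %||% list())
  do.call(pipeline_config, raw[names(raw) %in% names(formals(pipeline_config))])
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)), "stage_error"))
}

#' Run the full pipeline
#'
#' Executes design construction, featurization, beta-map simulation,
#' per-participant encoding, group cluster inference and the ROI model
#' comparison, writing all artifacts and a manifest (with content hashes and
#' per-stage seeds) to `out_dir`. Re-running with the same configuration
#' reproduces every file bit-exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage results (`design`,
#'   `dataset`, `maps`, `group`, `roi`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(design = derive_seed(config$seed, 1L),
                truth = derive_seed(config$seed, 2L),
                dataset = derive_seed(config$seed, 3L),
                analysis = derive_seed(config$seed, 4L))
  design <- stage("design", {
    d <- build_design(n_target = config$n_target, n_runs = config$n_runs,
                      seed = seeds$design)
    audit_design(d)
    write_design(d, file.path(out_dir, "design.tsv"))
    d
  })
  grid <- voxel_grid(config$grid_dims, config$voxel_size_mm)
  truth <- stage("ground_truth", {
    if (config$n_blobs > 0)
      plant_blobs(grid, n_blobs = config$n_blobs,
                  radius = config$blob_radius, models = config$blob_models,
                  signal_amplitude = config$signal_amplitude,
                  noise_sd = config$noise_sd, seed = seeds$truth)
    else null_truth(grid, noise_sd = config$noise_sd)
  })
  dataset <- stage("simulate", {
    ds <- generate_dataset(design, truth,
                           n_participants = config$n_participants,
                           attrition_rate = config$attrition_rate,
                           substitution_rate = config$substitution_rate,
                           seed = seeds$dataset)
    write_dataset(ds, file.path(out_dir, "dataset"))
    ds
  })
  maps <- stage("encode", {
    out <- list()
    for (model in config$models) {
      out[[model]] <- lapply(names(dataset$participants), function(p)
        vw_encode(dataset, p, model, fwhm_mm = config$fwhm_mm))
      names(out[[model]]) <- names(dataset$participants)
      for (p in names(out[[model]])) {
        map <- out[[model]][[p]]
        RNifti::writeNifti(
          RNifti::asNifti(map$image,
                          pixdim = rep(grid$voxel_size_mm, 3L)),
          file.path(out_dir, sprintf("%s_model-%s_gen.nii.gz", p, model)),
          datatype = "double")
      }
    }
    out
  })
  cfg_a <- config$analysis
  cfg_a$seed <- seeds$analysis
  group <- if (isTRUE(config$run_group)) stage("group", {
    out <- list()
    for (model in config$models) {
      pm <- permutation_maps(dataset, model, cfg_a, fwhm_mm = config$fwhm_mm)
      res <- group_cluster_test(maps[[model]], pm, cfg_a)
      if (nrow(res$clusters))
        utils::write.table(res$clusters,
                           file.path(out_dir,
                                     sprintf("clusters_model-%s.tsv", model)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      out[[model]] <- res
    }
    out
  }) else NULL
  roi <- if (isTRUE(config$run_roi)) stage("roi", {
    centers <- if (length(truth$blobs))
      lapply(truth$blobs, `[[`, "center")
    else list(round(grid$dims / 3), round(2 * grid$dims / 3))
    rois <- make_parcels(grid, centers, radius = config$blob_radius + 1,
                         names = paste0("roi", seq_along(centers)))
    perf <- roi_model_performance(maps, rois, modality = "production",
                                  cfg = config$selection)
    utils::write.table(perf, file.path(out_dir, "roi_performance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cmp <- NULL
    if (nrow(perf) && length(unique(perf$model)) >= 2L) {
      cmp <- compare_models(perf)
      jsonlite::write_json(list(effects = cmp$effects,
                                pairwise = cmp$pairwise,
                                random_used = cmp$random_used),
                           file.path(out_dir, "roi_effects.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    list(performance = perf, comparison = cmp)
  }) else NULL
  config_to_json(config, file.path(out_dir, "config.json"))
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("sentencode")),
    seed = config$seed, stage_seeds = seeds,
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(design = design, dataset = dataset, maps = maps,
                 group = group, roi = roi, manifest = manifest))
}
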