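#' Define a voxel grid
#'
#' @param dims Integer vector of three array dimensions (default 20 x 20 x 20).
#' @param voxel_size_mm Isotropic voxel size in millimetres (default 2.5).
#' @param mask Optional logical 3D array of in-analysis voxels; default all.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims = c(20L, 20L, 20L), voxel_size_mm = 2.5,
                       mask = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L), voxel_size_mm > 0)
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(identical(dim(mask), dims))
  if (!any(mask)) abort("empty mask", "empty_mask")
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm,
                 mask = mask, n_voxels = sum(mask)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("Voxel grid:", paste(x$dims, collapse = " x "), "at", x$voxel_size_mm,
      "mm;", x$n_voxels, "voxels in mask\n")
  invisible(x)
}

## linear array indices of in-mask voxels, in mask order
grid_mask_indices <- function(grid) which(grid$mask)

## place a per-mask-voxel vector into a 3D array (0 outside the mask)
vec_to_volume <- function(values, grid, fill = 0) {
  vol <- array(fill, grid$dims)
  vol[grid$mask] <- values
  vol
}

## voxels within `radius` (in voxels) of center, as linear indices
sphere_indices <- function(grid, center, radius) {
  d <- grid$dims
  cc <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  dist2 <- (cc$i - center[1])^2 + (cc$j - center[2])^2 + (cc$k - center[3])^2
  which(dist2 <= radius^2 & as.vector(grid$mask))
}

#' Plant spherical signal regions in a grid
#'
#' Creates a ground-truth object with spatially contiguous spherical blobs of
#' voxels whose activity is a linear function of one encoding model's
#' predictors. Per-voxel weights are drawn i.i.d. standard normal; at
#' simulation time they are rescaled per voxel so the signal standard
#' deviation over the production design equals
#' `signal_amplitude * noise_sd`, making `signal_amplitude` the per-voxel
#' signal-to-noise ratio. Voxels outside all blobs are null (zero weights).
#'
#' @param grid A `voxel_grid`.
#' @param n_blobs Number of blobs (default 4; used when `centers` is `NULL`).
#' @param radius Blob radius in voxels (default 3).
#' @param models Character vector of generating model names, recycled over
#'   blobs.
#' @param signal_amplitude Per-voxel signal-to-noise ratio of blob voxels.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian trial noise.
#' @param centers Optional list/matrix of blob centers (voxel coordinates).
#' @param seed Integer seed.
#' @return An object of class `ground_truth` with elements `grid`, `blobs`
#'   (each with `name`, `model`, `voxels` as linear indices, `weights`
#'   matrix voxels x predictors), `signal_amplitude`, `noise_sd`.
#' @export
plant_blobs <- function(grid, n_blobs = 4, radius = 3,
                        models = "narrow_roles", signal_amplitude = 1,
                        noise_sd = 1, centers = NULL, seed = 1) {
  models <- rep(models, length.out = max(n_blobs, length(models)))
  if (is.null(centers)) {
    centers <- with_seed(derive_seed(seed, 11L), {
      out <- list(); taken <- NULL
      lo <- radius + 2; hi <- grid$dims - radius - 1
      if (any(hi < lo)) abort("grid too small for blob radius", "invalid_grid")
      for (b in seq_len(n_blobs)) {
        for (attempt in 1:200) {
          ctr <- lo + vapply(hi - lo + 1L, function(m) sample.int(m, 1L), integer(1)) - 1L
          if (is.null(taken) ||
              all(sqrt(colSums((t(taken) - ctr)^2)) > 2 * radius + 1)) break
        }
        taken <- rbind(taken, ctr)
        out[[b]] <- ctr
      }
      out
    })
  } else if (is.matrix(centers)) {
    centers <- lapply(seq_len(nrow(centers)), function(i) centers[i, ])
  }
  n_blobs <- length(centers)
  models <- rep(models, length.out = n_blobs)
  blobs <- with_seed(derive_seed(seed, 12L), {
    lapply(seq_len(n_blobs), function(b) {
      vox <- sphere_indices(grid, centers[[b]], radius)
      p <- predictor_count(models[b])
      list(name = paste0("blob", b), model = models[b],
           center = centers[[b]], radius = radius, voxels = vox,
           weights = matrix(stats::rnorm(length(vox) * p), length(vox), p))
    })
  })
  structure(list(grid = grid, blobs = blobs,
                 signal_amplitude = signal_amplitude, noise_sd = noise_sd),
            class = "ground_truth")
}

#' Null ground truth (no planted signal)
#'
#' @inheritParams plant_blobs
#' @export
null_truth <- function(grid, noise_sd = 1) {
  structure(list(grid = grid, blobs = list(), signal_amplitude = 0,
                 noise_sd = noise_sd),
            class = "ground_truth")
}

#' Per-voxel ground-truth labels
#'
#' @param truth A `ground_truth` object.
#' @return Character vector over in-mask voxels: the generating model name,
#'   or `"null"`.
#' @export
truth_labels <- function(truth) {
  grid <- truth$grid
  lab <- rep("null", grid$n_voxels)
  pos <- match(seq_len(prod(grid$dims)), grid_mask_indices(grid))
  for (b in truth$blobs) lab[pos[b$voxels]] <- b$model
  lab
}

#' Simulate a multi-participant beta-map dataset
#'
#' For every participant, run and production trial, generates one beta value
#' per in-mask voxel: i.i.d. Gaussian noise, plus — in planted voxels — a
#' linear function of the produced sentence's features under the blob's
#' generating model, scaled to the requested signal-to-noise ratio.
#' Production imperfection is emulated by marking a fraction
#' `attrition_rate` of trials as unusable (`kept = FALSE`) and by replacing a
#' fraction `substitution_rate` of sentences with a different
#' lexicon-conforming sentence of the same voice (imperfect recall: the
#' produced sentence, which drives the betas, differs from the one read).
#'
#' @param design A `stimulus_design` (see [build_design()]).
#' @param truth A `ground_truth` from [plant_blobs()] or [null_truth()].
#' @param n_participants Number of participants.
#' @param attrition_rate,substitution_rate Rates in `[0, 1)`.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return An object of class `beta_dataset`: `grid`, `truth`, and
#'   `participants`, a list (one element per participant) of lists of runs,
#'   each run holding `events` (trial table with `kept` and `substituted`
#'   flags) and `betas` (trials x in-mask voxels matrix).
#' @export
generate_dataset <- function(design, truth, n_participants = 38,
                             attrition_rate = 0.05, substitution_rate = 0.23,
                             seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  grid <- truth$grid
  if (!any(grid$mask)) abort("empty mask", "empty_mask")
  if (attrition_rate < 0 || attrition_rate >= 1 ||
      substitution_rate < 0 || substitution_rate >= 1)
    abort("rates must lie in [0, 1)", "invalid_rate")
  lexicon <- attr(design, "lexicon") %||% default_lexicon()
  prod_all <- design[design$trial_type == "production", , drop = FALSE]
  pool <- enumerate_pool(lexicon)
  mask_pos <- match(seq_len(prod(grid$dims)), grid_mask_indices(grid))

  ## per-blob: model spec and per-voxel weight scaling against the full
  ## production design, so signal sd = signal_amplitude * noise_sd
  blob_info <- lapply(truth$blobs, function(b) {
    if (ncol(b$weights) != predictor_count(b$model))
      abort(sprintf("weights dimension mismatch for %s: %d columns vs %d predictors",
                    b$name, ncol(b$weights), predictor_count(b$model)),
            "weights_mismatch")
    X_full <- build_design_matrix(prod_all, b$model)
    sig <- X_full %*% t(b$weights)               # trials x blob voxels
    s <- apply(sig, 2L, pop_sd)
    s[s < 1e-12] <- 1
    list(model = b$model, cols = mask_pos[b$voxels],
         weights = b$weights / s)                # rows scaled per voxel
  })
  runs_idx <- sort(unique(design$run))
  participants <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    participants[[p]] <- with_seed(derive_seed(seed, 21L, p), {
      runs <- vector("list", length(runs_idx))
      for (ri in seq_along(runs_idx)) {
        ev <- prod_all[prod_all$run == runs_idx[ri], , drop = FALSE]
        n_tr <- nrow(ev)
        ev$substituted <- stats::runif(n_tr) < substitution_rate
        for (i in which(ev$substituted)) {
          repeat {
            cand <- pool[sample.int(nrow(pool), 1L), ]
            if (!identical(unname(unlist(cand)),
                           c(ev$agent[i], ev$verb[i], ev$patient[i]))) break
          }
          ev$agent[i] <- cand$agent
          ev$verb[i] <- cand$verb
          ev$patient[i] <- cand$patient
        }
        ev$kept <- stats::runif(n_tr) >= attrition_rate
        betas <- matrix(stats::rnorm(n_tr * grid$n_voxels,
                                     sd = truth$noise_sd),
                        n_tr, grid$n_voxels)
        if (truth$signal_amplitude != 0) {
          for (bi in blob_info) {
            Xr <- build_design_matrix(ev, bi$model)
            betas[, bi$cols] <- betas[, bi$cols] +
              truth$signal_amplitude * truth$noise_sd *
              (Xr %*% t(bi$weights))
          }
        }
        rownames(ev) <- NULL
        runs[[ri]] <- list(events = ev, betas = betas)
      }
      runs
    })
  }
  names(participants) <- sprintf("sub-%02d", seq_len(n_participants))
  structure(list(grid = grid, truth = truth, participants = participants),
            class = "beta_dataset")
}

#' @export
print.beta_dataset <- function(x, ...) {
  cat("Beta dataset:", length(x$participants), "participants x",
      length(x$participants[[1]]), "runs;",
      x$grid$n_voxels, "voxels\n")
  invisible(x)
}

#' Write / read a beta dataset
#'
#' Serializes the dataset to a directory: per participant and run a NIfTI-1
#' 4D volume of beta maps (`sub-XX/run-R_betas.nii.gz`, one 3D volume per
#' trial, double precision so round trips are bit-exact) and an events TSV
#' (`sub-XX/run-R_events.tsv`), plus the grid mask (`mask.nii.gz`), a dataset
#' metadata JSON and a ground-truth JSON sidecar.
#'
#' @param dataset A `beta_dataset`.
#' @param dir Output directory (created if missing).
#' @return `read_dataset` returns the reconstructed `beta_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- dataset$grid
  pd <- rep(grid$voxel_size_mm, 3L)
  RNifti::writeNifti(RNifti::asNifti(array(as.double(grid$mask), grid$dims),
                                     pixdim = pd),
                     file.path(dir, "mask.nii.gz"), datatype = "double")
  meta <- list(dims = grid$dims, voxel_size_mm = grid$voxel_size_mm,
               participants = names(dataset$participants),
               n_runs = length(dataset$participants[[1]]))
  jsonlite::write_json(meta, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  truth <- dataset$truth
  if (!is.null(truth)) {
    tr <- list(signal_amplitude = truth$signal_amplitude,
               noise_sd = truth$noise_sd,
               blobs = lapply(truth$blobs, function(b)
                 list(name = b$name, model = b$model, center = b$center,
                      radius = b$radius, voxels = b$voxels,
                      weights = b$weights)))
    jsonlite::write_json(tr, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  for (sub in names(dataset$participants)) {
    sd_ <- file.path(dir, sub)
    dir.create(sd_, showWarnings = FALSE)
    runs <- dataset$participants[[sub]]
    for (ri in seq_along(runs)) {
      ev <- runs[[ri]]$events
      betas <- runs[[ri]]$betas
      vol <- array(0, c(grid$dims, nrow(betas)))
      for (tr_i in seq_len(nrow(betas)))
        vol[, , , tr_i][grid$mask] <- betas[tr_i, ]
      RNifti::writeNifti(RNifti::asNifti(vol, pixdim = pd),
                         file.path(sd_, sprintf("run-%d_betas.nii.gz", ri)),
                         datatype = "double")
      utils::write.table(ev, file.path(sd_, sprintf("run-%d_events.tsv", ri)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta_path <- file.path(dir, "dataset.json")
  if (!file.exists(meta_path))
    abort(paste("missing dataset metadata:", meta_path), "io_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  mask <- array(RNifti::readNifti(file.path(dir, "mask.nii.gz")) > 0.5,
                as.integer(meta$dims))
  grid <- voxel_grid(meta$dims, meta$voxel_size_mm, mask)
  truth <- NULL
  tp <- file.path(dir, "ground_truth.json")
  if (file.exists(tp)) {
    tr <- jsonlite::read_json(tp, simplifyVector = TRUE)
    blobs <- lapply(seq_len(length(tr$blobs$name %||% character(0))),
                    function(i)
      list(name = tr$blobs$name[i], model = tr$blobs$model[i],
           center = tr$blobs$center[[i]], radius = tr$blobs$radius[i],
           voxels = tr$blobs$voxels[[i]],
           weights = do.call(rbind, lapply(tr$blobs$weights[[i]], unlist))))
    truth <- structure(list(grid = grid, blobs = blobs,
                            signal_amplitude = tr$signal_amplitude,
                            noise_sd = tr$noise_sd),
                       class = "ground_truth")
  }
  participants <- list()
  for (sub in meta$participants) {
    runs <- vector("list", meta$n_runs)
    for (ri in seq_len(meta$n_runs)) {
      bp <- file.path(dir, sub, sprintf("run-%d_betas.nii.gz", ri))
      ep <- file.path(dir, sub, sprintf("run-%d_events.tsv", ri))
      if (!file.exists(bp))
        abort(sprintf("missing beta file for %s run %d: %s", sub, ri, bp),
              "io_error")
      if (!file.exists(ep))
        abort(sprintf("missing events file for %s run %d: %s", sub, ri, ep),
              "io_error")
      vol <- RNifti::readNifti(bp)
      n_tr <- dim(vol)[4]
      betas <- t(vapply(seq_len(n_tr),
                        function(i) vol[, , , i][grid$mask],
                        numeric(grid$n_voxels)))
      ev <- utils::read.delim(ep, stringsAsFactors = FALSE)
      if (nrow(ev) != n_tr)
        abort(sprintf("events/beta mismatch for %s run %d: %d rows vs %d volumes",
                      sub, ri, nrow(ev), n_tr), "io_error")
      runs[[ri]] <- list(events = ev, betas = betas)
    }
    participants[[sub]] <- runs
  }
  structure(list(grid = grid, truth = truth, participants = participants),
            class = "beta_dataset")
}
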