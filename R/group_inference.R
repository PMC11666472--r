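#' Group-analysis configuration
#'
#' Defaults follow the study constants: 100 within-run permutations per
#' participant and model, 10,000 bootstrap group-average null maps, a
#' voxelwise cluster-forming threshold of P < 0.005 and a Benjamini-Hochberg
#' FDR cluster correction at q < 0.05.
#'
#' @param n_perm_per_subject Permutations per participant.
#' @param n_bootstrap Bootstrap group-average draws.
#' @param voxel_p Voxelwise cluster-forming p threshold.
#' @param cluster_q FDR level for cluster correction.
#' @param connectivity Voxel neighbourhood: 6, 18 or 26.
#' @param height `"voxelwise"` (per-voxel null quantile, default) or
#'   `"global"` (one pooled height threshold).
#' @param seed Integer seed.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(n_perm_per_subject = 100, n_bootstrap = 10000,
                            voxel_p = 0.005, cluster_q = 0.05,
                            connectivity = 18, height = "voxelwise",
                            seed = 1) {
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_q > 0, cluster_q < 1,
            connectivity %in% c(6, 18, 26))
  height <- match.arg(height, c("voxelwise", "global"))
  structure(list(n_perm_per_subject = n_perm_per_subject,
                 n_bootstrap = n_bootstrap, voxel_p = voxel_p,
                 cluster_q = cluster_q, connectivity = connectivity,
                 height = height, seed = seed),
            class = "analysis_config")
}

#' Per-participant permutation null maps
#'
#' For each participant and permutation, the sentence-to-feature-row mapping
#' is shuffled within each run (preserving the fold structure), the full
#' cross-validated encoding pipeline is re-run, and the resulting map is
#' smoothed like the observed maps. Permutation seeds derive
#' deterministically from `(config$seed, participant, permutation)`.
#'
#' @param dataset A `beta_dataset`.
#' @param model Encoding model name or object.
#' @param config An [analysis_config()].
#' @param fwhm_mm Smoothing applied to every permutation map (match the
#'   observed maps).
#' @param participants Subset of participants (default all).
#' @return A named list, one matrix per participant
#'   (`n_perm_per_subject` x voxels) of permutation map values, with the grid
#'   attached as attribute `"grid"`.
#' @export
permutation_maps <- function(dataset, model = "narrow_roles",
                             config = analysis_config(), fwhm_mm = 8,
                             participants = NULL) {
  if (is.character(model)) model <- encoding_model(model)
  participants <- participants %||% names(dataset$participants)
  grid <- dataset$grid
  out <- vector("list", length(participants))
  names(out) <- participants
  for (pi in seq_along(participants)) {
    p <- participants[pi]
    prepped <- prepare_participant(dataset, p, model)
    cvprep <- prepare_cv(prepped)
    M <- matrix(0, config$n_perm_per_subject, grid$n_voxels)
    for (b in seq_len(config$n_perm_per_subject)) {
      perm <- with_seed(derive_seed(config$seed, 31L, pi, b),
                        lapply(prepped, function(r) sample.int(nrow(r$X))))
      sc <- cv_scores(prepped, perm = perm, cvprep = cvprep)
      if (fwhm_mm > 0)
        sc <- smooth_map(vec_to_volume(sc, grid), fwhm_mm,
                         grid = grid)[grid$mask]
      M[b, ] <- sc
    }
    out[[pi]] <- M
  }
  attr(out, "grid") <- grid
  out
}

#' Bootstrap group-average null distribution
#'
#' Each bootstrap draw selects one permutation map per participant uniformly
#' with replacement and averages across participants, yielding group-average
#' maps under the null hypothesis.
#'
#' @param perm_maps Output of [permutation_maps()].
#' @param config An [analysis_config()]; `n_bootstrap` draws are made.
#' @return A `n_bootstrap` x voxels matrix of null group means, grid
#'   attached.
#' @export
bootstrap_group_null <- function(perm_maps, config = analysis_config()) {
  P <- length(perm_maps)
  if (P < 2L) abort("need at least 2 participants", "too_few_participants")
  if (any(vapply(perm_maps, nrow, 0L) < 1L))
    abort("empty permutation set", "empty_perms")
  B <- config$n_bootstrap
  V <- ncol(perm_maps[[1]])
  null <- matrix(0, B, V)
  with_seed(derive_seed(config$seed, 32L), {
    for (p in seq_len(P)) {
      idx <- sample.int(nrow(perm_maps[[p]]), B, replace = TRUE)
      null <- null + perm_maps[[p]][idx, , drop = FALSE]
    }
  })
  null <- null / P
  attr(null, "grid") <- attr(perm_maps, "grid")
  null
}

## connected components of a logical 3D array; returns sizes and a label
## array. Connectivity 6 = faces, 18 = + edges, 26 = + corners.
label_components <- function(mask, connectivity = 18) {
  d <- dim(mask)
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  nz <- abs(off$di) + abs(off$dj) + abs(off$dk)
  off <- off[nz > 0 & nz <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ]
  labels <- array(0L, d)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list(labels = labels, sizes = integer(0)))
  cur <- 0L
  sizes <- integer(0)
  for (s in seq_len(nrow(idx))) {
    v <- idx[s, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    cur <- cur + 1L
    queue <- matrix(v, 1L)
    labels[v[1], v[2], v[3]] <- cur
    size <- 1L
    while (nrow(queue) > 0L) {
      head <- queue[1L, ]
      queue <- queue[-1L, , drop = FALSE]
      ni <- head[1] + off$di; nj <- head[2] + off$dj; nk <- head[3] + off$dk
      ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
      for (t in which(ok)) {
        if (mask[ni[t], nj[t], nk[t]] && labels[ni[t], nj[t], nk[t]] == 0L) {
          labels[ni[t], nj[t], nk[t]] <- cur
          size <- size + 1L
          queue <- rbind(queue, c(ni[t], nj[t], nk[t]))
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(labels = labels, sizes = sizes)
}

#' Threshold a group map and run the FDR cluster test
#'
#' Voxelwise empirical p-values use the add-one rule
#' `p = (r + 1) / (B + 1)` with `r` the number of bootstrap null group means
#' at or above the observed value. Suprathreshold voxels (`p < voxel_p`) are
#' grouped into connected components; each null map is thresholded the same
#' way and its maximum cluster size collected, giving the null distribution
#' against which each observed cluster's uncorrected p-value is computed.
#' Cluster p-values are Benjamini-Hochberg corrected across clusters.
#'
#' @param observed A `genmap`, or a numeric vector of group-mean values over
#'   in-mask voxels.
#' @param null Bootstrap null matrix from [bootstrap_group_null()].
#' @param config An [analysis_config()].
#' @param grid Needed when `observed` is a bare vector and `null` carries no
#'   grid.
#' @return An object of class `cluster_result`: `clusters` (data frame with
#'   size, peak coordinates, peak value, `p_uncorrected`, `q_fdr`,
#'   `significant`), `voxel_p_map`, `thresholded` (3D array of observed
#'   values in significant clusters), `n_supra`, `config`.
#' @export
threshold_and_cluster <- function(observed, null, config = analysis_config(),
                                  grid = NULL) {
  grid <- grid %||% attr(null, "grid") %||%
    (if (inherits(observed, "genmap")) observed$grid)
  obs <- if (inherits(observed, "genmap")) map_values(observed)
         else as.numeric(observed)
  B <- nrow(null)
  V <- ncol(null)
  stopifnot(length(obs) == V)
  r <- colSums(sweep(null, 2L, obs, ">="))
  pv <- (r + 1) / (B + 1)
  ## m-th largest null value is the height threshold consistent with p < voxel_p
  m <- ceiling(config$voxel_p * (B + 1) - 1)
  empty <- function(reason) {
    structure(list(clusters = data.frame(), voxel_p_map = pv,
                   thresholded = array(0, grid$dims), n_supra = 0L,
                   config = config, reason = reason),
              class = "cluster_result")
  }
  if (m < 1) return(empty("B too small for voxel_p"))
  if (config$height == "voxelwise") {
    k <- B - m + 1L
    thr <- apply(null, 2L, function(x) sort(x, partial = k)[k])
  } else {
    thr <- rep(stats::quantile(null, 1 - config$voxel_p, names = FALSE), V)
  }
  supra <- obs > thr
  if (!any(supra)) return(empty("no suprathreshold voxels"))

  supra_vol <- vec_to_volume(supra, grid) > 0
  cc <- label_components(supra_vol, config$connectivity)
  ## null distribution of the maximum cluster size
  null_max <- numeric(B)
  for (b in seq_len(B)) {
    sb <- null[b, ] >= thr
    if (!any(sb)) { null_max[b] <- 0; next }
    null_max[b] <- max(label_components(vec_to_volume(sb, grid) > 0,
                                        config$connectivity)$sizes)
  }
  obs_vol <- vec_to_volume(obs, grid)
  rows <- lapply(seq_along(cc$sizes), function(ci) {
    vox <- which(cc$labels == ci, arr.ind = TRUE)
    vals <- obs_vol[cc$labels == ci]
    pk <- which.max(vals)
    data.frame(cluster = ci, size = cc$sizes[ci],
               peak_x = vox[pk, 1], peak_y = vox[pk, 2], peak_z = vox[pk, 3],
               peak_value = max(vals),
               p_uncorrected = (sum(null_max >= cc$sizes[ci]) + 1) / (B + 1))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$p_uncorrected, -tab$size), ]
  tab$q_fdr <- stats::p.adjust(tab$p_uncorrected, method = "BH")
  tab$significant <- tab$q_fdr <= config$cluster_q
  thr_vol <- array(0, grid$dims)
  for (ci in tab$cluster[tab$significant])
    thr_vol[cc$labels == ci] <- obs_vol[cc$labels == ci]
  structure(list(clusters = tab, voxel_p_map = pv, labels = cc$labels,
                 thresholded = thr_vol, n_supra = sum(supra),
                 config = config),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  if (nrow(x$clusters) == 0L) {
    cat("Cluster test: no suprathreshold voxels",
        if (!is.null(x$reason)) paste0("(", x$reason, ")"), "\n")
  } else {
    cat("Cluster test:", x$n_supra, "suprathreshold voxels,",
        nrow(x$clusters), "cluster(s),",
        sum(x$clusters$significant), "FDR-significant\n")
    print(x$clusters, row.names = FALSE)
  }
  invisible(x)
}

#' End-to-end group cluster inference
#'
#' Computes the observed group-mean map from per-participant generalization
#' maps, builds the permutation/bootstrap null, and runs the cluster test.
#'
#' @param maps List of `genmap` objects (one per participant), all smoothed
#'   the same way.
#' @param perm_maps Output of [permutation_maps()] for the same participants.
#' @param config An [analysis_config()].
#' @return A `cluster_result` (see [threshold_and_cluster()]), plus the
#'   observed group mean in element `group_mean`.
#' @export
group_cluster_test <- function(maps, perm_maps, config = analysis_config()) {
  vals <- vapply(maps, map_values, numeric(maps[[1]]$grid$n_voxels))
  gm <- rowMeans(vals)
  null <- bootstrap_group_null(perm_maps, config)
  res <- threshold_and_cluster(gm, null, config, grid = maps[[1]]$grid)
  res$group_mean <- gm
  res
}
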