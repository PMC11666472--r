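#' Fit per-voxel linear encoding weights
#'
#' Ordinary least squares with an intercept, solved by the Moore-Penrose
#' pseudoinverse so rank-deficient design matrices (e.g. duplicated
#' predictors, or more predictors than training sentences) yield the
#' minimum-norm least-squares solution rather than failing. No
#' regularization is applied.
#'
#' @param X_train Training design matrix (sentences x predictors).
#' @param Y_train Training betas (sentences x voxels or a vector).
#' @return A (predictors + 1) x voxels matrix of weights; row 1 is the
#'   intercept.
#' @export
fit_voxel_weights <- function(X_train, Y_train) {
  X_train <- as.matrix(X_train)
  Y_train <- as.matrix(Y_train)
  if (nrow(X_train) < 2L)
    abort("need at least 2 training sentences", "too_few_sentences")
  if (all(X_train == 0))
    abort("all-zero training design", "degenerate_design")
  A <- cbind(`(intercept)` = 1, X_train)
  MASS::ginv(A) %*% Y_train
}

## predictions for new sentences from fitted weights
predict_betas <- function(weights, X_test) {
  cbind(1, as.matrix(X_test)) %*% weights
}

#' Cross-validated generalization score for one voxel and run
#'
#' Computes the squared-difference matrix `D[i, j] = (pred_i - obs_j)^2` over
#' all prediction/observation pairings in a held-out run, z-scores all `n^2`
#' entries jointly (population SD), and contrasts the mean of the on-diagonal
#' entries (correct sentence pairings) with the mean of the off-diagonal
#' entries (incorrect pairings). Informative voxels give a negative value
#' (correct pairings have smaller prediction error); the final sign flip is
#' applied by [vw_encode()] after averaging runs, so that informative voxels
#' end up positive.
#'
#' @param pred,obs Numeric vectors of equal length `n >= 2`.
#' @return The run score. If all entries of `D` are equal (zero SD) the score
#'   is 0 and carries attribute `degenerate = TRUE`.
#' @export
#' @examples
#' generalization_score(c(1, 2, 4), c(1, 2, 4))  # negative: perfect prediction
generalization_score <- function(pred, obs) {
  n <- length(pred)
  stopifnot(n == length(obs), n >= 2L)
  D <- outer(pred, obs, function(p, o) (p - o)^2)
  s <- pop_sd(D)
  if (s < 1e-14 * (1 + mean(D)))
    return(structure(0, degenerate = TRUE))
  ## if either vector is constant, every observation (or prediction) enters
  ## the on- and off-diagonal means with equal weight: the contrast is zero
  ## by symmetry, exactly
  if (diff(range(pred)) == 0 || diff(range(obs)) == 0) return(0)
  Z <- (D - mean(D)) / s
  mean(diag(Z)) - (sum(Z) - sum(diag(Z))) / (n^2 - n)
}

## Vectorized run scores for many voxels at once, via moment sums:
##   sum(D)   = n(Sp2 + So2) - 2 Sp1 So1
##   sum(D^2) = n(Sp4 + So4) - 4(Sp3 So1 + Sp1 So3) + 6 Sp2 So2
## with Spk = colSums(pred^k), Sok = colSums(obs^k).
obs_moments <- function(obs) {
  n <- nrow(obs); V <- ncol(obs)
  o2 <- obs * obs
  list(So1 = .colSums(obs, n, V), So2 = .colSums(o2, n, V),
       So3 = .colSums(o2 * obs, n, V), So4 = .colSums(o2 * o2, n, V))
}

gen_score_cols <- function(pred, obs, om = obs_moments(obs)) {
  n <- nrow(pred); V <- ncol(pred)
  p2 <- pred * pred
  Sp1 <- .colSums(pred, n, V); Sp2 <- .colSums(p2, n, V)
  Sp3 <- .colSums(p2 * pred, n, V); Sp4 <- .colSums(p2 * p2, n, V)
  sumD <- n * (Sp2 + om$So2) - 2 * Sp1 * om$So1
  sumD2 <- n * (Sp4 + om$So4) - 4 * (Sp3 * om$So1 + Sp1 * om$So3) +
    6 * Sp2 * om$So2
  meanD <- sumD / n^2
  varD <- pmax(sumD2 / n^2 - meanD^2, 0)
  d <- pred - obs
  diag_sum <- .colSums(d * d, n, V)
  contrast <- diag_sum / n - (sumD - diag_sum) / (n^2 - n)
  s <- sqrt(varD)
  out <- contrast / s
  out[s < 1e-14 * (1 + meanD)] <- 0
  out
}

## Assemble per-run analysis data for one participant: kept production
## trials, their betas and the model design matrix.
prepare_participant <- function(dataset, participant, model) {
  if (is.character(model)) model <- encoding_model(model)
  runs <- dataset$participants[[participant]]
  if (is.null(runs)) abort(paste("no such participant:", participant),
                           "unknown_participant")
  prepped <- list()
  for (ri in seq_along(runs)) {
    ev <- runs[[ri]]$events
    use <- which((ev$kept %||% rep(TRUE, nrow(ev))) &
                 (ev$trial_type %||% "production") == "production")
    if (length(use) < 2L) {
      warning(sprintf("run %d of %s has < 2 usable sentences; dropped",
                      ri, participant))
      next
    }
    Y <- runs[[ri]]$betas[use, , drop = FALSE]
    prepped[[length(prepped) + 1L]] <-
      list(X = build_design_matrix(ev[use, , drop = FALSE], model),
           Y = Y, om = obs_moments(Y))
  }
  if (length(prepped) < 2L)
    abort("fewer than 2 usable runs", "too_few_runs")
  prepped
}

## Precompute per-fold quantities for leave-one-run-out scoring. For fold r,
## predictions are A_test %*% ginv(A_train) %*% Y_train; the hat-style matrix
## M = A_test %*% ginv(A_train) is fixed, and permuting the sentence ->
## feature-row mapping within runs is algebraically a column permutation of M
## (training runs) plus a row permutation of the predictions (test run),
## since ginv(P %*% A) = ginv(A) %*% t(P) for a permutation P.
prepare_cv <- function(prepped) {
  n_runs <- length(prepped)
  lapply(seq_len(n_runs), function(ri) {
    tr <- setdiff(seq_len(n_runs), ri)
    A_train <- do.call(rbind, lapply(prepped[tr], function(r) cbind(1, r$X)))
    if (nrow(A_train) < 2L)
      abort("need at least 2 training sentences", "too_few_sentences")
    Y_train <- do.call(rbind, lapply(prepped[tr], `[[`, "Y"))
    M <- cbind(1, prepped[[ri]]$X) %*% MASS::ginv(A_train)
    sizes <- vapply(prepped[tr], function(r) nrow(r$X), 0L)
    list(test = ri, train_runs = tr, train_sizes = sizes,
         M = M, Y_train = Y_train)
  })
}

## Cross-validated per-voxel scores (already sign-flipped: positive =
## informative). `perm` is an optional list of within-run permutations of the
## sentence -> feature-row mapping; `cvprep` may be passed to reuse the
## precomputed fold matrices.
cv_scores <- function(prepped, perm = NULL, cvprep = prepare_cv(prepped)) {
  n_runs <- length(prepped)
  V <- ncol(prepped[[1]]$Y)
  total <- numeric(V)
  for (fold in cvprep) {
    M <- fold$M
    if (!is.null(perm)) {
      off <- c(0L, cumsum(fold$train_sizes))
      qtrain <- unlist(lapply(seq_along(fold$train_runs), function(i)
        off[i] + perm[[fold$train_runs[i]]]))
      M <- M[, qtrain, drop = FALSE]
    }
    pred <- M %*% fold$Y_train
    if (!is.null(perm))
      pred <- pred[perm[[fold$test]], , drop = FALSE]
    total <- total + gen_score_cols(pred, prepped[[fold$test]]$Y,
                                    om = prepped[[fold$test]]$om)
  }
  -total / n_runs
}

#' Fit the voxel-wise encoding model for one participant
#'
#' The central fitting routine: for each leave-one-run-out fold, per-voxel
#' linear weights are estimated on the training runs
#' ([fit_voxel_weights()]), the held-out run's betas are predicted, and each
#' voxel receives the z-scored squared-difference diagonal-contrast score
#' ([generalization_score()]). Scores are averaged over folds and multiplied
#' by -1 so that informative voxels are positive.
#'
#' @param dataset A `beta_dataset`.
#' @param participant Participant name or index.
#' @param model Encoding model name or `encoding_model` object.
#' @param fwhm_mm If > 0, the resulting map is smoothed ([smooth_map()]).
#' @return An object of class `genmap`: the per-voxel generalization map with
#'   `image` (3D array), `grid`, `participant`, `model`, `smoothed`,
#'   `fwhm_mm`.
#' @export
vw_encode <- function(dataset, participant = 1, model = "narrow_roles",
                      fwhm_mm = 0) {
  if (is.numeric(participant))
    participant <- names(dataset$participants)[participant]
  if (is.character(model)) model <- encoding_model(model)
  if (model$name == "full_relational")
    warning(paste("full_relational has 512 predictors and is typically",
                  "untrainable at this design size; fitting anyway via",
                  "minimum-norm least squares"))
  prepped <- prepare_participant(dataset, participant, model)
  scores <- cv_scores(prepped)
  map <- genmap(scores, dataset$grid, participant, model$name)
  if (fwhm_mm > 0) map <- smooth_map(map, fwhm_mm) else map
}

genmap <- function(scores, grid, participant, model, smoothed = FALSE,
                   fwhm_mm = 0) {
  structure(list(image = vec_to_volume(scores, grid), grid = grid,
                 participant = participant, model = model,
                 smoothed = smoothed, fwhm_mm = fwhm_mm),
            class = "genmap")
}

#' Extract the per-voxel scores of a generalization map
#'
#' @param map A `genmap`.
#' @return Numeric vector over in-mask voxels.
#' @export
map_values <- function(map) map$image[map$grid$mask]

#' @export
print.genmap <- function(x, ...) {
  v <- map_values(x)
  cat("Generalization map:", x$participant, "/", x$model,
      if (x$smoothed) sprintf("(smoothed %.3g mm FWHM)", x$fwhm_mm)
      else "(unsmoothed)", "\n")
  cat(sprintf("  %d voxels; mean %.4g, sd %.4g, max %.4g\n",
              length(v), mean(v), stats::sd(v), max(v)))
  invisible(x)
}

#' @export
summary.genmap <- function(object, ...) {
  v <- map_values(object)
  c(n_voxels = length(v), mean = mean(v), sd = stats::sd(v),
    q95 = unname(stats::quantile(v, 0.95)), max = max(v))
}

#' @export
plot.genmap <- function(x, slice = NULL, ...) {
  slice <- slice %||% ceiling(dim(x$image)[3] / 2)
  graphics::image(x$image[, , slice], useRaster = TRUE,
                  main = sprintf("%s / %s (z = %d)", x$participant, x$model,
                                 slice), ...)
  invisible(x)
}

## ---- Gaussian smoothing -------------------------------------------------

gauss_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  R <- ceiling(4 * sigma)
  w <- exp(-(-R:R)^2 / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (d in -R:R) {
    idx <- seq_len(n)
    ok <- idx + d >= 1 & idx + d <= n
    K[cbind(idx[ok], (idx + d)[ok])] <- w[d + R + 1]
  }
  K
}

## separable 3D convolution with per-dimension band matrices
conv3_sep <- function(arr, Ks) {
  d <- dim(arr)
  m <- matrix(arr, d[1], d[2] * d[3])
  arr <- array(Ks[[1]] %*% m, d)
  a2 <- aperm(arr, c(2, 1, 3))
  m <- matrix(a2, d[2], d[1] * d[3])
  a2 <- array(Ks[[2]] %*% m, c(d[2], d[1], d[3]))
  arr <- aperm(a2, c(2, 1, 3))
  a3 <- aperm(arr, c(3, 1, 2))
  m <- matrix(a3, d[3], d[1] * d[2])
  a3 <- array(Ks[[3]] %*% m, c(d[3], d[1], d[2]))
  aperm(a3, c(2, 3, 1))
}

#' Smooth a generalization map
#'
#' Mask-aware Gaussian smoothing with
#' `sigma_voxels = fwhm_mm / (voxel_size_mm * 2 * sqrt(2 * log(2)))`.
#' Each voxel's value is redistributed with a Gaussian kernel renormalized to
#' the in-mask neighbourhood, so the total over the mask is preserved exactly
#' (to numerical precision) and values are not attenuated at mask or grid
#' edges.
#'
#' @param map A `genmap` (or a plain 3D array with a `grid` argument).
#' @param fwhm_mm Full width at half maximum in millimetres; 0 is the
#'   identity.
#' @param grid Required when `map` is a bare array.
#' @return The smoothed `genmap` (or array).
#' @export
smooth_map <- function(map, fwhm_mm = 8, grid = NULL) {
  if (fwhm_mm < 0) abort("fwhm must be nonnegative", "invalid_fwhm")
  bare <- !inherits(map, "genmap")
  if (bare) {
    stopifnot(!is.null(grid))
    img <- map
  } else {
    grid <- map$grid
    img <- map$image
  }
  if (fwhm_mm == 0) return(map)
  sigma <- fwhm_mm / (grid$voxel_size_mm * 2 * sqrt(2 * log(2)))
  Ks <- lapply(grid$dims, gauss_band, sigma = sigma)
  maskA <- array(as.double(grid$mask), grid$dims)
  norm <- conv3_sep(maskA, Ks)
  norm[norm == 0] <- 1
  sm <- conv3_sep((img * maskA) / norm, Ks) * maskA
  if (bare) return(sm)
  map$image <- sm
  map$smoothed <- TRUE
  map$fwhm_mm <- fwhm_mm
  map
}
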