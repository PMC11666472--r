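#' Define a region-of-interest mask
#'
#' @param grid A `voxel_grid`.
#' @param name ROI name (e.g. `"LIFGtri"`).
#' @param voxels Linear array indices, or a logical 3D array.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(grid, name, voxels) {
  if (is.array(voxels)) voxels <- which(voxels)
  voxels <- intersect(voxels, grid_mask_indices(grid))
  if (!length(voxels)) abort("empty ROI mask", "empty_roi")
  structure(list(name = name, grid = grid, voxels = voxels,
                 mask_cols = match(voxels, grid_mask_indices(grid))),
            class = "roi_mask")
}

#' Synthetic spherical parcels on a toy grid
#'
#' Emits ROI masks as spheres around given centers; a stand-in fixture
#' generator for atlas parcels when working with synthetic grids.
#'
#' @param grid A `voxel_grid`.
#' @param centers List or matrix of voxel-coordinate centers.
#' @param radius Sphere radius in voxels.
#' @param names ROI names.
#' @return A named list of `roi_mask` objects.
#' @export
make_parcels <- function(grid, centers, radius = 3, names = NULL) {
  if (is.matrix(centers))
    centers <- lapply(seq_len(nrow(centers)), function(i) centers[i, ])
  names <- names %||% paste0("parcel", seq_along(centers))
  out <- lapply(seq_along(centers), function(i)
    roi_mask(grid, names[i], sphere_indices(grid, centers[[i]], radius)))
  stats::setNames(out, names)
}

#' Voxel-selection thresholds
#'
#' @param t_high Primary one-sample t threshold (default 2.4).
#' @param t_low Fallback threshold when no voxel survives `t_high`
#'   (default 1.68).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(t_high = 2.4, t_low = 1.68) {
  stopifnot(t_low < t_high)
  structure(list(t_high = t_high, t_low = t_low), class = "selection_config")
}

## one-sample t over rows of a participants x voxels matrix
one_sample_t <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  s <- sqrt(colSums(sweep(M, 2L, mu)^2) / (n - 1))
  t <- mu / (s / sqrt(n))
  t[s == 0] <- 0
  t
}

#' Leave-one-participant-out ROI voxel selection
#'
#' For each held-out participant, a one-sample t-map (generalization score
#' against 0, across the remaining participants) is computed within the ROI;
#' the held-out participant's selection is the set of ROI voxels with
#' `t > t_high`, falling back to `t > t_low` if none survive. The held-out
#' participant's own data never enters their selection, avoiding
#' circularity.
#'
#' @param maps Named list of `genmap` objects, one per participant.
#' @param roi An `roi_mask`.
#' @param cfg A [selection_config()].
#' @return Named list, per participant: integer indices (columns into the
#'   in-mask voxel vector) of selected voxels, possibly empty (with a
#'   warning).
#' @export
lopo_select_voxels <- function(maps, roi, cfg = selection_config()) {
  P <- length(maps)
  if (P < 3L) abort("need at least 3 participants", "too_few_participants")
  cols <- roi$mask_cols
  M <- t(vapply(maps, function(m) map_values(m)[cols],
                numeric(length(cols))))
  sel <- vector("list", P)
  names(sel) <- names(maps)
  for (p in seq_len(P)) {
    t_map <- one_sample_t(M[-p, , drop = FALSE])
    keep <- which(t_map > cfg$t_high)
    if (!length(keep)) keep <- which(t_map > cfg$t_low)
    if (!length(keep))
      warning(sprintf("no voxels survive either threshold in %s for %s",
                      roi$name, names(maps)[p]))
    sel[[p]] <- cols[keep]
  }
  sel
}

#' ROI model-performance table
#'
#' Averages each participant's own generalization map over their
#' independently selected voxels, one row per participant x ROI x model x
#' modality cell; participants with empty selections are omitted.
#'
#' @param maps_by_model Named list: model name -> named list of per-
#'   participant `genmap`s.
#' @param rois Named list of `roi_mask` objects.
#' @param modality Label for these maps (`"production"` or
#'   `"comprehension"`).
#' @param cfg A [selection_config()].
#' @return Data frame with columns `participant`, `roi`, `model`,
#'   `modality`, `mean_score`, `n_voxels_selected`.
#' @export
roi_model_performance <- function(maps_by_model, rois,
                                  modality = "production",
                                  cfg = selection_config()) {
  rows <- list()
  for (model in names(maps_by_model)) {
    maps <- maps_by_model[[model]]
    for (roi in rois) {
      sel <- suppressWarnings(lopo_select_voxels(maps, roi, cfg))
      for (p in names(maps)) {
        vox <- sel[[p]]
        if (!length(vox)) next
        cols <- match(vox, grid_mask_indices(maps[[p]]$grid))
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, roi = roi$name, model = model,
          modality = modality,
          mean_score = mean(map_values(maps[[p]])[cols]),
          n_voxels_selected = length(vox),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Compare encoding models across ROIs with a linear mixed model
#'
#' Fits a linear mixed-effects model predicting mean generalization
#' performance from the factors `model`, `roi` and `modality` (factors with a
#' single level present are dropped from the formula), with by-participant
#' random effects. Each term is tested with a likelihood-ratio chi-square
#' (ML refits without the term, sum-to-zero contrasts), and pairwise model
#' contrasts within ROI x modality cells are computed with \pkg{emmeans}
#' (uncorrected by default, as is conventional for planned pairwise
#' follow-ups; set `adjust` otherwise).
#'
#' @param table Performance table from [roi_model_performance()] (rows from
#'   several models/modalities may be concatenated).
#' @param random Random-effects formula as a string; default
#'   `"(1 + roi | participant)"`, automatically simplified to
#'   `"(1 | participant)"` on singular or non-converging fits (with a
#'   message).
#' @param adjust Multiplicity adjustment for pairwise contrasts (default
#'   `"none"`).
#' @return An object of class `roi_comparison`: `effects` (term, Chisq, df,
#'   p), `pairwise` (emmeans contrast table), `fit`, `random_used`.
#' @export
compare_models <- function(table, random = "(1 + roi | participant)",
                           adjust = "none") {
  dat <- table
  stopifnot(nrow(dat) > 0)
  facs <- c("model", "roi", "modality")
  present <- facs[vapply(facs, function(f)
    length(unique(dat[[f]])) >= 2L, logical(1))]
  if (!length(present))
    abort("need at least one factor with 2+ levels", "invalid_factors")
  for (f in c(present, "participant"))
    dat[[f]] <- factor(dat[[f]])
  fixed <- paste(present, collapse = " * ")
  if (!"roi" %in% present)
    random <- sub("1 \\+ roi", "1", random)
  old_opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old_opts), add = TRUE)
  fit <- try_lmer(paste("mean_score ~", fixed, "+", random), dat)
  random_used <- random
  if (is.null(fit$fit) || fit$singular) {
    random_used <- "(1 | participant)"
    message("random-effects structure simplified to (1 | participant)")
    fit <- try_lmer(paste("mean_score ~", fixed, "+", random_used), dat)
    if (is.null(fit$fit))
      abort("mixed model failed to fit", "fit_error")
  }
  full <- fit$fit
  ## per-term likelihood-ratio tests: drop each term's model-matrix columns
  ## (sum-to-zero coding) and refit, so main effects remain testable in the
  ## presence of their interactions
  terms_obj <- stats::terms(stats::as.formula(paste("~", fixed)))
  terms_lab <- attr(terms_obj, "term.labels")
  mm <- stats::model.matrix(terms_obj, dat)
  asgn <- attr(mm, "assign")
  cn <- paste0(".mmcol", seq_len(ncol(mm)))
  dat2 <- dat
  dat2[cn] <- as.data.frame(mm)
  keep_int <- asgn != 0L                       # intercept handled by lmer
  full_cols <- try_lmer(paste("mean_score ~",
                              paste(cn[keep_int], collapse = " + "), "+",
                              random_used), dat2)$fit
  eff <- do.call(rbind, lapply(seq_along(terms_lab), function(ti) {
    kept <- cn[keep_int & asgn != ti]
    red_fixed <- if (length(kept)) paste(kept, collapse = " + ") else "1"
    red <- try_lmer(paste("mean_score ~", red_fixed, "+", random_used),
                    dat2)$fit
    if (is.null(red) || is.null(full_cols))
      return(data.frame(term = terms_lab[ti], Chisq = NA_real_,
                        Df = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    an <- suppressMessages(stats::anova(red, full_cols))
    data.frame(term = terms_lab[ti], Chisq = an$Chisq[2], Df = an$Df[2],
               p_value = an$`Pr(>Chisq)`[2], stringsAsFactors = FALSE)
  }))
  pw <- NULL
  if ("model" %in% present) {
    by <- intersect(c("roi", "modality"), present)
    em <- emmeans::emmeans(full, stats::as.formula("~ model"),
                           by = if (length(by)) by else NULL,
                           lmer.df = "asymptotic")
    pw <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = adjust))
  }
  structure(list(effects = eff, pairwise = pw, fit = full,
                 random_used = random_used),
            class = "roi_comparison")
}

try_lmer <- function(form, data) {
  form <- stats::as.formula(form)
  environment(form) <- environment()
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = data, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular =
                   lme4::.makeCC(action = "ignore", tol = 1e-4))))),
    error = function(e) NULL)
  list(fit = fit,
       singular = if (is.null(fit)) TRUE else lme4::isSingular(fit, tol = 1e-4))
}

#' @export
print.roi_comparison <- function(x, ...) {
  cat("Mixed-model term tests (likelihood-ratio chi-square):\n")
  print(x$effects, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("\nPairwise model contrasts:\n")
    print(utils::head(x$pairwise, 20), row.names = FALSE)
  }
  invisible(x)
}
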