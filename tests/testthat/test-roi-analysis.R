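## build genmap objects directly from score vectors
fake_maps <- function(score_matrix, grid, model = "narrow_roles") {
  maps <- lapply(seq_len(nrow(score_matrix)), function(p)
    sentencode:::genmap(score_matrix[p, ], grid, sprintf("sub-%02d", p),
                        model))
  names(maps) <- sprintf("sub-%02d", seq_len(nrow(score_matrix)))
  maps
}

test_that("LOPO selection finds a consistent sub-blob and never reads the held-out map", {
  grid <- voxel_grid(c(8, 8, 8))
  roi <- make_parcels(grid, list(c(4, 4, 4)), radius = 3)[[1]]
  P <- 6
  V <- grid$n_voxels
  ## deterministic background: alternating signs give |t| << t_low in every
  ## leave-one-out fold; the hot sub-blob has a large positive t in every fold
  scores <- matrix(rep_len(c(0.1, -0.1), P * V), P)
  hot <- roi$mask_cols[1:10]
  scores[, hot] <- 2 + 0.02 * seq_len(P)
  maps <- fake_maps(scores, grid)
  sel <- lopo_select_voxels(maps, roi)
  for (p in seq_len(P))
    expect_setequal(sel[[p]], roi$voxels[1:10])
  ## perturbing the held-out participant's own map leaves their selection fixed
  scores2 <- scores
  scores2[3, ] <- rnorm(V, 5, 3)
  sel2 <- lopo_select_voxels(fake_maps(scores2, grid), roi)
  expect_identical(sel2[[3]], sel[[3]])
  expect_error(lopo_select_voxels(maps[1:2], roi),
               class = "too_few_participants")
})

test_that("fallback threshold engages exactly when nothing passes t_high", {
  grid <- voxel_grid(c(6, 6, 6))
  roi <- roi_mask(grid, "R", which(grid$mask)[1:20])
  P <- 5
  V <- grid$n_voxels
  ## constant maps with controlled t: mean m, sd s across participants at one
  ## voxel gives t = m / (s / sqrt(P - 1)) for each held-out fold
  base <- matrix(0, P, V)
  vals <- c(0.9, 1.0, 1.1, 1.05, 0.95)          # high t at voxel 1
  base[, roi$mask_cols[1]] <- vals
  base[, roi$mask_cols[2]] <- c(0.5, -0.4, 0.6, -0.55, 0.1)  # sub-threshold
  cfg <- selection_config(t_high = 2.4, t_low = 1.68)
  sel <- lopo_select_voxels(fake_maps(base, grid), roi, cfg)
  for (p in 1:P) expect_identical(sel[[p]], roi$voxels[1])
  tstat <- function(x) mean(x) / (stats::sd(x) / sqrt(length(x)))
  ## values whose held-out-1 fold t lands between 1.68 and 2.4 -> t_low used
  shrunk <- base
  shrunk[, roi$mask_cols[1]] <- c(0.9, 1.6, -0.1, 1.5, 0.2)
  t_chk <- tstat(shrunk[-1, roi$mask_cols[1]])
  expect_true(t_chk > 1.68 && t_chk < 2.4)
  sel_low <- lopo_select_voxels(fake_maps(shrunk, grid), roi, cfg)
  expect_identical(sel_low[[1]], roi$voxels[1])
  ## near-null maps: empty selections warn
  nullm <- matrix(0, P, V)
  nullm[, roi$mask_cols] <- matrix(c(-1, 1, -1, 1, 0), P,
                                   length(roi$mask_cols))
  w <- testthat::capture_warnings(
    sel_null <- lopo_select_voxels(fake_maps(nullm, grid), roi, cfg))
  expect_true(any(grepl("no voxels survive", w)))
  expect_true(all(lengths(sel_null) == 0))
})

test_that("ROI performance averages the participant's own map over the selection", {
  grid <- voxel_grid(c(8, 8, 8))
  roi <- make_parcels(grid, list(c(4, 4, 4)), radius = 2,
                      names = "A")
  P <- 5
  V <- grid$n_voxels
  scores <- matrix(0, P, V)
  ## each participant's map is constant over the ROI; values vary across
  ## participants so the leave-one-out t is defined (and large) in every fold
  vals <- c(1.5, 0.7, 1.4, 1.6, 1.45)
  scores[, roi$A$mask_cols] <- vals             # recycled down rows
  maps <- fake_maps(scores, grid)
  perf <- roi_model_performance(list(narrow_roles = maps), roi)
  expect_equal(nrow(perf), P)
  expect_equal(perf$mean_score[perf$participant == "sub-02"], 0.7)
  expect_equal(perf$mean_score[perf$participant == "sub-01"], 1.5)
  expect_true(all(perf$n_voxels_selected >= 1))
})

test_that("identical model score patterns give a null pairwise contrast", {
  grid <- voxel_grid(c(6, 6, 6))
  roi <- make_parcels(grid, list(c(3, 3, 3)), radius = 2, names = "A")
  set.seed(3)
  scores <- matrix(rnorm(8 * grid$n_voxels, 0.5, 0.1), 8)
  maps <- fake_maps(scores, grid)
  perf <- roi_model_performance(list(m1 = maps, m2 = maps), roi)
  suppressMessages(cmp <- compare_models(perf, random = "(1 | participant)"))
  expect_lt(abs(cmp$pairwise$estimate[1]), 1e-10)
})

test_that("a planted model x ROI interaction is detected with chi-square tests", {
  set.seed(4)
  P <- 16
  tab <- expand.grid(participant = sprintf("s%02d", seq_len(P)),
                     roi = c("A", "B"), model = c("m1", "m2"),
                     modality = c("production", "comprehension"),
                     stringsAsFactors = FALSE)
  tab$mean_score <- stats::rnorm(nrow(tab), 0, 0.5) +
    ifelse(tab$roi == "A" & tab$model == "m2", 2, 0) +
    rep(stats::rnorm(P, 0, 0.3), length.out = nrow(tab))
  suppressMessages(cmp <- compare_models(tab))
  eff <- cmp$effects
  expect_lt(eff$p_value[eff$term == "model:roi"], 0.05)
  expect_true(all(is.finite(eff$Chisq)))
  expect_equal(nrow(eff), 7)                    # 3 mains, 3 two-way, 1 three-way
  ## pairwise contrast significant in ROI A, not in B (production)
  pw <- cmp$pairwise
  pa <- pw[pw$roi == "A" & pw$modality == "production", ]
  pb <- pw[pw$roi == "B" & pw$modality == "production", ]
  expect_lt(pa$p.value, 0.01)
  expect_gt(pb$p.value, 0.05)
})

test_that("single-level factors are dropped rather than breaking the fit", {
  set.seed(5)
  P <- 10
  tab <- expand.grid(participant = sprintf("s%02d", seq_len(P)),
                     roi = "A", model = c("m1", "m2"),
                     modality = "production", stringsAsFactors = FALSE)
  tab$mean_score <- stats::rnorm(nrow(tab)) + ifelse(tab$model == "m2", 1.5, 0)
  suppressMessages(cmp <- compare_models(tab))
  expect_equal(cmp$effects$term, "model")
  expect_lt(cmp$effects$p_value, 0.05)
})
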