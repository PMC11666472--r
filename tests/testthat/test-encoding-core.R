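test_that("voxel weights recover a noiseless linear system exactly", {
  set.seed(1)
  X <- matrix(rbinom(50 * 6, 1, 0.5), 50)
  w <- rnorm(6)
  y <- 1.5 + X %*% w
  W <- fit_voxel_weights(X, y)
  expect_lt(max(abs(cbind(1, X) %*% W - y)), 1e-10)
  expect_equal(unname(W[-1, 1]), w, tolerance = 1e-8)
})

test_that("rank-deficient designs yield finite minimum-norm solutions", {
  set.seed(2)
  X <- matrix(rnorm(20 * 3), 20)
  X <- cbind(X, X[, 3])                         # duplicated column
  y <- rnorm(20)
  W <- fit_voxel_weights(X, y)
  expect_true(all(is.finite(W)))
  ## predictions agree with the full-rank fit on the deduplicated design
  W0 <- fit_voxel_weights(X[, 1:3], y)
  expect_equal(cbind(1, X) %*% W, cbind(1, X[, 1:3]) %*% W0,
               tolerance = 1e-8)
  expect_error(fit_voxel_weights(X[1, , drop = FALSE], y[1]),
               class = "too_few_sentences")
  expect_error(fit_voxel_weights(matrix(0, 10, 2), rnorm(10)),
               class = "degenerate_design")
})

test_that("predictions equal a normal-equations oracle on full-rank problems", {
  set.seed(3)
  for (rep in 1:5) {
    X <- matrix(rnorm(10 * 4), 10)
    Y <- matrix(rnorm(10 * 3), 10)
    A <- cbind(1, X)
    W_oracle <- solve(crossprod(A), crossprod(A, Y))
    W <- fit_voxel_weights(X, Y)
    expect_equal(A %*% W, A %*% W_oracle, tolerance = 1e-8)
  }
})

test_that("generalization score matches the brute-force oracle to 1e-12", {
  set.seed(4)
  for (n in c(3, 4, 5, 7, 10)) {
    for (rep in 1:20) {
      pred <- rnorm(n)
      obs <- rnorm(n)
      expect_equal(generalization_score(pred, obs), brute_score(pred, obs),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
  ## the documented 3-point case
  expect_equal(generalization_score(c(1, 2, 4), c(1, 2, 4)),
               brute_score(c(1, 2, 4), c(1, 2, 4)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(generalization_score(c(1, 2, 4), c(1, 2, 4)), 0)
})

test_that("degenerate and constant-prediction inputs behave as specified", {
  obs <- c(0.3, -1, 2, 0.7)
  expect_identical(as.numeric(generalization_score(rep(2, 4), obs)), 0)
  deg <- generalization_score(rep(1, 3), rep(1, 3))
  expect_identical(as.numeric(deg), 0)
  expect_true(isTRUE(attr(deg, "degenerate")))
})

test_that("the score is invariant under joint affine rescaling", {
  set.seed(5)
  pred <- rnorm(8); obs <- rnorm(8)
  base <- generalization_score(pred, obs)
  for (a in c(0.1, 3, -2)) {
    for (b in c(0, 5)) {
      expect_equal(generalization_score(a * pred + b, a * obs + b), base,
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})

test_that("vectorized scoring equals the scalar implementation", {
  set.seed(6)
  pred <- matrix(rnorm(12 * 50), 12)
  obs <- matrix(rnorm(12 * 50), 12)
  fast <- sentencode:::gen_score_cols(pred, obs)
  slow <- vapply(seq_len(50), function(j)
    as.numeric(generalization_score(pred[, j], obs[, j])), numeric(1))
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("cross-validated maps are fold-order invariant and sign positive on planted voxels", {
  des <- cached_design(1)
  grid <- voxel_grid(c(8, 8, 8))
  truth <- plant_blobs(grid, centers = list(c(4, 4, 4)), radius = 2,
                       models = "narrow_roles", signal_amplitude = 1,
                       noise_sd = 1, seed = 7)
  ds <- generate_dataset(des, truth, n_participants = 1, seed = 7)
  prepped <- sentencode:::prepare_participant(ds, "sub-01", "narrow_roles")
  sc <- sentencode:::cv_scores(prepped)
  sc_perm_runs <- sentencode:::cv_scores(prepped[c(3, 1, 6, 2, 5, 4)])
  expect_equal(sort(sc), sort(sc_perm_runs), tolerance = 1e-10)

  blob_cols <- match(truth$blobs[[1]]$voxels, which(grid$mask))
  expect_gt(mean(sc[blob_cols]), 0)
  expect_gt(mean(sc[blob_cols]), 10 * abs(mean(sc[-blob_cols])))
})

test_that("row-permuted designs destroy planted signal", {
  des <- cached_design(1)
  grid <- voxel_grid(c(8, 8, 8))
  truth <- plant_blobs(grid, centers = list(c(4, 4, 4)), radius = 2,
                       models = "narrow_roles", signal_amplitude = 1,
                       noise_sd = 1, seed = 8)
  ds <- generate_dataset(des, truth, n_participants = 1, seed = 8)
  prepped <- sentencode:::prepare_participant(ds, "sub-01", "narrow_roles")
  blob_cols <- match(truth$blobs[[1]]$voxels, which(grid$mask))
  set.seed(8)
  perm_means <- replicate(15, {
    perm <- lapply(prepped, function(r) sample.int(nrow(r$X)))
    mean(sentencode:::cv_scores(prepped, perm = perm)[blob_cols])
  })
  obs_mean <- mean(sentencode:::cv_scores(prepped)[blob_cols])
  expect_gt(obs_mean, max(perm_means))                # signal >> any null draw
  expect_lt(abs(mean(perm_means)),
            4 * stats::sd(perm_means) / sqrt(length(perm_means)))
})

test_that("runs with too few usable trials are dropped, and too few runs error", {
  ds <- small_null_dataset()
  ds$participants[[1]][[2]]$events$kept <- FALSE
  expect_warning(vw_encode(ds, 1, "bag_of_nouns_cat"), "dropped")
  for (ri in 2:6) ds$participants[[1]][[ri]]$events$kept <- FALSE
  w <- testthat::capture_warnings(
    err <- tryCatch(vw_encode(ds, 1, "bag_of_nouns_cat"), error = identity))
  expect_s3_class(err, "too_few_runs")
  expect_true(any(grepl("dropped", w)))
})

test_that("smoothing follows the FWHM formula, preserves mass and has identity at 0", {
  grid <- voxel_grid(c(16, 16, 16), voxel_size_mm = 2.5)
  sigma <- 8 / (2.5 * 2 * sqrt(2 * log(2)))
  expect_equal(sigma, 1.3589, tolerance = 1e-4)
  delta <- array(0, grid$dims); delta[8, 8, 8] <- 1
  sm <- smooth_map(delta, 8, grid = grid)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_equal(sm[8, 8, 8],
               prod(rep(sentencode:::gauss_band(16, sigma)[8, 8], 3)) /
                 1,                      # central kernel weight cubed
               tolerance = 1e-6)
  set.seed(9)
  img <- array(rnorm(prod(grid$dims)), grid$dims)
  sm2 <- smooth_map(img, 8, grid = grid)
  expect_equal(sum(sm2), sum(img), tolerance = 1e-6 * abs(sum(img)) + 1e-8)
  expect_lt(stats::sd(sm2), stats::sd(img))           # smoothing shrinks variance
  ## identity and error cases
  m <- sentencode:::genmap(rnorm(grid$n_voxels), grid, "sub-01", "broad_roles")
  expect_identical(smooth_map(m, 0)$image, m$image)
  expect_error(smooth_map(m, -1), class = "invalid_fwhm")
  ## mask-aware: values outside the mask stay zero, in-mask mass preserved
  mask <- array(FALSE, grid$dims); mask[4:12, 4:12, 4:12] <- TRUE
  mgrid <- voxel_grid(grid$dims, 2.5, mask)
  img_m <- array(0, grid$dims); img_m[mask] <- rnorm(sum(mask))
  sm3 <- smooth_map(img_m, 8, grid = mgrid)
  expect_true(all(sm3[!mask] == 0))
  expect_equal(sum(sm3[mask]), sum(img_m[mask]), tolerance = 1e-8)
})

test_that("the full-relational model fits with a warning, not an error", {
  ds <- small_null_dataset()
  expect_warning(m <- vw_encode(ds, 1, "full_relational"), "512")
  expect_true(all(is.finite(map_values(m))))
})
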