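make_tiles <- function(md, noise = 0, seed = 2, cfg = small_config(tile_noise_sd = noise)) {
  generate_tiles(md, cfg, seed)
}

test_that("downsample_tiles keeps min(k, n) tiles per image, reproducibly", {
  cfg <- small_config()
  md <- generate_metadata(cfg, 1)
  tiles <- make_tiles(md)
  ds1 <- fibroscope:::with_seed(5, downsample_tiles(tiles, 6))
  ds2 <- fibroscope:::with_seed(5, downsample_tiles(tiles, 6))
  expect_identical(ds1, ds2)
  n <- table(tiles$image_id)
  nds <- table(ds1$image_id)
  expect_true(all(nds == pmin(n[names(nds)], 6)))
  expect_true(all(!duplicated(ds1$tile_id)))
  big <- tiles[tiles$image_id == names(which.max(n)), ]
  ds_big <- fibroscope:::with_seed(1, downsample_tiles(big, 6))
  expect_equal(nrow(ds_big), 6)
  small <- tiles[tiles$image_id == names(which.min(n)), ][1:3, ]
  expect_equal(nrow(fibroscope:::with_seed(1, downsample_tiles(small, 6))), 3)
  expect_error(downsample_tiles(tiles[0, ], 6), "empty")
})

test_that("patient features are tile-median PC scores matching a 2x2 eigen oracle", {
  # toy 2-feature covariance with known eigenstructure
  set.seed(3)
  n <- 400
  x1 <- rnorm(n, sd = 2); x2 <- x1 * 0.5 + rnorm(n, sd = 0.5)
  X <- cbind(x1, x2)
  basis <- fibroscope:::pca_fit(X, var_kept = 1)
  S <- cov(scale(X))
  eig <- eigen(S)
  # rotation spans the same eigenvectors (up to sign)
  for (k in 1:2) {
    expect_equal(abs(sum(basis$rotation[, k] * eig$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
  # identical tiles -> patient vector equals that tile's score
  tiles <- data.frame(image_id = rep(c("a", "b"), each = 3),
                      tile_id = paste0("t", 1:6))
  f <- matrix(rep(c(1, 2), each = 3), 6, 8)
  colnames(f) <- fibroscope:::TILE_FEATURE_NAMES
  tiles <- cbind(tiles, f)
  b2 <- fibroscope:::pca_fit(fibroscope:::tile_feature_matrix(tiles), 0.9)
  pf <- patient_features(tiles, b2)
  sc <- fibroscope:::pca_project(b2, fibroscope:::tile_feature_matrix(tiles))
  expect_equal(unname(pf["a", ]), unname(sc[1, ]))
  # median of symmetric scores is the midpoint
  expect_equal(unname((pf["a", 1] + pf["b", 1]) / 2),
               unname(median(sc[c(1, 4), 1])))
})

test_that("one rep gives stage-monotone mean predictions on noiseless tiles", {
  cfg <- small_config(tile_noise_sd = 0)
  md <- generate_metadata(cfg, 1)
  tiles <- make_tiles(md, 0)
  ic <- imagescore_config(n_reps = 1, cv_folds = 4, seed = 3)
  pred <- fibroscope:::with_seed(3, fit_predict_rep(tiles, md, ic))
  m <- tapply(pred[md$sample_id], md$stage, mean)
  expect_equal(unname(fibroscope:::kendall_tau(m, seq_along(m))), 1)
  # stage targets: normal histology trains at -1
  expect_equal(unname(ic$stage_targets["N"]), -1)
})

test_that("constant tile features give constant predictions", {
  md <- data.frame(sample_id = sprintf("s%02d", 1:12),
                   stage = stage_factor(rep(c("N", "F0", "F2", "F4"), 3)))
  f <- matrix(1, 36, 8, dimnames = list(NULL, fibroscope:::TILE_FEATURE_NAMES))
  tiles <- cbind(data.frame(image_id = rep(md$sample_id, each = 3),
                            tile_id = paste0("t", 1:36)), f)
  ic <- imagescore_config(n_reps = 1, cv_folds = 3, seed = 1)
  pred <- fibroscope:::with_seed(1, fit_predict_rep(tiles, md, ic))
  # the SVR cannot distinguish samples: predictions are fold-level constants
  expect_lte(length(unique(round(pred, 9))), ic$cv_folds)
})

test_that("imagescore is the median of rep scores and is seed-deterministic", {
  cfg <- small_config()
  md <- generate_metadata(cfg, 1)
  tiles <- make_tiles(md, 0.3)
  ic <- imagescore_config(n_reps = 5, cv_folds = 4, seed = 9)
  r1 <- compute_imagescore(tiles, md, ic)
  r2 <- compute_imagescore(tiles, md, ic)
  expect_identical(r1$rep_scores, r2$rep_scores)
  expect_equal(r1$per_sample$imagescore,
               apply(r1$rep_scores, 1, median), ignore_attr = TRUE)
  expect_true(all(r1$per_sample$n_predictions <= ic$n_reps))
  # median robustness: corrupting 2 of 5 reps by +0.2 moves the median <= 0.2
  rep2 <- r1$rep_scores
  rep2[, 1:2] <- rep2[, 1:2] + 0.2
  med2 <- apply(rep2, 1, median)
  expect_true(all(abs(med2 - r1$per_sample$imagescore) <= 0.2 + 1e-12))
})

test_that("tile row order does not change the imagescore", {
  cfg <- small_config()
  md <- generate_metadata(cfg, 1)
  tiles <- make_tiles(md, 0.1)
  ic <- imagescore_config(n_reps = 3, cv_folds = 4, seed = 4)
  r1 <- compute_imagescore(tiles, md, ic)
  perm <- fibroscope:::with_seed(99, sample(nrow(tiles)))
  r2 <- compute_imagescore(tiles[perm, ], md, ic)
  expect_equal(r1$per_sample$imagescore, r2$per_sample$imagescore,
               tolerance = 1e-9)
})

test_that("more reps shrink the across-seed spread of the imagescore", {
  cfg <- small_config()
  md <- generate_metadata(cfg, 1)
  tiles <- make_tiles(md, 0.3)
  spread <- sapply(c(2, 8), function(reps) {
    scores <- sapply(c(11, 12, 13), function(s) {
      ic <- imagescore_config(n_reps = reps, cv_folds = 4, seed = s)
      compute_imagescore(tiles, md, ic)$per_sample$imagescore
    })
    mean(apply(scores, 1, sd))
  })
  expect_lt(spread[2], spread[1])
})

test_that("cluster_tiles recovers separated blobs and sane ratios", {
  skip_if_not_installed("mclust")
  set.seed(6)
  centers <- matrix(rnorm(4 * 8, sd = 30), 4, 8)
  lab_true <- rep(1:4, each = 50)
  f <- centers[lab_true, ] + matrix(rnorm(200 * 8, sd = 0.5), 200, 8)
  colnames(f) <- fibroscope:::TILE_FEATURE_NAMES
  tiles <- cbind(data.frame(image_id = rep(sprintf("im%d", 1:10), each = 20),
                            tile_id = paste0("t", 1:200)), f)
  cl <- cluster_tiles(tiles, 4, seed = 2)
  expect_equal(mclust::adjustedRandIndex(cl$labels, lab_true), 1)
  expect_equal(rowSums(cl$cluster_ratios), rep(1, 10), ignore_attr = TRUE)
  expect_error(cluster_tiles(tiles[1:3, ], 4), "exceeds")
})

test_that("collagen-driven tile cluster ratios rise with stage", {
  st <- small_study()
  cl <- cluster_tiles(st$tiles, 4, st$metadata, seed = 5)
  expect_gt(max(cl$tau_vs_stage), 0)
})
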