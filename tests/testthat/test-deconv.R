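test_that("build_design summarizes profiles, variances and size factors", {
  ref <- toy_reference()
  d <- build_design(ref, min_cells = 2)
  expect_s3_class(d, "reference_design")
  # identical subjects -> zero cross-subject variance
  expect_equal(max(d$v), 0)
  expect_equal(colSums(d$theta_bar), c(A = 1, B = 1))
  # type A cells have total 19, type B 19 -> equal size factors here
  expect_equal(unname(d$size_factors["A"] / d$size_factors["B"]), 1)
  # absent cell type errors by name
  ref2 <- ref
  ref2$cell_types <- c("A", "B", "ghost")
  expect_error(build_design(ref2, min_cells = 2), "ghost")
})

test_that("size factors track cell library size", {
  cfg <- small_config()
  ref <- generate_reference(cfg, 5)
  d <- build_design(ref)
  # hepatocytes are generated with 2x mean library size
  r <- d$size_factors["hepatocyte"] / d$size_factors["macrophage"]
  expect_equal(unname(r), 2, tolerance = 0.1)
})

test_that("deconvolve recovers exact mixtures (3-gene toy and grid oracle)", {
  theta <- matrix(c(10, 0, 5, 0, 10, 5), ncol = 2,
                  dimnames = list(paste0("g", 1:3), c("A", "B")))
  theta <- sweep(theta, 2, colSums(theta), "/")
  design <- structure(list(theta_bar = theta,
                           v = theta * 0, size_factors = c(A = 1, B = 1),
                           cell_types = c("A", "B"), genes = rownames(theta),
                           n_subjects = 2),
                      class = "reference_design")
  y <- as.vector(theta %*% c(0.6, 0.4))
  bulk <- matrix(y, ncol = 1, dimnames = list(rownames(theta), "s1"))
  est <- deconvolve(bulk, design, min_shared_genes = 3)
  expect_equal(unname(est$proportions[1, ]), c(0.6, 0.4), tolerance = 1e-9)
  expect_lt(est$residual_norm[1], 1e-10)
  # brute-force simplex grid agrees within grid resolution
  oracle <- grid_simplex_solve(theta, y, res = 0.01)
  expect_equal(oracle$q, unname(est$proportions[1, ]), tolerance = 0.011)
  # pure-type bulk -> unit vector
  pure <- matrix(theta[, "B"], ncol = 1,
                 dimnames = list(rownames(theta), "p"))
  estp <- deconvolve(pure, design, min_shared_genes = 3)
  expect_equal(unname(estp$proportions[1, ]), c(0, 1), tolerance = 1e-9)
})

test_that("zero cross-subject variance reduces to single-pass NNLS", {
  set.seed(1)
  theta <- matrix(rexp(50 * 3), 50, 3,
                  dimnames = list(paste0("g", 1:50), c("A", "B", "C")))
  theta <- sweep(theta, 2, colSums(theta), "/")
  design <- structure(list(theta_bar = theta, v = theta * 0,
                           size_factors = c(A = 1, B = 1, C = 1),
                           cell_types = colnames(theta), genes = rownames(theta),
                           n_subjects = 2),
                      class = "reference_design")
  y <- as.vector(theta %*% c(0.2, 0.5, 0.3)) + abs(rnorm(50, 0, 1e-3))
  bulk <- matrix(y, ncol = 1, dimnames = list(rownames(theta), "s"))
  est <- deconvolve(bulk, design)
  sw <- pracma::lsqnonneg(theta, y / sum(y))$x
  expect_equal(unname(est$loadings[1, ]), sw, tolerance = 1e-9)
  expect_equal(unname(est$n_iter[1]), 2)  # weights constant -> immediate stop
})

test_that("deconvolution is scale invariant and errors on all-zero samples", {
  st <- small_study()
  design <- build_design(st$reference)
  bulk <- st$bulk_counts[, 1:3]
  est1 <- deconvolve(bulk, design)
  est2 <- deconvolve(bulk * 7.3, design)
  expect_equal(est1$proportions, est2$proportions, tolerance = 1e-12)
  bulk0 <- bulk; bulk0[, 2] <- 0
  expect_error(deconvolve(bulk0, design), "all zero")
})

test_that("pseudobulk conserves counts and hits its target proportions", {
  st <- small_study()
  pb <- make_pseudobulk(st$reference, n_mixtures = 6, cells_per_mixture = 60,
                        seed = 11)
  expect_equal(rowSums(pb$cells_drawn), rep(60, 6), tolerance = 1,
               ignore_attr = TRUE)
  expect_equal(rowSums(pb$true_proportions), rep(1, 6), ignore_attr = TRUE)
  # conservation: mixture totals equal summed cell totals
  tot <- colSums(pb$mixtures)
  expect_true(all(tot > 0))
  pb2 <- make_pseudobulk(st$reference, n_mixtures = 6, cells_per_mixture = 60,
                         seed = 11)
  expect_identical(pb$mixtures, pb2$mixtures)
})

test_that("evaluate_recovery matches hand calculations", {
  truth <- matrix(c(0.2, 0.5, 0.8, 0.8, 0.5, 0.2), 3,
                  dimnames = list(NULL, c("A", "B")))
  expect_equal(evaluate_recovery(truth, truth)$overall_rmse, 0)
  expect_equal(evaluate_recovery(truth, truth)$per_type$pearson_r, c(1, 1))
  est <- truth; est[, 1] <- est[, 1] + 0.01
  r <- evaluate_recovery(est, truth)
  expect_equal(r$per_type$rmse, c(0.01, 0), tolerance = 1e-12)
  expect_equal(r$overall_rmse, sqrt(mean(c(rep(1e-4, 3), 0, 0, 0))))
  # constant truth -> r is NA, not an error
  truth_c <- truth; truth_c[, 2] <- 0.5
  expect_true(is.na(evaluate_recovery(est, truth_c)$per_type$pearson_r[2]))
  expect_error(evaluate_recovery(truth[1:2, ], truth[1:2, ]), "3 mixtures")
})

test_that("associate_proportions reports trends and the <5% flag", {
  md <- data.frame(sample_id = sprintf("s%02d", 1:12),
                   stage = stage_factor(rep(c("N", "F0", "F2", "F4"), each = 3)))
  p <- cbind(rising = seq(0.2, 0.9, length.out = 12),
             rare = rep(0.03, 12))
  p <- cbind(p, other = 1 - rowSums(p))
  rownames(p) <- md$sample_id
  a <- associate_proportions(p, md)
  # strictly increasing proportion: tau = 1 on per-stage means
  expect_equal(a$per_type$tau_stage_means[1], 1, tolerance = 1e-9)
  expect_gt(a$per_type$tau_stage[1], 0.9)
  expect_true(a$per_type$flagged[a$per_type$cell_type == "rare"])
  expect_false(a$per_type$flagged[a$per_type$cell_type == "rising"])
  sc <- stats::setNames(seq_len(12), md$sample_id)
  a2 <- associate_proportions(p, md, imagescore = sc)
  expect_equal(a2$per_type$tau_imagescore[1], 1, tolerance = 1e-9)
})
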