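test_that("transform_expression is CPM-invariant log2", {
  m <- matrix(c(999, 1e6 - 999, 10, 90), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  tr <- transform_expression(m)
  expect_equal(tr["a", "s1"], log2(999 + 1), tolerance = 1e-9)
  expect_equal(transform_expression(m * c(1, 1))[, "s2"],
               transform_expression(cbind(m[, 1], m[, 2] * 13))[, 2],
               ignore_attr = TRUE)
  expect_equal(unname(transform_expression(matrix(c(0, 5), 2))[1, 1]), 0)
  m0 <- m; m0[, 2] <- 0
  expect_error(transform_expression(m0), "zero total")
})

test_that("composite score ranks by cv with deterministic tie-breaks", {
  sc <- rbind(constant = rep(2, 3),
              varying = c(1, 2, 3),
              varying2 = c(1, 2, 3) * 2)
  colnames(sc) <- paste0("s", 1:3)
  gs <- structure(list(scores = sc,
                       gene_stats = data.frame(
                         gene = rownames(sc),
                         mean = rowMeans(sc),
                         sd = apply(sc, 1, sd),
                         cv = apply(sc, 1, sd) / abs(rowMeans(sc)))),
                  class = "gene_score_matrix")
  # arithmetic: scores 1,2,3 -> mean 2, sd 1, cv 0.5
  expect_equal(gs$gene_stats$cv[2], 0.5)
  comp <- composite_score(gs, top_n = 2)
  # equal cv for the two varying genes: lexicographic tie-break
  expect_equal(comp$top_genes, c("varying", "varying2"))
  expect_equal(tail(comp$ranked_genes, 1), "constant")
  expect_equal(unname(comp$composite["s3"]), mean(c(3, 6)))
})

test_that("composite score is invariant to gene order", {
  st <- small_study()
  v <- transform_expression(st$bulk_counts)
  fit <- fit_ordinal_per_gene(v[1:60, ], st$metadata$stage)
  gs <- gene_level_score(fit, v[1:60, ])
  c1 <- composite_score(gs, top_n = 20, st$metadata$stage)
  perm <- rev(seq_len(nrow(gs$scores)))
  gs2 <- gs
  gs2$scores <- gs$scores[perm, ]
  gs2$gene_stats <- gs$gene_stats[perm, ]
  c2 <- composite_score(gs2, top_n = 20, st$metadata$stage)
  expect_equal(c1$composite, c2$composite)
  expect_equal(c1$top_genes, c2$top_genes)
})

test_that("lasso limits: full shrinkage, OLS at lambda -> 0, soft threshold", {
  set.seed(8)
  n <- 20; p <- 10
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  b <- c(2, -1.5, rep(0, p - 2))
  yresp <- as.vector(x %*% b + rnorm(n, 0, 0.1))
  expr <- t(x); colnames(expr) <- paste0("s", 1:n)
  names(yresp) <- colnames(expr)
  # lambda -> infinity: empty model, intercept = mean response
  sig_inf <- fit_lasso_signature(expr, yresp, folds = 5, seed = 1)
  xs <- scale(x)
  co_inf <- coef(glmnet::glmnet(xs, yresp, standardize = FALSE), s = 1e6)
  expect_equal(sum(co_inf[-1] != 0), 0)
  expect_equal(co_inf[1], mean(yresp), tolerance = 1e-8, ignore_attr = TRUE)
  # lambda = 0 on a full-rank toy equals OLS
  fit0 <- glmnet::glmnet(xs, yresp, lambda = c(1, 0.1, 0), standardize = FALSE,
                         thresh = 1e-14)
  ols <- coef(lm(yresp ~ xs))
  expect_equal(as.vector(coef(fit0, s = 0, exact = FALSE)),
               unname(ols), tolerance = 1e-4)
  # univariate soft-thresholding closed form
  x1 <- scale(x[, 1]) * sqrt(n / (n - 1))   # unit 1/n-variance
  yc <- yresp - mean(yresp)
  rho <- mean(x1 * yc)
  for (lam in c(0.05, 0.2)) {
    f1 <- glmnet::glmnet(cbind(x1, 0), yc, lambda = lam, standardize = FALSE,
                         intercept = FALSE, thresh = 1e-14)
    expect_equal(unname(f1$beta[1, 1]), sign(rho) * max(abs(rho) - lam, 0),
                 tolerance = 1e-6)
  }
  # nonzero count is monotone along the path
  sig <- fit_lasso_signature(expr, yresp, folds = 5, seed = 1)
  nz <- sig$cv_mse$nzero[order(sig$cv_mse$lambda, decreasing = TRUE)]
  expect_true(all(diff(nz) >= 0))
})

test_that("target-size lambda rule hits the requested signature size", {
  st <- small_study()
  v <- transform_expression(st$bulk_counts)
  fit <- fit_ordinal_per_gene(v, st$metadata$stage)
  gs <- gene_level_score(fit, v)
  comp <- composite_score(gs, top_n = 100, st$metadata$stage)
  sig <- fit_lasso_signature(v, comp$composite, folds = 5,
                             lambda_rule = "target_size:10", seed = 2)
  expect_equal(length(sig$genes), 10)
  sig_min <- fit_lasso_signature(v, comp$composite, folds = 5,
                                 lambda_rule = "min_mse", seed = 2)
  expect_equal(unname(sig_min$lambda),
               sig_min$cv_mse$lambda[which.min(sig_min$cv_mse$mse)])
  vl <- validate_lambda(v, comp$composite, sig$lambda, folds = 5, seed = 3)
  expect_true(is.finite(vl$mse) && vl$mse >= 0)
  expect_error(fit_lasso_signature(v, comp$composite, lambda_rule = "bogus"),
               "lambda_rule")
})

test_that("scoring reproduces fitted values and ignores zero-weight genes", {
  st <- small_study()
  v <- transform_expression(st$bulk_counts)
  fit <- fit_ordinal_per_gene(v, st$metadata$stage)
  gs <- gene_level_score(fit, v)
  comp <- composite_score(gs, top_n = 100, st$metadata$stage)
  sig <- fit_lasso_signature(v, comp$composite, folds = 5, seed = 2)
  val <- score_and_validate(sig, v, st$metadata$stage, comp$composite)
  # training-matrix scores equal the lasso fitted values
  xs <- scale(t(v)[, names(sig$center)], center = sig$center, scale = sig$scale)
  fitted <- sig$intercept + as.vector(xs[, sig$genes, drop = FALSE] %*% sig$weights)
  expect_equal(unname(val$scores), fitted, tolerance = 1e-9)
  # perturbing a zero-weight gene leaves scores unchanged
  zero_gene <- setdiff(rownames(v), sig$genes)[1]
  v2 <- v; v2[zero_gene, ] <- v2[zero_gene, ] + 5
  val2 <- score_and_validate(sig, v2, st$metadata$stage)
  expect_equal(val$scores, val2$scores)
  # missing genes: warn when some absent, error when none
  v3 <- v[setdiff(rownames(v), sig$genes[1]), ]
  expect_warning(score_and_validate(sig, v3), "missing")
  v4 <- v[setdiff(rownames(v), sig$genes), ]
  expect_error(score_and_validate(sig, v4), "no signature genes")
})

test_that("train/test signature generalization keeps tau close", {
  cfg <- study_config(n_per_stage = c(N = 16, F0 = 16, F1 = 16, F2 = 16,
                                      F3 = 16, F4 = 16),
                      n_genes = 400, de_frac = 0.1, lfc_scale = 1, seed = 31)
  st <- generate_study(cfg)
  v <- transform_expression(st$bulk_counts)
  idx_tr <- which(seq_len(ncol(v)) %% 2 == 1)
  idx_te <- setdiff(seq_len(ncol(v)), idx_tr)
  fit <- fit_ordinal_per_gene(v[, idx_tr], st$metadata$stage[idx_tr])
  gs <- gene_level_score(fit, v[, idx_tr])
  comp <- composite_score(gs, top_n = 100, st$metadata$stage[idx_tr])
  sig <- fit_lasso_signature(v[, idx_tr], comp$composite, folds = 5, seed = 3)
  tr <- score_and_validate(sig, v[, idx_tr], st$metadata$stage[idx_tr])
  te <- score_and_validate(sig, v[, idx_te], st$metadata$stage[idx_te])
  expect_lt(abs(tr$tau_stage - te$tau_stage), 0.15)
})

test_that("gene pattern clustering recovers planted trajectory archetypes", {
  skip_if_not_installed("mclust")
  set.seed(12)
  stages <- stage_factor(rep(c("N", "F0", "F1", "F2", "F3", "F4"), each = 5))
  sn <- fibroscope:::stage_numeric(stages)
  up <- t(sapply(1:100, function(i) sn + rnorm(30, 0, 0.1)))
  dn <- t(sapply(1:100, function(i) -sn + rnorm(30, 0, 0.1)))
  expr <- rbind(up, dn)
  rownames(expr) <- paste0("g", 1:200)
  colnames(expr) <- paste0("s", 1:30)
  cl <- cluster_gene_patterns(expr, stages, rownames(expr), n_clusters = 2,
                              min_cluster = 50)
  truth <- rep(1:2, each = 100)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  expect_equal(length(cl$reported), 2)
  # z-scored rows have mean 0, sd 1
  z <- t(scale(t(expr)))
  expect_equal(unname(rowMeans(z)[1]), 0, tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)[1]), 1, tolerance = 1e-12)
  # a cluster of exactly min_cluster genes is excluded (strictly "more than")
  cl2 <- cluster_gene_patterns(expr[c(1:50, 101:200), ], stages,
                               rownames(expr)[c(1:50, 101:200)],
                               n_clusters = 2, min_cluster = 50)
  sizes2 <- as.integer(cl2$sizes)
  expect_true(all(sort(sizes2) == c(50, 100)))
  expect_equal(length(cl2$reported), 1)
})

test_that("gene-set overlap reproduces the published signature arithmetic", {
  s26 <- fibrosis_signature_genes("26")
  s98 <- fibrosis_signature_genes("98")
  expect_equal(length(s26), 26)
  expect_equal(length(s98), 98)
  ov <- gene_set_overlap(list(sig26 = s26, sig98 = s98))
  expect_equal(unname(ov$pairwise["sig26", "sig98"]), 23L)
  # identical sets: intersection equals union; disjoint: zero
  ov2 <- gene_set_overlap(list(a = s26, b = s26))
  expect_equal(ov2$common, ov2$union)
  ov3 <- gene_set_overlap(list(a = c("x1"), b = c("y1")))
  expect_equal(length(ov3$common), 0)
  expect_error(gene_set_overlap(list(a = character(0))), "nonempty")
})
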