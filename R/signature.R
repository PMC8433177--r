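## Fibrosis gene signatures: per-gene proportional-odds models on
## variance-stabilized expression -> probability-weighted gene-level scores
## -> coefficient-of-variation ranking -> top-n composite sample score ->
## lasso regression of the composite on expression.

#' Variance-stabilizing transform stand-in
#'
#' `log2(CPM + 1)` per sample: a deterministic monotone variance-stabilizing
#' transform of raw counts. Pipelines with an externally transformed matrix
#' (e.g. a model-based VST) can pass it directly to the downstream steps.
#'
#' @param counts genes x samples nonnegative count matrix.
#' @return transformed genes x samples matrix.
#' @export
transform_expression <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  log2(sweep(counts, 2, tot / 1e6, "/") + 1)
}

#' Probability-weighted gene-level scores
#'
#' For each converged gene and each sample, the score is the expected stage
#' level under the fitted proportional-odds model,
#' `sum_k k * P(Y = k | x)` with levels coded `0..K-1`.
#'
#' @param fit an `ordinal_fit_set` from [fit_ordinal_per_gene()].
#' @param expr the genes x samples expression matrix the fit used.
#' @return a `gene_score_matrix`: list with `scores` (converged genes x
#'   samples) and `gene_stats` (mean, sd, cv per gene).
#' @export
gene_level_score <- function(fit, expr) {
  expr <- as.matrix(expr)
  genes <- names(fit$beta)[fit$converged]
  if (length(genes) == 0) stop("no converged gene fits")
  K <- length(fit$levels)
  scores <- matrix(NA_real_, length(genes), ncol(expr),
                   dimnames = list(genes, colnames(expr)))
  lev_vals <- seq_len(K) - 1
  for (g in genes) {
    pr <- ordinal_probs(fit$zeta[g, ], fit$beta[g], expr[g, ])
    scores[g, ] <- as.vector(lev_vals %*% pr)
  }
  mu <- rowMeans(scores)
  sd_ <- apply(scores, 1, stats::sd)
  gene_stats <- data.frame(gene = genes, mean = mu, sd = sd_,
                           cv = ifelse(abs(mu) < 1e-8, NA_real_, sd_ / abs(mu)),
                           stringsAsFactors = FALSE, row.names = NULL)
  structure(list(scores = scores, gene_stats = gene_stats),
            class = "gene_score_matrix")
}

#' Composite sample-level fibrosis score
#'
#' Ranks genes by the coefficient of variation of their gene-level scores
#' (descending; ties broken by gene identifier) and averages the top `top_n`
#' genes per sample. Genes with near-zero mean score are excluded from
#' ranking.
#'
#' @param scores a `gene_score_matrix` from [gene_level_score()].
#' @param top_n number of top-ranked genes averaged (default 1000).
#' @param stages optional per-sample stage labels; if given, Kendall tau of
#'   the composite against ordinal stage is reported.
#' @return list: `composite` (named per-sample score), `top_genes`,
#'   `ranked_genes`, `tau_stage` (or NA).
#' @export
composite_score <- function(scores, top_n = 1000, stages = NULL) {
  st <- scores$gene_stats
  st <- st[!is.na(st$cv), , drop = FALSE]
  if (nrow(st) == 0) stop("no scored genes with nonzero mean")
  ord <- order(-st$cv, st$gene)
  ranked <- st$gene[ord]
  top <- ranked[seq_len(min(top_n, length(ranked)))]
  composite <- colMeans(scores$scores[top, , drop = FALSE])
  tau <- if (is.null(stages)) NA_real_ else
    kendall_tau(composite, stage_numeric(stages))
  list(composite = composite, top_genes = top, ranked_genes = ranked,
       tau_stage = tau)
}

parse_lambda_rule <- function(lambda_rule) {
  if (grepl("^target_size:[0-9]+$", lambda_rule)) {
    list(kind = "target_size", k = as.integer(sub("target_size:", "", lambda_rule)))
  } else if (lambda_rule %in% c("min_mse", "one_se")) {
    list(kind = lambda_rule)
  } else {
    stop("lambda_rule must be 'min_mse', 'one_se' or 'target_size:<k>'")
  }
}

#' Fit a lasso gene signature against the composite score
#'
#' Standardizes predictors, computes the lasso path over a log-spaced lambda
#' grid (4 decades below the all-zero lambda) and selects lambda by k-fold
#' cross-validated mean squared error: the MSE-minimizing lambda
#' (`"min_mse"`), the one-standard-error lambda (`"one_se"`), or the lambda
#' whose path solution has a requested number of nonzero genes
#' (`"target_size:k"`, smallest-CV-MSE among matches; nearest size with a
#' warning if no exact match).
#'
#' @param expr genes x samples expression matrix.
#' @param composite named per-sample response (the composite score).
#' @param folds CV folds (default 10).
#' @param lambda_rule selection rule (see above).
#' @param seed seed for fold assignment.
#' @param nlambda,lambda_min_ratio lasso path grid controls.
#' @return a `lasso_signature`: list with `lambda`, `genes`, `weights`,
#'   `intercept`, `cv_mse` (lambda, mse, mse_se, nzero), `center`, `scale`,
#'   `lambda_rule`, `folds`, `seed`.
#' @export
fit_lasso_signature <- function(expr, composite, folds = 10,
                                lambda_rule = "min_mse", seed = 1,
                                nlambda = 100, lambda_min_ratio = 1e-4) {
  expr <- as.matrix(expr)
  if (!is.null(names(composite))) {
    composite <- composite[colnames(expr)]
  }
  n <- ncol(expr)
  if (n < folds) stop("need at least `folds` samples")
  x <- t(expr)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  keep <- scl > 0
  xs <- scale(x[, keep, drop = FALSE], center = ctr[keep], scale = scl[keep])
  rule <- parse_lambda_rule(lambda_rule)
  foldid <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  cv <- glmnet::cv.glmnet(xs, composite, family = "gaussian", alpha = 1,
                          nlambda = nlambda, lambda.min.ratio = lambda_min_ratio,
                          foldid = foldid, standardize = FALSE, thresh = 1e-10)
  cv_tab <- data.frame(lambda = cv$lambda, mse = cv$cvm, mse_se = cv$cvsd,
                       nzero = as.integer(cv$nzero))
  lambda <- switch(rule$kind,
    min_mse = cv$lambda.min,
    one_se = cv$lambda.1se,
    target_size = {
      hits <- cv_tab[cv_tab$nzero == rule$k, , drop = FALSE]
      if (nrow(hits) > 0) {
        hits$lambda[which.min(hits$mse)]
      } else {
        warning("no lambda on the grid yields exactly ", rule$k,
                " genes; returning nearest size")
        cv_tab$lambda[which.min(abs(cv_tab$nzero - rule$k))]
      }
    })
  co <- as.matrix(stats::coef(cv$glmnet.fit, s = lambda, exact = FALSE))
  nz <- which(co[-1, 1] != 0)
  structure(list(lambda = lambda, genes = rownames(co)[-1][nz],
                 weights = co[-1, 1][nz], intercept = co[1, 1],
                 cv_mse = cv_tab, center = ctr[keep], scale = scl[keep],
                 lambda_rule = lambda_rule, folds = folds, seed = seed),
            class = "lasso_signature")
}

#' @export
print.lasso_signature <- function(x, ...) {
  cat("Lasso fibrosis signature:", length(x$genes), "genes at lambda =",
      signif(x$lambda, 4), "(rule:", x$lambda_rule, ")\n")
  invisible(x)
}

#' Re-validate a chosen lambda by cross-validation
#'
#' Recomputes the CV mean squared error at a fixed lambda with a fresh fold
#' split (e.g. five folds to confirm a ten-fold choice).
#'
#' @inheritParams fit_lasso_signature
#' @param lambda penalty value to validate.
#' @return list: `lambda`, `folds`, `mse`.
#' @export
validate_lambda <- function(expr, composite, lambda, folds = 5, seed = 1) {
  expr <- as.matrix(expr)
  if (!is.null(names(composite))) composite <- composite[colnames(expr)]
  x <- t(expr)
  scl <- apply(x, 2, stats::sd)
  x <- scale(x[, scl > 0, drop = FALSE])
  n <- nrow(x)
  foldid <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  errs <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- foldid != f
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], composite[tr],
                          standardize = FALSE, thresh = 1e-10)
    pred <- stats::predict(fit, newx = x[!tr, , drop = FALSE], s = lambda)
    errs[!tr] <- (composite[!tr] - pred)^2
  }
  list(lambda = lambda, folds = folds, mse = mean(errs))
}

#' Score samples with a lasso signature
#'
#' Standardizes expression with the signature's stored centers/scales and
#' computes `intercept + sum(weights * z)`. Signature genes missing from the
#' matrix are treated as zero after standardization (with a warning); fewer
#' than half present is an error.
#'
#' @param signature a `lasso_signature`.
#' @param expr genes x samples expression matrix to score.
#' @param stages optional stage labels for a Kendall tau report.
#' @param composite optional reference score for a Kendall tau report.
#' @return list: `scores` (named per-sample), `tau_stage`, `tau_composite`,
#'   `n_genes_used`.
#' @export
score_and_validate <- function(signature, expr, stages = NULL, composite = NULL) {
  expr <- as.matrix(expr)
  present <- intersect(signature$genes, rownames(expr))
  if (length(present) == 0) stop("no signature genes present in expression matrix")
  if (length(present) < length(signature$genes)) {
    miss <- setdiff(signature$genes, present)
    if (length(present) < length(signature$genes) / 2) {
      stop("fewer than half of the signature genes present (",
           length(present), "/", length(signature$genes), ")")
    }
    warning(length(miss), " signature gene(s) missing; treated as zero: ",
            paste(utils::head(miss, 5), collapse = ", "))
  }
  z <- (expr[present, , drop = FALSE] - signature$center[present]) /
    signature$scale[present]
  scores <- signature$intercept +
    as.vector(crossprod(z, signature$weights[present]))
  names(scores) <- colnames(expr)
  list(scores = scores,
       tau_stage = if (is.null(stages)) NA_real_ else
         kendall_tau(scores, stage_numeric(stages)),
       tau_composite = if (is.null(composite)) NA_real_ else
         kendall_tau(scores, composite[colnames(expr)]),
       n_genes_used = length(present))
}

#' Cluster gene expression patterns along the stage axis
#'
#' Z-scores each gene across samples, summarizes it as its per-stage mean
#' trajectory, clusters trajectories hierarchically (correlation distance,
#' average linkage) and cuts the tree at `n_clusters`. Clusters with
#' `min_cluster` genes or fewer are excluded from the reported set (strictly
#' "more than `min_cluster`").
#'
#' @param expr genes x samples expression matrix.
#' @param stages per-sample stage labels.
#' @param de_genes genes to cluster (must be rows of `expr`).
#' @param n_clusters number of tree cuts.
#' @param min_cluster report clusters with strictly more genes than this.
#' @return list: `labels` (named gene -> cluster), `sizes`, `reported`
#'   (cluster ids passing the size rule), `trajectories` (genes x stages).
#' @export
cluster_gene_patterns <- function(expr, stages, de_genes, n_clusters = 6,
                                  min_cluster = 50) {
  expr <- as.matrix(expr)
  missing <- setdiff(de_genes, rownames(expr))
  if (length(missing) > 0) stop("de_genes not in expr: ",
                                paste(utils::head(missing, 5), collapse = ", "))
  stg <- droplevels(stage_factor(stages))
  x <- expr[de_genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  x <- x[sds > 0, , drop = FALSE]
  z <- t(scale(t(x)))
  traj <- sapply(levels(stg), function(s) rowMeans(z[, stg == s, drop = FALSE]))
  n_clusters <- min(n_clusters, nrow(traj))
  d <- stats::as.dist(1 - stats::cor(t(traj)))
  d[!is.finite(d)] <- 2   # constant trajectories: maximal distance
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = n_clusters)
  sizes <- table(labels)
  reported <- as.integer(names(sizes)[sizes > min_cluster])
  list(labels = labels, sizes = sizes, reported = reported,
       trajectories = traj)
}

#' Gene-set overlap arithmetic
#'
#' Case-normalizes identifiers and reports pairwise intersection sizes, the
#' intersection across all sets, and the union.
#'
#' @param sets named list of character gene vectors.
#' @return list: `pairwise` (sets x sets intersection-size matrix), `common`
#'   (genes in every set), `union`, `sizes`.
#' @export
gene_set_overlap <- function(sets) {
  if (length(sets) == 0 || any(lengths(sets) == 0)) stop("sets must be nonempty")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, function(s) unique(toupper(trimws(s))))
  k <- length(sets)
  pairwise <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  }
  list(pairwise = pairwise,
       common = sort(Reduce(intersect, sets)),
       union = sort(Reduce(union, sets)),
       sizes = lengths(sets))
}
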