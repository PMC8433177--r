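## Continuous fibrosis score (ImageScore) from tile-level morphometric
## features: repeated tile down-sampling, per-fold PCA patient features, and
## cross-validated epsilon-insensitive support-vector regression against
## numeric stage targets; the per-sample score is the median over
## repetitions. Tiles are also clustered (k-means on standardized PC scores)
## and cluster occupancy ratios related to stage.

TILE_FEATURE_NAMES <- c("compactness_tissue", "compactness_voids", "n_voids",
                        "equivalence_radius", "collagen_area",
                        "collagen_per_tissue", "collagen_per_section",
                        "void_area")

#' ImageScore configuration
#'
#' @param n_reps down-sampling repetitions (default 100).
#' @param tiles_per_image tiles retained per image per repetition (default 6;
#'   images with fewer tiles keep them all).
#' @param cv_folds patient-level cross-validation folds (default 20).
#' @param stage_targets named numeric regression targets per stage, strictly
#'   increasing over the stage order (default N=-1, F0..F4=0..4).
#' @param pca_var_kept cumulative variance fraction retained by the PCA.
#' @param svr_cost,svr_epsilon SVR cost and epsilon (RBF kernel); gamma is
#'   `1/n_features` of the PCA score space.
#' @param seed integer seed.
#' @return validated `imagescore_config` list.
#' @export
imagescore_config <- function(n_reps = 100, tiles_per_image = 6, cv_folds = 20,
                              stage_targets = STAGE_TARGETS,
                              pca_var_kept = 0.90, svr_cost = 1,
                              svr_epsilon = 0.1, seed = 1) {
  stopifnot(n_reps >= 1, tiles_per_image >= 1, cv_folds >= 2,
            pca_var_kept > 0, pca_var_kept <= 1)
  tg <- stage_targets[STAGE_LEVELS]
  if (anyNA(tg) || any(diff(tg) <= 0)) {
    stop("stage_targets must cover all stages and increase strictly over the stage order")
  }
  structure(list(n_reps = as.integer(n_reps),
                 tiles_per_image = as.integer(tiles_per_image),
                 cv_folds = as.integer(cv_folds), stage_targets = tg,
                 pca_var_kept = pca_var_kept, svr_cost = svr_cost,
                 svr_epsilon = svr_epsilon, seed = as.integer(seed)),
            class = "imagescore_config")
}

tile_feature_matrix <- function(tiles) {
  missing <- setdiff(TILE_FEATURE_NAMES, colnames(tiles))
  if (length(missing) > 0) stop("tile table missing feature column(s): ",
                                paste(missing, collapse = ", "))
  m <- as.matrix(tiles[, TILE_FEATURE_NAMES])
  if (anyNA(m)) stop("tile features contain missing values")
  m
}

#' Down-sample tiles per image
#'
#' Samples `k` tiles per image without replacement; images with fewer than
#' `k` tiles keep all their tiles. Uses the current RNG stream.
#'
#' @param tiles tile feature table (image_id, tile_id, features).
#' @param k tiles per image.
#' @return subset of `tiles`.
#' @export
downsample_tiles <- function(tiles, k) {
  if (nrow(tiles) == 0) stop("empty tile table")
  stopifnot(k >= 1)
  ## canonical order by tile_id inside each image so the selection (and the
  ## final score) is invariant to the row order of the input table
  idx <- unlist(lapply(split(seq_len(nrow(tiles)), tiles$image_id), function(ii) {
    ii <- ii[order(tiles$tile_id[ii])]
    if (length(ii) <= k) ii else sort(ii[sample(length(ii), k)])
  }), use.names = FALSE)
  out <- tiles[idx, , drop = FALSE]
  out[order(out$image_id, out$tile_id), , drop = FALSE]
}

## PCA with zero-variance-safe scaling; keeps the smallest component count
## reaching `var_kept` cumulative variance.
pca_fit <- function(X, var_kept) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(X, center = ctr, scale = scl)
  sv <- svd(Z)
  ev <- sv$d^2
  if (sum(ev) == 0) {
    n_pc <- 1L
  } else {
    cum <- cumsum(ev) / sum(ev)
    n_pc <- max(1L, which(cum >= var_kept)[1])
  }
  list(center = ctr, scale = scl, rotation = sv$v[, seq_len(n_pc), drop = FALSE],
       n_pc = n_pc, var_explained = if (sum(ev) == 0) rep(0, length(ev)) else ev / sum(ev))
}

pca_project <- function(basis, X) {
  scale(X, center = basis$center, scale = basis$scale) %*% basis$rotation
}

#' Patient-wise features from tile PC scores
#'
#' Projects tiles onto a fitted PCA basis and takes the componentwise median
#' of each image's tile scores.
#'
#' @param tiles tile feature table.
#' @param pca_basis a basis from the internal PCA fit (center, scale,
#'   rotation), fit on training tiles only.
#' @return images x components matrix of medians.
#' @export
patient_features <- function(tiles, pca_basis) {
  sc <- pca_project(pca_basis, tile_feature_matrix(tiles))
  ids <- unique(tiles$image_id)
  out <- t(vapply(ids, function(im) {
    apply(sc[tiles$image_id == im, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(sc))))
  if (ncol(sc) == 1) out <- matrix(out, ncol = 1)
  rownames(out) <- ids
  out
}

#' One down-sampling repetition of the ImageScore fit
#'
#' Down-samples tiles, partitions samples into patient-level CV folds, and
#' per fold fits PCA on training tiles and an RBF SVR of training patient
#' features on the numeric stage targets; held-out patients are predicted
#' from their projected tile medians. Every sample receives exactly one
#' prediction.
#'
#' @param tiles tile feature table.
#' @param metadata data.frame with sample_id and stage.
#' @param config an [imagescore_config()].
#' @return named numeric vector of predicted scores, one per sample.
#' @export
fit_predict_rep <- function(tiles, metadata, config = imagescore_config()) {
  n <- nrow(metadata)
  if (n < config$cv_folds) stop("need >= cv_folds samples with stage labels")
  ds <- downsample_tiles(tiles, config$tiles_per_image)
  fold <- sample(rep(seq_len(config$cv_folds), length.out = n))
  targets <- config$stage_targets[as.character(metadata$stage)]
  preds <- stats::setNames(rep(NA_real_, n), metadata$sample_id)
  for (f in seq_len(config$cv_folds)) {
    train_ids <- metadata$sample_id[fold != f]
    test_ids <- metadata$sample_id[fold == f]
    if (length(train_ids) < 2) stop("fold ", f, " has < 2 training samples")
    tr_tiles <- ds[ds$image_id %in% train_ids, , drop = FALSE]
    te_tiles <- ds[ds$image_id %in% test_ids, , drop = FALSE]
    basis <- pca_fit(tile_feature_matrix(tr_tiles), config$pca_var_kept)
    xtr <- patient_features(tr_tiles, basis)
    xte <- patient_features(te_tiles, basis)
    ytr <- targets[match(rownames(xtr), metadata$sample_id)]
    fit <- e1071::svm(x = xtr, y = ytr, type = "eps-regression",
                      kernel = "radial", cost = config$svr_cost,
                      epsilon = config$svr_epsilon, gamma = 1 / ncol(xtr),
                      scale = FALSE)
    preds[rownames(xte)] <- stats::predict(fit, newdata = xte)
  }
  preds
}

#' Compute per-sample ImageScores
#'
#' Runs `n_reps` down-sampling repetitions of [fit_predict_rep()]; the final
#' per-sample ImageScore is the median of its repetition predictions.
#' Reports Kendall tau between ImageScore and ordinal stage.
#'
#' @inheritParams fit_predict_rep
#' @return an `imagescore_result`: list with `per_sample` (sample_id,
#'   imagescore, n_predictions), `rep_scores` (samples x reps),
#'   `tau_vs_stage` (Kendall tau-b), `gamma_vs_stage` (Goodman-Kruskal
#'   gamma; 1 when every stage-untied pair is ranked correctly), `config`.
#' @export
compute_imagescore <- function(tiles, metadata, config = imagescore_config()) {
  rep_scores <- with_seed(config$seed, {
    vapply(seq_len(config$n_reps),
           function(r) fit_predict_rep(tiles, metadata, config),
           numeric(nrow(metadata)))
  })
  rep_scores <- matrix(rep_scores, nrow = nrow(metadata),
                       dimnames = list(metadata$sample_id, NULL))
  imagescore <- apply(rep_scores, 1, stats::median, na.rm = TRUE)
  per_sample <- data.frame(sample_id = metadata$sample_id,
                           imagescore = imagescore,
                           n_predictions = rowSums(!is.na(rep_scores)),
                           row.names = NULL, stringsAsFactors = FALSE)
  stg <- stage_numeric(metadata$stage)
  structure(list(per_sample = per_sample, rep_scores = rep_scores,
                 tau_vs_stage = kendall_tau(imagescore, stg),
                 gamma_vs_stage = rank_concordance(imagescore, stg),
                 config = config),
            class = "imagescore_result")
}

#' @export
print.imagescore_result <- function(x, ...) {
  cat("ImageScore over", ncol(x$rep_scores), "repetitions,",
      nrow(x$per_sample), "samples; Kendall tau vs stage =",
      round(x$tau_vs_stage, 3), "\n")
  invisible(x)
}

#' Cluster tiles and relate cluster occupancy to stage
#'
#' k-means (k-means++-style multi-restart via `nstart`) on the standardized
#' PC scores of all tiles; per-sample ratio vectors are the fraction of each
#' image's tiles per cluster. If metadata is supplied, Kendall tau of each
#' cluster's ratio against stage is reported.
#'
#' @param tiles tile feature table.
#' @param n_clusters number of clusters (default 4).
#' @param metadata optional data.frame with sample_id and stage.
#' @param pca_var_kept cumulative variance retained before clustering.
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return list: `labels` (per tile), `cluster_ratios` (samples x clusters),
#'   `tau_vs_stage` (per cluster, if metadata given), `centers`.
#' @export
cluster_tiles <- function(tiles, n_clusters = 4, metadata = NULL,
                          pca_var_kept = 0.90, seed = 1, nstart = 10) {
  X <- tile_feature_matrix(tiles)
  if (n_clusters > nrow(X)) stop("n_clusters exceeds number of tiles")
  basis <- pca_fit(X, pca_var_kept)
  sc <- scale(pca_project(basis, X))
  sc[, attr(sc, "scaled:scale") == 0] <- 0
  km <- with_seed(seed, stats::kmeans(sc, centers = n_clusters, nstart = nstart))
  ratios <- t(vapply(split(km$cluster, tiles$image_id), function(lab) {
    tabulate(lab, n_clusters) / length(lab)
  }, numeric(n_clusters)))
  colnames(ratios) <- paste0("cluster", seq_len(n_clusters))
  tau <- NULL
  if (!is.null(metadata)) {
    stg <- stage_numeric(metadata$stage[match(rownames(ratios), metadata$sample_id)])
    tau <- apply(ratios, 2, function(r) kendall_tau(r, stg))
  }
  list(labels = km$cluster, cluster_ratios = ratios, tau_vs_stage = tau,
       centers = km$centers)
}
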