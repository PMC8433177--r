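## Cross-subject-consistency-weighted NNLS deconvolution of bulk RNA-seq
## against a multi-subject single-cell reference, in the spirit of MuSiC:
## genes whose cell-type profiles are inconsistent across reference subjects
## are down-weighted, and cell-size factors convert transcript loadings into
## cell-count proportions. The weight iteration implemented here is
## MuSiC-style, not a clone of that package.

#' Build a deconvolution design from a single-cell reference
#'
#' Summarizes a labeled multi-subject reference into per-subject relative
#' expression profiles `theta_gcs` (columns sum to 1 per (cell type, subject)),
#' their cross-subject mean `theta_bar` and variance `v`, and cell-size
#' factors `S_c` (mean library size of cells of type c). Genes with an
#' all-zero mean profile are dropped.
#'
#' @param reference a `single_cell_reference` (sparse cells x genes `counts` +
#'   `annotation` with cell_type and subject).
#' @param min_cells minimum cells required for a (subject, cell type) block to
#'   contribute.
#' @return a `reference_design`: list with `theta_bar`, `v` (genes x types),
#'   `size_factors`, `cell_types`, `genes`, `n_subjects`.
#' @export
build_design <- function(reference, min_cells = 10) {
  ann <- reference$annotation
  types <- reference$cell_types %||% sort(unique(ann$cell_type))
  subjects <- unique(ann$subject)
  if (length(subjects) < 2) stop("need >= 2 reference subjects")
  g <- ncol(reference$counts)
  theta <- list()   # per subject: genes x types relative profiles (NA if absent)
  for (s in subjects) {
    m <- matrix(NA_real_, g, length(types), dimnames = list(colnames(reference$counts), types))
    for (ct in types) {
      rows <- which(ann$cell_type == ct & ann$subject == s)
      if (length(rows) >= min_cells) {
        mn <- Matrix::colMeans(reference$counts[rows, , drop = FALSE])
        if (sum(mn) > 0) m[, ct] <- mn / sum(mn)
      }
    }
    theta[[s]] <- m
  }
  n_subj <- Reduce(`+`, lapply(theta, function(m) !is.na(m[1, , drop = FALSE])))
  absent <- types[n_subj[1, ] == 0]
  if (length(absent) > 0) {
    stop("cell type(s) absent (>= ", min_cells, " cells) in every subject: ",
         paste(absent, collapse = ", "))
  }
  arr <- simplify2array(theta)                       # genes x types x subjects
  theta_bar <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  v <- apply(arr, c(1, 2), function(x) {
    x <- x[!is.na(x)]
    if (length(x) >= 2) stats::var(x) else 0
  })
  lib <- Matrix::rowSums(reference$counts)
  size_factors <- vapply(types, function(ct) mean(lib[ann$cell_type == ct]), 0)
  keep <- rowSums(theta_bar) > 0
  structure(list(theta_bar = theta_bar[keep, , drop = FALSE],
                 v = v[keep, , drop = FALSE],
                 size_factors = size_factors, cell_types = types,
                 genes = rownames(theta_bar)[keep],
                 n_subjects = length(subjects)),
            class = "reference_design")
}

## One weighted NNLS solve: minimize sum_g w_g (y_g - sum_c theta_gc q_c)^2.
wnnls <- function(theta, y, w) {
  sw <- sqrt(w)
  fit <- pracma::lsqnonneg(theta * sw, y * sw)
  fit$x
}

#' Deconvolve bulk samples into cell-type proportions
#'
#' For each bulk sample, iterates between a non-negative least-squares solve
#' for the raw cell-type loadings q and a gene-weight update
#' `w_g = 1 / (nu + sum_c q_c^2 v_gc)` penalizing genes with inconsistent
#' cross-subject profiles, until the relative change of q falls below `tol`.
#' Loadings are converted to cell-count proportions via the cell-size factors:
#' `p_c = (q_c / S_c) / sum_c' (q_c' / S_c')`.
#'
#' @param bulk genes x samples count (or expression) matrix.
#' @param design a [build_design()] result.
#' @param tol relative-change convergence tolerance on q.
#' @param max_iter maximum weight iterations per sample.
#' @param nu stabilizer added to the weighted variance in the weights.
#' @param min_shared_genes minimum genes shared between bulk and design.
#' @return a `proportion_estimate`: list with `proportions` (samples x types),
#'   `loadings`, `residual_norm`, `n_iter`, `converged`, `weights`
#'   (genes x samples at convergence), `genes`.
#' @export
deconvolve <- function(bulk, design, tol = 1e-6, max_iter = 100, nu = 1e-8,
                       min_shared_genes = 50) {
  bulk <- as.matrix(bulk)
  shared <- intersect(rownames(bulk), design$genes)
  if (length(shared) < min_shared_genes) {
    stop("only ", length(shared), " genes shared between bulk and reference (need >= ",
         min_shared_genes, ")")
  }
  theta <- design$theta_bar[shared, , drop = FALSE]
  v <- design$v[shared, , drop = FALSE]
  S <- design$size_factors
  n <- ncol(bulk)
  types <- design$cell_types
  P <- Q <- matrix(NA_real_, n, length(types),
                   dimnames = list(colnames(bulk), types))
  res_norm <- numeric(n); n_iter <- integer(n); conv <- logical(n)
  W <- matrix(NA_real_, length(shared), n, dimnames = list(shared, colnames(bulk)))
  for (i in seq_len(n)) {
    tot <- sum(bulk[shared, i])
    if (tot <= 0) stop("bulk sample ", colnames(bulk)[i] %||% i, " is all zero")
    y <- bulk[shared, i] / tot
    w <- rep(1, length(y))
    q <- wnnls(theta, y, w)
    it <- 1L; converged <- FALSE
    while (it < max_iter) {
      vhat <- as.vector(v %*% q^2)
      w_new <- 1 / (nu + vhat)
      q_new <- wnnls(theta, y, w_new)
      delta <- max(abs(q_new - q)) / max(sum(q), .Machine$double.eps)
      q <- q_new; w <- w_new; it <- it + 1L
      if (delta < tol) { converged <- TRUE; break }
    }
    Q[i, ] <- q
    p_raw <- q / S
    P[i, ] <- if (sum(p_raw) > 0) p_raw / sum(p_raw) else p_raw
    res_norm[i] <- sqrt(sum(w * (y - as.vector(theta %*% q))^2))
    n_iter[i] <- it; conv[i] <- converged
    W[, i] <- w
  }
  structure(list(proportions = P, loadings = Q, residual_norm = res_norm,
                 n_iter = n_iter, converged = conv, weights = W,
                 genes = shared),
            class = "proportion_estimate")
}

#' Resample pseudo-bulk mixtures with known proportions
#'
#' Each mixture draws target proportions from a flat Dirichlet, samples the
#' implied number of cells per type without replacement from one reference
#' subject and sums their counts. True proportions are recorded as realized
#' cell-count fractions. Target draws requiring more cells of a type than the
#' subject holds are redrawn (bounded retries).
#'
#' @param reference a `single_cell_reference`.
#' @param n_mixtures number of pseudo-bulk samples.
#' @param cells_per_mixture total cells per mixture.
#' @param seed integer seed.
#' @param max_retries resampling attempts per mixture before erroring.
#' @return a `pseudo_bulk_set`: list with `mixtures` (genes x mixtures),
#'   `true_proportions` (mixtures x types), `subject`, `cells_drawn`.
#' @export
make_pseudobulk <- function(reference, n_mixtures = 50, cells_per_mixture = 400,
                            seed = 1, max_retries = 50) {
  ann <- reference$annotation
  types <- reference$cell_types %||% sort(unique(ann$cell_type))
  subjects <- unique(ann$subject)
  with_seed(seed, {
    G <- ncol(reference$counts)
    mix <- matrix(0, G, n_mixtures,
                  dimnames = list(colnames(reference$counts),
                                  sprintf("mix%03d", seq_len(n_mixtures))))
    tp <- matrix(0, n_mixtures, length(types),
                 dimnames = list(colnames(mix), types))
    subj_used <- character(n_mixtures)
    drawn <- matrix(0L, n_mixtures, length(types),
                    dimnames = dimnames(tp))
    for (i in seq_len(n_mixtures)) {
      s <- sample(subjects, 1)
      avail <- vapply(types, function(ct) sum(ann$cell_type == ct & ann$subject == s), 0L)
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        p <- as.vector(rdirichlet_rows(matrix(1, 1, length(types))))
        n_cells <- round(p * cells_per_mixture)
        if (all(n_cells <= avail)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not satisfy cell demand from subject ", s,
                    " after ", max_retries, " proportion redraws")
      cells <- unlist(lapply(seq_along(types), function(k) {
        pool <- which(ann$cell_type == types[k] & ann$subject == s)
        if (n_cells[k] == 0) integer(0) else sample(pool, n_cells[k])
      }))
      mix[, i] <- Matrix::colSums(reference$counts[cells, , drop = FALSE])
      tp[i, ] <- n_cells / sum(n_cells)
      drawn[i, ] <- n_cells
      subj_used[i] <- s
    }
    structure(list(mixtures = mix, true_proportions = tp,
                   subject = subj_used, cells_drawn = drawn),
              class = "pseudo_bulk_set")
  })
}

#' Evaluate proportion recovery against known truth
#'
#' @param estimates samples x types matrix (or a `proportion_estimate`).
#' @param truth samples x types matrix of true proportions, rows aligned.
#' @return list with `per_type` (data.frame: cell_type, pearson_r, rmse) and
#'   `overall_rmse`. Pearson r is `NA` for a type whose truth is constant.
#' @export
evaluate_recovery <- function(estimates, truth) {
  if (inherits(estimates, "proportion_estimate")) estimates <- estimates$proportions
  estimates <- as.matrix(estimates); truth <- as.matrix(truth)
  stopifnot(all(dim(estimates) == dim(truth)))
  if (nrow(truth) < 3) stop("need >= 3 mixtures for correlation")
  per_type <- data.frame(
    cell_type = colnames(truth),
    pearson_r = vapply(seq_len(ncol(truth)), function(k) {
      if (stats::sd(truth[, k]) == 0) NA_real_ else
        stats::cor(estimates[, k], truth[, k])
    }, 0),
    rmse = vapply(seq_len(ncol(truth)), function(k) {
      sqrt(mean((estimates[, k] - truth[, k])^2))
    }, 0),
    stringsAsFactors = FALSE
  )
  list(per_type = per_type,
       overall_rmse = sqrt(mean((estimates - truth)^2)))
}

#' Associate estimated proportions with fibrosis severity
#'
#' Per cell type: Pearson and Kendall correlation against the continuous
#' ImageScore (if supplied) and Kendall correlation against ordinal stage;
#' per-stage mean and sd of each proportion; and a high-variability flag for
#' cell types predicted below 5% at every stage (such types are excluded
#' from downstream interpretation).
#'
#' @param proportions samples x types matrix (or `proportion_estimate`).
#' @param metadata data.frame with `sample_id` and `stage`.
#' @param imagescore optional named numeric vector of continuous scores.
#' @param flag_threshold proportion below which a type is flagged when its
#'   stage means never exceed it.
#' @return list with `per_type` data.frame (tau_stage on per-sample values,
#'   tau_stage_means on per-stage means, pearson_imagescore, tau_imagescore,
#'   flagged) and `stage_means`, `stage_sds` matrices.
#' @export
associate_proportions <- function(proportions, metadata, imagescore = NULL,
                                  flag_threshold = 0.05) {
  if (inherits(proportions, "proportion_estimate")) proportions <- proportions$proportions
  p <- as.matrix(proportions)
  idx <- match(metadata$sample_id, rownames(p))
  if (anyNA(idx)) stop("metadata samples missing from proportions: ",
                       paste(metadata$sample_id[is.na(idx)][1:3], collapse = ", "))
  p <- p[idx, , drop = FALSE]
  stg <- stage_numeric(metadata$stage)
  stages_present <- levels(droplevels(metadata$stage))
  stage_means <- t(vapply(stages_present, function(s) {
    colMeans(p[metadata$stage == s, , drop = FALSE])
  }, numeric(ncol(p))))
  stage_sds <- t(vapply(stages_present, function(s) {
    apply(p[metadata$stage == s, , drop = FALSE], 2, stats::sd)
  }, numeric(ncol(p))))
  per_type <- data.frame(
    cell_type = colnames(p),
    tau_stage = vapply(seq_len(ncol(p)), function(k) kendall_tau(p[, k], stg), 0),
    tau_stage_means = vapply(seq_len(ncol(p)), function(k)
      kendall_tau(stage_means[, k], seq_len(nrow(stage_means))), 0),
    stringsAsFactors = FALSE
  )
  if (!is.null(imagescore)) {
    sc <- imagescore[metadata$sample_id]
    per_type$pearson_imagescore <- vapply(seq_len(ncol(p)), function(k) {
      if (stats::sd(p[, k]) == 0) NA_real_ else
        stats::cor(p[, k], sc, use = "complete.obs")
    }, 0)
    per_type$tau_imagescore <- vapply(seq_len(ncol(p)), function(k)
      kendall_tau(p[, k], sc), 0)
  }
  per_type$flagged <- apply(stage_means, 2, max) < flag_threshold
  list(per_type = per_type, stage_means = stage_means, stage_sds = stage_sds)
}
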