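## Cell-type-specific differential expression between advanced fibrosis
## (F3/F4) and non-fibrotic (F0/normal) samples by regressing transformed
## bulk expression on estimated cell-type proportions and
## proportion x disease interactions (ctassoc-style). The interaction
## coefficient beta_gc reads as the cell-type-specific disease log2 fold
## change after the log2(TPM + 1) transform.

#' Configuration for cell-type-specific differential expression
#'
#' @param disease_levels stages forming the disease group (default F3, F4).
#' @param control_levels stages forming the control group (default F0, N).
#' @param covariates metadata columns adjusted for (default sex).
#' @param ridge_penalty ridge stabilizer applied to the interaction block of
#'   the normal equations (proportions sum to 1, so the design is close to
#'   collinear without it).
#' @return validated `ctde_config` list.
#' @export
ctde_config <- function(disease_levels = c("F3", "F4"),
                        control_levels = c("F0", "N"),
                        covariates = "sex",
                        ridge_penalty = 1e-6) {
  if (length(intersect(disease_levels, control_levels)) > 0) {
    stop("disease and control stage sets must be disjoint")
  }
  stopifnot(ridge_penalty >= 0)
  structure(list(disease_levels = disease_levels,
                 control_levels = control_levels,
                 covariates = covariates, ridge_penalty = ridge_penalty),
            class = "ctde_config")
}

#' Cell-type-specific differential expression by proportion interaction
#'
#' Restricts samples to the disease and control groups and fits, per gene,
#' the no-intercept least-squares model
#' `y_i = sum_c p_ic alpha_gc + sum_c p_ic d_i beta_gc + sum_k gamma_k z_ik`
#' with `d_i` the disease indicator, `y = log2(TPM + 1)`, ridge-stabilized on
#' the interaction block. Wald t tests on `beta_gc` are corrected by
#' Benjamini-Hochberg jointly across all (gene, cell type) pairs.
#'
#' @param expression genes x samples TPM (or other nonnegative expression)
#'   matrix.
#' @param proportions samples x cell-types matrix of estimated proportions.
#' @param metadata data.frame with sample_id, stage and the covariates.
#' @param config a [ctde_config()].
#' @return a `celltype_de` data.frame: gene, cell_type, beta, se, t, p, q,
#'   with attributes `n_samples`, `condition_flag`.
#' @export
ctassoc <- function(expression, proportions, metadata, config = ctde_config()) {
  expression <- as.matrix(expression)
  p <- as.matrix(proportions)
  keep <- metadata$stage %in% c(config$disease_levels, config$control_levels)
  md <- metadata[keep, , drop = FALSE]
  if (nrow(md) < ncol(p) * 2 + 2) stop("too few samples in disease + control groups")
  idx <- match(md$sample_id, rownames(p))
  if (anyNA(idx)) stop("proportions missing for sample(s): ",
                       paste(md$sample_id[is.na(idx)][1:3], collapse = ", "))
  p <- p[idx, , drop = FALSE]
  y <- t(log2(expression[, match(md$sample_id, colnames(expression)), drop = FALSE] + 1))
  d <- as.integer(md$stage %in% config$disease_levels)
  types <- colnames(p)
  C <- length(types)
  Z <- NULL
  if (length(config$covariates) > 0) {
    ff <- stats::as.formula(paste("~", paste(config$covariates, collapse = "+")))
    Z <- stats::model.matrix(ff, data = md)[, -1, drop = FALSE]
  }
  X <- cbind(p, p * d, Z)
  colnames(X) <- c(paste0("base_", types), paste0("dis_", types), colnames(Z))
  n <- nrow(X); np <- ncol(X)
  kappa_x <- kappa(X, exact = TRUE)
  R <- diag(c(rep(0, C), rep(config$ridge_penalty, C),
              rep(0, np - 2 * C)), np)
  A <- crossprod(X) + R
  Ainv <- solve(A)
  B <- Ainv %*% crossprod(X, y)                     # np x genes
  resid <- y - X %*% B
  df <- n - np
  sigma2 <- colSums(resid^2) / df
  ## Var(beta_hat) = sigma^2 * diag(Ainv X'X Ainv) (sandwich for the ridge-
  ## stabilized solve; equals the OLS variance as ridge_penalty -> 0)
  Vd <- diag(Ainv %*% crossprod(X) %*% Ainv)
  inter <- C + seq_len(C)
  beta <- t(B[inter, , drop = FALSE])               # genes x types
  se <- sqrt(outer(sigma2, Vd[inter]))
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  out <- data.frame(
    gene = rep(rownames(beta), times = C),
    cell_type = rep(types, each = nrow(beta)),
    beta = as.vector(beta), se = as.vector(se), t = as.vector(tstat),
    p = as.vector(pval), stringsAsFactors = FALSE
  )
  out$q <- stats::p.adjust(out$p, method = "BH")
  attr(out, "n_samples") <- n
  attr(out, "condition_flag") <- kappa_x > 1e8
  class(out) <- c("celltype_de", class(out))
  out
}

#' Select cell-type marker genes from a reference
#'
#' A gene is a marker of cell type c if its mean expression (counts per ten
#' thousand, pooled over that type's cells) is at least `min_expr` and at
#' least `fold` times the maximum over the other types. With `fold > 1` the
#' sets are disjoint by construction.
#'
#' @param reference a `single_cell_reference`.
#' @param fold fold-specificity threshold (default 4).
#' @param min_expr minimum own-type mean expression (CP10K, default 1).
#' @return named list of marker gene vectors per cell type.
#' @export
select_markers <- function(reference, fold = 4, min_expr = 1.0) {
  ann <- reference$annotation
  types <- reference$cell_types %||% sort(unique(ann$cell_type))
  theta <- sapply(types, function(ct) {
    m <- Matrix::colSums(reference$counts[ann$cell_type == ct, , drop = FALSE])
    1e4 * m / sum(m)
  })
  out <- lapply(types, function(ct) {
    own <- theta[, ct]
    other_max <- apply(theta[, setdiff(types, ct), drop = FALSE], 1, max)
    ok <- own >= min_expr & own >= fold * other_max
    ok[is.na(ok)] <- FALSE
    rownames(theta)[ok]
  })
  names(out) <- types
  out
}

#' Count marker-gene overlap with expression-pattern clusters
#'
#' @param marker_sets named list of marker gene vectors (e.g. from
#'   [select_markers()]).
#' @param gene_clusters named vector mapping gene -> cluster label (e.g. from
#'   [cluster_gene_patterns()]).
#' @return matrix `n[type, cluster]` of intersection counts.
#' @export
overlap_with_clusters <- function(marker_sets, gene_clusters) {
  clusters <- sort(unique(gene_clusters))
  out <- matrix(0L, length(marker_sets), length(clusters),
                dimnames = list(names(marker_sets), as.character(clusters)))
  for (ty in names(marker_sets)) {
    for (cl in clusters) {
      out[ty, as.character(cl)] <-
        length(intersect(marker_sets[[ty]],
                         names(gene_clusters)[gene_clusters == cl]))
    }
  }
  out
}
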