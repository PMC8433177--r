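## Synthetic-study generator: stage-structured liver cohorts with a known
## single-cell reference, bulk negative-binomial mixtures carrying planted
## stage-monotone and cell-type-specific effects, and tile-level morphometric
## features monotone in a latent continuous fibrosis severity.

#' Study configuration for the synthetic-data generator
#'
#' Collects every tunable of the generator. The defaults mirror the cohort
#' shape of the emulated study: 143 biopsies split N=31, F0=35, F1=30, F2=27,
#' F3=8, F4=12 over the ordered histology scale, four major liver cell types,
#' and biopsy images carrying from 8 up to 500 tiles.
#'
#' @param n_per_stage named integer vector of samples per stage; names must be
#'   exactly `N, F0..F4`.
#' @param n_genes number of genes simulated.
#' @param cell_types ordered character vector of cell-type names.
#' @param n_subjects_ref number of reference subjects (>= 3).
#' @param cells_per_type cells sampled per (subject, cell type) block.
#' @param markers_per_type marker genes planted per cell type; each marker's
#'   archetype mean in its own type is >= 10x any other type's.
#' @param de_frac fraction of genes given a stage-monotone log2 effect.
#' @param lfc_scale scale (log2 units per severity unit) of the planted
#'   stage-monotone effects.
#' @param celltype_de_frac fraction of genes given a cell-type-specific
#'   disease effect.
#' @param celltype_lfc_scale magnitude (log2) of the planted cell-type-specific
#'   disease effects beta_gc (disease = stages F3/F4).
#' @param nb_dispersion negative-binomial dispersion phi (variance
#'   `mu + phi * mu^2`).
#' @param subject_sd sdlog of the lognormal subject-level jitter on cell-type
#'   expression profiles.
#' @param cell_libsize mean cell library size per cell type (recycled).
#' @param mean_libsize mean bulk library size.
#' @param libsize_sd sdlog of the lognormal bulk library sizes.
#' @param prop_concentration Dirichlet concentration of sample proportions
#'   around their stage means (larger = less between-sample variability; the
#'   default of 50 gives a within-stage sd of roughly 0.05-0.08 for the
#'   major types, comparable to the patient-to-patient spread deconvolution
#'   studies report).
#' @param stage_prop_means optional stage x cell-type matrix of mean
#'   proportions; rows must sum to 1. Default: hepatocytes fall 0.82 -> 0.32
#'   across N..F4 while cholangiocytes, HSCs and macrophages rise.
#' @param tile_range integer min/max tiles per biopsy image.
#' @param tile_noise_sd sd of the Gaussian tile-level feature noise.
#' @param seed integer seed for all generator randomness.
#' @return a validated `study_config` list.
#' @export
study_config <- function(n_per_stage = c(N = 31, F0 = 35, F1 = 30, F2 = 27, F3 = 8, F4 = 12),
                         n_genes = 2000,
                         cell_types = c("hepatocyte", "cholangiocyte", "HSC", "macrophage"),
                         n_subjects_ref = 3,
                         cells_per_type = 250,
                         markers_per_type = 10,
                         de_frac = 0.05,
                         lfc_scale = 0.5,
                         celltype_de_frac = 0.05,
                         celltype_lfc_scale = 1,
                         nb_dispersion = 0.1,
                         subject_sd = 0.3,
                         cell_libsize = c(4000, 2000, 2000, 2000),
                         mean_libsize = 1e6,
                         libsize_sd = 0.3,
                         prop_concentration = 50,
                         stage_prop_means = NULL,
                         tile_range = c(8, 500),
                         tile_noise_sd = 0.3,
                         seed = 1) {
  if (!setequal(names(n_per_stage), STAGE_LEVELS)) {
    stop("n_per_stage names must be exactly {", paste(STAGE_LEVELS, collapse = ","), "}")
  }
  n_per_stage <- n_per_stage[STAGE_LEVELS]
  stopifnot(all(n_per_stage > 0), n_genes > 0, length(cell_types) >= 2,
            n_subjects_ref >= 3, cells_per_type >= 30, markers_per_type >= 1,
            de_frac >= 0, de_frac <= 1, celltype_de_frac >= 0, celltype_de_frac <= 1,
            nb_dispersion > 0, length(tile_range) == 2,
            tile_range[1] >= 1, tile_range[1] <= tile_range[2],
            tile_noise_sd >= 0, prop_concentration > 0)
  if (n_genes < length(cell_types) * markers_per_type) {
    stop("n_genes (", n_genes, ") < cell_types x markers_per_type (",
         length(cell_types) * markers_per_type, ")")
  }
  if (length(cell_libsize) == 1) cell_libsize <- rep(cell_libsize, length(cell_types))
  if (length(cell_libsize) != length(cell_types)) {
    stop("cell_libsize must have length 1 or length(cell_types)")
  }
  names(cell_libsize) <- cell_types
  if (!is.null(stage_prop_means)) {
    stage_prop_means <- as.matrix(stage_prop_means)
    stopifnot(nrow(stage_prop_means) == length(STAGE_LEVELS),
              ncol(stage_prop_means) == length(cell_types),
              all(abs(rowSums(stage_prop_means) - 1) < 1e-8))
    rownames(stage_prop_means) <- STAGE_LEVELS
    colnames(stage_prop_means) <- cell_types
  }
  cfg <- list(n_per_stage = n_per_stage, n_genes = as.integer(n_genes),
              cell_types = cell_types, n_subjects_ref = as.integer(n_subjects_ref),
              cells_per_type = as.integer(cells_per_type),
              markers_per_type = as.integer(markers_per_type),
              de_frac = de_frac, lfc_scale = lfc_scale,
              celltype_de_frac = celltype_de_frac,
              celltype_lfc_scale = celltype_lfc_scale,
              nb_dispersion = nb_dispersion, subject_sd = subject_sd,
              cell_libsize = cell_libsize, mean_libsize = mean_libsize,
              libsize_sd = libsize_sd, prop_concentration = prop_concentration,
              stage_prop_means = stage_prop_means,
              tile_range = as.integer(tile_range), tile_noise_sd = tile_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "study_config"
  cfg
}

#' Published fibrosis signature gene lists
#'
#' Returns the packaged 26- or 98-gene candidate fibrosis signature list.
#'
#' @param which `"26"` or `"98"`.
#' @return character vector of gene symbols.
#' @export
fibrosis_signature_genes <- function(which = c("26", "98")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("table2_signature", which, ".txt"),
                   package = "fibroscope", mustWork = TRUE)
  readLines(f)
}

## Gene identifier vector: the published signature symbols form a reserved
## prefix block so that fixture tests on printed gene lists can run against
## generated matrices; remaining ids are synthetic.
syn_gene_ids <- function(n_genes) {
  reserved <- sort(unique(c(fibrosis_signature_genes("26"),
                            fibrosis_signature_genes("98"))))
  if (n_genes <= length(reserved)) return(reserved[seq_len(n_genes)])
  c(reserved, sprintf("GENE%05d", seq_len(n_genes - length(reserved))))
}

## Marker genes occupy the tail of the gene vector, away from the reserved
## signature block.
marker_index <- function(config) {
  n_mark <- length(config$cell_types) * config$markers_per_type
  idx <- seq(config$n_genes - n_mark + 1L, config$n_genes)
  matrix(idx, nrow = config$markers_per_type,
         dimnames = list(NULL, config$cell_types))
}

#' Generate sample metadata for a synthetic cohort
#'
#' Samples per stage follow `config$n_per_stage`. Each sample carries sex, age
#' and batch covariates plus a hidden continuous fibrosis severity
#' (`latent_severity` = numeric stage target + N(0, 0.15) jitter) that drives
#' the tile generator and the planted stage-monotone expression effects.
#'
#' @param config a [study_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return data.frame with sample_id, stage (ordered), sex, age, batch,
#'   latent_severity.
#' @export
generate_metadata <- function(config, seed = config$seed) {
  with_seed(seed, {
    stage <- rep(STAGE_LEVELS, times = config$n_per_stage)
    n <- length(stage)
    stage <- stage_factor(stage)
    tgt <- STAGE_TARGETS[as.character(stage)]
    data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      stage = stage,
      sex = factor(ifelse(stats::runif(n) < 0.7, "F", "M"), levels = c("M", "F")),
      age = round(stats::rnorm(n, 45 + 2.5 * stage_numeric(stage), 10), 1),
      batch = factor(sample(paste0("b", 1:5), n, replace = TRUE)),
      latent_severity = tgt + stats::rnorm(n, 0, 0.15),
      stringsAsFactors = FALSE
    )
  })
}

## Archetype mean-expression matrix (genes x cell types) with planted markers.
syn_archetypes <- function(config) {
  g <- config$n_genes
  types <- config$cell_types
  base <- stats::rlnorm(g, meanlog = 1, sdlog = 1)
  theta <- base * matrix(exp(stats::rnorm(g * length(types), 0, 0.2)),
                         nrow = g, dimnames = list(syn_gene_ids(g), types))
  mk <- marker_index(config)
  ## marker contrast is set high enough (64x at the archetype level) that the
  ## >= 10x specificity also holds for observed per-cell-type count means,
  ## which are compressed by cell-type library-size differences (up to 2x)
  ## and subject-level jitter
  for (ct in types) {
    idx <- mk[, ct]
    theta[idx, ] <- base[idx] * 0.25 * exp(stats::rnorm(length(idx) * length(types), 0, 0.2))
    theta[idx, ct] <- base[idx] * 16
  }
  theta
}

#' Generate a multi-subject single-cell reference
#'
#' Per subject s and cell type c, gene means are the cell-type archetype times
#' a lognormal subject jitter; each cell's counts are negative-binomial around
#' its type's relative profile scaled to a lognormal cell library size. Each
#' cell type carries `markers_per_type` planted marker genes whose archetype
#' mean in the own type is at least 10x any other type's.
#'
#' @inheritParams generate_metadata
#' @return a `single_cell_reference`: list with sparse `counts` (cells x
#'   genes), `annotation` (cell_id, cell_type, subject), `gene_ids`, and the
#'   planted `marker_truth` (gene -> cell type).
#' @export
generate_reference <- function(config, seed = config$seed) {
  with_seed(seed, {
    theta <- syn_archetypes(config)
    types <- config$cell_types
    subjects <- sprintf("subj%d", seq_len(config$n_subjects_ref))
    blocks <- list()
    ann <- list()
    size <- 1 / config$nb_dispersion
    for (s in subjects) {
      for (ct in types) {
        prof <- theta[, ct] * exp(stats::rnorm(config$n_genes, 0, config$subject_sd))
        prof <- prof / sum(prof)
        n_cells <- config$cells_per_type
        lib <- stats::rlnorm(n_cells, log(config$cell_libsize[ct]), 0.2)
        mu <- outer(prof, lib)                      # genes x cells
        cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                      nrow = config$n_genes)
        blocks[[paste(s, ct)]] <- methods::as(Matrix::Matrix(t(cnt), sparse = TRUE),
                                              "CsparseMatrix")
        ann[[paste(s, ct)]] <- data.frame(cell_type = ct, subject = s,
                                          stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(rbind, blocks)
    annotation <- do.call(rbind, lapply(ann, function(d) {
      d[rep(1, config$cells_per_type), , drop = FALSE]
    }))
    annotation$cell_id <- sprintf("cell%06d", seq_len(nrow(annotation)))
    annotation <- annotation[, c("cell_id", "cell_type", "subject")]
    rownames(annotation) <- NULL
    dimnames(counts) <- list(annotation$cell_id, rownames(theta))
    mk <- marker_index(config)
    marker_truth <- data.frame(
      gene = rownames(theta)[as.vector(mk)],
      cell_type = rep(colnames(mk), each = nrow(mk)),
      stringsAsFactors = FALSE
    )
    structure(list(counts = counts, annotation = annotation,
                   gene_ids = rownames(theta), cell_types = types,
                   marker_truth = marker_truth),
              class = "single_cell_reference")
  })
}

## Stage-mean proportion vectors: hepatocytes fall monotonically N -> F4 while
## the three non-parenchymal types rise, qualitatively matching deconvolution
## of real NASH cohorts.
default_stage_prop_means <- function(cell_types) {
  if (identical(cell_types, c("hepatocyte", "cholangiocyte", "HSC", "macrophage"))) {
    m <- cbind(hepatocyte    = c(0.82, 0.76, 0.67, 0.57, 0.45, 0.32),
               cholangiocyte = c(0.02, 0.04, 0.07, 0.10, 0.14, 0.18),
               HSC           = c(0.06, 0.08, 0.11, 0.15, 0.19, 0.24),
               macrophage    = c(0.10, 0.12, 0.15, 0.18, 0.22, 0.26))
  } else {
    ## generic fallback: first type falls 0.8 -> 0.36, the rest rise equally
    k <- length(cell_types) - 1
    first <- seq(0.80, 0.36, length.out = 6)
    rest <- sapply(seq_len(k), function(i) (1 - first) / k)
    m <- cbind(first, rest)
    colnames(m) <- cell_types
  }
  rownames(m) <- STAGE_LEVELS
  m
}

#' Generate true cell-type proportions per sample
#'
#' Each sample's proportion vector is a Dirichlet draw around its stage's mean
#' vector with concentration `config$prop_concentration`. The hepatocyte mean
#' decreases strictly N -> F4; cholangiocyte, HSC and macrophage means
#' increase strictly.
#'
#' @param metadata data.frame from [generate_metadata()].
#' @inheritParams generate_metadata
#' @return samples x cell-types matrix on the simplex (rows sum to 1).
#' @export
generate_proportions <- function(metadata, config, seed = config$seed + 1L) {
  m <- config$stage_prop_means %||% default_stage_prop_means(config$cell_types)
  with_seed(seed, {
    alpha <- m[as.character(metadata$stage), , drop = FALSE] * config$prop_concentration
    p <- rdirichlet_rows(alpha)
    dimnames(p) <- list(metadata$sample_id, config$cell_types)
    p
  })
}

## Subject-specific relative expression profiles (genes x types x subjects)
## summarized from a generated reference.
reference_profiles <- function(reference) {
  ann <- reference$annotation
  subjects <- unique(ann$subject)
  types <- reference$cell_types
  out <- array(0, dim = c(ncol(reference$counts), length(types), length(subjects)),
               dimnames = list(reference$gene_ids, types, subjects))
  for (s in subjects) {
    for (ct in types) {
      rows <- ann$cell_type == ct & ann$subject == s
      m <- Matrix::colMeans(reference$counts[rows, , drop = FALSE])
      out[, ct, s] <- m / sum(m)
    }
  }
  out
}

#' Generate bulk count mixtures with planted effects
#'
#' The expected expression of gene g in sample i is
#' `libsize_i * sum_c p_ic * theta_gc(subject_i) * 2^(beta_gc * d_i) *
#' 2^(lfc_g * severity_i)`, where `d_i = 1` iff the stage is F3/F4 and
#' `theta` is the subject-specific relative profile summarized from the
#' reference. Observed counts are negative-binomial with dispersion
#' `config$nb_dispersion`; `exact = TRUE` returns the expectations themselves
#' (noiseless mode) with the library size fixed at `config$mean_libsize`.
#'
#' @param reference a `single_cell_reference`.
#' @param true_proportions samples x cell-types matrix, rows aligned with
#'   `metadata`.
#' @param metadata data.frame from [generate_metadata()].
#' @inheritParams generate_metadata
#' @param exact logical; return exact expectations instead of sampled counts.
#' @return genes x samples matrix with a `truth` attribute (data.frames
#'   `lfc` and `beta`, and the per-sample subject assignment).
#' @export
generate_bulk <- function(reference, true_proportions, metadata, config,
                          seed = config$seed + 2L, exact = FALSE) {
  if (nrow(true_proportions) != nrow(metadata)) {
    stop("true_proportions rows (", nrow(true_proportions),
         ") do not align with metadata samples (", nrow(metadata), ")")
  }
  if (ncol(true_proportions) != length(config$cell_types)) {
    stop("true_proportions columns do not match config$cell_types")
  }
  prof <- reference_profiles(reference)
  g <- dim(prof)[1]; types <- config$cell_types
  with_seed(seed, {
    ## planted truth
    n_de <- round(config$de_frac * g)
    mk <- as.vector(marker_index(config))
    eligible <- setdiff(seq_len(g), mk)
    de_idx <- sort(sample(eligible, n_de))
    lfc <- stats::runif(n_de, 0.5, 1.5) * config$lfc_scale *
      sample(c(-1, 1), n_de, replace = TRUE)
    lfc_g <- numeric(g); lfc_g[de_idx] <- lfc
    n_ctde <- round(config$celltype_de_frac * g)
    ct_idx <- sort(sample(setdiff(eligible, de_idx), n_ctde))
    ct_type <- sample(types, n_ctde, replace = TRUE)
    ct_beta <- config$celltype_lfc_scale * sample(c(-1, 1), n_ctde, replace = TRUE)
    beta <- matrix(0, g, length(types), dimnames = list(rownames(prof), types))
    beta[cbind(ct_idx, match(ct_type, types))] <- ct_beta

    subj <- sample(dimnames(prof)[[3]], nrow(metadata), replace = TRUE)
    d <- as.integer(metadata$stage %in% c("F3", "F4"))
    lib <- if (exact) rep(config$mean_libsize, nrow(metadata)) else
      stats::rlnorm(nrow(metadata), log(config$mean_libsize), config$libsize_sd)
    mu <- matrix(0, g, nrow(metadata),
                 dimnames = list(rownames(prof), metadata$sample_id))
    for (i in seq_len(nrow(metadata))) {
      th <- prof[, , subj[i]]
      if (d[i] == 1L) th <- th * 2^beta
      mix <- as.vector(th %*% true_proportions[i, ])
      mu[, i] <- lib[i] * mix * 2^(lfc_g * metadata$latent_severity[i])
    }
    counts <- if (exact) mu else
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
             nrow = g, dimnames = dimnames(mu))
    attr(counts, "truth") <- list(
      lfc = data.frame(gene = rownames(prof)[de_idx], lfc = lfc,
                       stringsAsFactors = FALSE),
      beta = data.frame(gene = rownames(prof)[ct_idx], cell_type = ct_type,
                        beta = ct_beta, stringsAsFactors = FALSE),
      subject = stats::setNames(subj, metadata$sample_id)
    )
    counts
  })
}

## Tile feature model: affine monotone loadings on latent severity. Collagen
## abundance and void counts rise with fibrosis; tissue/void compactness fall.
TILE_FEATURES <- data.frame(
  feature = c("compactness_tissue", "compactness_voids", "n_voids",
              "equivalence_radius", "collagen_area", "collagen_per_tissue",
              "collagen_per_section", "void_area"),
  intercept = c(2.0, 1.5, 5.0, 3.0, 1.0, 0.8, 0.9, 2.0),
  slope = c(-0.8, -0.5, 1.2, 0.6, 1.0, 0.9, 0.7, 0.5),
  stringsAsFactors = FALSE
)

#' Generate tile-level morphometric features
#'
#' Each biopsy image receives a uniform number of tiles within
#' `config$tile_range`; each tile's eight named features are affine monotone
#' functions of the sample's latent severity plus Gaussian noise
#' (`tile_noise_sd`). Collagen-area features load positively, compactness
#' features negatively.
#'
#' @inheritParams generate_proportions
#' @return long data.frame: image_id, tile_id, eight feature columns.
#' @export
generate_tiles <- function(metadata, config, seed = config$seed + 3L) {
  with_seed(seed, {
    n_tiles <- sample(seq(config$tile_range[1], config$tile_range[2]),
                      nrow(metadata), replace = TRUE)
    image_id <- rep(metadata$sample_id, n_tiles)
    sev <- rep(metadata$latent_severity, n_tiles)
    total <- length(sev)
    feats <- sapply(seq_len(nrow(TILE_FEATURES)), function(k) {
      TILE_FEATURES$intercept[k] + TILE_FEATURES$slope[k] * sev +
        stats::rnorm(total, 0, config$tile_noise_sd)
    })
    colnames(feats) <- TILE_FEATURES$feature
    tile_id <- unlist(lapply(n_tiles, seq_len), use.names = FALSE)
    cbind(data.frame(image_id = image_id,
                     tile_id = sprintf("%s_t%03d", image_id, tile_id),
                     stringsAsFactors = FALSE),
          as.data.frame(feats))
  })
}

#' Generate a complete synthetic study
#'
#' Runs every generator with sub-seeds derived deterministically from
#' `config$seed` and bundles reference, true proportions, bulk counts, tiles,
#' metadata and the planted truth.
#'
#' @inheritParams generate_metadata
#' @return a `generated_study` list: `metadata`, `reference`,
#'   `true_proportions`, `bulk_counts`, `tiles`, `truth`.
#' @export
generate_study <- function(config = study_config(), seed = config$seed) {
  seeds <- derive_seeds(seed, 5)
  metadata <- generate_metadata(config, seeds[1])
  reference <- generate_reference(config, seeds[2])
  props <- generate_proportions(metadata, config, seeds[3])
  bulk <- generate_bulk(reference, props, metadata, config, seeds[4])
  tiles <- generate_tiles(metadata, config, seeds[5])
  truth <- attr(bulk, "truth")
  truth$marker <- reference$marker_truth
  attr(bulk, "truth") <- NULL
  structure(list(metadata = metadata, reference = reference,
                 true_proportions = props, bulk_counts = bulk,
                 tiles = tiles, truth = truth, config = config,
                 seed = seed),
            class = "generated_study")
}

#' @export
print.generated_study <- function(x, ...) {
  cat("Synthetic fibrosis study:",
      nrow(x$metadata), "samples,",
      nrow(x$bulk_counts), "genes,",
      nrow(x$reference$annotation), "reference cells,",
      nrow(x$tiles), "tiles\n")
  print(table(x$metadata$stage))
  invisible(x)
}
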