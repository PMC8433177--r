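## End-to-end orchestration: simulate -> imagescore -> deconvolve -> ctde ->
## signature, with deterministic per-stage seeds derived from one global
## seed, per-stage timing, and a checksummed run manifest.

#' Pipeline run configuration
#'
#' @param outdir output directory.
#' @param seed global seed; per-stage seeds are derived from it
#'   deterministically.
#' @param study_cfg a [study_config()] for the simulate stage.
#' @param imagescore_cfg an [imagescore_config()].
#' @param ctde_cfg a [ctde_config()].
#' @param stages character subset of
#'   `c("simulate", "imagescore", "deconvolve", "ctde", "signature")`;
#'   simulate is always required (it provides inputs to the rest).
#' @param top_n composite-score gene count.
#' @param lambda_rule lasso selection rule (see [fit_lasso_signature()]).
#' @param signature_folds lasso CV folds.
#' @return validated `run_config` list.
#' @export
run_config <- function(outdir = tempfile("fibroscope_run_"), seed = 1,
                       study_cfg = study_config(),
                       imagescore_cfg = imagescore_config(n_reps = 25),
                       ctde_cfg = ctde_config(),
                       stages = c("simulate", "imagescore", "deconvolve",
                                  "ctde", "signature"),
                       top_n = 1000, lambda_rule = "min_mse",
                       signature_folds = 10) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!"simulate" %in% stages) stop("the simulate stage is required")
  structure(list(outdir = outdir, seed = as.integer(seed),
                 study_cfg = study_cfg, imagescore_cfg = imagescore_cfg,
                 ctde_cfg = ctde_cfg, stages = stages, top_n = top_n,
                 lambda_rule = lambda_rule, signature_folds = signature_folds),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writing each stage's tables under
#' `config$outdir` and finally an atomically written `manifest.json` with the
#' config echo, per-stage wall time, output checksums and collected warnings.
#' Any stage failure halts with the stage name.
#'
#' @param config a [run_config()].
#' @return the manifest list, invisibly.
#' @export
run_all <- function(config = run_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 6)
  timings <- list(); warns <- character(0)
  wrap <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warns <<- c(warns, paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  cfg <- config$study_cfg; cfg$seed <- seeds[1]
  study <- wrap("simulate", {
    st <- generate_study(cfg)
    write_study(st, file.path(config$outdir, "study"))
    st
  })

  imgscore <- NULL
  if ("imagescore" %in% config$stages) {
    imgscore <- wrap("imagescore", {
      ic <- config$imagescore_cfg; ic$seed <- seeds[2]
      res <- compute_imagescore(study$tiles, study$metadata, ic)
      write_table_file(res$per_sample, file.path(config$outdir, "imagescore.tsv"))
      cl <- cluster_tiles(study$tiles, 4, study$metadata, seed = seeds[3])
      write_table_file(
        data.frame(tile_id = study$tiles$tile_id, cluster = cl$labels),
        file.path(config$outdir, "tile_clusters.tsv"))
      write_json_report(list(tau_vs_stage = res$tau_vs_stage,
                             cluster_ratio_tau = as.list(cl$tau_vs_stage)),
                        file.path(config$outdir, "imagescore_summary.json"))
      res
    })
  }

  props <- NULL
  if ("deconvolve" %in% config$stages) {
    props <- wrap("deconvolve", {
      design <- build_design(study$reference)
      est <- deconvolve(study$bulk_counts, design)
      write_table_file(data.frame(sample_id = rownames(est$proportions),
                                  signif(est$proportions, 6), check.names = FALSE),
                       file.path(config$outdir, "proportions.tsv"))
      sc <- if (!is.null(imgscore))
        stats::setNames(imgscore$per_sample$imagescore,
                        imgscore$per_sample$sample_id) else NULL
      assoc <- associate_proportions(est, study$metadata, sc)
      write_table_file(assoc$per_type,
                       file.path(config$outdir, "proportion_associations.tsv"))
      est
    })
  }

  if ("ctde" %in% config$stages) {
    wrap("ctde", {
      pmat <- if (!is.null(props)) props$proportions else study$true_proportions
      tpm <- sweep(study$bulk_counts, 2, colSums(study$bulk_counts), "/") * 1e6
      de <- ctassoc(tpm, pmat, study$metadata, config$ctde_cfg)
      write_table_file(de, file.path(config$outdir, "celltype_de.tsv"))
      de
    })
  }

  if ("signature" %in% config$stages) {
    wrap("signature", {
      vst <- transform_expression(study$bulk_counts)
      fit <- fit_ordinal_per_gene(vst, study$metadata$stage)
      gs <- gene_level_score(fit, vst)
      comp <- composite_score(gs, top_n = config$top_n,
                              stages = study$metadata$stage)
      sig <- fit_lasso_signature(vst, comp$composite,
                                 folds = config$signature_folds,
                                 lambda_rule = config$lambda_rule,
                                 seed = seeds[4])
      val <- score_and_validate(sig, vst, study$metadata$stage, comp$composite)
      write_table_file(data.frame(sample_id = names(comp$composite),
                                  composite = signif(comp$composite, 6),
                                  signature_score = signif(val$scores, 6)),
                       file.path(config$outdir, "composite_scores.tsv"))
      write_json_report(list(lambda = sig$lambda, lambda_rule = sig$lambda_rule,
                             n_genes = length(sig$genes),
                             genes = sig$genes,
                             weights = as.list(signif(sig$weights, 6)),
                             intercept = sig$intercept,
                             tau_composite_vs_stage = comp$tau_stage,
                             tau_signature_vs_stage = val$tau_stage),
                        file.path(config$outdir, "signature.json"))
      sig
    })
  }

  files <- setdiff(list.files(config$outdir, recursive = TRUE, full.names = TRUE),
                   file.path(config$outdir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("fibroscope")),
    seed = config$seed,
    stage_seeds = as.list(stats::setNames(seeds, c("simulate", "imagescore",
                                                   "tile_clusters", "signature_folds",
                                                   "reserved1", "reserved2"))),
    stages_run = names(timings),
    n_stages = length(timings),
    wall_time_s = timings,
    checksums = as.list(tools::md5sum(files)),
    warnings = warns
  )
  write_json_report(manifest, file.path(config$outdir, "manifest.json"))
  invisible(manifest)
}
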