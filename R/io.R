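## Readers and writers for the pipeline's on-disk formats: TSV expression
## matrices (genes as rows, bulk convention), MatrixMarket sparse matrices
## with plain-text row/column name sidecars (cells as rows, single-cell
## convention), TSV/CSV tables, and JSON reports. Every writer's output is
## re-readable by the matching reader.

sidecar_paths <- function(path) {
  list(rows = paste0(path, ".rownames"), cols = paste0(path, ".colnames"))
}

#' Read an expression matrix
#'
#' TSV: header row of sample ids, first column of gene ids (genes x samples).
#' MTX: MatrixMarket file with `<path>.rownames` / `<path>.colnames`
#' sidecars. Duplicate identifiers are rejected.
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"` (default: from the file extension).
#' @return numeric matrix (dense for TSV, as stored for MTX).
#' @export
read_expression <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- df[[1]]
    if (anyDuplicated(ids)) stop("duplicate gene identifiers in ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers in ", path)
    if (!is.numeric(m)) stop("non-numeric entries (ragged rows?) in ", path)
    rownames(m) <- ids
    m
  } else {
    sc <- sidecar_paths(path)
    ## `* 1` promotes pattern matrices (zero stored entries) to numeric;
    ## generalMatrix avoids symmetric classes hijacking dimnames
    m <- methods::as(methods::as(Matrix::readMM(path) * 1, "generalMatrix"),
                     "CsparseMatrix")
    rn <- readLines(sc$rows)
    cn <- readLines(sc$cols)
    if (length(rn) != nrow(m)) stop("row-name sidecar ", sc$rows,
                                    " has ", length(rn), " entries for ",
                                    nrow(m), " rows")
    if (length(cn) != ncol(m)) stop("column-name sidecar ", sc$cols,
                                    " has ", length(cn), " entries for ",
                                    ncol(m), " columns")
    if (anyDuplicated(rn) || anyDuplicated(cn)) stop("duplicate identifiers in sidecars of ", path)
    dimnames(m) <- list(rn, cn)
    m
  }
}

#' Write an expression matrix
#'
#' @param mat matrix with dimnames.
#' @param path output path.
#' @param format `"tsv"` (dense, genes as rows) or `"mtx"` (sparse +
#'   name sidecars).
#' @param digits significant digits for TSV floats.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, format = c("tsv", "mtx"), digits = 6) {
  format <- match.arg(format)
  if (format == "tsv") {
    m <- as.matrix(mat)
    vals <- if (is.double(m) && any(m != round(m))) signif(m, digits) else m
    df <- data.frame(gene_id = rownames(m), vals, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    sc <- sidecar_paths(path)
    Matrix::writeMM(methods::as(Matrix::Matrix(mat, sparse = TRUE), "generalMatrix"), path)
    writeLines(rownames(mat), sc$rows)
    writeLines(colnames(mat), sc$cols)
  }
  invisible(path)
}

#' Read a single-cell reference from MTX + annotation
#'
#' @param mtx_path MatrixMarket counts (cells x genes) with name sidecars.
#' @param annotation_path TSV with columns cell_id, cell_type, subject.
#' @param cell_types optional ordered cell-type vector (default: sorted
#'   unique annotation values).
#' @return a `single_cell_reference`.
#' @export
read_single_cell_reference <- function(mtx_path, annotation_path,
                                       cell_types = NULL) {
  counts <- read_expression(mtx_path, "mtx")
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "cell_type", "subject")
  if (!all(need %in% colnames(ann))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (!identical(sort(ann$cell_id), sort(rownames(counts)))) {
    stop("annotation cell ids do not match matrix rows")
  }
  ann <- ann[match(rownames(counts), ann$cell_id), ]
  structure(list(counts = counts, annotation = ann,
                 gene_ids = colnames(counts),
                 cell_types = cell_types %||% sort(unique(ann$cell_type)),
                 marker_truth = NULL),
            class = "single_cell_reference")
}

#' Read/write plain tables
#'
#' Thin wrappers enforcing headers and tab/comma separation so every table
#' written by the pipeline round-trips through its own reader.
#'
#' @param df data.frame to write.
#' @param path file path (`.csv` comma, otherwise tab).
#' @return the data.frame (readers) or `path` invisibly (writers).
#' @export
write_table_file <- function(df, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_file
#' @export
read_table_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a JSON report atomically
#'
#' Writes to a temporary file in the same directory and renames into place.
#'
#' @param x list to serialize.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' Write a generated study to disk
#'
#' Bulk counts as TSV (genes x samples) and MTX + sidecars; reference counts
#' as MTX (cells x genes) + annotation TSV; metadata, proportions and tiles
#' as TSV/CSV; planted truth and a seed manifest as JSON.
#'
#' @param study a `generated_study`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    bulk_tsv = file.path(dir, "bulk_counts.tsv"),
    bulk_mtx = file.path(dir, "bulk_counts.mtx"),
    ref_mtx = file.path(dir, "reference_counts.mtx"),
    ref_ann = file.path(dir, "reference_annotation.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    proportions = file.path(dir, "true_proportions.tsv"),
    tiles = file.path(dir, "tiles.csv"),
    truth = file.path(dir, "truth.json"),
    manifest = file.path(dir, "study_manifest.json")
  )
  write_expression(study$bulk_counts, paths["bulk_tsv"], "tsv")
  write_expression(study$bulk_counts, paths["bulk_mtx"], "mtx")
  write_expression(study$reference$counts, paths["ref_mtx"], "mtx")
  write_table_file(study$reference$annotation, paths["ref_ann"])
  write_table_file(study$metadata, paths["metadata"])
  write_table_file(data.frame(sample_id = rownames(study$true_proportions),
                              signif(study$true_proportions, 6),
                              check.names = FALSE),
                   paths["proportions"])
  write_table_file(study$tiles, paths["tiles"])
  write_json_report(study$truth, paths["truth"])
  write_json_report(list(seed = study$seed,
                         n_samples = nrow(study$metadata),
                         n_genes = nrow(study$bulk_counts),
                         generator = "fibroscope::generate_study"),
                    paths["manifest"])
  invisible(paths)
}
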