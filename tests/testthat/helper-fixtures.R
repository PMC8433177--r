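# Small, fast study configurations shared across test files. All fixtures
# are generated in code; nothing is read from disk except the packaged
# signature lists.

small_config <- function(seed = 42, ...) {
  study_config(n_per_stage = c(N = 6, F0 = 6, F1 = 6, F2 = 6, F3 = 4, F4 = 4),
               n_genes = 300, cells_per_type = 30, markers_per_type = 4,
               tile_range = c(5, 20), seed = seed, ...)
}

small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_study(small_config())
    cache
  }
})

# deterministic tiny reference: 2 types x 2 subjects with block-structured
# means, built without RNG
toy_reference <- function() {
  genes <- paste0("g", 1:6)
  types <- c("A", "B")
  cells <- expand.grid(type = types, subject = c("s1", "s2"),
                       rep = 1:12, stringsAsFactors = FALSE)
  mean_a <- c(10, 0, 5, 2, 1, 1)
  mean_b <- c(0, 10, 5, 1, 2, 1)
  counts <- t(vapply(seq_len(nrow(cells)), function(i) {
    if (cells$type[i] == "A") mean_a else mean_b
  }, numeric(6)))
  colnames(counts) <- genes
  rownames(counts) <- sprintf("c%03d", seq_len(nrow(cells)))
  structure(list(counts = Matrix::Matrix(counts, sparse = TRUE),
                 annotation = data.frame(cell_id = rownames(counts),
                                         cell_type = cells$type,
                                         subject = cells$subject,
                                         stringsAsFactors = FALSE),
                 gene_ids = genes, cell_types = types, marker_truth = NULL),
            class = "single_cell_reference")
}

# brute-force simplex search for the NNLS-with-sum-constraint oracle
grid_simplex_solve <- function(theta, y, res = 0.01) {
  k <- ncol(theta)
  stopifnot(k <= 3)
  grid <- seq(0, 1, by = res)
  best <- NULL; best_err <- Inf
  if (k == 2) {
    for (a in grid) {
      q <- c(a, 1 - a)
      err <- sum((y - theta %*% q)^2)
      if (err < best_err) { best <- q; best_err <- err }
    }
  } else {
    for (a in grid) for (b in grid[grid <= 1 - a + 1e-12]) {
      q <- c(a, b, 1 - a - b)
      err <- sum((y - theta %*% q)^2)
      if (err < best_err) { best <- q; best_err <- err }
    }
  }
  list(q = best, err = best_err)
}
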