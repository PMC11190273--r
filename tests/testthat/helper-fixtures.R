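# small deterministic fixtures built in code

# a tiny count_matrix with explicit counts and a mito gene
toy_counts <- function() {
  m <- matrix(c(5, 0, 2, 1,
                0, 3, 0, 4,
                1, 1, 1, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("MT-G1", "G2", "G3"),
                              paste0("c", 1:4)))
  count_matrix(m, genes = tibble::tibble(gene = rownames(m),
                                         mito = c(TRUE, FALSE, FALSE)))
}

# random count_matrix with named dims, no structure
random_counts <- function(n_genes, n_cells, lambda = 1, seed = 1,
                          n_mito = 0) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  gn <- sprintf("G%03d", seq_len(n_genes))
  mito <- rep(FALSE, n_genes)
  if (n_mito > 0) {
    mito[seq_len(n_mito)] <- TRUE
    gn[seq_len(n_mito)] <- sub("^G", "MT-G", gn[seq_len(n_mito)])
  }
  rownames(m) <- gn
  colnames(m) <- sprintf("c%04d", seq_len(n_cells))
  count_matrix(m, genes = tibble::tibble(gene = gn, mito = mito))
}

# exhaustive two-sided rank-sum p by enumerating all group assignments
exact_ranksum_p <- function(a, b) {
  n <- length(a) + length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_along(a)])
  combos <- utils::combn(n, length(a))
  ws <- apply(combos, 2, function(idx) sum(ranks[idx]))
  mu <- length(a) * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# build a normalized_matrix directly from a dense value matrix
manual_normalized <- function(values, cluster, extra_cells = NULL) {
  v <- Matrix::Matrix(values, sparse = TRUE)
  rownames(v) <- sprintf("G%03d", seq_len(nrow(v)))
  colnames(v) <- sprintf("c%04d", seq_len(ncol(v)))
  cells <- tibble::tibble(barcode = colnames(v), cluster = cluster)
  if (!is.null(extra_cells)) cells <- dplyr::bind_cols(cells, extra_cells)
  structure(list(values = v, cells = cells,
                 genes = tibble::tibble(gene = rownames(v)),
                 scale_factor = 1e4),
            class = "normalized_matrix")
}
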