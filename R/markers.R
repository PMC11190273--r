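#' Total-count log normalization
#'
#' Transforms UMI counts to `ln(1 + scale_factor * c / cell_total)`:
#' natural-log expression adjusted for total UMI counts per cell. Sparse
#' zeros are preserved (a zero count maps to 0) and values are strictly
#' monotone in the count within a cell.
#'
#' @param cm A post-QC [count_matrix()].
#' @param scale_factor Counts-per-`scale_factor` scaling (default 10,000).
#' @return An object of class `normalized_matrix`: list with `values`
#'   (sparse gene x cell matrix), `cells`, `genes`, `scale_factor`.
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 40, n_cells = 80,
#'                                       doublet_rate = 0, seed = 2))
#' nm <- normalize_counts(sim$counts)
#' range(nm$values@x)
normalize_counts <- function(cm, scale_factor = 1e4) {
  stopifnot(inherits(cm, "count_matrix"), scale_factor > 0)
  totals <- Matrix::colSums(cm$counts)
  if (any(totals == 0)) {
    stop("cell(s) with zero total counts: ",
         paste(utils::head(cm$cells$barcode[totals == 0], 5),
               collapse = ", "))
  }
  v <- cm$counts
  # per-column scaling on the nonzero entries only
  j <- rep(seq_len(ncol(v)), diff(v@p))
  v@x <- log1p(scale_factor * v@x / totals[j])
  structure(list(values = v, cells = cm$cells, genes = cm$genes,
                 scale_factor = scale_factor),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d genes x %d cells (scale %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

# detection fraction of each gene across a set of columns
detection_fraction <- function(values, cols) {
  if (length(cols) == 0) return(rep(NA_real_, nrow(values)))
  Matrix::rowSums(values[, cols, drop = FALSE] > 0) / length(cols)
}

row_means <- function(values, cols) {
  if (length(cols) == 0) return(rep(NA_real_, nrow(values)))
  Matrix::rowSums(values[, cols, drop = FALSE]) / length(cols)
}

# mean expression on the de-logged scale: mean(expm1(value)) per gene.
# Fold changes are computed on this scale (the FindMarkers convention):
# means of log values compress true fold changes at high expression.
row_means_delog <- function(values, cols) {
  if (length(cols) == 0) return(rep(NA_real_, nrow(values)))
  v <- values[, cols, drop = FALSE]
  v@x <- expm1(v@x)
  Matrix::rowSums(v) / length(cols)
}

# two-sided Wilcoxon rank-sum p-values for each row of a (small) dense
# matrix, cells in `a` vs cells in `b`
rowwise_wilcox_p <- function(values, genes, a, b) {
  m <- as.matrix(values[genes, c(a, b), drop = FALSE])
  ia <- seq_along(a)
  apply(m, 1, function(y) {
    suppressWarnings(
      stats::wilcox.test(y[ia], y[-ia], alternative = "two.sided")$p.value)
  })
}

#' Conserved cluster markers across diagnosis groups
#'
#' A gene is a conserved marker of a cluster iff, in both diagnosis groups
#' separately: it is detected in more than `min_pct` of the cluster's
#' nuclei; its natural-log fold change of mean expression (cluster vs all
#' other clusters, same group, means taken on the de-logged `expm1` scale
#' with a pseudocount of 1) exceeds `min_lnfc`; and its
#' two-sided Wilcoxon rank-sum Bonferroni-adjusted p-value (adjusted across
#' genes tested in the cluster) is below `alpha`. When the cluster has only
#' one group, markers are computed on the available group and the result
#' carries a `degraded` attribute.
#'
#' @param norm A [normalize_counts()] result whose cell metadata has
#'   `cluster` and the grouping column.
#' @param cluster_id Cluster to characterize.
#' @param group_col Cell metadata column holding the two groups.
#' @param groups The two group labels (order sets the output column
#'   suffixes).
#' @param min_pct,min_lnfc,alpha The three thresholds (defaults 0.20, 0.25,
#'   0.05: the published rules).
#' @return Tibble of marker records: `cluster`, `gene`, then per-group
#'   detection fraction `pct_<group>`, fold change `lnfc_<group>` and
#'   Bonferroni-adjusted `p_<group>`. Attribute `n_tested` is the
#'   Bonferroni denominator.
#' @export
conserved_markers <- function(norm, cluster_id, group_col = "diagnosis",
                              groups = c("AD", "control"),
                              min_pct = 0.20, min_lnfc = 0.25,
                              alpha = 0.05) {
  stopifnot(inherits(norm, "normalized_matrix"))
  cl <- norm$cells$cluster
  grp <- norm$cells[[group_col]]
  in_cluster <- cl == cluster_id
  if (!any(in_cluster)) stop("cluster ", cluster_id, " has no cells")
  present <- groups[vapply(groups, function(g) any(in_cluster & grp == g),
                           TRUE)]
  degraded <- length(present) < length(groups)
  if (degraded) {
    warning("cluster ", cluster_id, " has cells from only one group; ",
            "markers computed on the available group")
  }
  pct_in <- lapply(present, function(g) {
    detection_fraction(norm$values, which(in_cluster & grp == g))
  })
  candidate <- Reduce(`&`, lapply(pct_in, function(p) p > min_pct))
  genes <- which(candidate)
  out <- tibble::tibble(cluster = cluster_id,
                        gene = norm$genes$gene[genes])
  keep <- rep(TRUE, length(genes))
  for (i in seq_along(present)) {
    g <- present[i]
    a <- which(in_cluster & grp == g)
    b <- which(!in_cluster & grp == g)
    lnfc <- log(row_means_delog(norm$values, a)[genes] + 1) -
      log(row_means_delog(norm$values, b)[genes] + 1)
    p <- if (length(genes)) {
      pmin(1, rowwise_wilcox_p(norm$values, genes, a, b) * length(genes))
    } else numeric(0)
    out[[paste0("pct_", g)]] <- pct_in[[i]][genes]
    out[[paste0("lnfc_", g)]] <- lnfc
    out[[paste0("p_", g)]] <- p
    keep <- keep & lnfc > min_lnfc & p < alpha
  }
  res <- out[keep, , drop = FALSE]
  attr(res, "n_tested") <- length(genes)
  attr(res, "groups_used") <- present
  attr(res, "degraded") <- degraded
  res
}

#' Upper-tail hypergeometric over-representation test
#'
#' `p = P(X >= overlap)` where X is hypergeometric with population size
#' `|universe|`, `|reference|` successes and `|query|` draws. Used both for
#' cell-type assignment against marker reference lists and for gene-set
#' over-representation generally.
#'
#' @param query_genes,reference_genes Gene sets (subsets of `universe`;
#'   stray genes are dropped with a warning).
#' @param universe The gene universe (all genes surviving QC, by
#'   convention).
#' @return One-row tibble: `overlap`, `n_query`, `n_reference`,
#'   `n_universe`, `p`.
#' @export
hypergeometric_enrichment <- function(query_genes, reference_genes,
                                      universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query_genes)
  ref <- unique(reference_genes)
  if (!all(query %in% universe) || !all(ref %in% universe)) {
    warning("genes outside the universe dropped from query/reference")
    query <- intersect(query, universe)
    ref <- intersect(ref, universe)
  }
  ov <- length(intersect(query, ref))
  p <- stats::phyper(ov - 1, length(ref), length(universe) - length(ref),
                     length(query), lower.tail = FALSE)
  tibble::tibble(overlap = ov, n_query = length(query),
                 n_reference = length(ref), n_universe = length(universe),
                 p = p)
}

#' Assign one cell type per cluster by marker over-representation
#'
#' Primary call: the reference cell type whose marker list is most
#' over-represented (smallest hypergeometric p) among the cluster's
#' markers. Ties are broken by larger overlap, then lexicographically, and
#' flagged. A cluster where every type gives p = 1 is labelled
#' "unassigned". Secondary check: whether any canonical marker of the
#' assigned type appears among the cluster's markers, reported as
#' agreement.
#'
#' @param cluster_markers Named list: cluster id -> character vector of the
#'   cluster's marker genes.
#' @param reference Tibble/data frame with columns `cell_type`, `gene`
#'   (BRETIGEA-style reference marker lists).
#' @param universe Gene universe for the hypergeometric test.
#' @param canonical Optional named list: cell type -> canonical marker
#'   genes used for the secondary check.
#' @return Tibble: `cluster`, `cell_type`, `p`, `overlap`, `tie`,
#'   `canonical_agree` (NA when no canonical list covers the call).
#' @export
assign_cell_types <- function(cluster_markers, reference, universe,
                              canonical = NULL) {
  reference <- tibble::as_tibble(reference)
  stopifnot(all(c("cell_type", "gene") %in% names(reference)))
  types <- sort(unique(reference$cell_type))
  purrr::map_dfr(names(cluster_markers), function(cl) {
    q <- cluster_markers[[cl]]
    if (length(q) == 0) stop("cluster ", cl, " has an empty marker list")
    enr <- purrr::map_dfr(types, function(tp) {
      r <- reference$gene[reference$cell_type == tp]
      dplyr::mutate(
        suppressWarnings(hypergeometric_enrichment(q, r, universe)),
        cell_type = tp)
    })
    if (all(enr$p >= 1 - 1e-15)) {
      return(tibble::tibble(cluster = cl, cell_type = "unassigned",
                            p = 1, overlap = 0L, tie = FALSE,
                            canonical_agree = NA))
    }
    best_p <- min(enr$p)
    top <- enr[enr$p == best_p, , drop = FALSE]
    tie <- nrow(top) > 1
    top <- top[order(-top$overlap, top$cell_type), , drop = FALSE]
    call <- top$cell_type[1]
    agree <- NA
    if (!is.null(canonical) && call %in% names(canonical)) {
      agree <- any(canonical[[call]] %in% q)
    }
    tibble::tibble(cluster = cl, cell_type = call, p = best_p,
                   overlap = as.integer(top$overlap[1]), tie = tie,
                   canonical_agree = agree)
  })
}

#' Signature genes of clusters within one cell type
#'
#' A signature gene of a cluster is present in at least `min_pct` of its
#' cells, has average log2 fold change of at least `min_log2fc`, and a
#' Wilcoxon rank-sum Bonferroni-adjusted p below `alpha` when compared to
#' EACH of the other clusters of the same cell type (a conjunction across
#' comparisons). Fold changes are log2 ratios of mean expression on the
#' de-logged (`expm1`) scale with a pseudocount of 1; the Bonferroni
#' denominator is the number of genes tested in the cluster.
#'
#' @param norm A [normalize_counts()] result with a `cluster` cell column.
#' @param cluster_ids Clusters of one cell type to compare among.
#' @param min_pct,min_log2fc,alpha Thresholds (defaults 0.50, 1.0, 0.05:
#'   the published rules).
#' @return Tibble: `cluster`, `gene`, `pct`, `min_log2fc`, `max_p_adj`,
#'   one row per emitted signature gene. A single-cluster input returns an
#'   empty tibble with a warning.
#' @export
signature_genes <- function(norm, cluster_ids, min_pct = 0.50,
                            min_log2fc = 1.0, alpha = 0.05) {
  stopifnot(inherits(norm, "normalized_matrix"))
  cluster_ids <- unique(cluster_ids)
  empty <- tibble::tibble(cluster = character(), gene = character(),
                          pct = double(), min_log2fc = double(),
                          max_p_adj = double())
  if (length(cluster_ids) < 2) {
    warning("need >= 2 clusters of the cell type; returning no signatures")
    return(empty)
  }
  cl <- norm$cells$cluster
  purrr::map_dfr(cluster_ids, function(a_id) {
    a <- which(cl == a_id)
    pct <- detection_fraction(norm$values, a)
    genes <- which(pct >= min_pct)
    if (length(genes) == 0) return(empty)
    m <- length(genes)
    mean_a <- row_means_delog(norm$values, a)[genes]
    fc <- p_adj <- matrix(NA_real_, m, length(cluster_ids) - 1)
    others <- setdiff(cluster_ids, a_id)
    for (i in seq_along(others)) {
      b <- which(cl == others[i])
      fc[, i] <- log2(mean_a + 1) -
        log2(row_means_delog(norm$values, b)[genes] + 1)
      p_adj[, i] <- pmin(1, rowwise_wilcox_p(norm$values, genes, a, b) * m)
    }
    keep <- apply(fc, 1, min) >= min_log2fc & apply(p_adj, 1, max) < alpha
    tibble::tibble(cluster = as.character(a_id),
                   gene = norm$genes$gene[genes][keep],
                   pct = pct[genes][keep],
                   min_log2fc = apply(fc, 1, min)[keep],
                   max_p_adj = apply(p_adj, 1, max)[keep])
  })
}

#' Top variable genes by cross-cell variance of normalized expression
#'
#' @param norm A [normalize_counts()] result.
#' @param n Number of genes to return (default 2000).
#' @return Character vector of gene names in decreasing variance order.
#' @export
select_variable_genes <- function(norm, n = 2000) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (n > nrow(norm$values)) {
    warning("`n` exceeds the gene count; returning all genes")
    n <- nrow(norm$values)
  }
  nc <- ncol(norm$values)
  mu <- Matrix::rowMeans(norm$values)
  ex2 <- Matrix::rowSums(norm$values^2) / nc
  v <- (ex2 - mu^2) * nc / max(1, nc - 1)
  norm$genes$gene[order(v, decreasing = TRUE)][seq_len(n)]
}

#' Number of principal components exceeding a variance threshold
#'
#' The smallest k whose cumulative share of total explained variance is
#' strictly greater than `threshold`.
#'
#' @param explained_variance Non-negative vector of per-component
#'   variances, in decreasing component order.
#' @param threshold Proportion of total variance to exceed (default 0.95).
#' @return Integer k.
#' @export
#' @examples
#' choose_n_pcs(c(0.6, 0.3, 0.1), 0.95)  # 3
choose_n_pcs <- function(explained_variance, threshold = 0.95) {
  if (any(explained_variance < 0)) stop("variances must be non-negative")
  tot <- sum(explained_variance)
  if (tot <= 0) stop("total variance is zero")
  if (threshold >= 1) stop("`threshold` must be below the total variance")
  cum <- cumsum(explained_variance) / tot
  as.integer(which(cum > threshold)[1])
}
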