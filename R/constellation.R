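# deterministic 31-bit seed derived from the global seed and the sorted
# pair identity, so a pair's result is independent of argument order and
# of other pairs
pair_seed <- function(seed, id_a, id_b) {
  key <- paste(sort(c(as.character(id_a), as.character(id_b))),
               collapse = "|")
  h <- as.double(seed %% 2147483647)
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' PCA feature matrix for cluster cross-classification
#'
#' Standardizes the top variable genes (per-gene mean 0, sd 1, sd floor
#' 1e-8) and projects cells onto the smallest set of principal components
#' whose cumulative explained variance exceeds the threshold (capped at
#' `max_pcs` and at the matrix rank).
#'
#' @param norm A [normalize_counts()] result.
#' @param cells Optional barcodes to restrict to (default: all).
#' @param n_variable_genes Number of top-variance genes (default 2000; if
#'   fewer genes exist, all are used with a warning).
#' @param pc_variance_threshold Cumulative-variance threshold (default
#'   0.95).
#' @param max_pcs Hard cap on the number of components (default 50).
#' @return A cells x components score matrix with barcode row names.
#' @export
build_features <- function(norm, cells = NULL, n_variable_genes = 2000,
                           pc_variance_threshold = 0.95, max_pcs = 50) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (is.null(cells)) cells <- norm$cells$barcode
  if (length(cells) < 2) stop("need at least 2 cells")
  genes <- suppressWarnings(
    select_variable_genes(norm, n_variable_genes))
  ci <- match(cells, norm$cells$barcode)
  if (anyNA(ci)) stop("unknown barcode(s) in `cells`")
  m <- t(as.matrix(norm$values[genes, ci, drop = FALSE]))
  sds <- pmax(apply(m, 2, stats::sd), 1e-8)
  m <- scale(m, center = TRUE, scale = sds)
  pc <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev[ev > 1e-12]
  k <- min(choose_n_pcs(ev, pc_variance_threshold), max_pcs, length(ev))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- cells
  scores
}

#' Pairwise cluster-ambiguity statistic by repeated cross-classification
#'
#' Pools the cells of two clusters; in each of `n_repeats` repeats the
#' pooled cells are randomly divided into `n_folds` groups, and for each
#' group a random forest trained on the other groups classifies its cells
#' into one of the two clusters, so every cell is classified exactly once
#' per repeat. Cells misclassified more than `threshold` times are
#' "intermediate", and
#' `percent_intermediate = 100 * n_intermediate / (n_cells_a + n_cells_b)`.
#' A repeat whose training split loses a class entirely is redrawn and
#' logged. The statistic is fully determined by the seed and the sorted
#' pair identity, so results are invariant to cell and argument order.
#'
#' @param features Cells x features matrix with barcode row names (e.g.
#'   from [build_features()]).
#' @param cells_a,cells_b Barcodes of the two clusters.
#' @param cluster_a,cluster_b Cluster labels used in the output.
#' @param n_repeats Number of repeats (default 100).
#' @param n_folds Number of folds per repeat (default 4).
#' @param threshold Misclassification-count cutoff for calling a cell
#'   intermediate (default 25, i.e. > 25 of 100).
#' @param num_trees Trees per random forest (default 100).
#' @param seed Global seed; the pair-level seed is derived from it and the
#'   sorted pair identity.
#' @param stratify_folds Stratify the fold split by cluster (default
#'   FALSE: the pooled cells are divided at random).
#' @return One-row tibble of class `ambiguity_result`: `cluster_a`,
#'   `cluster_b`, `n_cells_a`, `n_cells_b`, `n_intermediate`,
#'   `percent_intermediate`, `n_repeats`, `threshold`, `n_redrawn`, and a
#'   list-column `cell_counts` holding the per-cell misclassification
#'   counts.
#' @export
pairwise_ambiguity <- function(features, cells_a, cells_b,
                               cluster_a = "a", cluster_b = "b",
                               n_repeats = 100, n_folds = 4,
                               threshold = 25, num_trees = 100,
                               seed = 1L, stratify_folds = FALSE) {
  if (length(cells_a) < n_folds || length(cells_b) < n_folds) {
    stop("both clusters need at least `n_folds` cells")
  }
  # canonical order: sorted pair identity, then sorted barcodes
  if (as.character(cluster_a) > as.character(cluster_b)) {
    tmp <- cells_a; cells_a <- cells_b; cells_b <- tmp
    tmpl <- cluster_a; cluster_a <- cluster_b; cluster_b <- tmpl
  }
  cells_a <- sort(cells_a)
  cells_b <- sort(cells_b)
  pooled <- c(cells_a, cells_b)
  lab <- factor(rep(c("a", "b"), c(length(cells_a), length(cells_b))))
  fx <- features[pooled, , drop = FALSE]
  df <- as.data.frame(fx)
  colnames(df) <- paste0("F", seq_len(ncol(df)))
  n <- length(pooled)
  mis <- stats::setNames(integer(n), pooled)
  n_redrawn <- 0L
  set.seed(pair_seed(seed, cluster_a, cluster_b))
  for (r in seq_len(n_repeats)) {
    for (try in 1:100) {
      fold <- if (stratify_folds) {
        f <- integer(n)
        for (g in levels(lab)) {
          idx <- which(lab == g)
          f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
        }
        f
      } else {
        sample(rep_len(seq_len(n_folds), n))
      }
      ok <- all(vapply(seq_len(n_folds), function(k) {
        length(unique(lab[fold != k])) == 2
      }, TRUE))
      if (ok) break
      n_redrawn <- n_redrawn + 1L
    }
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      d_tr <- df[tr, , drop = FALSE]
      d_tr$..cl <- lab[tr]
      fit <- ranger::ranger(dependent.variable.name = "..cl", data = d_tr,
                            num.trees = num_trees, num.threads = 1,
                            seed = sample.int(.Machine$integer.max, 1))
      pred <- stats::predict(fit, data = df[!tr, , drop = FALSE],
                             num.threads = 1)$predictions
      wrong <- pred != lab[!tr]
      mis[which(!tr)[wrong]] <- mis[which(!tr)[wrong]] + 1L
    }
  }
  stopifnot(all(mis <= n_repeats))
  n_int <- sum(mis > threshold)
  out <- tibble::tibble(
    cluster_a = as.character(cluster_a),
    cluster_b = as.character(cluster_b),
    n_cells_a = length(cells_a), n_cells_b = length(cells_b),
    n_intermediate = n_int,
    percent_intermediate = 100 * n_int / (length(cells_a) +
                                            length(cells_b)),
    n_repeats = n_repeats, threshold = threshold, n_redrawn = n_redrawn,
    cell_counts = list(tibble::tibble(barcode = pooled,
                                      misclassified = unname(mis))))
  class(out) <- c("ambiguity_result", class(out))
  out
}

#' Ambiguity statistics for every pair of clusters
#'
#' @param features Cells x features matrix with barcode row names.
#' @param labels Named vector (barcode -> cluster) or tibble with
#'   `barcode` and `cluster` columns.
#' @param cluster_ids Clusters to include (default: all in `labels`).
#' @param ... Passed to [pairwise_ambiguity()].
#' @return Tibble with one row per unordered pair; pairs with fewer cells
#'   than folds are skipped with a warning.
#' @export
ambiguity_matrix <- function(features, labels, cluster_ids = NULL, ...) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$cluster, labels$barcode)
  }
  if (is.null(cluster_ids)) {
    cluster_ids <- sort(unique(as.character(labels)))
  } else {
    cluster_ids <- as.character(cluster_ids)
  }
  if (length(cluster_ids) < 2) stop("need at least 2 clusters")
  dots <- list(...)
  n_folds <- if (is.null(dots$n_folds)) 4 else dots$n_folds
  pairs <- utils::combn(cluster_ids, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- names(labels)[as.character(labels) == pr[1]]
    b <- names(labels)[as.character(labels) == pr[2]]
    if (length(a) < n_folds || length(b) < n_folds) {
      warning("pair (", pr[1], ", ", pr[2], ") skipped: undersized cluster")
      return(NULL)
    }
    pairwise_ambiguity(features, a, b, cluster_a = pr[1],
                       cluster_b = pr[2], ...)
  })
}
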