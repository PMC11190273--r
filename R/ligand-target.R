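#' Construct a prior regulatory model from components
#'
#' @param strength Ligand x target matrix of non-negative regulation
#'   strengths with dimnames.
#' @param pairs Tibble/data frame with columns `ligand`, `receptor`.
#' @return A `prior_model` object.
#' @export
prior_model <- function(strength, pairs) {
  stopifnot(is.matrix(strength), !is.null(rownames(strength)),
            !is.null(colnames(strength)))
  if (any(strength < 0)) stop("regulation strengths must be >= 0")
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("ligand", "receptor") %in% names(pairs)))
  if (!all(pairs$ligand %in% rownames(strength))) {
    stop("every ligand in the pair table must appear in the matrix")
  }
  structure(list(ligands = rownames(strength),
                 targets = colnames(strength),
                 strength = strength, pairs = pairs),
            class = "prior_model")
}

#' @export
print.prior_model <- function(x, ...) {
  cat(sprintf("<prior_model> %d ligands x %d targets, %d L-R pairs\n",
              length(x$ligands), length(x$targets), nrow(x$pairs)))
  invisible(x)
}

#' Read a prior model from long-format TSV files
#'
#' @param strength_path TSV with columns `ligand`, `target`, `strength`.
#' @param pairs_path TSV with columns `ligand`, `receptor`.
#' @return A [prior_model()].
#' @export
read_prior_model <- function(strength_path, pairs_path) {
  long <- readr::read_tsv(strength_path, show_col_types = FALSE)
  pairs <- readr::read_tsv(pairs_path, show_col_types = FALSE)
  ligands <- sort(unique(long$ligand))
  targets <- sort(unique(long$target))
  m <- matrix(0, length(ligands), length(targets),
              dimnames = list(ligands, targets))
  m[cbind(match(long$ligand, ligands), match(long$target, targets))] <-
    long$strength
  prior_model(m, pairs)
}

#' Write a prior model as long-format TSV files
#'
#' @param prior A [prior_model()].
#' @param strength_path,pairs_path Output paths.
#' @return `strength_path`, invisibly.
#' @export
write_prior_model <- function(prior, strength_path, pairs_path) {
  stopifnot(inherits(prior, "prior_model"))
  idx <- which(prior$strength > 0, arr.ind = TRUE)
  long <- tibble::tibble(
    ligand = prior$ligands[idx[, 1]],
    target = prior$targets[idx[, 2]],
    strength = prior$strength[idx])
  long <- dplyr::arrange(long, .data$ligand, .data$target)
  readr::write_tsv(long, strength_path)
  readr::write_tsv(prior$pairs, pairs_path)
  invisible(strength_path)
}

#' Genes expressed in a cluster
#'
#' Genes detected in at least `min_detection` of the cluster's cells
#' (inclusive). With `min_detection = 0`, all genes with at least one
#' positive cell.
#'
#' @param norm A [normalize_counts()] result.
#' @param cluster_id Cluster of interest.
#' @param min_detection Detection-fraction threshold (default 0.10,
#'   mirroring the DE eligibility convention).
#' @return Character vector of gene names.
#' @export
expressed_genes <- function(norm, cluster_id, min_detection = 0.10) {
  stopifnot(inherits(norm, "normalized_matrix"))
  cols <- which(norm$cells$cluster == cluster_id)
  if (length(cols) == 0) stop("cluster ", cluster_id, " has no cells")
  d <- detection_fraction(norm$values, cols)
  if (min_detection == 0) {
    norm$genes$gene[d > 0]
  } else {
    norm$genes$gene[d >= min_detection]
  }
}

#' Candidate ligands for a source-target cluster pair
#'
#' A ligand is retained iff it is a DEG of the source cluster, appears as
#' a ligand in the prior model, and has at least one receptor expressed in
#' the target cluster.
#'
#' @param source_degs DEG gene names of the source cluster.
#' @param prior A [prior_model()].
#' @param target_expressed Expressed gene set of the target cluster.
#' @return Character vector of candidate ligands.
#' @export
candidate_ligands <- function(source_degs, prior, target_expressed) {
  stopifnot(inherits(prior, "prior_model"))
  ligs <- intersect(source_degs, prior$ligands)
  keep <- vapply(ligs, function(l) {
    any(prior$pairs$receptor[prior$pairs$ligand == l] %in% target_expressed)
  }, TRUE)
  ligs[keep]
}

#' Candidate targets: top-k regulated DEGs per ligand
#'
#' For each ligand, its top-`k` targets by regulation strength (zero
#' -strength targets never qualify; ties at rank k include all tied
#' targets and are flagged), intersected with the target cluster's DEGs.
#'
#' @param target_degs DEG gene names of the target cluster.
#' @param ligands Candidate ligands (must be in the prior).
#' @param prior A [prior_model()].
#' @param k Top cutoff (default 250).
#' @return Named list ligand -> character vector of targets; attribute
#'   `tie_at_k` names ligands whose rank-k strength was tied.
#' @export
candidate_targets <- function(target_degs, ligands, prior, k = 250) {
  stopifnot(inherits(prior, "prior_model"), k >= 1)
  if (!all(ligands %in% prior$ligands)) {
    stop("ligand(s) absent from the prior model: ",
         paste(setdiff(ligands, prior$ligands), collapse = ", "))
  }
  ties <- character(0)
  out <- lapply(ligands, function(l) {
    s <- prior$strength[l, ]
    s <- s[s > 0]
    if (length(s) == 0) return(character(0))
    if (length(s) > k) {
      cut <- sort(s, decreasing = TRUE)[k]
      top <- names(s)[s >= cut]
      if (length(top) > k) ties <<- c(ties, l)
    } else {
      top <- names(s)
    }
    intersect(top, target_degs)
  })
  names(out) <- ligands
  attr(out, "tie_at_k") <- ties
  out
}

#' Prioritize ligand-to-target edges across cluster pairs
#'
#' For every source x target cluster pair, runs [candidate_ligands()] then
#' [candidate_targets()], takes the union of targets per target cluster,
#' removes blacklisted genes (ubiquitous DEGs such as MALAT1), and emits
#' edges annotated with regulation strength and the AD direction of ligand
#' and target from the DE results. Output order is deterministic: target
#' cluster, ligand, descending strength.
#'
#' @param source_degs Named list: source cluster -> DEG tibble (as from
#'   [select_degs()], with `gene` and `direction`).
#' @param target_degs Named list: target cluster -> DEG tibble.
#' @param prior A [prior_model()].
#' @param expressed Named list: target cluster -> expressed gene set.
#' @param blacklist Genes removed from targets (default none).
#' @param k Top-target cutoff (default 250).
#' @return Tibble: `ligand`, `source_cluster`, `target`, `target_cluster`,
#'   `regulation_strength`, `ligand_direction`, `target_direction`.
#' @export
prioritize_edges <- function(source_degs, target_degs, prior, expressed,
                             blacklist = character(0), k = 250) {
  stopifnot(inherits(prior, "prior_model"))
  if (length(prior$ligands) == 0 || all(prior$strength == 0)) {
    stop("empty prior model")
  }
  edges <- purrr::map_dfr(names(target_degs), function(tc) {
    t_deg_tbl <- tibble::as_tibble(target_degs[[tc]])
    t_genes <- setdiff(t_deg_tbl$gene, blacklist)
    purrr::map_dfr(names(source_degs), function(sc) {
      s_deg_tbl <- tibble::as_tibble(source_degs[[sc]])
      ligs <- candidate_ligands(s_deg_tbl$gene, prior, expressed[[tc]])
      if (length(ligs) == 0) return(NULL)
      tgt <- candidate_targets(t_genes, ligs, prior, k)
      purrr::map_dfr(ligs, function(l) {
        if (length(tgt[[l]]) == 0) return(NULL)
        tibble::tibble(
          ligand = l, source_cluster = sc, target = tgt[[l]],
          target_cluster = tc,
          regulation_strength = prior$strength[l, tgt[[l]]],
          ligand_direction =
            s_deg_tbl$direction[match(l, s_deg_tbl$gene)],
          target_direction =
            t_deg_tbl$direction[match(tgt[[l]], t_deg_tbl$gene)])
      })
    })
  })
  if (nrow(edges) == 0) {
    return(tibble::tibble(ligand = character(), source_cluster = character(),
                          target = character(), target_cluster = character(),
                          regulation_strength = double(),
                          ligand_direction = character(),
                          target_direction = character()))
  }
  dplyr::arrange(edges, .data$target_cluster, .data$ligand,
                 dplyr::desc(.data$regulation_strength), .data$target)
}
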