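#' Configuration for the synthetic snRNA-seq experiment generator
#'
#' Collects and validates all knobs of [simulate_experiment()]. The generator
#' draws per-gene baseline mean UMI rates from a Gamma law, per-cell library
#' size factors from a lognormal law, and counts from a Poisson law, giving
#' an NB-like zero-inflated marginal: the data regime the two-part hurdle
#' model is designed for.
#'
#' @param n_genes,n_cells,n_clusters,n_donors Problem sizes.
#' @param frac_ad_donors Proportion of donors labelled AD (diagnosis is a
#'   donor-level property: every cell of a donor shares it).
#' @param library_size_log_mean,library_size_log_sd Meanlog/sdlog of the
#'   lognormal per-cell library-size factor (dimensionless, centred near 1
#'   for `log_mean = 0`).
#' @param baseline_gene_mean_shape,baseline_gene_mean_scale Gamma shape and
#'   scale for the per-gene baseline mean UMI per cell (at library factor 1).
#' @param cluster_marker_count Marker genes planted per cluster.
#' @param cluster_marker_multiplier Fold elevation (> 1) of marker genes in
#'   their own cluster.
#' @param planted_de List of `list(cluster =, n_genes =, effect =)` entries:
#'   `n_genes` genes receive a natural-log fold change `effect` in AD cells
#'   of `cluster`.
#' @param planted_de_base_mean Baseline mean UMI assigned to planted DE
#'   genes (jittered by +/- 20%). A moderate fixed value keeps the planted
#'   genes well-detected (so the effect is identifiable on the model scale)
#'   while keeping their share of the transcriptome small (so library-size
#'   normalization does not induce compositional shifts in null genes); see
#'   the methods vignette.
#' @param mito_gene_frac Proportion of genes flagged mitochondrial.
#' @param damaged_cell_frac Proportion of cells given an inflated
#'   mitochondrial share (> 0.10), i.e. planted QC positives.
#' @param doublet_rate Proportion of extra barcodes appended as doublets.
#' @param donor_effect_sd SD (natural-log scale) of per-donor, per-gene
#'   random effects.
#' @param seed Integer seed; fully determines the output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300,
                       n_cells = 1500,
                       n_clusters = 3,
                       n_donors = 8,
                       frac_ad_donors = 0.5,
                       library_size_log_mean = 0,
                       library_size_log_sd = 0.25,
                       baseline_gene_mean_shape = 0.5,
                       baseline_gene_mean_scale = 2,
                       cluster_marker_count = 10,
                       cluster_marker_multiplier = 4,
                       planted_de = list(),
                       planted_de_base_mean = 1.0,
                       mito_gene_frac = 0.05,
                       damaged_cell_frac = 0.05,
                       doublet_rate = 0.05,
                       donor_effect_sd = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
    n_clusters = as.integer(n_clusters), n_donors = as.integer(n_donors),
    frac_ad_donors = frac_ad_donors,
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    baseline_gene_mean_shape = baseline_gene_mean_shape,
    baseline_gene_mean_scale = baseline_gene_mean_scale,
    cluster_marker_count = as.integer(cluster_marker_count),
    cluster_marker_multiplier = cluster_marker_multiplier,
    planted_de = planted_de,
    planted_de_base_mean = planted_de_base_mean,
    mito_gene_frac = mito_gene_frac,
    damaged_cell_frac = damaged_cell_frac,
    doublet_rate = doublet_rate,
    donor_effect_sd = donor_effect_sd,
    seed = as.integer(seed))
  props <- c(cfg$frac_ad_donors, cfg$mito_gene_frac, cfg$damaged_cell_frac,
             cfg$doublet_rate)
  if (any(props < 0 | props > 1)) stop("all proportions must lie in [0, 1]")
  if (cfg$cluster_marker_multiplier <= 1) {
    stop("`cluster_marker_multiplier` must be > 1")
  }
  if (cfg$n_cells < cfg$n_clusters) stop("need n_cells >= n_clusters")
  if (cfg$library_size_log_sd < 0 || cfg$donor_effect_sd < 0) {
    stop("scale parameters must be non-negative")
  }
  n_mito <- round(cfg$mito_gene_frac * cfg$n_genes)
  n_marker <- cfg$n_clusters * cfg$cluster_marker_count
  n_de <- sum(vapply(cfg$planted_de, function(e) as.integer(e$n_genes), 1L))
  if (n_mito + n_marker + n_de > cfg$n_genes) {
    stop("planted mito/marker/DE gene sets exceed `n_genes`")
  }
  for (e in cfg$planted_de) {
    if (!all(c("cluster", "n_genes", "effect") %in% names(e))) {
      stop("each `planted_de` entry needs cluster, n_genes, effect")
    }
    if (!e$cluster %in% seq_len(cfg$n_clusters)) {
      stop("`planted_de` cluster out of range")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Simulate an snRNA-seq experiment with planted ground truth
#'
#' Generates a gene x cell UMI [count_matrix()] with cluster structure,
#' donor/diagnosis effects, mitochondrial genes, damaged cells and appended
#' doublets, plus the ground truth needed to score every downstream stage.
#'
#' The per-cell rate of gene g is
#' `baseline_g * multiplier(if marker of the cell's cluster) *
#'  exp(effect) (if planted DE and the cell's donor is AD) *
#'  exp(donor effect) * library factor`, and counts are Poisson draws from
#' it. Doublets are sums of two randomly paired singlet profiles, thinned
#' back to a freshly drawn library size and appended as extra barcodes (the
#' singlet columns are never mutated). Damaged cells have their
#' mitochondrial rows rescaled so the expected mitochondrial share equals a
#' Beta-distributed fraction above 0.10.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (a [count_matrix()]) and `truth`
#'   (cluster of each cell, doublet barcodes, marker genes per cluster,
#'   planted DE genes and effects, damaged cells, donor table).
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 50, n_cells = 100,
#'                                       n_clusters = 2, seed = 7))
#' dim(sim$counts)
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  n_mito <- round(cfg$mito_gene_frac * cfg$n_genes)
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  mito <- rep(FALSE, cfg$n_genes)
  if (n_mito > 0) {
    mito[seq_len(n_mito)] <- TRUE
    gene_ids[seq_len(n_mito)] <- sprintf("MT-G%04d", seq_len(n_mito))
  }
  base <- pmax(stats::rgamma(cfg$n_genes, shape = cfg$baseline_gene_mean_shape,
                             scale = cfg$baseline_gene_mean_scale), 1e-6)

  # donors: fixed AD count, cells inherit the donor diagnosis
  n_ad <- round(cfg$frac_ad_donors * cfg$n_donors)
  donors <- tibble::tibble(
    donor = sprintf("D%02d", seq_len(cfg$n_donors)),
    diagnosis = rep(c("AD", "control"),
                    c(n_ad, cfg$n_donors - n_ad))[
                      sample.int(cfg$n_donors)],
    sex = sample(c("M", "F"), cfg$n_donors, replace = TRUE),
    apoe4 = sample(c(1L, 0L), cfg$n_donors, replace = TRUE),
    batch = sample(sprintf("B%d", 1:2), cfg$n_donors, replace = TRUE))

  cluster <- sample(rep_len(seq_len(cfg$n_clusters), cfg$n_cells))
  donor_idx <- sample.int(cfg$n_donors, cfg$n_cells, replace = TRUE)
  barcodes <- sprintf("cell_%05d", seq_len(cfg$n_cells))

  # planted markers: disjoint, non-mito, drawn from genes at or above the
  # median baseline (marker genes emulate genes expressed in their
  # cluster; an undetectable "marker" is not a meaningful planted truth)
  free <- which(!mito)
  marker_genes <- list()
  if (cfg$cluster_marker_count > 0) {
    for (k in seq_len(cfg$n_clusters)) {
      pool <- free[base[free] >= stats::median(base[free])]
      if (length(pool) < cfg$cluster_marker_count) pool <- free
      pick <- sample(pool, cfg$cluster_marker_count)
      marker_genes[[as.character(k)]] <- gene_ids[pick]
      free <- setdiff(free, pick)
    }
  }

  # planted DE: disjoint across entries; baselines pinned to a moderate
  # mean so the genes are well-detected yet a small share of the
  # transcriptome
  de_rows <- list()
  de_pool <- free
  for (e in cfg$planted_de) {
    n <- as.integer(e$n_genes)
    pick <- sample(de_pool, n)
    de_pool <- setdiff(de_pool, pick)
    base[pick] <- cfg$planted_de_base_mean * stats::runif(n, 0.8, 1.2)
    de_rows[[length(de_rows) + 1L]] <- tibble::tibble(
      cluster = as.integer(e$cluster), gene = gene_ids[pick],
      effect = e$effect)
  }
  de_genes <- if (length(de_rows)) dplyr::bind_rows(de_rows) else
    tibble::tibble(cluster = integer(), gene = character(),
                   effect = double())

  donor_effect <- matrix(
    stats::rnorm(cfg$n_genes * cfg$n_donors, 0, cfg$donor_effect_sd),
    cfg$n_genes, cfg$n_donors)
  libf <- stats::rlnorm(cfg$n_cells, cfg$library_size_log_mean,
                        cfg$library_size_log_sd)

  lam <- base * exp(donor_effect[, donor_idx, drop = FALSE])
  for (k in names(marker_genes)) {
    gi <- match(marker_genes[[k]], gene_ids)
    ci <- which(cluster == as.integer(k))
    lam[gi, ci] <- lam[gi, ci] * cfg$cluster_marker_multiplier
  }
  cell_dx <- donors$diagnosis[donor_idx]
  if (nrow(de_genes) > 0) {
    for (k in unique(de_genes$cluster)) {
      sub <- de_genes[de_genes$cluster == k, ]
      gi <- match(sub$gene, gene_ids)
      ci <- which(cluster == k & cell_dx == "AD")
      if (length(ci)) lam[gi, ci] <- lam[gi, ci] * exp(sub$effect)
    }
  }
  lam <- sweep(lam, 2, libf, `*`)

  # damaged cells: rescale mito rows so the expected mito share is the drawn
  # fraction (> 0.10), giving the QC filter planted positives
  damaged <- character(0)
  if (cfg$damaged_cell_frac > 0 && n_mito > 0) {
    di <- sort(sample.int(cfg$n_cells,
                          round(cfg$damaged_cell_frac * cfg$n_cells)))
    if (length(di)) {
      f <- 0.10 + 0.40 * stats::rbeta(length(di), 2, 6)
      for (j in seq_along(di)) {
        c0 <- di[j]
        mt <- sum(lam[mito, c0]); tot <- sum(lam[, c0])
        if (mt > 0 && mt < tot) {
          scale <- f[j] * (tot - mt) / ((1 - f[j]) * mt)
          lam[mito, c0] <- lam[mito, c0] * scale
        }
      }
      damaged <- barcodes[di]
    }
  }

  counts <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))

  # doublets: sums of two random singlet profiles, thinned to a fresh
  # library size, appended (never mutating the singlet columns)
  n_doub <- round(cfg$doublet_rate * cfg$n_cells)
  doub_barcodes <- character(0)
  doub_meta <- NULL
  if (n_doub > 0) {
    pairs <- replicate(n_doub, sample.int(cfg$n_cells, 2), simplify = FALSE)
    target <- stats::rlnorm(n_doub, cfg$library_size_log_mean,
                            cfg$library_size_log_sd) * sum(base)
    dcols <- vapply(seq_len(n_doub), function(j) {
      v <- counts[, pairs[[j]][1]] + counts[, pairs[[j]][2]]
      tot <- sum(v)
      p <- if (tot > 0) min(1, target[j] / tot) else 1
      stats::rbinom(length(v), v, p)
    }, numeric(cfg$n_genes))
    dcols <- matrix(dcols, nrow = cfg$n_genes)
    doub_barcodes <- sprintf("doublet_%04d", seq_len(n_doub))
    first <- vapply(pairs, `[`, 1L, 1)
    doub_meta <- tibble::tibble(
      barcode = doub_barcodes,
      donor = donors$donor[donor_idx[first]],
      diagnosis = donors$diagnosis[donor_idx[first]],
      sex = donors$sex[donor_idx[first]],
      apoe4 = donors$apoe4[donor_idx[first]],
      batch = donors$batch[donor_idx[first]],
      cluster = cluster[first])
    counts <- cbind(counts, dcols)
  }

  all_barcodes <- c(barcodes, doub_barcodes)
  dimnames(counts) <- list(gene_ids, all_barcodes)
  cells <- dplyr::bind_rows(
    tibble::tibble(barcode = barcodes,
                   donor = donors$donor[donor_idx],
                   diagnosis = donors$diagnosis[donor_idx],
                   sex = donors$sex[donor_idx],
                   apoe4 = donors$apoe4[donor_idx],
                   batch = donors$batch[donor_idx],
                   cluster = cluster),
    doub_meta)
  gene_meta <- tibble::tibble(gene = gene_ids, mito = mito,
                              protein_coding = TRUE,
                              baseline_mean = base)

  truth <- list(
    cluster_of_cell = tibble::tibble(barcode = barcodes, cluster = cluster),
    doublet_cells = doub_barcodes,
    marker_genes = marker_genes,
    de_genes = de_genes,
    damaged_cells = damaged,
    donors = donors)
  list(counts = count_matrix(Matrix::Matrix(counts, sparse = TRUE),
                             cells, gene_meta),
       truth = truth)
}

#' Simulate a ligand-to-target regulation-strength prior model
#'
#' Builds a sparse ligand x target regulation-strength matrix with planted
#' edges guaranteed to rank inside each ligand's top-`k` targets: planted
#' strengths are drawn from (1, 2), background strengths from (0, 1), so a
#' full sort of any ligand row puts planted targets first. Every ligand
#' receives at least one receptor in the ligand-receptor table.
#'
#' @param n_ligands,n_targets Numbers of ligands/targets when `ligands` /
#'   `targets` names are not supplied.
#' @param planted_edges Tibble or data frame with columns `ligand`,
#'   `target` (names must appear in the ligand/target vocabularies).
#' @param background_density Proportion of non-planted entries given a
#'   nonzero background strength.
#' @param seed Integer seed.
#' @param k Top-target cutoff the construction must respect (default 250).
#' @param ligands,targets Optional explicit name vectors.
#' @param receptors Optional named list ligand -> receptor gene(s); default
#'   one synthetic receptor per ligand.
#' @return A list of class `prior_model`: `ligands`, `targets`,
#'   `strength` (dense ligand x target matrix), `pairs` (ligand-receptor
#'   tibble).
#' @export
simulate_prior_model <- function(n_ligands = 5, n_targets = 100,
                                 planted_edges = NULL,
                                 background_density = 0.1,
                                 seed = 1L, k = 250,
                                 ligands = NULL, targets = NULL,
                                 receptors = NULL) {
  set.seed(as.integer(seed))
  if (is.null(ligands)) ligands <- sprintf("LIG%02d", seq_len(n_ligands))
  if (is.null(targets)) targets <- sprintf("TGT%04d", seq_len(n_targets))
  if (background_density < 0 || background_density > 1) {
    stop("`background_density` must lie in [0, 1]")
  }
  if (is.null(planted_edges)) {
    planted_edges <- tibble::tibble(ligand = character(),
                                    target = character())
  }
  planted_edges <- tibble::as_tibble(planted_edges)
  if (nrow(planted_edges) > 0) {
    if (!all(planted_edges$ligand %in% ligands) ||
        !all(planted_edges$target %in% targets)) {
      stop("planted edges must reference known ligand/target names")
    }
    per <- table(planted_edges$ligand)
    if (any(per > k)) {
      stop("a ligand has more planted edges than `k`; they cannot all rank ",
           "in its top-k")
    }
  }
  strength <- matrix(0, length(ligands), length(targets),
                     dimnames = list(ligands, targets))
  n_bg <- round(background_density * length(strength))
  if (n_bg > 0) {
    idx <- sample.int(length(strength), n_bg)
    strength[idx] <- stats::runif(n_bg, 0, 1)
  }
  if (nrow(planted_edges) > 0) {
    strength[cbind(match(planted_edges$ligand, ligands),
                   match(planted_edges$target, targets))] <-
      stats::runif(nrow(planted_edges), 1, 2)
  }
  if (is.null(receptors)) {
    receptors <- stats::setNames(as.list(paste0("REC_", ligands)), ligands)
  }
  pairs <- tibble::tibble(
    ligand = rep(names(receptors), lengths(receptors)),
    receptor = unlist(receptors, use.names = FALSE))
  if (!all(ligands %in% pairs$ligand)) {
    stop("every ligand needs at least one receptor")
  }
  structure(list(ligands = ligands, targets = targets, strength = strength,
                 pairs = pairs),
            class = "prior_model")
}

#' Simulate per-cohort effect estimates around a shared true effect
#'
#' Each cohort's estimate is a Normal draw around `true_beta` with that
#' cohort's standard error; inputs for [dl_meta()].
#'
#' @param true_beta True shared effect.
#' @param se_per_cohort Vector of per-cohort standard errors (>= 0; zero is
#'   a degenerate case allowed for tests).
#' @param seed Integer seed.
#' @param unit Unit id attached to every row (default "unit1").
#' @return Tibble with columns `unit`, `cohort`, `beta`, `se`.
#' @export
simulate_cohort_effects <- function(true_beta, se_per_cohort, seed = 1L,
                                    unit = "unit1") {
  if (any(se_per_cohort < 0)) stop("standard errors must be >= 0")
  set.seed(as.integer(seed))
  n <- length(se_per_cohort)
  tibble::tibble(
    unit = unit,
    cohort = sprintf("cohort%02d", seq_len(n)),
    beta = stats::rnorm(n, true_beta, se_per_cohort),
    se = se_per_cohort)
}

#' Simulate a qPCR cycle-threshold (CT) table
#'
#' CT values are `baseline - log2(expression) + noise`; a treatment effect
#' enters as a log2 expression shift (so a +1 log2 effect lowers the target
#' CT by one cycle). Every (subject, duration, condition) block contains a
#' target and a reference CT, so the table is complete by construction.
#'
#' @param n_subjects Subjects per condition.
#' @param durations Treatment durations (hours).
#' @param treatment_effect_log2 Log2 expression shift of the target gene in
#'   treated samples (0 = null).
#' @param noise_sd SD of Gaussian CT noise (cycles).
#' @param target,reference Gene names for the target and endogenous
#'   reference roles.
#' @param target_base_ct,reference_base_ct Baseline CTs at expression 1.
#' @param n_batches Number of batches subjects are assigned to.
#' @param seed Integer seed.
#' @return Tibble with columns `subject`, `batch`, `condition`, `duration`,
#'   `gene`, `role` ("target"/"reference"), `ct`.
#' @export
simulate_ct_table <- function(n_subjects = 4, durations = c(6, 12, 24),
                              treatment_effect_log2 = 0, noise_sd = 0,
                              target = "SMAD3", reference = "GAPDH",
                              target_base_ct = 24, reference_base_ct = 18,
                              n_batches = 2, seed = 1L) {
  set.seed(as.integer(seed))
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  batch <- sample(sprintf("B%d", seq_len(n_batches)), n_subjects,
                  replace = TRUE)
  grid <- tidyr::expand_grid(
    subject = subjects,
    condition = c("non-treated", "treated"),
    duration = durations)
  grid$batch <- batch[match(grid$subject, subjects)]
  out <- dplyr::bind_rows(
    dplyr::mutate(grid, gene = target, role = "target",
                  ct = target_base_ct -
                    ifelse(.data$condition == "treated",
                           treatment_effect_log2, 0) +
                    stats::rnorm(dplyr::n(), 0, noise_sd)),
    dplyr::mutate(grid, gene = reference, role = "reference",
                  ct = reference_base_ct +
                    stats::rnorm(dplyr::n(), 0, noise_sd)))
  dplyr::arrange(out, .data$subject, .data$duration, .data$condition,
                 .data$role)
}
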