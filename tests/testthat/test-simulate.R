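test_that("simulation is bit-identical under one seed, distinct under another", {
  cfg <- sim_config(n_genes = 60, n_cells = 120, n_clusters = 2, seed = 4)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$truth, b$truth)
  c3 <- simulate_experiment(sim_config(n_genes = 60, n_cells = 120,
                                       n_clusters = 2, seed = 5))
  expect_false(identical(as.matrix(a$counts$counts),
                         as.matrix(c3$counts$counts)))
})

test_that("zero doublet rate yields no doublets; doublets never mutate singlets", {
  cfg0 <- sim_config(n_genes = 50, n_cells = 100, doublet_rate = 0,
                     seed = 8)
  expect_length(simulate_experiment(cfg0)$truth$doublet_cells, 0)

  args <- list(n_genes = 50, n_cells = 100, seed = 8)
  with_d <- simulate_experiment(do.call(sim_config, c(args,
                                                      doublet_rate = 0.1)))
  singlets <- setdiff(colnames(with_d$counts$counts),
                      with_d$truth$doublet_cells)
  expect_length(with_d$truth$doublet_cells, 10)
  expect_true(all(startsWith(with_d$truth$doublet_cells, "doublet_")))
  expect_setequal(singlets, with_d$truth$cluster_of_cell$barcode)
})

test_that("detection fraction matches the closed-form Poisson zero mass", {
  # all genes at constant rate 1 (degenerate Gamma, unit library factor):
  # P(detected) = 1 - exp(-1)
  cfg <- sim_config(n_genes = 50, n_cells = 2000, n_clusters = 1,
                    library_size_log_sd = 0,
                    baseline_gene_mean_shape = 1e6,
                    baseline_gene_mean_scale = 1e-6,
                    cluster_marker_count = 0, doublet_rate = 0,
                    mito_gene_frac = 0, damaged_cell_frac = 0,
                    donor_effect_sd = 0, seed = 12)
  sim <- simulate_experiment(cfg)
  det <- Matrix::rowMeans(sim$counts$counts > 0)
  target <- 1 - exp(-1)
  expect_lt(abs(mean(det) - target), 0.01)
  # per-gene binomial noise at 2,000 cells keeps almost every gene
  # inside the +/- 0.03 band
  expect_gte(mean(abs(det - target) < 0.03), 0.9)
})

test_that("marker fold elevation tracks the configured multiplier", {
  cfg <- sim_config(n_genes = 100, n_cells = 1000, n_clusters = 2,
                    baseline_gene_mean_shape = 2,
                    baseline_gene_mean_scale = 1,
                    cluster_marker_count = 5, cluster_marker_multiplier = 4,
                    doublet_rate = 0, mito_gene_frac = 0,
                    damaged_cell_frac = 0, donor_effect_sd = 0, seed = 13)
  sim <- simulate_experiment(cfg)
  cpm <- sweep(as.matrix(sim$counts$counts), 2,
               Matrix::colSums(sim$counts$counts), "/")
  cl <- sim$counts$cells$cluster
  for (k in c("1", "2")) {
    gi <- match(sim$truth$marker_genes[[k]], rownames(cpm))
    ratio <- rowMeans(cpm[gi, cl == as.integer(k), drop = FALSE]) /
      rowMeans(cpm[gi, cl != as.integer(k), drop = FALSE])
    expect_true(all(abs(ratio - 4) / 4 < 0.15))
  }
})

test_that("damaged cells have mitochondrial fraction above 0.10", {
  cfg <- sim_config(n_genes = 100, n_cells = 500, mito_gene_frac = 0.1,
                    damaged_cell_frac = 0.1, doublet_rate = 0, seed = 14)
  sim <- simulate_experiment(cfg)
  mito <- sim$counts$genes$mito
  frac <- Matrix::colSums(sim$counts$counts[mito, ]) /
    Matrix::colSums(sim$counts$counts)
  dmg <- sim$counts$cells$barcode %in% sim$truth$damaged_cells
  expect_gt(mean(frac[dmg] > 0.10), 0.9)
  expect_gt(mean(frac[dmg]), mean(frac[!dmg]))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(cluster_marker_multiplier = 1), "> 1")
  expect_error(sim_config(doublet_rate = 1.5), "proportions")
  expect_error(sim_config(n_genes = 10, cluster_marker_count = 10,
                          n_clusters = 3), "exceed")
  expect_error(sim_config(planted_de = list(list(cluster = 9,
                                                 n_genes = 5,
                                                 effect = 1))),
               "out of range")
})

test_that("prior model construction guarantees planted top-k ranks", {
  edges <- tibble::tibble(ligand = c("LIG01", "LIG01", "LIG02"),
                          target = c("TGT0001", "TGT0002", "TGT0003"))
  pm <- simulate_prior_model(3, 50, edges, background_density = 0.4,
                             seed = 3, k = 10)
  # brute-force full sort oracle for each planted target's rank
  for (i in seq_len(nrow(edges))) {
    row <- pm$strength[edges$ligand[i], ]
    rk <- which(names(sort(row, decreasing = TRUE)) == edges$target[i])
    expect_lte(rk, 10)
  }
  expect_true(all(pm$ligands %in% pm$pairs$ligand))

  pm0 <- simulate_prior_model(3, 50, edges, background_density = 0,
                              seed = 3)
  nz <- which(pm0$strength > 0, arr.ind = TRUE)
  expect_equal(nrow(nz), nrow(edges))
  expect_setequal(paste(rownames(pm0$strength)[nz[, 1]],
                        colnames(pm0$strength)[nz[, 2]]),
                  paste(edges$ligand, edges$target))

  expect_error(simulate_prior_model(1, 50,
                                    tibble::tibble(
                                      ligand = rep("LIG01", 5),
                                      target = sprintf("TGT%04d", 1:5)),
                                    k = 3),
               "top-k")
})

test_that("cohort effect simulation is exact in the degenerate case and unbiased", {
  deg <- simulate_cohort_effects(0.7, c(0, 0), seed = 1)
  expect_equal(deg$beta, c(0.7, 0.7))

  # Monte-Carlo oracle: pooled estimate centred on the truth
  pooled <- vapply(1:300, function(s) {
    eff <- simulate_cohort_effects(0, c(0.1, 0.1), seed = s)
    dl_meta(eff)$beta_re
  }, 1)
  expect_lt(abs(mean(pooled)), 0.01)
})

test_that("random-effects interval covers a true effect at nominal rate", {
  hits <- vapply(1:300, function(s) {
    eff <- simulate_cohort_effects(0.5, c(0.1, 0.15, 0.2), seed = 1000 + s)
    m <- dl_meta(eff)
    abs(m$beta_re - 0.5) <= 2 * m$se_re
  }, TRUE)
  expect_gte(mean(hits), 0.94)
})

test_that("CT tables are complete blocks and carry injected shifts exactly", {
  ct <- simulate_ct_table(n_subjects = 3, noise_sd = 0,
                          treatment_effect_log2 = 0, seed = 2)
  blocks <- dplyr::count(ct, subject, condition, duration)
  expect_true(all(blocks$n == 2))  # target + reference everywhere

  ct1 <- simulate_ct_table(n_subjects = 3, noise_sd = 0,
                           treatment_effect_log2 = 1, seed = 2)
  tgt <- dplyr::filter(ct1, role == "target")
  expect_equal(unique(tgt$ct[tgt$condition == "non-treated"] -
                        tgt$ct[tgt$condition == "treated"]), 1)
})

test_that("count matrix round-trips through MTX + TSV on disk", {
  sim <- simulate_experiment(sim_config(n_genes = 80, n_cells = 50,
                                        seed = 6))
  dir <- withr::local_tempdir()
  write_count_matrix(sim$counts, dir)
  back <- read_count_matrix(dir)
  expect_equal(as.matrix(back$counts), as.matrix(sim$counts$counts))
  expect_equal(back$cells$diagnosis, sim$counts$cells$diagnosis)
  expect_equal(back$genes$mito, sim$counts$genes$mito)
})
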