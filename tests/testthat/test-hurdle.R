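make_norm_one_cluster <- function(cfg_seed, ...) {
  cfg <- sim_config(n_clusters = 1, n_donors = 8, cluster_marker_count = 0,
                    doublet_rate = 0, mito_gene_frac = 0,
                    damaged_cell_frac = 0, donor_effect_sd = 0,
                    seed = cfg_seed, ...)
  normalize_counts(simulate_experiment(cfg)$counts)
}

test_that("eligibility is an inclusive 10% OR rule, matching brute force", {
  v <- matrix(0, 3, 20)
  v[1, 1:2] <- 1     # exactly 10% in the AD half (cells 1:10)... see labels
  v[2, 11] <- 1      # 10% in control half only
  dimnames(v) <- list(paste0("g", 1:3), paste0("c", 1:20))
  nm <- manual_normalized(v, cluster = rep(1, 20),
                          extra_cells = tibble::tibble(
                            diagnosis = rep(c("AD", "control"), each = 10)))
  rownames(nm$values) <- paste0("g", 1:3)
  nm$genes$gene <- paste0("g", 1:3)
  el <- eligible_genes(nm, 1)
  expect_setequal(el, c("g1", "g2"))  # zero-count gene g3 ineligible

  # brute-force scan on a simulated cluster
  nm2 <- make_norm_one_cluster(51, n_genes = 100, n_cells = 200)
  el2 <- eligible_genes(nm2, 1)
  dx <- nm2$cells$diagnosis
  d1 <- Matrix::rowMeans(nm2$values[, dx == "AD"] > 0)
  d0 <- Matrix::rowMeans(nm2$values[, dx == "control"] > 0)
  expect_setequal(el2, nm2$genes$gene[d1 >= 0.1 | d0 >= 0.1])
})

test_that("degenerate continuous parts are floored and flagged", {
  X <- cbind("(Intercept)" = rep(1, 20))
  y <- rep(c(0, 2), each = 10)  # all positives equal
  fit <- fit_hurdle_gene(y, X)
  expect_true("cont_var_floor" %in% fit$flags)
  expect_true(is.finite(fit$loglik_cont))
  expect_equal(fit$sigma2, 1e-8)

  y2 <- c(rep(0, 18), 1.5, 2)  # < 3 positives
  fit2 <- fit_hurdle_gene(y2, X)
  expect_false(fit2$cont_testable)
  expect_true("cont_untestable" %in% fit2$flags)
})

test_that("the LRT reduces to p = 1 on identical fits and matches chi-square arithmetic", {
  set.seed(2)
  X <- cbind("(Intercept)" = 1, grp = rep(0:1, each = 25))
  y <- rexp(50) * rbinom(50, 1, 0.7)
  fit <- fit_hurdle_gene(y, X)
  expect_equal(as.numeric(hurdle_lrt(fit, fit)), 1)

  # distribution arithmetic: upper tail at 3.841 with df 1
  expect_equal(stats::pchisq(3.841, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)

  X0 <- cbind("(Intercept)" = rep(1, 50))
  fit0 <- fit_hurdle_gene(y, X0)
  p <- hurdle_lrt(fit, fit0)
  expect_equal(attr(p, "df"), 2)
  expect_error(hurdle_lrt(fit0, fit), "not nest|not nested")
})

test_that("model lnFC obeys its limiting cases", {
  fit <- structure(list(
    coef_disc = c("(Intercept)" = 0.4, grp = 0),
    coef_cont = c("(Intercept)" = 1.1, grp = 0),
    cont_testable = TRUE, terms = c("(Intercept)", "grp"),
    xbar = c("(Intercept)" = 1, grp = 0.5)), class = "hurdle_fit")
  expect_equal(as.numeric(model_lnfc(fit, "grp")), 0)

  # saturated logistic: lnFC equals the continuous group coefficient
  fit$coef_disc <- c("(Intercept)" = 30, grp = 0)
  fit$coef_cont <- c("(Intercept)" = 1.1, grp = 0.8)
  expect_equal(as.numeric(model_lnfc(fit, "grp")), 0.8, tolerance = 1e-8)
})

test_that("model lnFC agrees with the empirical group-mean difference at large n", {
  set.seed(99)
  n <- 5000
  grp <- rep(0:1, each = n)
  lam <- 3 * exp(0.4 * grp)
  y <- log1p(5 * rpois(2 * n, lam))
  X <- cbind("(Intercept)" = 1, grp = grp)
  fit <- fit_hurdle_gene(y, X)
  emp <- mean(y[grp == 1]) - mean(y[grp == 0])
  expect_equal(as.numeric(model_lnfc(fit, "grp")), emp, tolerance = 0.05)
})

test_that("planted diagnosis effects are recovered with calibrated error control", {
  sim <- simulate_experiment(sim_config(
    n_genes = 300, n_cells = 600, n_clusters = 1, n_donors = 8,
    baseline_gene_mean_shape = 2, baseline_gene_mean_scale = 1.5,
    cluster_marker_count = 0, doublet_rate = 0, mito_gene_frac = 0,
    damaged_cell_frac = 0, donor_effect_sd = 0,
    planted_de = list(list(cluster = 1, n_genes = 30, effect = 0.5)),
    seed = 52))
  nm <- normalize_counts(sim$counts)
  res <- run_hurdle_de(nm, 1, "diagnosis")
  planted <- sim$truth$de_genes$gene
  degs <- select_degs(res)
  expect_gte(mean(planted %in% degs$gene), 0.8)
  if (nrow(degs) > 0) {
    expect_lte(mean(!degs$gene %in% planted), 0.15)
  }
  expect_lt(abs(mean(res$lnfc[res$gene %in% planted]) - 0.5), 0.15)

  # BH q-values are a monotone step transform of p
  tested <- dplyr::arrange(dplyr::filter(res, tested), p)
  expect_true(all(diff(tested$q) >= -1e-12))
  expect_true(all(tested$q >= tested$p - 1e-12))
})

test_that("relabeling the binary coding flips lnFC and leaves p unchanged", {
  nm <- make_norm_one_cluster(53, n_genes = 60, n_cells = 300)
  res <- run_hurdle_de(nm, 1, "diagnosis")
  nm_flip <- nm
  nm_flip$cells$diagnosis <- ifelse(nm$cells$diagnosis == "AD",
                                    "control", "AD")
  res_flip <- run_hurdle_de(nm_flip, 1, "diagnosis")
  j <- dplyr::inner_join(tibble::as_tibble(res),
                         tibble::as_tibble(res_flip), by = "gene")
  expect_equal(j$lnfc.x, -j$lnfc.y, tolerance = 1e-6)
  expect_equal(j$p.x, j$p.y, tolerance = 1e-6)
})

test_that("power increases with the planted effect size", {
  sens <- vapply(c(0.25, 0.5, 1.0), function(delta) {
    sim <- simulate_experiment(sim_config(
      n_genes = 150, n_cells = 300, n_clusters = 1, n_donors = 8,
      baseline_gene_mean_shape = 2, baseline_gene_mean_scale = 1.5,
      cluster_marker_count = 0, doublet_rate = 0, mito_gene_frac = 0,
      damaged_cell_frac = 0, donor_effect_sd = 0,
      planted_de = list(list(cluster = 1, n_genes = 15, effect = delta)),
      seed = 54))
    nm <- normalize_counts(sim$counts)
    res <- run_hurdle_de(nm, 1, "diagnosis")
    mean(sim$truth$de_genes$gene %in% select_degs(res)$gene)
  }, 1)
  expect_true(all(diff(sens) >= 0))
})

test_that("DEG selection applies the detection, q and fold-change conjunction", {
  res <- tibble::tibble(
    gene = paste0("g", 1:5),
    lnfc = c(0.05, -0.3, 0.5, 0.4, -0.2),
    p = c(0.001, 0.001, 0.001, 0.2, 0.001),
    q = c(0.04, 0.04, 0.04, 0.4, 0.04),
    pct_group1 = c(0.5, 0.25, 0.1, 0.5, 0.19),
    pct_group0 = c(0.5, 0.10, 0.15, 0.5, 0.12),
    tested = TRUE, flags = "")
  degs <- select_degs(res)
  # g1: |lnfc| too small; g3: detection too low; g4: q too big; g5: pct
  expect_equal(degs$gene, "g2")
  expect_equal(degs$direction, "down")

  # brute-force filter equality on a simulated table
  nm <- make_norm_one_cluster(55, n_genes = 80, n_cells = 200)
  res2 <- run_hurdle_de(nm, 1, "diagnosis")
  bf <- res2$gene[res2$tested &
                    (dplyr::coalesce(res2$pct_group1, 0) >= 0.2 |
                       dplyr::coalesce(res2$pct_group0, 0) >= 0.2) &
                    res2$q < 0.05 & abs(res2$lnfc) > 0.1]
  expect_setequal(select_degs(res2)$gene, bf)
})

test_that("an empty eligible set returns an empty table with a warning", {
  v <- matrix(0, 4, 30)
  v[, 1] <- 0.5  # every gene detected in ~3% of cells only
  v[1, 1] <- 0
  nm <- manual_normalized(v, cluster = rep(1, 30),
                          extra_cells = tibble::tibble(
                            diagnosis = rep(c("AD", "control"), 15)))
  expect_warning(res <- run_hurdle_de(nm, 1, "diagnosis"), "no eligible")
  expect_equal(nrow(res), 0)
})
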