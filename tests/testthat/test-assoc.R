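test_that("cluster proportions are exact ratios that sum to one per donor", {
  cells <- tibble::tibble(
    donor = rep(c("d1", "d2", "d3"), c(4, 6, 2)),
    cluster = c(1, 1, 2, 3, 1, 2, 2, 2, 3, 3, 1, 1),
    diagnosis = rep(c("AD", "control", "AD"), c(4, 6, 2)))
  tbl <- cluster_proportions(cells)
  sums <- dplyr::summarise(dplyr::group_by(tbl, donor),
                           s = sum(proportion))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  # brute-force group-count division
  expect_equal(tbl$proportion[tbl$donor == "d1" & tbl$cluster == 1], 0.5)
  expect_equal(tbl$proportion[tbl$donor == "d2" & tbl$cluster == 2], 0.5)
  # donor with all cells in one cluster: 1 there, 0 elsewhere
  expect_equal(sort(tbl$proportion[tbl$donor == "d3"]), c(0, 0, 1))
  expect_equal(tbl$diagnosis[tbl$donor == "d3"][1], "AD")
})

test_that("complete separation of 4 vs 4 donors gives the exact rank-sum p = 2/70", {
  tbl <- tibble::tibble(
    donor = paste0("d", 1:8), cluster = "c1",
    proportion = c(0.1, 0.12, 0.14, 0.16, 0.3, 0.32, 0.34, 0.36),
    diagnosis = rep(c("control", "AD"), each = 4))
  res <- proportion_association(tbl, "c1", "diagnosis")
  expect_equal(res$method, "wilcoxon_exact")
  expect_equal(res$p, 2 / 70, tolerance = 1e-12)
  # exhaustive enumeration of all 70 rank assignments agrees
  expect_equal(exact_ranksum_p(tbl$proportion[5:8], tbl$proportion[1:4]),
               2 / 70, tolerance = 1e-12)
})

test_that("a symmetric configuration gives p = 1 and monotone data give rho = 1", {
  tbl <- tibble::tibble(
    donor = paste0("d", 1:8), cluster = "c1",
    proportion = c(1, 4, 6, 7, 2, 3, 5, 8) / 36,
    diagnosis = rep(c("AD", "control"), each = 4))
  res <- proportion_association(tbl, "c1", "diagnosis")
  expect_equal(res$p, 1)

  sp <- tibble::tibble(donor = paste0("d", 1:5), cluster = "c1",
                       proportion = c(0.1, 0.2, 0.3, 0.4, 0.5),
                       braak = c(1, 2, 3, 4, 5))
  res_sp <- proportion_association(sp, "c1", "braak")
  expect_equal(res_sp$method, "spearman")
  expect_equal(unname(res_sp$statistic), 0)  # rho = 1 <-> S = 0
  expect_lt(res_sp$p, 0.05)

  expect_error(proportion_association(
    dplyr::mutate(sp, braak = 1), "c1", "braak"), "constant")
})

test_that("exact and normal-approximation rank-sum p agree for moderate n", {
  set.seed(4)
  for (rep in 1:5) {
    a <- rnorm(15); b <- rnorm(15, 0.3)
    p_ex <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    p_ap <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_ex - p_ap), 0.02)
  }
})

test_that("DerSimonian-Laird pooling matches the closed-form arithmetic exactly", {
  m <- dl_meta(tibble::tibble(unit = "u", beta = c(0.2, 0.6),
                              se = c(0.1, 0.1)))
  expect_equal(m$beta_fixed, 0.4, tolerance = 1e-12)
  expect_equal(m$q, 8, tolerance = 1e-12)
  expect_equal(m$tau2, 0.07, tolerance = 1e-12)
  expect_equal(m$beta_re, 0.4, tolerance = 1e-12)
  expect_equal(m$se_re, 0.2, tolerance = 1e-12)
  expect_equal(m$i2, 87.5, tolerance = 1e-12)

  # homogeneous case collapses to fixed effects
  h <- dl_meta(data.frame(beta = c(0.5, 0.5), se = c(0.1, 0.1)))
  expect_equal(h$q, 0)
  expect_equal(h$tau2, 0)
  expect_equal(h$i2, 0)
  expect_equal(h$beta_re, 0.5)

  # a single cohort duplicated n times pools to exactly that beta
  d <- dl_meta(data.frame(beta = rep(0.31, 5), se = rep(0.07, 5)))
  expect_equal(d$beta_re, 0.31)

  expect_error(dl_meta(data.frame(beta = 1, se = 1)), ">= 2")
  expect_error(dl_meta(data.frame(beta = c(1, 1), se = c(1, 0))), "> 0")
})

test_that("whenever Q <= df the pooling reduces to inverse-variance fixed effects", {
  eff <- data.frame(beta = c(0.40, 0.42, 0.41), se = c(0.2, 0.25, 0.3))
  m <- dl_meta(eff)
  expect_lte(m$q, 2)
  expect_equal(m$tau2, 0)
  w <- 1 / eff$se^2
  expect_equal(m$beta_re, sum(w * eff$beta) / sum(w), tolerance = 1e-12)
})

test_that("pooled results agree with an independent reference implementation", {
  skip_if_not_installed("metafor")
  set.seed(10)
  for (rep in 1:5) {
    eff <- data.frame(beta = rnorm(4, 0.3, 0.2),
                      se = runif(4, 0.05, 0.3))
    m <- dl_meta(eff)
    ref <- metafor::rma(yi = eff$beta, sei = eff$se, method = "DL")
    expect_equal(m$beta_re, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(m$se_re, ref$se, tolerance = 1e-10)
    expect_equal(m$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(m$q, ref$QE, tolerance = 1e-10)
  }
})

test_that("the dual-endpoint screen equals a brute-force row filter", {
  set.seed(6)
  n <- 50
  m1 <- tibble::tibble(unit = paste0("v", 1:n), k = 2,
                       beta_re = rnorm(n), se_re = 0.1,
                       p_re = runif(n)^2, tau2 = 0, q = 0, i2 = 0,
                       beta_fixed = 0)
  m2 <- tibble::tibble(unit = paste0("v", 1:n), k = 2,
                       beta_re = rnorm(n), se_re = 0.1,
                       p_re = runif(n)^2, tau2 = 0, q = 0, i2 = 0,
                       beta_fixed = 0)
  got <- dual_endpoint_screen(m1, m2, alpha = 0.05,
                              required_sign1 = -1, required_sign2 = 1)
  bf <- m1$unit[m1$p_re < 0.05 & m2$p_re < 0.05 &
                  m1$beta_re < 0 & m2$beta_re > 0]
  expect_setequal(got$unit, bf)
  expect_gt(nrow(got), 0)

  # screening rules on hand-built cases
  mk <- function(unit, beta, p) tibble::tibble(
    unit = unit, k = 2, beta_re = beta, se_re = 0.1, p_re = p, tau2 = 0,
    q = 0, i2 = 0, beta_fixed = beta)
  keep <- dual_endpoint_screen(mk("a", -1, 0.04), mk("a", 1, 0.03))
  expect_equal(keep$unit, "a")
  drop1 <- dual_endpoint_screen(mk("a", -1, 0.04), mk("a", 1, 0.30))
  expect_equal(nrow(drop1), 0)
  expect_warning(dual_endpoint_screen(mk("a", -1, 0.01),
                                      mk("b", 1, 0.01)),
                 "one endpoint")
})

test_that("ddCT relative quantities follow the comparative-CT arithmetic", {
  ct <- tibble::tibble(
    subject = rep(c("cal", "s1", "s2"), each = 2),
    gene = rep(c("TG", "REF"), 3),
    ct = c(30, 24,   # calibrator dCT = 6
           29, 24,   # s1 dCT = 5 -> RQ 2
           32, 24))  # s2 dCT = 8 -> RQ 1/4
  rq <- ddct_relative_quantity(ct, "TG", "REF", "cal")
  expect_equal(rq$rq[rq$subject == "cal"], 1)
  expect_equal(rq$rq[rq$subject == "s1"], 2)
  expect_equal(rq$rq[rq$subject == "s2"], 0.25)

  # a global CT shift leaves every RQ unchanged
  rq_shift <- ddct_relative_quantity(dplyr::mutate(ct, ct = ct + 3.7),
                                     "TG", "REF", "cal")
  expect_equal(rq_shift$rq, rq$rq)

  # composing two calibrator shifts multiplies RQs
  rq_s1 <- ddct_relative_quantity(ct, "TG", "REF", "s1")
  expect_equal(rq$rq / rq$rq[rq$subject == "s1"], rq_s1$rq)

  # technical replicates are averaged on the CT scale
  ct_rep <- dplyr::bind_rows(ct, dplyr::mutate(ct, ct = ct + 0.2))
  rq_rep <- ddct_relative_quantity(ct_rep, "TG", "REF", "cal")
  expect_equal(rq_rep$rq, rq$rq)

  expect_error(ddct_relative_quantity(ct, "TG", "REF", "nope"),
               "calibrator")
})

test_that("treatment normalization uses duration-matched non-treated medians", {
  # all samples identical -> all values 1
  flat <- simulate_ct_table(n_subjects = 3, noise_sd = 0,
                            treatment_effect_log2 = 0, seed = 5)
  v <- ddct_treatment_normalization(flat, "SMAD3", "GAPDH")
  expect_true(all(abs(v$value - 1) < 1e-12))

  # a -1 log2 expression effect (target CT one cycle above baseline)
  # halves the treated value; a +1 effect doubles it
  up <- simulate_ct_table(n_subjects = 4, noise_sd = 0,
                          treatment_effect_log2 = 1, seed = 5)
  vu <- ddct_treatment_normalization(up, "SMAD3", "GAPDH")
  expect_true(all(abs(vu$value[vu$condition == "treated"] - 2) < 1e-12))
  expect_true(all(abs(vu$value[vu$condition == "non-treated"] - 1) <
                    1e-12))

  # output is invariant to input row order
  perm <- up[sample(nrow(up)), ]
  expect_equal(ddct_treatment_normalization(perm, "SMAD3", "GAPDH"), vu)

  # a duration with no non-treated baseline is an error
  broken <- dplyr::filter(up, !(condition == "non-treated" &
                                  duration == 12))
  expect_error(ddct_treatment_normalization(broken, "SMAD3", "GAPDH"),
               "baseline")
})

test_that("tidiers expose estimates and heterogeneity", {
  m <- dl_meta(data.frame(unit = "u", beta = c(0.2, 0.6),
                          se = c(0.1, 0.1)))
  td <- generics::tidy(m)
  expect_equal(td$estimate, 0.4)
  gl <- generics::glance(m)
  expect_equal(gl$i2, 87.5)

  set.seed(1)
  X <- cbind("(Intercept)" = 1, grp = rep(0:1, 20))
  y <- rexp(40) * rbinom(40, 1, 0.8)
  fit <- fit_hurdle_gene(y, X)
  td2 <- generics::tidy(fit)
  expect_setequal(unique(td2$component), c("discrete", "continuous"))
  expect_equal(generics::glance(fit)$n, 40)
})
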