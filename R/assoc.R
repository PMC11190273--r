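#' Per-donor cluster proportions
#'
#' For each donor and cluster, the number of the donor's cells in that
#' cluster divided by the donor's total cell count; donors with no cells
#' in a cluster get 0, so per-donor proportions sum to 1.
#'
#' @param cell_metadata Tibble with `donor` and `cluster` columns (one row
#'   per cell); donor phenotype columns are carried through.
#' @return Tibble: `donor`, `cluster`, `n_cells`, `proportion`, plus any
#'   donor-level phenotype columns present in the input.
#' @export
cluster_proportions <- function(cell_metadata) {
  cm <- tibble::as_tibble(cell_metadata)
  stopifnot(all(c("donor", "cluster") %in% names(cm)))
  if (anyNA(cm$donor) || anyNA(cm$cluster)) {
    stop("every cell needs a donor and a cluster")
  }
  counts <- dplyr::count(cm, .data$donor, .data$cluster, name = "n_cells")
  full <- tidyr::complete(counts, .data$donor, .data$cluster,
                          fill = list(n_cells = 0L))
  full <- dplyr::group_by(full, .data$donor)
  full <- dplyr::mutate(full, proportion = .data$n_cells /
                          sum(.data$n_cells))
  full <- dplyr::ungroup(full)
  pheno_cols <- setdiff(names(cm), c("barcode", "cluster"))
  pheno <- dplyr::distinct(cm[, pheno_cols, drop = FALSE])
  if (anyDuplicated(pheno$donor)) {
    stop("donor phenotype columns are not constant within donor")
  }
  dplyr::left_join(full, pheno, by = "donor")
}

#' Association of a cluster's cell distribution with a donor phenotype
#'
#' Dispatches on the phenotype type: a two-sided Wilcoxon rank-sum test
#' for binary variables (exact enumeration when the combined donor count
#' is at most 20 and there are no ties; normal approximation with tie and
#' continuity correction otherwise) or a two-sided Spearman rank
#' correlation for quantitative/semi-quantitative variables.
#'
#' @param proportions A [cluster_proportions()] table.
#' @param cluster_id Cluster to test.
#' @param variable Phenotype column name.
#' @param binary Force the dispatch; default guesses from the column type
#'   (non-numeric or 0/1-valued with two levels = binary).
#' @return One-row tibble: `cluster`, `variable`, `method`, `statistic`,
#'   `p`, `n`.
#' @export
proportion_association <- function(proportions, cluster_id, variable,
                                   binary = NULL) {
  tbl <- dplyr::filter(tibble::as_tibble(proportions),
                       .data$cluster == cluster_id)
  if (nrow(tbl) == 0) stop("cluster ", cluster_id, " absent from the table")
  x <- tbl[[variable]]
  if (length(unique(x)) < 2) stop("`", variable, "` is constant")
  if (is.null(binary)) {
    binary <- !is.numeric(x) || all(x %in% c(0, 1))
  }
  if (binary) {
    g <- as.factor(x)
    if (nlevels(g) != 2) stop("binary variable must have two levels")
    a <- tbl$proportion[g == levels(g)[2]]  # coded-1 / later level first
    b <- tbl$proportion[g == levels(g)[1]]
    if (length(a) < 2 || length(b) < 2) {
      stop("need >= 2 donors per group")
    }
    exact <- (length(a) + length(b)) <= 20 &&
      !anyDuplicated(c(a, b))
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = !exact))
    method <- if (exact) "wilcoxon_exact" else "wilcoxon_normal"
  } else {
    if (length(x) < 3) stop("need >= 3 donors for correlation")
    ht <- suppressWarnings(
      stats::cor.test(tbl$proportion, x, method = "spearman",
                      alternative = "two.sided"))
    method <- "spearman"
  }
  tibble::tibble(cluster = as.character(cluster_id), variable = variable,
                 method = method,
                 statistic = unname(ht$statistic), p = ht$p.value,
                 n = nrow(tbl))
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-cohort effect estimates with the method-of-moments
#' between-study variance: with fixed weights `w = 1/se^2`,
#' `Q = sum w (b - b_fixed)^2`, `C = sum w - sum w^2 / sum w`,
#' `tau^2 = max(0, (Q - df) / C)`; random-effects weights
#' `w* = 1/(se^2 + tau^2)` give `beta_RE = sum w* b / sum w*`,
#' `se_RE = (sum w*)^(-1/2)`, a two-sided normal p-value, and
#' `I^2 = max(0, 100 (Q - df) / Q)`.
#'
#' @param effects Tibble/data frame with columns `beta` and `se` (> 0),
#'   one row per cohort; an optional `unit` column (constant) is carried
#'   through.
#' @return One-row tibble of class `meta_result`: `unit` (NA if absent),
#'   `k`, `beta_re`, `se_re`, `p_re`, `tau2`, `q`, `i2`, `beta_fixed`.
#' @export
#' @examples
#' dl_meta(data.frame(beta = c(0.2, 0.6), se = c(0.1, 0.1)))
dl_meta <- function(effects) {
  eff <- tibble::as_tibble(effects)
  stopifnot(all(c("beta", "se") %in% names(eff)))
  if (nrow(eff) < 2) stop("need >= 2 cohorts")
  if (any(eff$se <= 0)) stop("all standard errors must be > 0")
  b <- eff$beta
  w <- 1 / eff$se^2
  k <- length(b)
  b_fixed <- sum(w * b) / sum(w)
  q <- sum(w * (b - b_fixed)^2)
  df <- k - 1
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - df) / cc)
  ws <- 1 / (eff$se^2 + tau2)
  beta_re <- sum(ws * b) / sum(ws)
  se_re <- 1 / sqrt(sum(ws))
  p_re <- 2 * stats::pnorm(-abs(beta_re / se_re))
  i2 <- max(0, 100 * (q - df) / q)
  if (q == 0) i2 <- 0
  out <- tibble::tibble(
    unit = if ("unit" %in% names(eff)) eff$unit[1] else NA_character_,
    k = k, beta_re = beta_re, se_re = se_re, p_re = p_re,
    tau2 = tau2, q = q, i2 = i2, beta_fixed = b_fixed)
  class(out) <- c("meta_result", class(out))
  out
}

#' Meta-analyze many units at once
#'
#' @param effects Tibble with columns `unit`, `beta`, `se`.
#' @return A [dl_meta()] row per unit.
#' @export
dl_meta_by_unit <- function(effects) {
  eff <- tibble::as_tibble(effects)
  stopifnot("unit" %in% names(eff))
  purrr::map_dfr(split(eff, eff$unit), dl_meta)
}

#' Dual-endpoint concordance screen
#'
#' Retains units nominally significant (`p_re < alpha`) in BOTH endpoints
#' with pooled-effect signs matching the required pattern (e.g. negative
#' for infarct risk and positive for expression). Units present in only
#' one endpoint are skipped with a warning.
#'
#' @param meta1,meta2 [dl_meta_by_unit()] tables for the two endpoints.
#' @param alpha Significance threshold (default 0.05).
#' @param required_sign1,required_sign2 `-1` or `+1`.
#' @return Tibble of retained units with both endpoints' `beta_re`/`p_re`.
#' @export
dual_endpoint_screen <- function(meta1, meta2, alpha = 0.05,
                                 required_sign1 = -1, required_sign2 = 1) {
  m1 <- tibble::as_tibble(meta1)
  m2 <- tibble::as_tibble(meta2)
  missing <- union(setdiff(m1$unit, m2$unit), setdiff(m2$unit, m1$unit))
  if (length(missing)) {
    warning(length(missing), " unit(s) present in only one endpoint ",
            "skipped")
  }
  j <- dplyr::inner_join(
    dplyr::select(m1, unit = "unit", beta_1 = "beta_re", p_1 = "p_re"),
    dplyr::select(m2, unit = "unit", beta_2 = "beta_re", p_2 = "p_re"),
    by = "unit")
  dplyr::filter(j, .data$p_1 < alpha, .data$p_2 < alpha,
                sign(.data$beta_1) == required_sign1,
                sign(.data$beta_2) == required_sign2)
}

# average technical replicates on the CT scale and compute per-sample dCT
sample_dct <- function(ct, target, reference,
                       sample_cols = c("subject", "condition", "duration")) {
  tbl <- tibble::as_tibble(ct)
  stopifnot(all(c("gene", "ct") %in% names(tbl)))
  sample_cols <- intersect(sample_cols, names(tbl))
  if (length(sample_cols) == 0) stop("no sample-identifying columns found")
  keep <- c(sample_cols, intersect("batch", names(tbl)))
  agg <- dplyr::summarise(
    dplyr::group_by(tbl, dplyr::across(dplyr::all_of(c(keep, "gene")))),
    ct = mean(.data$ct), .groups = "drop")
  wide <- tidyr::pivot_wider(
    dplyr::filter(agg, .data$gene %in% c(target, reference)),
    names_from = "gene", values_from = "ct")
  if (!all(c(target, reference) %in% names(wide))) {
    stop("table lacks target or reference CT values")
  }
  incomplete <- is.na(wide[[target]]) | is.na(wide[[reference]])
  if (any(incomplete)) {
    warning(sum(incomplete), " sample(s) without both target and ",
            "reference CT skipped")
    wide <- wide[!incomplete, , drop = FALSE]
  }
  wide$dct <- wide[[target]] - wide[[reference]]
  wide
}

#' Comparative-CT relative quantification
#'
#' `dCT = CT_target - CT_reference` per sample (technical replicates
#' averaged on the CT scale first), `ddCT = dCT_sample - dCT_calibrator`,
#' `RQ = 2^(-ddCT)`. The calibrator sample has RQ exactly 1.
#'
#' @param ct Long CT table with columns `subject` (and optionally
#'   `condition`, `duration`, `batch`), `gene`, `ct`.
#' @param target,reference Gene names of the target and the endogenous
#'   reference (e.g. RNU2-1).
#' @param calibrator_subject Subject id of the calibrator sample (e.g.
#'   brain homogenate).
#' @return Tibble with the sample-identifying columns plus `dct`, `ddct`,
#'   `rq`.
#' @export
ddct_relative_quantity <- function(ct, target, reference,
                                   calibrator_subject) {
  wide <- sample_dct(ct, target, reference)
  cal <- wide$dct[wide$subject == calibrator_subject]
  if (length(cal) == 0) stop("calibrator sample not found")
  cal <- mean(cal)
  wide$ddct <- wide$dct - cal
  wide$rq <- 2^(-wide$ddct)
  dplyr::select(wide, -dplyr::all_of(c(target, reference)))
}

#' Treatment ddCT normalization for plotting
#'
#' For each treatment duration, the median dCT of non-treated samples is
#' the baseline point. Non-treated samples are reported as their dCT
#' divided by that duration's baseline; treated samples as
#' `2^(-(dCT_treated - baseline))`, i.e. 2 to the negative ddCT against
#' the duration-matched non-treated median.
#'
#' @param ct Long CT table with columns `subject`, `condition`
#'   ("treated"/"non-treated"), `duration`, `gene`, `ct`.
#' @param target,reference Gene names of the target and reference roles.
#' @return Tibble: sample columns plus `dct`, `baseline_dct`, `value`.
#' @export
ddct_treatment_normalization <- function(ct, target, reference) {
  wide <- sample_dct(ct, target, reference)
  stopifnot(all(c("condition", "duration") %in% names(wide)))
  base <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(wide, .data$condition == "non-treated"),
                    .data$duration),
    baseline_dct = stats::median(.data$dct), .groups = "drop")
  missing <- setdiff(unique(wide$duration), base$duration)
  if (length(missing)) {
    stop("duration(s) without non-treated baseline: ",
         paste(missing, collapse = ", "))
  }
  out <- dplyr::left_join(wide, base, by = "duration")
  out$value <- ifelse(out$condition == "treated",
                      2^(-(out$dct - out$baseline_dct)),
                      out$dct / out$baseline_dct)
  out <- dplyr::select(out, -dplyr::all_of(c(target, reference)))
  dplyr::arrange(out, .data$duration, .data$condition, .data$subject)
}
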