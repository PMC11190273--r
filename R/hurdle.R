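#' Genes eligible for differential expression testing in a cluster
#'
#' A gene is eligible iff it is detected (UMI >= 1, i.e. nonzero
#' normalized value) in at least `min_detection` of the cluster's cells in
#' group 1 OR in group 0 (inclusive thresholds).
#'
#' @param norm A [normalize_counts()] result with `cluster` and the group
#'   column in its cell metadata.
#' @param cluster_id Cluster to test.
#' @param group_col Cell metadata column holding the two groups.
#' @param groups The two group labels (group 1 first).
#' @param min_detection Detection-fraction threshold (default 0.10).
#' @return Character vector of eligible gene names.
#' @export
eligible_genes <- function(norm, cluster_id, group_col = "diagnosis",
                           groups = c("AD", "control"),
                           min_detection = 0.10) {
  stopifnot(inherits(norm, "normalized_matrix"))
  in_cl <- norm$cells$cluster == cluster_id
  if (!any(in_cl)) stop("cluster ", cluster_id, " has no cells")
  grp <- norm$cells[[group_col]]
  d1 <- detection_fraction(norm$values, which(in_cl & grp == groups[1]))
  d0 <- detection_fraction(norm$values, which(in_cl & grp == groups[2]))
  d1[is.na(d1)] <- 0
  d0[is.na(d0)] <- 0
  norm$genes$gene[d1 >= min_detection | d0 >= min_detection]
}

# Newton ridge-penalized logistic regression (penalty on non-intercept
# coefficients); returns unpenalized log-likelihood at the solution.
ridge_logistic <- function(X, z, lambda = 1e-2, maxit = 50) {
  p <- ncol(X)
  pen <- rep(lambda, p)
  pen[colnames(X) == "(Intercept)"] <- 0
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, z - mu)) - pen * beta
    hess <- crossprod(X * w, X) + diag(pen, p)
    step <- tryCatch(solve(hess, grad), error = function(e) rep(0, p))
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- drop(X %*% beta)
  ll <- sum(z * eta - log1p(exp(eta)))
  list(coef = stats::setNames(beta, colnames(X)), loglik = ll)
}

logistic_part <- function(X, z, ridge = 1e-2) {
  flags <- character(0)
  if (all(z == z[1])) {
    # no variation in detection: saturated likelihood is 0, coefficients
    # undefined beyond the sign of the intercept
    beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
    beta["(Intercept)"] <- if (z[1] > 0) 20 else -20
    return(list(coef = beta, loglik = 0, rank = 1L,
                flags = "disc_degenerate"))
  }
  qrX <- qr(X)
  rank <- qrX$rank
  keep <- qrX$pivot[seq_len(rank)]
  Xr <- X[, keep, drop = FALSE]
  sep <- FALSE
  fit <- withCallingHandlers(
    suppressWarnings(stats::glm.fit(Xr, z, family = stats::binomial())),
    warning = function(w) invokeRestart("muffleWarning"))
  mu <- fit$fitted.values
  if (!fit$converged || any(mu < 1e-8) || any(mu > 1 - 1e-8)) sep <- TRUE
  if (sep) {
    rfit <- ridge_logistic(Xr, z, lambda = ridge)
    coef <- rfit$coef
    ll <- rfit$loglik
    flags <- "disc_ridge"
  } else {
    coef <- stats::setNames(fit$coefficients, colnames(Xr))
    ll <- sum(z * log(pmax(mu, 1e-12)) + (1 - z) * log(pmax(1 - mu, 1e-12)))
  }
  full_coef <- stats::setNames(rep(0, ncol(X)), colnames(X))
  full_coef[names(coef)] <- coef
  list(coef = full_coef, loglik = ll, rank = rank, flags = flags)
}

gaussian_part <- function(X, y, var_floor = 1e-8) {
  n <- length(y)
  qrX <- qr(X)
  rank <- qrX$rank
  res <- qr.resid(qrX, y)
  coef <- qr.coef(qrX, y)
  coef[is.na(coef)] <- 0
  sigma2 <- max(sum(res^2) / n, var_floor)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  flags <- if (sum(res^2) / n < var_floor) "cont_var_floor" else character(0)
  list(coef = stats::setNames(coef, colnames(X)), loglik = ll, rank = rank,
       sigma2 = sigma2, flags = flags)
}

#' Fit a two-part hurdle model to one gene
#'
#' Discrete part: logistic regression of detection (`y > 0`) on the design.
#' Continuous part: Gaussian linear model of the normalized expression on
#' the design, restricted to cells with `y > 0`. This is the zero-inflation
#' -aware model used for snRNA-seq differential expression. On
#' quasi-complete separation the logistic fit falls back to a small ridge
#' penalty and the fit is flagged; genes with fewer than 3 positive cells
#' skip the continuous part and are flagged untestable on that component. A
#' variance floor keeps the Gaussian log-likelihood finite on degenerate
#' genes.
#'
#' @param y Normalized expression vector (zeros = undetected).
#' @param X Design matrix including an `"(Intercept)"` column. Constant
#'   non-intercept columns are dropped and logged.
#' @param ridge Ridge penalty used on separation (default 1e-2).
#' @param var_floor Continuous-part variance floor (default 1e-8).
#' @return An object of class `hurdle_fit`.
#' @export
fit_hurdle_gene <- function(y, X, ridge = 1e-2, var_floor = 1e-8) {
  stopifnot(is.matrix(X), length(y) == nrow(X),
            "(Intercept)" %in% colnames(X))
  flags <- character(0)
  const <- apply(X, 2, function(col) length(unique(col)) == 1)
  const["(Intercept)" == colnames(X)] <- FALSE
  if (any(const)) {
    flags <- c(flags, paste0("dropped:", colnames(X)[const]))
    X <- X[, !const, drop = FALSE]
  }
  z <- as.numeric(y > 0)
  disc <- logistic_part(X, z, ridge = ridge)
  n_pos <- sum(z)
  cont_testable <- n_pos >= 3
  cont <- NULL
  if (cont_testable) {
    cont <- gaussian_part(X[z > 0, , drop = FALSE], y[z > 0],
                          var_floor = var_floor)
    flags <- c(flags, cont$flags)
  } else {
    flags <- c(flags, "cont_untestable")
  }
  structure(list(
    coef_disc = disc$coef, loglik_disc = disc$loglik,
    rank_disc = disc$rank,
    coef_cont = if (cont_testable) cont$coef else NULL,
    loglik_cont = if (cont_testable) cont$loglik else NA_real_,
    rank_cont = if (cont_testable) cont$rank else 0L,
    sigma2 = if (cont_testable) cont$sigma2 else NA_real_,
    n = length(y), n_pos = n_pos, cont_testable = cont_testable,
    xbar = colMeans(X), terms = colnames(X),
    flags = unique(c(flags, disc$flags))), class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf("<hurdle_fit> n = %d, positives = %d\n", x$n, x$n_pos))
  cat("discrete coef:\n"); print(x$coef_disc)
  if (x$cont_testable) {
    cat("continuous coef:\n"); print(x$coef_cont)
  } else cat("continuous part untestable (< 3 positive cells)\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Hurdle likelihood-ratio test
#'
#' Combines both components: `stat = 2 * (delta loglik_disc) + 2 *
#' (delta loglik_cont)` against a chi-square reference with
#' `df = df_disc + df_cont`, where the continuous degrees of freedom are
#' counted only when the continuous part is testable in both fits.
#'
#' @param fit_full,fit_reduced [fit_hurdle_gene()] results; the reduced
#'   design must nest the full design.
#' @return Two-sided (upper-tail) p-value; attributes `statistic` and `df`.
#' @export
hurdle_lrt <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "hurdle_fit"),
            inherits(fit_reduced, "hurdle_fit"))
  if (fit_full$n != fit_reduced$n ||
      !all(fit_reduced$terms %in% fit_full$terms)) {
    stop("reduced model does not nest the full model")
  }
  df_disc <- fit_full$rank_disc - fit_reduced$rank_disc
  both_cont <- fit_full$cont_testable && fit_reduced$cont_testable
  df_cont <- if (both_cont) fit_full$rank_cont - fit_reduced$rank_cont else 0L
  if (df_disc < 0 || df_cont < 0) stop("models are not nested")
  stat <- 2 * (fit_full$loglik_disc - fit_reduced$loglik_disc)
  if (both_cont) {
    stat <- stat + 2 * (fit_full$loglik_cont - fit_reduced$loglik_cont)
  }
  stat <- max(stat, 0)
  df <- df_disc + df_cont
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(p, statistic = stat, df = df)
}

#' Model-based natural-log fold change
#'
#' `lnFC = m(group = 1) - m(group = 0)` where
#' `m(x) = sigmoid(x' beta_disc) * (x' beta_cont)` is the model's expected
#' (unconditional) normalized expression, evaluated at the covariate means
#' with the group indicator toggled. When the continuous part is
#' untestable, the fold change degrades to the log ratio of detection
#' probabilities and is flagged via the `"disc_only"` attribute.
#'
#' @param fit A [fit_hurdle_gene()] result.
#' @param variable Name of the design column to toggle between 0 and 1.
#' @return Numeric lnFC; attribute `disc_only` marks the degraded case.
#' @export
model_lnfc <- function(fit, variable) {
  stopifnot(inherits(fit, "hurdle_fit"))
  if (!variable %in% fit$terms) {
    # the variable was dropped (constant in the cluster): no contrast
    return(structure(0, disc_only = FALSE))
  }
  x1 <- x0 <- fit$xbar
  x1[variable] <- 1
  x0[variable] <- 0
  p1 <- stats::plogis(sum(x1 * fit$coef_disc[fit$terms]))
  p0 <- stats::plogis(sum(x0 * fit$coef_disc[fit$terms]))
  if (!fit$cont_testable) {
    return(structure(log(pmax(p1, 1e-12) / pmax(p0, 1e-12)),
                     disc_only = TRUE))
  }
  m1 <- p1 * sum(x1 * fit$coef_cont[fit$terms])
  m0 <- p0 * sum(x0 * fit$coef_cont[fit$terms])
  structure(m1 - m0, disc_only = FALSE)
}

# fixed covariate coding: AD/positive/carrier/male = 1
code_variable <- function(x, name = "variable") {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.logical(x)) return(as.numeric(x))
  map <- c("AD" = 1, "control" = 0, "normal" = 0,
           "M" = 1, "male" = 1, "F" = 0, "female" = 0,
           "positive" = 1, "negative" = 0,
           "carrier" = 1, "non-carrier" = 0, "noncarrier" = 0,
           "yes" = 1, "no" = 0)
  x <- as.character(x)
  if (!all(x %in% names(map))) {
    stop("cannot code column `", name, "`: unknown level(s) ",
         paste(setdiff(unique(x), names(map)), collapse = ", "))
  }
  unname(map[x])
}

build_design <- function(cells, variable, covariates) {
  cols <- c(variable, covariates)
  X <- cbind("(Intercept)" = 1,
             vapply(cols, function(nm) code_variable(cells[[nm]], nm),
                    numeric(nrow(cells))))
  colnames(X) <- c("(Intercept)", cols)
  X
}

#' Hurdle-model differential expression for one cluster
#'
#' Fits the two-part hurdle model per eligible gene with the variable of
#' interest plus covariates (full) against covariates only (reduced),
#' tests the variable by the combined likelihood-ratio test, computes the
#' model-based natural-log fold change, and adjusts p-values by
#' Benjamini-Hochberg across the cluster's tested genes. Binary variables
#' are coded 1/0 (AD = 1, male = 1, carrier = 1, positive = 1);
#' quantitative variables enter linearly.
#'
#' @param norm A [normalize_counts()] result.
#' @param cluster_id Cluster to test.
#' @param variable Cell metadata column of interest.
#' @param covariates Character vector of covariate column names.
#' @param group_col,groups Grouping used for eligibility and detection
#'   fractions (defaults: diagnosis AD vs control).
#' @param min_detection Eligibility threshold (default 0.10).
#' @param cdr Include the cellular detection rate (centred fraction of
#'   genes detected per cell) as a covariate in both model parts (default
#'   FALSE). On genome-scale data the CDR absorbs library-size artifacts;
#'   on small gene panels it is itself driven by the differential genes
#'   and conditioning on it can bias null genes, so it is off by default.
#' @param ridge,var_floor Passed to [fit_hurdle_gene()].
#' @return Tibble of class `de_result`: `gene`, `lnfc`, `p`, `q`,
#'   `pct_group1`, `pct_group0`, `tested`, `flags`.
#' @export
run_hurdle_de <- function(norm, cluster_id, variable = "diagnosis",
                          covariates = character(),
                          group_col = "diagnosis",
                          groups = c("AD", "control"),
                          min_detection = 0.10, cdr = FALSE,
                          ridge = 1e-2, var_floor = 1e-8) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (variable %in% covariates) {
    stop("`variable` must not be duplicated in `covariates`")
  }
  genes <- eligible_genes(norm, cluster_id, group_col, groups,
                          min_detection)
  if (length(genes) == 0) {
    warning("no eligible genes in cluster ", cluster_id)
    return(structure(tibble::tibble(
      gene = character(), lnfc = double(), p = double(), q = double(),
      pct_group1 = double(), pct_group0 = double(), tested = logical(),
      flags = character()), class = c("de_result", "tbl_df", "tbl",
                                      "data.frame")))
  }
  in_cl <- which(norm$cells$cluster == cluster_id)
  cells <- norm$cells[in_cl, , drop = FALSE]
  if (cdr) {
    det_rate <- Matrix::colSums(norm$values[, in_cl, drop = FALSE] > 0) /
      nrow(norm$values)
    cells$cdr <- as.numeric(scale(det_rate, scale = FALSE))
    covariates <- c(covariates, "cdr")
  }
  X_full <- build_design(cells, variable, covariates)
  X_red <- X_full[, setdiff(colnames(X_full), variable), drop = FALSE]
  grp <- cells[[group_col]]
  y_mat <- as.matrix(norm$values[genes, in_cl, drop = FALSE])
  i1 <- grp == groups[1]
  i0 <- grp == groups[2]

  rows <- purrr::map(seq_along(genes), function(i) {
    y <- y_mat[i, ]
    fit_f <- fit_hurdle_gene(y, X_full, ridge, var_floor)
    fit_r <- fit_hurdle_gene(y, X_red, ridge, var_floor)
    p_lrt <- tryCatch(as.numeric(hurdle_lrt(fit_f, fit_r)),
                      error = function(e) NA_real_)
    fc <- model_lnfc(fit_f, variable)
    gene_flags <- paste(unique(c(fit_f$flags,
                                 if (isTRUE(attr(fc, "disc_only")))
                                   "disc_only")),
                        collapse = ";")
    tibble::tibble(
      gene = genes[i], lnfc = as.numeric(fc), p = p_lrt,
      pct_group1 = if (any(i1)) mean(y[i1] > 0) else NA_real_,
      pct_group0 = if (any(i0)) mean(y[i0] > 0) else NA_real_,
      tested = !is.na(p_lrt),
      flags = gene_flags)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- NA_real_
  out$q[out$tested] <- stats::p.adjust(out$p[out$tested], method = "BH")
  out <- dplyr::relocate(out, "q", .after = "p")
  class(out) <- c("de_result", class(out))
  attr(out, "cluster_id") <- cluster_id
  attr(out, "variable") <- variable
  out
}

#' Select differentially expressed genes from a hurdle DE table
#'
#' A gene is a DEG iff it is detected in at least `min_pct` of group-1 or
#' group-0 cells, has `q < alpha`, and (for binary variables) has
#' `|lnFC| > min_lnfc`. Direction labels follow the sign of the fold
#' change.
#'
#' @param results A [run_hurdle_de()] table.
#' @param binary Whether the variable of interest is binary (the fold
#'   -change rule applies only then).
#' @param min_pct Detection threshold (default 0.20).
#' @param alpha FDR threshold (default 0.05).
#' @param min_lnfc Absolute natural-log fold-change threshold for binary
#'   variables (default 0.1).
#' @return Tibble: `gene`, `lnfc`, `q`, `direction` ("up"/"down").
#' @export
select_degs <- function(results, binary = TRUE, min_pct = 0.20,
                        alpha = 0.05, min_lnfc = 0.1) {
  res <- dplyr::filter(
    results, .data$tested,
    dplyr::coalesce(.data$pct_group1, 0) >= min_pct |
      dplyr::coalesce(.data$pct_group0, 0) >= min_pct,
    .data$q < alpha)
  if (binary) res <- dplyr::filter(res, abs(.data$lnfc) > min_lnfc)
  dplyr::transmute(res, gene = .data$gene, lnfc = .data$lnfc, q = .data$q,
                   direction = ifelse(.data$lnfc >= 0, "up", "down"))
}
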