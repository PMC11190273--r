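#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hurdle-model fit
#'
#' @param x A [fit_hurdle_gene()] result.
#' @param ... Unused.
#' @return Tibble with one row per (component, term): `component`
#'   ("discrete"/"continuous"), `term`, `estimate`.
#' @export
tidy.hurdle_fit <- function(x, ...) {
  out <- tibble::tibble(component = "discrete",
                        term = names(x$coef_disc),
                        estimate = unname(x$coef_disc))
  if (x$cont_testable) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      component = "continuous", term = names(x$coef_cont),
      estimate = unname(x$coef_cont)))
  }
  out
}

#' One-row summary of a hurdle-model fit
#'
#' @param x A [fit_hurdle_gene()] result.
#' @param ... Unused.
#' @return Tibble: `n`, `n_pos`, `loglik_disc`, `loglik_cont`, `sigma2`,
#'   `cont_testable`, `flags`.
#' @export
glance.hurdle_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_pos = x$n_pos,
                 loglik_disc = x$loglik_disc,
                 loglik_cont = x$loglik_cont, sigma2 = x$sigma2,
                 cont_testable = x$cont_testable,
                 flags = paste(x$flags, collapse = ";"))
}

#' Tidy a random-effects meta-analysis result
#'
#' @param x A [dl_meta()] result.
#' @param ... Unused.
#' @return Tibble: `unit`, `estimate`, `std.error`, `p.value`.
#' @export
tidy.meta_result <- function(x, ...) {
  tibble::tibble(unit = x$unit, estimate = x$beta_re,
                 std.error = x$se_re, p.value = x$p_re)
}

#' Heterogeneity summary of a random-effects meta-analysis
#'
#' @param x A [dl_meta()] result.
#' @param ... Unused.
#' @return Tibble: `k`, `q`, `tau2`, `i2`, `beta_fixed`.
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(k = x$k, q = x$q, tau2 = x$tau2, i2 = x$i2,
                 beta_fixed = x$beta_fixed)
}

#' Summarize a differential-expression table
#'
#' @param x A [run_hurdle_de()] table.
#' @param ... Unused.
#' @return Tibble: `n_genes`, `n_tested`, `n_q05`.
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x), n_tested = sum(x$tested),
                 n_q05 = sum(x$q < 0.05, na.rm = TRUE))
}
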