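# broom-style accessors for fitted refinement objects.

#' Tidy a formation-constant refinement
#'
#' One row per refined log beta, broom conventions: `term`, `estimate`,
#' `std.error`, plus the stoichiometry and detectability columns.
#'
#' @param x A `beta_refinement`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.beta_refinement <- function(x, ...) {
  est <- x$estimates
  tibble(term = est$species, p = est$p, q = est$q, r = est$r,
         estimate = est$log_beta, std.error = est$sigma,
         max_abundance = est$max_abundance, detectable = est$detectable)
}

#' Glance at a formation-constant refinement
#'
#' @param x A `beta_refinement`.
#' @param ... Unused.
#' @return A one-row tibble with fit statistics (Hamilton R-factor and its
#'   limit, residual sum of squares, counts, convergence).
#' @export
glance.beta_refinement <- function(x, ...) {
  tibble(R_H = x$R_H, R_lim = x$R_lim, rss = sum(x$residuals^2),
         n_points = x$n_points, n_par = x$n_par,
         iterations = x$iterations, converged = x$converged)
}
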