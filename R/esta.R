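# Classical Irving-Rossotti / ESTA experimental-data functions.
#
# At a titration point with measured pH and known analytical totals, the
# proton excess bound to ligand is B = T_H - [H] + Kw/[H]. Assuming the
# complexes carry no net protons, B is carried entirely by the free-ligand
# protonation ladder, so the free ligand follows from
#   B = [L] * sum_r r beta_01r [H]^r
# and the formation function is
#   Zbar = (T_L - [L] * sum_r beta_01r [H]^r) / T_M      (beta_010 = 1).
# The deprotonation function compares the measured proton balance with the
# metal-free expectation at the same pH:
#   Qbar = (nbar(pH) * T_L - B) / T_M.
# Points where the inversion gives [L] <= 0 (strong-complexation regime
# where the assumption fails) are masked rather than erroring.

#' Ligand protonation function n-bar
#'
#' Average number of protons bound per ligand not bound to metal, at a
#' given pH: \eqn{\bar n = \sum_r r \beta_{01r} [H]^r / \sum_r \beta_{01r}
#' [H]^r} with \eqn{\beta_{010} = 1}.
#'
#' @param x Either an [eq_model()] (its (0,1,r) ladder is used) or a
#'   numeric vector of cumulative log beta_01r values for r = 1..n.
#' @param pH Numeric vector of pH values.
#' @return Numeric vector of n-bar values, one per pH.
#' @export
#' @examples
#' nbar(c(9.20, 17.88, 19.91), pH = c(2.03, 9.20))
nbar <- function(x, pH) {
  lb <- if (inherits(x, "eq_model")) unname(protonation_log_betas(x)) else x
  vapply(pH, function(p) {
    lt <- lb + seq_along(lb) * (-p)   # log10 of beta_01r * h^r
    t <- 10^(lt - max(lt, 0))         # overflow-safe rescale
    one <- 10^(0 - max(lt, 0))
    sum(seq_along(lb) * t) / (one + sum(t))
  }, numeric(1))
}

# shared Z/Q computation
esta_point_functions <- function(curve, model) {
  lb <- unname(protonation_log_betas(model))
  rr <- seq_along(lb)
  Kw <- 10^(-model$pKw)
  h <- 10^(-curve$pH)
  alpha <- outer(h, rr, function(hh, k) 10^(lb[k]) * hh^k)  # beta_01r h^r
  alpha_sum <- 1 + rowSums(alpha)                           # incl. r = 0
  denom <- rowSums(sweep(alpha, 2, rr, `*`))                # sum r beta h^r
  B <- curve$T_H - h + Kw / h
  L_free <- B / denom
  masked <- !is.finite(L_free) | L_free <= 0
  L_free[masked] <- NA_real_
  nb <- rowSums(sweep(alpha, 2, rr, `*`)) / alpha_sum
  zbar <- (curve$T_L - L_free * alpha_sum) / curve$T_M
  qbar <- (nb * curve$T_L - B) / curve$T_M
  zbar[curve$T_M <= 0] <- NA_real_
  qbar[curve$T_M <= 0] <- NA_real_
  tibble(point = curve$point, pH = curve$pH, pL = -log10(L_free),
         zbar = zbar, qbar = qbar, nbar = nb, masked = masked)
}

#' Metal formation function Z-bar along a titration curve
#'
#' Computes the average number of ligands bound per metal ion at every
#' titration point, by inverting the proton balance for the free-ligand
#' concentration (see Details in the package vignette). Points where the
#' inversion yields a non-positive free-ligand concentration are masked.
#'
#' @param curve A `titration_curve` (needs `pH, T_M, T_L, T_H`).
#' @param model An [eq_model()] supplying the ligand protonation ladder.
#' @return A tibble of class `zq_curve` with columns
#'   `ratio, point, pH, pL, zbar, qbar, nbar, masked`.
#' @export
zbar_curve <- function(curve, model) {
  if (all(curve$T_M <= 0)) abort("Z-bar needs metal in the cell (T_M > 0).")
  out <- esta_point_functions(curve, model)
  out <- tibble(ratio = attr(curve, "ratio") %||% NA_character_, out)
  class(out) <- c("zq_curve", class(out))
  out
}

#' Metal deprotonation function Q-bar along a titration curve
#'
#' Number of protons released per metal ion upon complexation, relative to
#' the metal-free expectation at the same pH:
#' \eqn{\bar Q = (\bar n(pH) T_L - (T_H - [H] + K_w/[H])) / T_M}.
#'
#' @inheritParams zbar_curve
#' @return A tibble of class `zq_curve` (same columns as [zbar_curve()]).
#' @export
qbar_curve <- function(curve, model) {
  if (all(curve$T_M <= 0)) abort("Q-bar needs metal in the cell (T_M > 0).")
  zbar_curve(curve, model)
}

#' Qualitative diagnostics across metal-to-ligand ratios
#'
#' Inspects Z-bar curves from two or more ratios and raises advisory flags:
#' \describe{
#'   \item{ratio_splitting}{the curves for different ratios separate by
#'     more than `threshold` at common pL (protonated or polynuclear
#'     species);}
#'   \item{fan_back}{a curve doubles back in pL at its high-pH end
#'     (hydroxo / mixed-hydroxo or metal-assisted deprotonated species);}
#'   \item{plateau_deviation}{the apparent plateau differs from 1 by more
#'     than `threshold` (mononuclear ML is not the only complex).}
#' }
#' The flags inform the user; they never modify a model.
#'
#' @param zq A list of `zq_curve` tibbles (or one combined tibble with a
#'   `ratio` column) covering at least 2 ratios.
#' @param threshold Flag threshold for splitting and plateau deviation.
#' @return A tibble with columns `flag`, `raised`, `detail`.
#' @export
diagnose <- function(zq, threshold = 0.05) {
  if (is.data.frame(zq)) zq <- split(zq, zq$ratio)
  zq <- lapply(zq, function(d) d[!d$masked & is.finite(d$zbar), ])
  zq <- zq[vapply(zq, nrow, 1L) > 3]
  if (length(zq) < 2) abort("Need Z-bar curves from at least 2 ratios.")

  # ratio splitting: spread between interpolated curves at common pL
  los <- vapply(zq, function(d) min(d$pL), 1); his <- vapply(zq, function(d) max(d$pL), 1)
  lo <- max(los); hi <- min(his)
  split_max <- 0
  if (hi > lo) {
    grid <- seq(lo, hi, length.out = 50)
    mat <- vapply(zq, function(d) {
      o <- order(d$pL)
      approx(d$pL[o], d$zbar[o], xout = grid, ties = mean)$y
    }, numeric(50))
    split_max <- max(apply(mat, 1, function(z) diff(range(z, na.rm = TRUE))),
                     na.rm = TRUE)
  }

  # fan-back: along a base titration pL normally falls monotonically (free
  # ligand rises); hydroxo/deprotonated-complex formation makes the
  # apparent pL turn back up at the high-pH end
  fan <- vapply(zq, function(d) {
    i_min <- which.min(d$pL)
    i_min < nrow(d) && (max(d$pL[i_min:nrow(d)]) - d$pL[i_min]) > 0.1
  }, logical(1))

  # plateau: Z-bar level approached at the saturation (low-pL) end
  plateaus <- vapply(zq, function(d) {
    o <- order(d$pL)
    median(head(d$zbar[o], max(3, round(0.1 * nrow(d)))))
  }, numeric(1))
  plat_dev <- max(abs(plateaus - 1))

  tibble(
    flag = c("ratio_splitting", "fan_back", "plateau_deviation"),
    raised = c(split_max > threshold, any(fan), plat_dev > threshold),
    detail = c(sprintf("max inter-ratio Z-bar spread %.3f", split_max),
               sprintf("pL reversal in %d of %d curves", sum(fan), length(fan)),
               sprintf("max |plateau - 1| = %.3f", plat_dev)))
}
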