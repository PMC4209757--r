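# Core damped-Newton mass-balance solver.
#
# Unknowns are log10 free concentrations of the components (M, L, H).
# For a species i with stoichiometry (p_i, q_i, r_i) and overall constant
# beta_i, its concentration is C_i = 10^(log_beta_i + p_i x_M + q_i x_L +
# r_i x_H). The mass balances are
#   T_M = [M] + sum p_i C_i,   T_L = [L] + sum q_i C_i,
#   T_H = [H] + sum r_i C_i    (hydroxide enters as (0,0,-1), so the
#                               familiar -Kw/[H] term is just a species).
# Residuals are scaled by max(|T|, sum of |term| magnitudes) so that both
# large totals and near-cancelling proton balances converge to machine
# accuracy; after the scaled tolerance is met two polishing Newton steps are
# taken, which in practice drives raw residuals to roundoff.

solver_tol <- 1e-12
solver_max_iter <- 200L

model_matrices <- function(model) {
  sp <- model$species
  list(nu = cbind(p = as.numeric(sp$p), q = as.numeric(sp$q),
                  r = as.numeric(sp$r)),
       logb = sp$log_beta)
}

# default initial guess on log10 scale (design: free = 1e-3 * total,
# floor 1e-15 M; [H] from the sign of T_H)
default_guess <- function(totals, pKw) {
  g <- numeric(3)
  g[1] <- log10(max(1e-3 * totals[1], 1e-15))
  g[2] <- log10(max(1e-3 * totals[2], 1e-15))
  g[3] <- if (totals[3] > 1e-12) {
    log10(totals[3])
  } else if (totals[3] < -1e-12) {
    log10(10^(-pKw) / (-totals[3]))
  } else {
    -7
  }
  g
}

# Solve the mass balances. `fixed_h`: when non-NULL, [H] is clamped to that
# value and only the M/L balances are solved. Components with zero totals
# (and not fixed) are excluded: their free concentration is exactly 0 and
# species involving them are absent.
solve_free <- function(nu, logb, totals, pKw, fixed_h = NULL, x0 = NULL,
                       tol = solver_tol, max_iter = solver_max_iter) {
  active <- c(totals[1] > 0, totals[2] > 0, TRUE)
  if (!is.null(fixed_h)) active[3] <- FALSE
  # species feasible only if every excluded zero-total component is absent
  feasible <- rep(TRUE, length(logb))
  for (k in 1:2) {
    if (!active[k] && totals[k] == 0) feasible <- feasible & nu[, k] == 0
  }
  nu_f <- nu[feasible, , drop = FALSE]
  logb_f <- logb[feasible]

  x <- if (is.null(x0)) default_guess(totals, pKw) else x0
  x[1:2][!active[1:2]] <- -Inf
  if (!is.null(fixed_h)) x[3] <- log10(fixed_h)
  ai <- which(active)
  if (length(ai) == 0) {
    # nothing to solve (e.g. pure water at fixed pH)
    return(list(x = x, conc = species_conc_full(nu, logb, x, feasible),
                residual_scaled = 0, raw_residual = 0, iterations = 0L,
                converged = TRUE, J = NULL, active = ai, scales = NULL,
                feasible = feasible))
  }

  eval_F <- function(x) {
    xs <- ifelse(is.finite(x), x, -500)  # 0 * -Inf guard; 10^-500 == 0
    C <- 10^(logb_f + drop(nu_f %*% xs))
    free <- 10^x
    calc <- free
    calc[!is.finite(calc)] <- 0
    Tcalc <- calc + drop(crossprod(nu_f, C))
    absmag <- calc + drop(crossprod(abs(nu_f), C))
    s <- pmax(abs(totals), absmag, 1e-15)
    list(F = ((Tcalc - totals) / s)[ai], C = C, s = s,
         raw = (Tcalc - totals)[ai])
  }
  jac <- function(x, ev) {
    nA <- nu_f[, ai, drop = FALSE]
    J <- ln10 * (crossprod(nA, nA * ev$C))
    free <- 10^x[ai]
    diag(J) <- diag(J) + ln10 * free
    J / ev$s[ai]
  }

  ev <- eval_F(x)
  fnorm <- max(abs(ev$F))
  it <- 0L
  polish <- 0L
  repeat {
    if (it >= max_iter) break
    it <- it + 1L
    J <- jac(x, ev)
    step <- tryCatch(solve(J, -ev$F), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      step <- -ev$F / pmax(diag(J), 1e-30)  # fallback: scaled gradient-ish
    }
    # cap step length in log units
    m <- max(abs(step))
    if (m > 2) step <- step * (2 / m)
    lambda <- 1
    ok <- FALSE
    for (h in 0:20) {
      xn <- x
      xn[ai] <- x[ai] + lambda * step
      evn <- tryCatch(eval_F(xn), error = function(e) NULL)
      if (!is.null(evn) && all(is.finite(evn$F))) {
        fn <- max(abs(evn$F))
        if (fn < fnorm || fnorm < tol) { ok <- TRUE; break }
      }
      lambda <- lambda / 2
    }
    if (!ok) {
      # accept the most damped finite step anyway to escape flat regions
      if (!is.null(evn) && all(is.finite(evn$F))) {
        x <- xn; ev <- evn; fnorm <- max(abs(evn$F))
      } else break
    } else {
      x <- xn; ev <- evn; fnorm <- fn
    }
    if (fnorm < tol) {
      polish <- polish + 1L
      if (polish >= 3L) break
    }
  }
  converged <- fnorm < tol
  list(x = x, conc = species_conc_full(nu, logb, x, feasible),
       residual_scaled = fnorm, raw_residual = ev$raw,
       iterations = it, converged = converged,
       J = jac(x, ev), active = ai, scales = ev$s, C = ev$C,
       nu_f = nu_f, feasible = feasible)
}

species_conc_full <- function(nu, logb, x, feasible) {
  conc <- numeric(length(logb))
  xx <- x
  xx[!is.finite(xx)] <- -Inf
  e <- logb + drop(nu %*% ifelse(is.finite(xx), xx, 0))
  conc[feasible] <- 10^(e[feasible])
  # zero-total components force zero concentration for species carrying them
  conc[!feasible] <- 0
  conc
}

new_speciation_state <- function(model, sol, totals, implied_T_H = NULL) {
  sp <- model$species
  free <- 10^sol$x
  free[!is.finite(free)] <- 0
  out <- list(
    free = setNames(free, model$components),
    pH = -sol$x[3],
    species = tibble(p = sp$p, q = sp$q, r = sp$r, log_beta = sp$log_beta,
                     species = species_label(sp$p, sp$q, sp$r),
                     conc = sol$conc),
    totals = setNames(totals, c("T_M", "T_L", "T_H")),
    implied_T_H = implied_T_H,
    residual = max(abs(sol$raw_residual)),
    iterations = sol$iterations,
    converged = sol$converged,
    solver = sol)
  class(out) <- "speciation_state"
  out
}

#' @export
print.speciation_state <- function(x, ...) {
  cat(sprintf("<speciation_state> pH = %.4f | converged: %s (%d iter, max raw residual %.2e)\n",
              x$pH, x$converged, x$iterations, x$residual))
  cat(sprintf("  free: [%s] = %.4g, [%s] = %.4g, [%s] = %.4g\n",
              names(x$free)[1], x$free[1], names(x$free)[2], x$free[2],
              names(x$free)[3], x$free[3]))
  print(x$species, n = nrow(x$species))
  invisible(x)
}

#' @export
as_tibble.speciation_state <- function(x, ...) x$species

#' Solve the mass-balance equations at given analytical totals
#'
#' Finds the free concentrations `[M]`, `[L]`, `[H]` satisfying the three
#' mass balances for the analytical (total) concentrations `T_M`, `T_L`,
#' `T_H`, by damped Newton iteration on the log10 free concentrations with
#' an analytic Jacobian. `T_H` counts dissociable protons relative to the
#' fully deprotonated ligand reference and may be negative (excess strong
#' base); hydroxide is the built-in species (0,0,-1).
#'
#' @param model An [eq_model()].
#' @param T_M,T_L,T_H Analytical totals in mol/dm3. `T_M`, `T_L` must be
#'   non-negative; a zero total excludes the component entirely.
#' @param guess Optional initial log10 free-concentration triple.
#' @return A `speciation_state`: free concentrations, a species tibble with
#'   concentrations, convergence diagnostics and the pH.
#' @export
#' @examples
#' m <- example_model("Ni_L1_model1")
#' solve_state(m, T_M = 5e-4, T_L = 1e-3, T_H = 2e-3)
solve_state <- function(model, T_M, T_L, T_H, guess = NULL) {
  stopifnot(inherits(model, "eq_model"))
  if (T_M < 0 || T_L < 0) abort("T_M and T_L must be non-negative.")
  mm <- model_matrices(model)
  totals <- c(T_M, T_L, T_H)
  sol <- solve_free(mm$nu, mm$logb, totals, model$pKw, x0 = guess)
  if (!sol$converged) {
    # restart ladder: alternative proton guesses, then pH grid walk
    for (h0 in c(-7, -3, -10, -1, -12)) {
      g <- default_guess(totals, model$pKw); g[3] <- h0
      sol2 <- solve_free(mm$nu, mm$logb, totals, model$pKw, x0 = g)
      if (sol2$converged) { sol <- sol2; break }
    }
  }
  if (!sol$converged) {
    abort(sprintf(
      "Mass-balance solver failed to converge (max scaled residual %.3e after %d iterations).",
      sol$residual_scaled, sol$iterations), class = "eqspec_solver_error")
  }
  new_speciation_state(model, sol, totals)
}

#' Solve the mass balances at fixed pH
#'
#' Clamps `[H]` to `10^-pH` and solves the two-dimensional mass balance in
#' `[M]` and `[L]`; the proton total implied by the solution is reported in
#' the `implied_T_H` field.
#'
#' @inheritParams solve_state
#' @param pH Fixed pH (0-14), concentration scale.
#' @return A `speciation_state` with `implied_T_H` filled in.
#' @export
solve_at_ph <- function(model, T_M, T_L, pH, guess = NULL) {
  stopifnot(inherits(model, "eq_model"))
  if (pH < 0 || pH > 14) abort("pH must lie within 0-14.")
  if (T_M < 0 || T_L < 0) abort("T_M and T_L must be non-negative.")
  mm <- model_matrices(model)
  h <- 10^(-pH)
  totals <- c(T_M, T_L, NA_real_)
  sol <- solve_free(mm$nu, mm$logb, c(T_M, T_L, 0), model$pKw,
                    fixed_h = h, x0 = guess)
  if (!sol$converged && (T_M > 0 || T_L > 0)) {
    for (shift in c(-3, -8, -1, -12)) {
      g <- default_guess(c(T_M, T_L, 0), model$pKw)
      g[1:2] <- g[1:2] + shift
      sol2 <- solve_free(mm$nu, mm$logb, c(T_M, T_L, 0), model$pKw,
                         fixed_h = h, x0 = g)
      if (sol2$converged) { sol <- sol2; break }
    }
  }
  if (!sol$converged) {
    abort(sprintf("Fixed-pH solver failed to converge at pH %.3f.", pH),
          class = "eqspec_solver_error")
  }
  implied_T_H <- h + sum(model$species$r * sol$conc)
  totals[3] <- implied_T_H
  new_speciation_state(model, sol, totals, implied_T_H = implied_T_H)
}

#' Speciation distribution as a function of pH
#'
#' Solves the equilibrium at every pH of a grid and expresses each species'
#' concentration as a fraction of the total metal (when `T_M > 0`) or of the
#' total ligand (when `T_M = 0`). Free M (or L) is included as its own row,
#' so fractions sum to 1 at every grid point.
#'
#' @inheritParams solve_state
#' @param pH Monotone numeric grid of pH values.
#' @return A tibble of class `speciation_distribution` with columns
#'   `pH, p, q, r, species, fraction` and attributes `basis`, `T_M`, `T_L`.
#' @export
#' @examples
#' d <- speciation_vs_ph(example_model("Ni_L3"), 5.1e-4, 1.01e-3,
#'                       pH = seq(2, 11, by = 0.5))
#' predominant_species(d, 7.4)
speciation_vs_ph <- function(model, T_M, T_L, pH = seq(2, 11, by = 0.1)) {
  stopifnot(inherits(model, "eq_model"))
  if (is.unsorted(pH) && is.unsorted(rev(pH))) {
    abort("pH grid must be monotone.")
  }
  basis <- if (T_M > 0) "metal" else "ligand"
  total <- if (basis == "metal") T_M else T_L
  if (total <= 0) abort("Need a positive metal or ligand total.")
  sp <- model$species
  coef_basis <- if (basis == "metal") sp$p else sp$q
  keep <- coef_basis > 0
  guess <- NULL
  rows <- vector("list", length(pH))
  for (i in seq_along(pH)) {
    st <- tryCatch(
      solve_at_ph(model, T_M, T_L, pH[i], guess = guess),
      eqspec_solver_error = function(e) {
        abort(sprintf("Speciation solve failed at pH %.3f: %s",
                      pH[i], conditionMessage(e)),
              class = "eqspec_solver_error")
      })
    guess <- st$solver$x
    frac_sp <- coef_basis[keep] * st$species$conc[keep] / total
    free_frac <- if (basis == "metal") st$free[1] / total else st$free[2] / total
    rows[[i]] <- tibble(
      pH = pH[i],
      p = c(if (basis == "metal") 1L else 0L, sp$p[keep]),
      q = c(if (basis == "metal") 0L else 1L, sp$q[keep]),
      r = c(0L, sp$r[keep]),
      species = c(if (basis == "metal") "M" else "L",
                  species_label(sp$p[keep], sp$q[keep], sp$r[keep])),
      fraction = c(free_frac, frac_sp))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "basis") <- basis
  attr(out, "T_M") <- T_M
  attr(out, "T_L") <- T_L
  class(out) <- c("speciation_distribution", class(out))
  out
}

#' Predominant species at a pH
#'
#' Returns the stoichiometry holding the largest fraction at the grid point
#' nearest the requested pH. Ties are broken toward the species with the
#' smaller |r| and the choice is reported in the `tie` column.
#'
#' @param distribution A [speciation_vs_ph()] result.
#' @param pH pH at which to look (must lie inside the grid).
#' @return One-row tibble `pH, p, q, r, species, fraction, tie`.
#' @export
predominant_species <- function(distribution, pH) {
  if (!nrow(distribution)) abort("Empty distribution.")
  grid <- unique(distribution$pH)
  if (pH < min(grid) - 1e-9 || pH > max(grid) + 1e-9) {
    abort("pH lies outside the distribution grid.")
  }
  at <- grid[which.min(abs(grid - pH))]
  d <- distribution[distribution$pH == at, ]
  mx <- max(d$fraction)
  cand <- d[d$fraction >= mx - 1e-12, ]
  cand <- cand[order(abs(cand$r)), ]
  tibble(pH = at, p = cand$p[1], q = cand$q[1], r = cand$r[1],
         species = cand$species[1], fraction = cand$fraction[1],
         tie = nrow(cand) > 1)
}
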