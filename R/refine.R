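# Formation-constant refinement.
#
# The observable is the electrode signal (emf in mV by default; pH by
# flag). For trial log beta values the equilibrium is solved at every
# titration point's analytical totals and the calculated observable is
# compared with the measured one. Minimization is Levenberg-Marquardt
# (minpack.lm::nls.lm) with an analytic Jacobian obtained by implicit
# differentiation of the mass balances: at a solution F(x; theta) = 0,
#   dx/dtheta_j = -J_x^{-1} dF/dtheta_j,
#   dF_X/dtheta_j = ln10 * nu_jX * C_j / s_X,
# and d(pH)/dtheta_j = -dx_H/dtheta_j. Parameter standard deviations follow
# the crystallographic convention sigma^2 = diag((J'J)^-1) * RSS/(n-k).

normalise_curves <- function(curves) {
  if (is.data.frame(curves)) curves <- list(curves)
  if (!length(curves)) abort("Need at least one titration curve.")
  curves
}

refinable_index <- function(model) {
  idx <- which(model$species$refine)
  if (!length(idx)) abort("Model has no refinable parameters (refine = TRUE).")
  idx
}

electrode_of <- function(curve, electrode) {
  E0 <- attr(curve, "E0"); s <- attr(curve, "slope")
  if (is.null(E0) || !is.finite(E0)) E0 <- electrode$E0
  if (is.null(s) || !is.finite(s)) s <- electrode$slope
  list(E0 = E0, slope = s)
}

point_weights <- function(curves, weights, sigma_E, sigma_v, electrode,
                          observable) {
  unlist(lapply(curves, function(cv) {
    n <- nrow(cv)
    if (weights == "unit") return(rep(1, n))
    el <- electrode_of(cv, electrode)
    # propagated per-point uncertainty of the observable
    dEdv <- dobs_dv(cv, observable, el)
    sig_obs <- if (observable == "emf") sigma_E else sigma_E / abs(el$slope)
    delta2 <- sig_obs^2 + (dEdv * sigma_v)^2
    1 / pmax(delta2, 1e-12)
  }))
}

# local slope of the observable along the titration (per curve). The
# envelope of the two one-sided differences is used rather than a central
# difference: near an equivalence jump the central stencil smooths the
# slope and would understate the propagated volume-error variance at
# exactly the points where it dominates; a conservative (upper) estimate
# keeps error-propagated weights calibrated.
dobs_dv <- function(curve, observable, el) {
  obs <- observed_vector(curve, observable, el)
  v <- curve$v_cm3
  n <- length(v)
  if (n < 2) return(rep(0, n))
  fwd <- c(diff(obs) / diff(v), NA)
  bwd <- c(NA, diff(obs) / diff(v))
  g <- pmax(abs(fwd), abs(bwd), na.rm = TRUE)
  g
}

observed_vector <- function(curve, observable, el) {
  if (observable == "emf") {
    if ("emf_mV" %in% names(curve) && all(is.finite(curve$emf_mV))) {
      curve$emf_mV
    } else {
      el$E0 - el$slope * curve$pH
    }
  } else {
    curve$pH
  }
}

# Solve every point of every curve at the given log betas, warm-started.
# Returns calculated pH plus, when `derivs`, the sensitivity d(x_H)/d(theta).
calc_observable <- function(curves, model, par, refine_idx, derivs = FALSE,
                            cache = NULL) {
  mm <- model_matrices(model)
  mm$logb[refine_idx] <- par
  k <- length(refine_idx)
  out_pH <- vector("list", length(curves))
  out_dxh <- vector("list", length(curves))
  failures <- 0L
  total_pts <- 0L
  for (ci in seq_along(curves)) {
    cv <- curves[[ci]]
    n <- nrow(cv)
    total_pts <- total_pts + n
    pHs <- numeric(n)
    dxh <- if (derivs) matrix(0, n, k)
    guess <- if (!is.null(cache)) cache[[ci]] else NULL
    for (i in seq_len(n)) {
      x0 <- if (!is.null(guess) && is.matrix(guess)) guess[i, ] else guess
      sol <- solve_free(mm$nu, mm$logb, c(cv$T_M[i], cv$T_L[i], cv$T_H[i]),
                        model$pKw, x0 = x0)
      if (!sol$converged) {
        sol <- solve_free(mm$nu, mm$logb,
                          c(cv$T_M[i], cv$T_L[i], cv$T_H[i]), model$pKw)
      }
      if (!sol$converged) {
        failures <- failures + 1L
        pHs[i] <- NA_real_
        next
      }
      if (!is.matrix(guess)) guess <- sol$x else guess[i, ] <- sol$x
      pHs[i] <- -sol$x[3]
      if (derivs) {
        ai <- sol$active
        hpos <- match(3L, ai)
        if (!is.na(hpos)) {
          # dF/dtheta_j, scaled like the solver residuals
          feas_ref <- refine_idx[refine_idx %in% which(sol$feasible)]
          if (length(feas_ref)) {
            Cj <- sol$conc[feas_ref]
            g <- (t(mm$nu[feas_ref, ai, drop = FALSE]) * ln10) %*%
              diag(Cj, nrow = length(Cj)) / sol$scales[ai]
            dx <- tryCatch(solve(sol$J, -g), error = function(e) NULL)
            if (!is.null(dx)) {
              cols <- match(feas_ref, refine_idx)
              dxh[i, cols] <- dx[hpos, ]
            }
          }
        }
      }
    }
    out_pH[[ci]] <- pHs
    out_dxh[[ci]] <- dxh
  }
  if (failures / total_pts > 0.05) {
    abort(sprintf("Equilibrium solver failed at %d of %d points (> 5%%).",
                  failures, total_pts), class = "eqspec_solver_error")
  }
  list(pH = out_pH, dxh = out_dxh, failures = failures)
}

#' Weighted residual vector for a trial model
#'
#' For every titration point the equilibrium is solved at the point's
#' analytical totals and the residual `sqrt(w) * (observed - calculated)`
#' of the chosen observable is returned. More than 5 percent failed points
#' aborts with an error.
#'
#' @param curves A `titration_curve` or list of them.
#' @param model An [eq_model()] whose current log beta values are used.
#' @param observable `"emf"` (mV, default) or `"pH"`.
#' @param weights `"unit"` or `"propagated"` (inverse propagated variance
#'   from `sigma_E`, `sigma_v`).
#' @param sigma_E,sigma_v Experimental noise levels for the weights.
#' @param electrode Fallback electrode parameters when a curve carries none.
#' @return Numeric residual vector (one element per point).
#' @export
refinement_residuals <- function(curves, model,
                                 observable = c("emf", "pH"),
                                 weights = c("unit", "propagated"),
                                 sigma_E = 0.1, sigma_v = 0.005,
                                 electrode = list(E0 = 400, slope = 59.16)) {
  observable <- match.arg(observable)
  weights <- match.arg(weights)
  curves <- normalise_curves(curves)
  sp <- model$species
  idx <- seq_len(nrow(sp))
  cc <- calc_observable(curves, model, sp$log_beta, idx)
  w <- point_weights(curves, weights, sigma_E, sigma_v, electrode, observable)
  res <- unlist(lapply(seq_along(curves), function(ci) {
    el <- electrode_of(curves[[ci]], electrode)
    obs <- observed_vector(curves[[ci]], observable, el)
    calc <- if (observable == "emf") el$E0 - el$slope * cc$pH[[ci]] else cc$pH[[ci]]
    obs - calc
  }))
  res[is.na(res)] <- 0
  sqrt(w) * res
}

#' Hamilton R-factor
#'
#' \eqn{R = \sqrt{\sum w (obs - calc)^2 / \sum w \, obs^2}}: the normalized
#' weighted residual statistic used to judge refinement quality.
#'
#' @param observed,calculated Equal-length numeric vectors.
#' @param weights Weights (recycled).
#' @return A scalar.
#' @export
#' @examples
#' hamilton_r(c(1, 2, 3), c(1.1, 1.9, 3.0))  # sqrt(0.02/14)
hamilton_r <- function(observed, calculated, weights = 1) {
  stopifnot(length(observed) == length(calculated))
  w <- rep_len(weights, length(observed))
  denom <- sum(w * observed^2)
  if (denom == 0) abort("All-zero observed vector: R-factor undefined.")
  sqrt(sum(w * (observed - calculated)^2) / denom)
}

#' Limiting R-factor expected from experimental errors alone
#'
#' Replaces each residual by the first-order propagated experimental
#' uncertainty of the observable, \eqn{\delta_i = \sqrt{\sigma_E^2 +
#' (dE/dv)_i^2 \sigma_v^2}} (divided by the Nernst slope for the pH
#' observable), and evaluates the Hamilton R expression with them. A
#' refinement whose R-factor approaches this limit explains the data to
#' within experimental error.
#'
#' @inheritParams refinement_residuals
#' @return A scalar.
#' @export
r_limit <- function(curves, observable = c("emf", "pH"),
                    weights = c("unit", "propagated"),
                    sigma_E = 0.1, sigma_v = 0.005,
                    electrode = list(E0 = 400, slope = 59.16)) {
  observable <- match.arg(observable)
  weights <- match.arg(weights)
  curves <- normalise_curves(curves)
  w <- point_weights(curves, weights, sigma_E, sigma_v, electrode, observable)
  obs <- unlist(lapply(curves, function(cv) {
    observed_vector(cv, observable, electrode_of(cv, electrode))
  }))
  delta <- unlist(lapply(curves, function(cv) {
    el <- electrode_of(cv, electrode)
    g <- dobs_dv(cv, observable, el)
    sig_obs <- if (observable == "emf") sigma_E else sigma_E / abs(el$slope)
    sqrt(sig_obs^2 + (g * sigma_v)^2)
  }))
  sqrt(sum(w * delta^2) / sum(w * obs^2))
}

#' Refine formation constants by Levenberg-Marquardt least squares
#'
#' Adjusts the log beta values flagged `refine = TRUE` in the model to
#' minimize the weighted residual sum of squares of the chosen observable
#' over one or more titration curves. Reports per-parameter standard
#' deviations (scaled by sqrt of the reduced chi-square), the parameter
#' correlation matrix, the Hamilton R-factor and its experimental limit.
#' Refined species whose maximal abundance anywhere in the data falls below
#' 2 percent of the relevant total are flagged as not supported by the data.
#'
#' @inheritParams refinement_residuals
#' @param start Optional numeric vector of starting log beta values for the
#'   refinable species (in model order); defaults to the model's values.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `beta_refinement`; see [tidy()] and
#'   [glance()] methods, and [write_report()].
#' @export
#' @examples
#' \donttest{
#' cs <- generate_study_dataset("L1", metal = FALSE, noise = FALSE)
#' m <- example_model("L1_protonation")
#' m$species$log_beta[m$species$refine] <-
#'   m$species$log_beta[m$species$refine] + c(0.5, -0.5, 0.5)
#' refine_constants(cs, m)
#' }
refine_constants <- function(curves, model,
                             observable = c("emf", "pH"),
                             weights = c("unit", "propagated"),
                             sigma_E = 0.1, sigma_v = 0.005,
                             electrode = list(E0 = 400, slope = 59.16),
                             start = NULL, max_iter = 100) {
  observable <- match.arg(observable)
  weights <- match.arg(weights)
  curves <- normalise_curves(curves)
  ridx <- refinable_index(model)
  par0 <- start %||% model$species$log_beta[ridx]
  if (length(par0) != length(ridx) || any(!is.finite(par0))) {
    abort("start must supply one finite value per refinable species.")
  }
  els <- lapply(curves, electrode_of, electrode = electrode)
  obs_list <- lapply(seq_along(curves), function(ci) {
    observed_vector(curves[[ci]], observable, els[[ci]])
  })
  obs <- unlist(obs_list)
  w <- if (weights == "unit") {
    rep(1, length(obs))
  } else {
    # propagated weights from the slope of the *model-calculated* curve at
    # the starting values: using noisy data slopes would correlate the
    # weights with the measurement errors themselves and bias the fit
    cc0 <- calc_observable(curves, model, par0, ridx)
    unlist(lapply(seq_along(curves), function(ci) {
      cv <- curves[[ci]]
      calc0 <- if (observable == "emf") {
        els[[ci]]$E0 - els[[ci]]$slope * cc0$pH[[ci]]
      } else cc0$pH[[ci]]
      pseudo <- cv
      if (observable == "emf") pseudo$emf_mV <- calc0 else pseudo$pH <- calc0
      g <- dobs_dv(pseudo, observable, els[[ci]])
      sig_obs <- if (observable == "emf") sigma_E
        else sigma_E / abs(els[[ci]]$slope)
      1 / pmax(sig_obs^2 + (g * sigma_v)^2, 1e-12)
    }))
  }
  sw <- sqrt(w)

  eval_full <- function(par, derivs) {
    calc_observable(curves, model, par, ridx, derivs = derivs)
  }
  calc_vec <- function(cc) {
    unlist(lapply(seq_along(curves), function(ci) {
      if (observable == "emf") {
        els[[ci]]$E0 - els[[ci]]$slope * cc$pH[[ci]]
      } else cc$pH[[ci]]
    }))
  }
  fn <- function(par) {
    cc <- eval_full(par, derivs = FALSE)
    res <- obs - calc_vec(cc)
    res[is.na(res)] <- 0
    sw * res
  }
  jac <- function(par) {
    cc <- eval_full(par, derivs = TRUE)
    J <- do.call(rbind, lapply(seq_along(curves), function(ci) {
      dpH <- -cc$dxh[[ci]]                       # dpH/dtheta = -dx_H/dtheta
      if (observable == "emf") els[[ci]]$slope * dpH else -dpH
    }))
    # residual = obs - calc; d(residual)/dtheta = -d(calc)/dtheta
    # calc(emf) = E0 - s*pH  => dcalc = -s*dpH  => dres = s*dpH
    # (signs folded above: J rows are already d(res)/d(theta))
    sw * J
  }
  lmres <- minpack.lm::nls.lm(
    par = par0, fn = fn, jac = jac,
    control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                         ftol = 1e-12, ptol = 1e-12))
  par_hat <- lmres$par
  res <- fn(par_hat)
  Jh <- jac(par_hat)
  n <- length(res); k <- length(par_hat)
  rss <- sum(res^2)
  dof <- max(n - k, 1)
  s2 <- rss / dof
  XtX <- crossprod(Jh)
  sv <- svd(XtX)
  bad <- sv$d < max(sv$d) * 1e-10
  dinv <- ifelse(bad, 0, 1 / sv$d)
  cov <- sv$v %*% (dinv * t(sv$u)) * s2
  sig <- sqrt(pmax(diag(cov), 0))
  if (any(bad)) {
    involved <- rowSums(abs(sv$u[, bad, drop = FALSE])) > 0.1
    sig[involved] <- Inf
    warn(paste0("Singular normal matrix: parameter(s) ",
                paste(which(involved), collapse = ", "),
                " are undetermined by the data."))
  }
  cor <- if (all(is.finite(sig)) && all(sig > 0)) {
    cov / tcrossprod(sig)
  } else matrix(NA_real_, k, k)

  fitted_model <- model
  fitted_model$species$log_beta[ridx] <- par_hat
  fitted_model$species$sigma[ridx] <- sig

  # detectability: maximal share of the relevant total across all points
  maxshare <- rep(0, k)
  mm <- model_matrices(fitted_model)
  for (ci in seq_along(curves)) {
    cv <- curves[[ci]]
    guess <- NULL
    for (i in seq_len(nrow(cv))) {
      sol <- solve_free(mm$nu, mm$logb, c(cv$T_M[i], cv$T_L[i], cv$T_H[i]),
                        fitted_model$pKw, x0 = guess)
      if (!sol$converged) next
      guess <- sol$x
      sp <- fitted_model$species
      for (j in seq_len(k)) {
        jj <- ridx[j]
        share <- if (sp$p[jj] > 0 && cv$T_M[i] > 0) {
          sp$p[jj] * sol$conc[jj] / cv$T_M[i]
        } else if (sp$q[jj] > 0 && cv$T_L[i] > 0) {
          sp$q[jj] * sol$conc[jj] / cv$T_L[i]
        } else 0
        if (is.finite(share)) maxshare[j] <- max(maxshare[j], share)
      }
    }
  }

  sp <- fitted_model$species[ridx, ]
  estimates <- tibble(
    p = sp$p, q = sp$q, r = sp$r,
    species = species_label(sp$p, sp$q, sp$r),
    log_beta = par_hat, sigma = sig,
    max_abundance = maxshare, detectable = maxshare >= 0.02)

  calc <- obs - res / ifelse(sw > 0, sw, 1)
  out <- list(
    model = fitted_model, estimates = estimates, fitted = calc,
    R_H = hamilton_r(obs, calc, w),
    R_lim = r_limit(curves, observable, weights, sigma_E, sigma_v, electrode),
    iterations = lmres$niter,
    converged = lmres$info %in% 1:4,
    info = lmres$info, message = lmres$message,
    residuals = res, rss_trace = lmres$rsstrace,
    correlation = cor, covariance = cov,
    n_points = n, n_par = k,
    observable = observable, weights = weights,
    obs = obs, start = par0)
  class(out) <- "beta_refinement"
  out
}

#' @export
print.beta_refinement <- function(x, ...) {
  cat(sprintf("<beta_refinement> %d parameter(s), %d points | R_H = %.4f, R_lim = %.4f | %s in %d iter\n",
              x$n_par, x$n_points, x$R_H, x$R_lim,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  %2d %2d %3d  %9.4f (%.4f)%s\n", est$p[i], est$q[i],
                est$r[i], est$log_beta[i], est$sigma[i],
                if (!est$detectable[i]) "  [not supported by data]" else ""))
  }
  invisible(x)
}

#' Compare competing refinement results on identical data
#'
#' Tabulates R-factors, parameter dispersions and convergence for models
#' refined on the same titration data, flagging parameters with sigma above
#' 0.2 log units. No automatic winner is declared: model choice combines
#' these statistics with chemical knowledge (e.g. curve splitting at low
#' pH favouring an MLH species).
#'
#' @param results List of `beta_refinement` objects fitted to the same data.
#' @param labels Optional model labels.
#' @param sigma_flag Threshold for flagging a poorly determined parameter.
#' @return A tibble with one row per model.
#' @export
compare_models <- function(results, labels = NULL, sigma_flag = 0.2) {
  stopifnot(length(results) >= 2)
  ns <- vapply(results, function(r) r$n_points, 1)
  if (length(unique(ns)) != 1) abort("Results were refined on different datasets.")
  ob <- results[[1]]$obs
  for (r in results[-1]) {
    if (max(abs(r$obs - ob)) > 1e-9) {
      abort("Results were refined on different datasets (observations differ).")
    }
  }
  labels <- labels %||% paste0("model", seq_along(results))
  tibble(
    model = labels,
    R_H = vapply(results, function(r) r$R_H, 1),
    R_lim = vapply(results, function(r) r$R_lim, 1),
    n_par = vapply(results, function(r) r$n_par, 1),
    converged = vapply(results, function(r) r$converged, TRUE),
    max_sigma = vapply(results, function(r) max(r$estimates$sigma), 1),
    flagged = vapply(results, function(r) {
      bad <- r$estimates$sigma > sigma_flag | !r$estimates$detectable
      if (any(bad)) paste(r$estimates$species[bad], collapse = ", ") else ""
    }, ""))
}
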