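# Glass-electrode titration simulator.
#
# A protocol holds the initial cell contents (moles of metal, ligand and
# strong acid in v0 cm3), the titrant, the electrode parameters and the
# noise model. Simulation marches down the burette: at each cumulative
# volume v the dilution-corrected totals are
#   T_X(v) = n_X(v) / ((v0 + v)/1000)
# and the equilibrium is solved with a warm start from the previous point;
# pH = -log10[H] and emf = E0 - s * pH.

#' Define a titration protocol
#'
#' @param v0 Initial volume in cm3.
#' @param n_M,n_L Initial moles of metal and ligand in the cell.
#' @param n_acid Initial moles of strong acid (negative = strong base).
#' @param titrant_conc Titrant concentration in mol/dm3.
#' @param titrant `"base"` (NaOH, removes protons) or `"acid"`.
#' @param increment Burette step in cm3.
#' @param v_max Optional total titrant volume; when `NULL` the simulation
#'   runs until `pH_stop` is crossed.
#' @param pH_stop pH at which an open-ended base titration stops.
#' @param E0 Electrode intercept in mV (in-situ calibrated).
#' @param slope Nernst slope in mV per pH unit (59.16 at 25 degrees C).
#' @param sigma_E,sigma_v Gaussian noise levels for emf (mV) and delivered
#'   volume (cm3), used by [add_noise()] and for R-factor limits.
#' @param carbonate_frac Fraction of the nominal hydroxide converted to
#'   carbonate (2 OH- -> CO3^2-); only supported for ligand-free cells and
#'   used to simulate contaminated titrant for Gran diagnostics.
#' @return A `titration_protocol` object.
#' @export
titration_protocol <- function(v0 = 25, n_M = 0, n_L = 0, n_acid = 0,
                               titrant_conc = 0.1,
                               titrant = c("base", "acid"),
                               increment = 0.05, v_max = NULL,
                               pH_stop = 11.05,
                               E0 = 400, slope = 59.16,
                               sigma_E = 0.1, sigma_v = 0.005,
                               carbonate_frac = 0) {
  titrant <- match.arg(titrant)
  if (v0 <= 0) abort("v0 must be positive.")
  if (increment <= 0) abort("increment must be positive.")
  if (slope == 0) abort("Electrode slope must be nonzero.")
  if (sigma_E < 0 || sigma_v < 0) abort("Noise sigmas must be >= 0.")
  structure(list(v0 = v0, n_M = n_M, n_L = n_L, n_acid = n_acid,
                 titrant_conc = titrant_conc, titrant = titrant,
                 increment = increment, v_max = v_max, pH_stop = pH_stop,
                 E0 = E0, slope = slope, sigma_E = sigma_E,
                 sigma_v = sigma_v, carbonate_frac = carbonate_frac),
            class = "titration_protocol")
}

# carbonate protonation constants used when simulating contaminated NaOH
# (conditional values at 25 C, I = 0.15 M)
carbonate_model <- function(pKw) {
  eq_model(eq_species(0, 1, 1:2, c(9.9, 16.0)), components = c("M", "CO3", "H"),
           pKw = pKw)
}

protocol_totals <- function(protocol, v) {
  V <- (protocol$v0 + v) / 1000
  f <- protocol$carbonate_frac
  sgn <- if (protocol$titrant == "base") -1 else 1
  # contaminated base delivers (1-f) OH and f/2 CO3 per nominal OH
  oh_scale <- if (protocol$titrant == "base" && f > 0) (1 - f) else 1
  n_H <- protocol$n_acid + sgn * oh_scale * protocol$titrant_conc * v / 1000
  n_L <- protocol$n_L
  if (f > 0 && protocol$titrant == "base") {
    n_L <- n_L + (f / 2) * protocol$titrant_conc * v / 1000
  }
  c(T_M = protocol$n_M / V, T_L = n_L / V, T_H = n_H / V)
}

#' Simulate a noise-free glass-electrode titration
#'
#' Marches the burette in `increment` steps, computing dilution-corrected
#' totals and solving the equilibrium at every point (warm-started from the
#' previous one). The curve records cumulative volume, emf, pH and the
#' totals per point. Noise is added separately by [add_noise()].
#'
#' @param model An [eq_model()]. For carbonate-contamination runs
#'   (`carbonate_frac > 0`) the cell must be ligand-free and an internal
#'   carbonate model is substituted.
#' @param protocol A [titration_protocol()].
#' @return A `titration_curve` tibble with columns
#'   `point, v_cm3, emf_mV, pH, T_M, T_L, T_H` and protocol attributes.
#' @export
#' @examples
#' m <- example_model("L1_protonation")
#' pr <- titration_protocol(n_L = 1e-3 * 25e-3,
#'                          n_acid = (0.01 + 3e-3) * 25e-3)
#' tc <- simulate_titration(m, pr)
simulate_titration <- function(model, protocol) {
  stopifnot(inherits(model, "eq_model"), inherits(protocol, "titration_protocol"))
  if (protocol$carbonate_frac > 0) {
    if (protocol$n_L != 0) {
      abort("Carbonate-contamination simulation requires a ligand-free cell.")
    }
    model <- carbonate_model(model$pKw)
  }
  open_ended <- is.null(protocol$v_max)
  v_cap <- if (open_ended) {
    # enough base to neutralise everything plus ~[OH]=2.5e-3 excess
    need <- abs(protocol$n_acid) + 3 * protocol$n_L + 2 * protocol$n_M +
      2.5e-3 * (protocol$v0 + 50) / 1000
    min(1000 * need / protocol$titrant_conc * 1.5 + 1, 100)
  } else protocol$v_max
  vols <- seq(0, v_cap, by = protocol$increment)
  n <- length(vols)
  pH <- numeric(n); TT <- matrix(NA_real_, n, 3)
  guess <- NULL
  last <- n
  for (i in seq_len(n)) {
    tot <- protocol_totals(protocol, vols[i])
    st <- tryCatch(
      solve_state(model, tot[1], tot[2], tot[3], guess = guess),
      eqspec_solver_error = function(e) {
        abort(sprintf("Titration solve failed at v = %.3f cm3: %s",
                      vols[i], conditionMessage(e)),
              class = "eqspec_solver_error")
      })
    guess <- st$solver$x
    pH[i] <- st$pH
    TT[i, ] <- tot
    if (open_ended && protocol$titrant == "base" && pH[i] >= protocol$pH_stop) {
      last <- i
      break
    }
  }
  idx <- seq_len(last)
  out <- tibble(point = idx, v_cm3 = vols[idx],
                emf_mV = protocol$E0 - protocol$slope * pH[idx],
                pH = pH[idx],
                T_M = TT[idx, 1], T_L = TT[idx, 2], T_H = TT[idx, 3])
  attr(out, "E0") <- protocol$E0
  attr(out, "slope") <- protocol$slope
  attr(out, "v0") <- protocol$v0
  attr(out, "protocol") <- protocol
  attr(out, "seed") <- NA_real_
  class(out) <- c("titration_curve", class(out))
  out
}

#' Add Gaussian measurement noise to a titration curve
#'
#' Adds independent Gaussian noise to the emf readings and to the
#' *delivered* titrant volumes. A volume error means the burette delivered
#' `v + e` while `v` was recorded: the emf is therefore re-evaluated at the
#' true delivered volume (an exact re-solve when `model` is supplied,
#' otherwise a monotone spline interpolation of the clean curve) while the
#' recorded volumes and the totals computed from them stay nominal —
#' exactly the inconsistency a real burette error creates. The pH column
#' is recomputed from the noisy emf through the electrode equation.
#'
#' @param curve A noise-free `titration_curve`.
#' @param sigma_E,sigma_v Noise standard deviations (mV, cm3); default to
#'   the protocol values carried by the curve.
#' @param seed Optional integer seed for reproducibility.
#' @param model Optional [eq_model()]: when given, the emf at the perturbed
#'   volume is computed by an exact equilibrium solve.
#' @return A `titration_curve` with noise applied and the seed recorded.
#' @export
add_noise <- function(curve, sigma_E = NULL, sigma_v = NULL, seed = NULL,
                      model = NULL) {
  pr <- attr(curve, "protocol")
  sigma_E <- sigma_E %||% (pr$sigma_E %||% 0.1)
  sigma_v <- sigma_v %||% (pr$sigma_v %||% 0.005)
  if (sigma_E < 0 || sigma_v < 0) abort("Noise sigmas must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(curve)
  out <- curve
  emf <- curve$emf_mV
  if (sigma_v > 0) {
    dv <- rnorm(n, 0, sigma_v)
    v_true <- pmax(curve$v_cm3 + dv, 0)
    if (!is.null(model) && !is.null(pr)) {
      guess <- NULL
      for (i in seq_len(n)) {
        tot <- protocol_totals(pr, v_true[i])
        st <- solve_state(model, tot[1], tot[2], tot[3], guess = guess)
        guess <- st$solver$x
        emf[i] <- pr$E0 - pr$slope * st$pH
      }
    } else {
      sf <- stats::splinefun(curve$v_cm3, curve$emf_mV, method = "monoH.FC")
      emf <- sf(v_true)
    }
  }
  if (sigma_E > 0) emf <- emf + rnorm(n, 0, sigma_E)
  out$emf_mV <- emf
  E0 <- attr(curve, "E0"); s <- attr(curve, "slope")
  if (!is.null(E0) && is.finite(E0) && !is.null(s)) out$pH <- (E0 - emf) / s
  attr(out, "seed") <- seed %||% NA_real_
  out
}

#' Generate a synthetic study dataset for one ligand system
#'
#' Emulates a typical potentiometric study design: 25 degrees C, I = 0.15 M
#' NaCl, pH window 2-11, total metal 5e-4 mol/dm3 at metal:ligand ratios
#' 1:1, 1:2 and 1:3, with the bundled model-1 constants as ground truth and
#' default electrode noise. With `metal = FALSE` a single metal-free curve
#' (T_L = 1e-3) is produced from the protonation block instead.
#'
#' @param ligand `"L1"`, `"L2"` or `"L3"`.
#' @param ratios Ligand:metal ratios (default 1:1 to 1:3).
#' @param T_M Initial total metal concentration, mol/dm3.
#' @param metal Simulate the Ni(II) system (`TRUE`) or the metal-free
#'   protonation titration (`FALSE`).
#' @param noise Add Gaussian noise? Zero-noise curves are used for
#'   round-trip refinement checks.
#' @param seed Integer seed; curve i uses `seed + i`.
#' @param dir Optional directory: curves are written as CSV with a
#'   ground-truth JSON sidecar (generating constants and seed).
#' @return A list of `titration_curve` tibbles, invisibly carrying the
#'   ground-truth model as attribute `truth`.
#' @export
generate_study_dataset <- function(ligand = c("L1", "L2", "L3"),
                                   ratios = c(1, 2, 3), T_M = 5e-4,
                                   metal = TRUE, noise = TRUE, seed = 1,
                                   dir = NULL) {
  ligand <- match.arg(ligand)
  model_name <- if (!metal) {
    paste0(ligand, "_protonation")
  } else if (ligand == "L3") "Ni_L3" else paste0("Ni_", ligand, "_model1")
  model <- example_model(model_name)
  v0 <- 25
  make_protocol <- function(T_L0, T_M0) {
    titration_protocol(
      v0 = v0, n_M = T_M0 * v0 / 1000, n_L = T_L0 * v0 / 1000,
      n_acid = (0.01 + 3 * T_L0) * v0 / 1000)
  }
  if (!metal) {
    protos <- list(make_protocol(1e-3, 0))
    labels <- "metal-free"
  } else {
    protos <- lapply(ratios, function(rr) make_protocol(rr * T_M, T_M))
    labels <- paste0("1:", ratios)
  }
  curves <- vector("list", length(protos))
  for (i in seq_along(protos)) {
    cv <- simulate_titration(model, protos[[i]])
    if (noise) cv <- add_noise(cv, seed = seed + i, model = model)
    attr(cv, "ratio") <- labels[i]
    curves[[i]] <- cv
  }
  names(curves) <- labels
  attr(curves, "truth") <- model
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sp <- model$species
    jsonlite::write_json(
      list(ligand = ligand, model = model_name, seed = seed, T_M = T_M,
           metal = metal, ratios = if (metal) ratios else numeric(),
           truth = data.frame(p = sp$p, q = sp$q, r = sp$r,
                              logbeta = sp$log_beta)),
      file.path(dir, paste0(ligand, "_truth.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (i in seq_along(curves)) {
      write_titration(curves[[i]],
                      file.path(dir, sprintf("%s_curve%d.csv", ligand, i)))
    }
  }
  curves
}

#' Calibrate electrode intercept and slope from a strong-acid region
#'
#' Fits emf against -log10[H] over the strong-acid region of an acid-base
#' titration (computed pH < 3.5, where [H] follows from the strong-acid
#' total and Kw alone), returning the in-situ intercept E0 and the response
#' slope.
#'
#' @param curve A `titration_curve` from a strong acid-base titration.
#' @param pKw Water autoionization exponent.
#' @param pH_max Upper limit of the acid region used for the fit.
#' @return A list with elements `E0`, `slope`, `n` and the `lm` fit.
#' @export
calibrate_electrode <- function(curve, pKw = 13.73, pH_max = 3.5) {
  T_H <- curve$T_H
  h <- (T_H + sqrt(T_H^2 + 4 * 10^(-pKw))) / 2
  pch <- -log10(h)
  use <- pch < pH_max
  if (sum(use) < 4) abort("Fewer than 4 usable strong-acid points (pH < 3.5).")
  if (sd(curve$emf_mV[use]) < 1e-9) abort("Flat emf series; cannot calibrate.")
  fit <- lm(curve$emf_mV[use] ~ pch[use])
  slope <- -unname(coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < 1) {
    abort("Degenerate calibration: fitted slope is ~0.")
  }
  list(E0 = unname(coef(fit)[1]), slope = slope, n = sum(use), fit = fit)
}

#' Gran linearization, endpoint estimate and carbonate flag
#'
#' Computes the acid-side Gran function G(v) = (v0+v) * 10^(-pH)
#' (proportional to the classical (v0+v) * 10^(emf/s)) over the strong-acid
#' branch and extrapolates the fitted line to G = 0 to estimate the
#' equivalence volume. When enough alkaline points exist, the base-side
#' function (v0+v) * 10^(pH - pKw) gives a second endpoint; carbonate
#' contamination of the titrant is flagged when the two disagree by more
#' than 1 percent, the classical Gran consistency check.
#'
#' @param curve A `titration_curve` from a strong acid vs base titration.
#' @param v0 Initial volume; taken from the curve attributes when `NULL`.
#' @param pKw Water autoionization exponent.
#' @return A list: `gran` tibble (`v_cm3`, `G`, `side`), `v_eq_acid`,
#'   `v_eq_base` (NA when not determinable) and `carbonate_flag`.
#' @export
gran_check <- function(curve, v0 = NULL, pKw = 13.73) {
  if (!nrow(curve)) abort("Empty titration curve.")
  v0 <- v0 %||% attr(curve, "v0")
  if (is.null(v0) || !is.finite(v0)) abort("Initial volume v0 is unknown.")
  v <- curve$v_cm3
  acid <- curve$pH < 3.5
  base <- curve$pH > 10.3
  if (sum(acid) < 4) abort("No usable linear acid-side Gran region.")
  G_a <- (v0 + v[acid]) * 10^(-curve$pH[acid])
  fa <- lm(G_a ~ v[acid])
  v_eq_acid <- -unname(coef(fa)[1] / coef(fa)[2])
  v_eq_base <- NA_real_
  if (sum(base) >= 4) {
    G_b <- (v0 + v[base]) * 10^(curve$pH[base] - pKw)
    fb <- lm(G_b ~ v[base])
    v_eq_base <- -unname(coef(fb)[1] / coef(fb)[2])
  }
  flag <- is.finite(v_eq_base) &&
    abs(v_eq_base - v_eq_acid) / abs(v_eq_acid) > 0.01
  gran <- rbind(
    tibble(v_cm3 = v[acid], G = G_a, side = "acid"),
    if (sum(base) >= 4) tibble(v_cm3 = v[base],
                               G = (v0 + v[base]) * 10^(curve$pH[base] - pKw),
                               side = "base"))
  list(gran = gran, v_eq_acid = v_eq_acid, v_eq_base = v_eq_base,
       carbonate_flag = flag)
}
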