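#' Define an equilibrium species
#'
#' A species \eqn{M_pL_qH_r} is characterised by its stoichiometric
#' coefficients with respect to the free metal ion (p), free ligand (q) and
#' proton (r), together with the decadic logarithm of its overall formation
#' constant \eqn{\beta_{pqr} = [M_pL_qH_r] / ([M]^p [L]^q [H]^r)}.
#' Negative r denotes proton loss (amide deprotonation or hydroxo species).
#'
#' @param p,q,r Integer stoichiometric coefficients; r may be negative.
#' @param log_beta Decadic log of the overall formation constant
#'   (concentration basis, conditional at the working ionic strength).
#' @param sigma Optional standard deviation of `log_beta`.
#' @param refine Logical: is `log_beta` adjustable during refinement?
#' @return A one-row tibble.
#' @export
#' @examples
#' eq_species(1, 1, -2, -10.92)
eq_species <- function(p, q, r, log_beta, sigma = NA_real_, refine = FALSE) {
  n <- max(length(p), length(q), length(r), length(log_beta))
  p <- rep_len(p, n); q <- rep_len(q, n); r <- rep_len(r, n)
  log_beta <- rep_len(log_beta, n)
  if (any(p != round(p) | q != round(q) | r != round(r))) {
    abort("Stoichiometric coefficients p, q, r must be integers.")
  }
  tibble(p = as.integer(p), q = as.integer(q), r = as.integer(r),
         log_beta = as.numeric(log_beta),
         sigma = rep_len(as.numeric(sigma), n),
         refine = rep_len(as.logical(refine), n))
}

#' Construct a multicomponent equilibrium model
#'
#' Bundles a species list with the water autoionization constant and the
#' conditions the constants refer to. Hydroxide is represented internally as
#' the species (0, 0, -1) with `log_beta = -pKw`; it is added automatically
#' when absent, so models never need separate OH bookkeeping. The free
#' components M, L and H themselves are implicit with `log_beta = 0`.
#'
#' No activity-coefficient corrections are applied: all constants are
#' conditional at the stated ionic strength and temperature, and pH means
#' \eqn{-\log_{10}[H^+]} on the concentration scale.
#'
#' @param species A tibble as built by [eq_species()] (rows may be
#'   concatenated with `rbind`/`dplyr::bind_rows`).
#' @param components Length-3 character labels for metal, ligand, proton.
#' @param pKw Water autoionization exponent; default 13.73
#'   (25 degrees C, I = 0.15 mol/dm3 NaCl).
#' @param temperature Temperature in degrees C.
#' @param ionic_strength Ionic strength in mol/dm3.
#' @return An object of class `eq_model`.
#' @export
#' @examples
#' m <- eq_model(eq_species(0, 1, 1:3, c(9.20, 17.88, 19.91)))
#' compute_pka(m)
eq_model <- function(species, components = c("M", "L", "H"), pKw = 13.73,
                     temperature = 25, ionic_strength = 0.15) {
  stopifnot(is.data.frame(species), length(components) == 3)
  species <- as_tibble(species)
  need <- c("p", "q", "r", "log_beta")
  if (!all(need %in% names(species))) {
    abort(paste0("species must have columns ", paste(need, collapse = ", ")))
  }
  if (is.null(species$sigma)) species$sigma <- NA_real_
  if (is.null(species$refine)) species$refine <- FALSE
  species <- species[c("p", "q", "r", "log_beta", "sigma", "refine")]
  if (!is.numeric(pKw) || length(pKw) != 1 || pKw <= 0) {
    abort("pKw must be a single positive number.")
  }
  bad <- species$p == 0 & species$q == 0 & species$r == 0
  if (any(bad)) abort("Species (0,0,0) is not allowed.")
  key <- paste(species$p, species$q, species$r)
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate species (p,q,r): ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  free <- species$p + species$q + abs(species$r) == 1 &
    (species$p == 1 | species$q == 1 | species$r == 1)
  if (any(free)) {
    abort("Free components (1,0,0), (0,1,0), (0,0,1) are implicit; do not list them.")
  }
  # hydroxide as (0,0,-1) with log_beta = -pKw
  ohi <- which(species$p == 0 & species$q == 0 & species$r == -1L)
  if (length(ohi) == 0) {
    species <- rbind(species, eq_species(0, 0, -1, -pKw))
  } else if (abs(species$log_beta[ohi] + pKw) > 1e-9) {
    abort("Hydroxide species (0,0,-1) must have log_beta = -pKw.")
  }
  structure(
    list(components = as.character(components), species = species, pKw = pKw,
         temperature = temperature, ionic_strength = ionic_strength),
    class = "eq_model")
}

#' @export
print.eq_model <- function(x, ...) {
  cat("<eq_model> components:", paste(x$components, collapse = ", "),
      sprintf("| pKw = %.2f | %g degC | I = %g M\n",
              x$pKw, x$temperature, x$ionic_strength))
  sp <- x$species
  sp$species <- species_label(sp$p, sp$q, sp$r)
  print(as_tibble(sp), n = nrow(sp))
  invisible(x)
}

#' Human-readable species labels
#'
#' Builds conventional labels such as `"ML"`, `"MLH-2"`, `"LH3"`, `"OH"`
#' from stoichiometric coefficients.
#'
#' @param p,q,r Integer stoichiometric coefficients.
#' @return Character vector.
#' @export
species_label <- function(p, q, r) {
  lab <- function(pp, qq, rr) {
    if (pp == 0 && qq == 0 && rr == -1) return("OH")
    if (pp == 0 && qq == 0) return(if (rr == 1) "H" else paste0("H", rr))
    s <- ""
    if (pp > 0) s <- paste0(s, "M", if (pp > 1) pp else "")
    if (qq > 0) s <- paste0(s, "L", if (qq > 1) qq else "")
    if (rr != 0) s <- paste0(s, "H", if (rr != 1) rr else "")
    if (s == "") s <- paste0("(", pp, ",", qq, ",", rr, ")")
    s
  }
  mapply(lab, p, q, r, USE.NAMES = FALSE)
}

# ordered cumulative protonation log betas (0,1,1)..(0,1,n); errors on gaps
protonation_log_betas <- function(model) {
  sp <- model$species
  prot <- sp[sp$p == 0 & sp$q == 1 & sp$r >= 1, ]
  if (nrow(prot) == 0) abort("Model contains no protonation species (0,1,r).")
  prot <- prot[order(prot$r), ]
  expected <- seq_len(max(prot$r))
  missing <- setdiff(expected, prot$r)
  if (length(missing)) {
    abort(paste0("Gap in protonation sequence: missing species (0,1,",
                 paste(missing, collapse = "), (0,1,"), ")."))
  }
  setNames(prot$log_beta, paste0("logb01", prot$r))
}

#' Stepwise ligand pKa values from cumulative protonation constants
#'
#' With cumulative constants \eqn{\log\beta_{01r}} for the species
#' \eqn{LH_r}, the stepwise constants are
#' \eqn{pK_{a1} = \log\beta_{011}} and
#' \eqn{pK_{ak} = \log\beta_{01k} - \log\beta_{01(k-1)}}.
#' Note the numbering: pKa1 is the *most basic* site (first proton onto the
#' bare ligand), so pKa values come out in decreasing order for a typical
#' poly(amino)amido ligand.
#'
#' @param model An [eq_model()] containing consecutive protonation species
#'   (0,1,1) ... (0,1,n).
#' @return A tibble with columns `step` and `pka`.
#' @export
#' @examples
#' compute_pka(example_model("L1_protonation"))
compute_pka <- function(model) {
  lb <- protonation_log_betas(model)
  tibble(step = seq_along(lb), pka = diff(c(0, unname(lb))))
}

#' Bundled example equilibrium models
#'
#' Returns one of the packaged model fixtures for the Ni(II) /
#' poly(amino)amido ligand systems (ligands L1-L3), read from the JSON files
#' under `inst/extdata/models`. Protonation-only variants carry the ligand
#' protonation block; the metal variants add the Ni(II) species of the
#' corresponding refinement model.
#'
#' @param name One of `"L1_protonation"`, `"L2_protonation"`,
#'   `"L3_protonation"`, `"Ni_L1_model1"`, `"Ni_L1_model2"`,
#'   `"Ni_L2_model1"`, `"Ni_L2_model2"`, `"Ni_L3"`.
#' @return An [eq_model()].
#' @export
example_model <- function(name) {
  path <- system.file("extdata", "models", paste0(name, ".json"),
                      package = "eqspec")
  if (path == "") {
    abort(paste0("Unknown example model '", name, "'."))
  }
  read_model(path, quiet = TRUE)
}
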