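# Reduced blood-plasma equilibrium model.
#
# Convention of large plasma-speciation programs: the free concentrations
# of the metal ions are FIXED inputs (the protein pools buffer the free
# ion), pH is fixed (7.4), and only the low-molecular-mass (lmm) ligand
# mass balances are solved. Because every complex involves exactly one
# ligand type, each ligand balance is an independent monotone equation in
# its own free concentration:
#   T_j = l * (1 + sum_r beta_01r h^r) + sum_cplx q beta m^p h^r l^q
# solved by 1-D Newton on log10 l (closed form when all q = 1).
#
# The plasma mobilizing index of a drug ligand for metal M is
#   pmi(M, c) = lmm_M(drug total = c) / lmm_M(0),
# where lmm_M counts all metal-containing lmm complexes, the drug's
# included.

#' Construct a plasma model specification
#'
#' @param metals A data frame with columns `metal` and `free_conc`
#'   (mol/dm3, fixed free-ion concentrations).
#' @param ligands A list; each element a list with `id`, `total` (mol/dm3)
#'   and `species`, a data frame with columns `metal` (`""` or `NA` for
#'   protonation species), `p`, `q`, `r`, `logbeta`.
#' @param drug A list like a ligand entry but without `total` (the drug
#'   total is scanned over `grid`).
#' @param pH Fixed plasma pH.
#' @param grid Strictly increasing total drug concentrations (mol/dm3).
#' @param pKw Water autoionization exponent.
#' @return An object of class `plasma_spec`.
#' @export
plasma_spec <- function(metals, ligands, drug, pH = 7.4,
                        grid = 10^seq(-6, -2.5, length.out = 15),
                        pKw = 13.73) {
  metals <- as_tibble(metals)
  stopifnot(all(c("metal", "free_conc") %in% names(metals)))
  if (any(metals$free_conc <= 0)) abort("Free metal concentrations must be > 0.")
  if (any(diff(grid) <= 0)) abort("Drug concentration grid must be strictly increasing.")
  norm_lig <- function(lg, need_total = TRUE) {
    stopifnot(!is.null(lg$id), !is.null(lg$species))
    if (need_total && (is.null(lg$total) || lg$total < 0)) {
      abort(paste0("Ligand ", lg$id, " needs a non-negative total."))
    }
    sp <- as_tibble(as.data.frame(lg$species))
    if (is.null(sp$metal)) sp$metal <- NA_character_
    sp$metal[sp$metal %in% c("", "none")] <- NA_character_
    stopifnot(all(c("p", "q", "r", "logbeta") %in% names(sp)))
    if (any(is.na(sp$metal) & sp$p != 0)) {
      abort(paste0("Ligand ", lg$id, ": species with p > 0 must name a metal."))
    }
    unknown <- setdiff(stats::na.omit(unique(sp$metal)), metals$metal)
    if (length(unknown)) {
      abort(paste0("Ligand ", lg$id, " references unknown metal(s): ",
                   paste(unknown, collapse = ", ")))
    }
    if (any(sp$q < 1)) abort(paste0("Ligand ", lg$id, ": species need q >= 1."))
    lg$species <- sp
    lg
  }
  ligands <- lapply(ligands, norm_lig)
  drug <- norm_lig(drug, need_total = FALSE)
  structure(list(metals = metals, ligands = ligands, drug = drug,
                 pH = pH, grid = grid, pKw = pKw),
            class = "plasma_spec")
}

# solve one ligand's free concentration at fixed h and fixed free metals
solve_ligand_free <- function(lig, total, h, mfree) {
  if (total <= 0) return(0)
  sp <- lig$species
  m <- ifelse(is.na(sp$metal), 1, mfree[sp$metal])
  # binding factor terms: coefficient of l^q in the mass balance is
  # q * beta * m^p * h^r summed within each q
  kterm <- sp$q * 10^(sp$logbeta + sp$p * log10(m) + sp$r * log10(h))
  qs <- sp$q
  if (all(qs == 1)) return(total / (1 + sum(kterm)))
  f <- function(l) l * (1 + sum(kterm[qs == 1])) +
    sum(kterm[qs > 1] * l^qs[qs > 1]) - total
  # monotone in l: bisection on log10 l
  lo <- log10(total) - 25; hi <- log10(total)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(10^mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-14) break
  }
  10^((lo + hi) / 2)
}

#' Solve the plasma model at one drug total concentration
#'
#' Holds the free metal-ion concentrations and pH fixed, solves every
#' ligand mass balance (endogenous ligands and the drug) for the free
#' ligand concentration, and sums the metal-containing low-molecular-mass
#' complexes per metal.
#'
#' @param spec A [plasma_spec()].
#' @param drug_total Total drug-ligand concentration (mol/dm3); 0 gives the
#'   normal-plasma baseline.
#' @return A tibble with one row per metal: `metal`, `free_conc`,
#'   `lmm_total` and `drug_bound` (metal in drug complexes only).
#' @export
solve_plasma <- function(spec, drug_total = 0) {
  stopifnot(inherits(spec, "plasma_spec"))
  if (drug_total < 0) abort("drug_total must be >= 0.")
  h <- 10^(-spec$pH)
  mfree <- setNames(spec$metals$free_conc, spec$metals$metal)
  all_ligs <- c(spec$ligands,
                if (drug_total > 0) {
                  d <- spec$drug; d$total <- drug_total; list(d)
                })
  lmm <- setNames(numeric(nrow(spec$metals)), spec$metals$metal)
  drug_bound <- lmm
  for (li in seq_along(all_ligs)) {
    lg <- all_ligs[[li]]
    l <- solve_ligand_free(lg, lg$total, h, mfree)
    sp <- lg$species
    is_cplx <- !is.na(sp$metal)
    if (!any(is_cplx) || l == 0) next
    m <- mfree[sp$metal[is_cplx]]
    conc <- sp$p[is_cplx] *
      10^(sp$logbeta[is_cplx] + sp$p[is_cplx] * log10(m) +
            sp$r[is_cplx] * log10(h) + sp$q[is_cplx] * log10(l))
    contrib <- tapply(conc, sp$metal[is_cplx], sum)
    lmm[names(contrib)] <- lmm[names(contrib)] + contrib
    if (li > length(spec$ligands)) {
      drug_bound[names(contrib)] <- drug_bound[names(contrib)] + contrib
    }
  }
  tibble(metal = spec$metals$metal, free_conc = spec$metals$free_conc,
         lmm_total = unname(lmm), drug_bound = unname(drug_bound))
}

#' Plasma mobilizing index curve
#'
#' Computes pmi(metal, c) = lmm(c) / lmm(0) for every metal over the drug
#' concentration grid. pmi = 1 means the drug does not change the
#' low-molecular-mass speciation of that metal.
#'
#' @param spec A [plasma_spec()].
#' @return A tibble of class `pmi_curve` with columns
#'   `metal, drug_total, log10_drug, pmi, log10_pmi`.
#' @export
pmi_curve <- function(spec) {
  base <- solve_plasma(spec, 0)
  if (any(base$lmm_total <= 0)) {
    abort(paste0("Baseline lmm total is zero for metal(s): ",
                 paste(base$metal[base$lmm_total <= 0], collapse = ", ")))
  }
  rows <- lapply(spec$grid, function(cc) {
    s <- solve_plasma(spec, cc)
    tibble(metal = s$metal, drug_total = cc, log10_drug = log10(cc),
           pmi = s$lmm_total / base$lmm_total,
           log10_pmi = log10(s$lmm_total / base$lmm_total))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "baseline") <- base
  class(out) <- c("pmi_curve", class(out))
  out
}

#' Selectivity factor between two metals
#'
#' Ratio pmi(metal1, c) / pmi(metal2, c) at a drug total concentration
#' inside the grid (log-linear interpolation between grid points).
#'
#' @param pmi A [pmi_curve()] result.
#' @param metal1,metal2 Metal identifiers present on the curve.
#' @param drug_total Concentration at which to evaluate (mol/dm3).
#' @return A scalar ratio.
#' @export
selectivity <- function(pmi, metal1, metal2, drug_total) {
  for (m in c(metal1, metal2)) {
    if (!m %in% pmi$metal) abort(paste0("Metal not on the pmi curve: ", m))
  }
  g <- sort(unique(pmi$drug_total))
  if (drug_total < min(g) - 1e-15 || drug_total > max(g) * (1 + 1e-12)) {
    abort("drug_total lies outside the pmi grid.")
  }
  val <- function(m) {
    d <- pmi[pmi$metal == m, ]
    10^approx(d$log10_drug, d$log10_pmi, xout = log10(drug_total),
              ties = mean)$y
  }
  val(metal1) / val(metal2)
}

#' Read a plasma model specification from JSON
#'
#' Schema: `{metals: [{id, free_conc}], ligands: [{id, total, species:
#' [{metal, p, q, r, logbeta}]}], drug: {id, species: [...]}, pH, grid,
#' pKw}`.
#'
#' @param path Path to a plasma JSON file.
#' @return A [plasma_spec()].
#' @export
read_plasma_spec <- function(path) {
  if (!file.exists(path)) abort(paste0("No such plasma file: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  metals <- tibble(metal = raw$metals$id, free_conc = raw$metals$free_conc)
  mk <- function(row) list(id = row$id, total = row$total, species = row$species)
  ligands <- lapply(seq_len(nrow(raw$ligands)), function(i) {
    list(id = raw$ligands$id[i], total = raw$ligands$total[i],
         species = raw$ligands$species[[i]])
  })
  drug <- list(id = raw$drug$id, species = raw$drug$species)
  plasma_spec(metals, ligands, drug,
              pH = raw$pH %||% 7.4,
              grid = raw$grid %||% 10^seq(-6, -2.5, length.out = 15),
              pKw = raw$pKw %||% 13.73)
}

#' Bundled synthetic plasma model fixture
#'
#' A clearly synthetic, desk-scale stand-in for a full blood-plasma
#' equilibrium database: four metals (Cu, Ni, Zn, Ca) with fixed free-ion
#' concentrations in the ratios free Ca : Ni = 1e15 and Zn : Ni = 1e9, and
#' about a dozen endogenous low-molecular-mass ligands (amino acids,
#' citrate-, lactate-, carbonate- and phosphate-like entries) with
#' order-of-magnitude plausible constants. The drug entry carries the
#' refined Ni(II) constants of the pyridine-dicarboxamide ligand L3
#' together with synthetic Cu/Zn/Ca constants. Suitable for qualitative
#' ordering and property tests only, not for absolute pmi values.
#'
#' @return A [plasma_spec()].
#' @export
example_plasma_spec <- function() {
  read_plasma_spec(system.file("extdata", "plasma",
                               "plasma_synthetic.json", package = "eqspec"))
}
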