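test_that("identity and pure-water limits are exact", {
  st <- solve_state(water_model, T_M = 1e-3, T_L = 0, T_H = 0)
  expect_equal(unname(st$free[1]), 1e-3)
  expect_equal(unname(st$free[3]), 10^(-13.73 / 2), tolerance = 1e-9)
  oh <- st$species$conc[st$species$r == -1]
  expect_equal(oh, unname(st$free[3]), tolerance = 1e-9)  # [H] = [OH]
})

test_that("half-protonation of a monoprotic ligand lands at pH = pKa", {
  # T_H such that half the ligand is protonated
  T_L <- 1e-3
  T_H <- 10^-9.2 - 10^(-13.73 + 9.2) + T_L / 2
  st <- solve_state(monoprotic_model, 0, T_L, T_H)
  lh <- st$species$conc[st$species$q == 1 & st$species$r == 1]
  expect_equal(lh / unname(st$free[2]), 1, tolerance = 1e-3)
  expect_equal(st$pH, 9.20, tolerance = 1e-3)
})

test_that("Newton solver agrees with the nested-bisection oracle to 6 s.f.", {
  cases <- list(
    list(model = monoprotic_model, T = c(0, 1e-3, 5e-4)),
    list(model = ml_model, T = c(5e-4, 1e-3, 2e-4)),
    list(model = eq_model(rbind(eq_species(0, 1, 1, 9.0),
                                eq_species(1, 1, -1, -2.0))),
         T = c(3e-4, 6e-4, -1e-4)),
    list(model = eq_model(rbind(eq_species(0, 1, 1:2, c(9.2, 17.9)))),
         T = c(0, 8e-4, 1.2e-3)))
  for (cs in cases) {
    st <- solve_state(cs$model, cs$T[1], cs$T[2], cs$T[3])
    orc <- oracle_solve(cs$model, cs$T[1], cs$T[2], cs$T[3])
    for (k in 1:3) {
      if (orc[k] > 0) {
        expect_equal(unname(st$free[k]), orc[k], tolerance = 5e-7)
      } else {
        expect_equal(unname(st$free[k]), 0)
      }
    }
  }
})

test_that("mass-balance residuals of converged states are at conservation level", {
  check_state <- function(st) {
    sp <- st$species
    tot_calc <- c(
      sum(sp$p * sp$conc) + st$free[1],
      sum(sp$q * sp$conc) + st$free[2],
      sum(sp$r * sp$conc) + st$free[3])
    for (k in 1:3) {
      Tk <- unname(st$totals[k])
      res <- abs(unname(tot_calc[k]) - Tk)
      if (Tk != 0) {
        expect_lt(res, 1e-10 * abs(Tk))
      } else {
        expect_lt(res, 1e-16)
      }
    }
  }
  grid <- expand.grid(T_M = c(0, 3e-4, 1e-3), T_H = c(-5e-4, 0, 2e-3))
  for (i in seq_len(nrow(grid))) {
    check_state(solve_state(example_model("Ni_L1_model1"),
                            grid$T_M[i], 1e-3, grid$T_H[i]))
  }
  check_state(solve_state(example_model("Ni_L3"), 5.1e-4, 1.01e-3, 3e-3))
})

test_that("dimensional rescaling symmetry holds exactly", {
  # concentrations in units scaled by lambda: totals scale by lambda and
  # each log beta shifts by (1 - p - q - r) * log10(lambda); all fractions
  # are invariant and free concentrations scale by lambda
  lam <- 10
  m <- example_model("Ni_L1_model1")
  sp <- m$species
  sp2 <- sp
  sp2$log_beta <- sp$log_beta + (1 - sp$p - sp$q - sp$r) * log10(lam)
  oh <- sp2$p == 0 & sp2$q == 0 & sp2$r == -1
  m2 <- eq_model(sp2[!oh, ], pKw = -sp2$log_beta[oh])
  st1 <- solve_state(m, 5e-4, 1e-3, 2e-3)
  st2 <- solve_state(m2, lam * 5e-4, lam * 1e-3, lam * 2e-3)
  expect_equal(unname(st2$free), unname(lam * st1$free), tolerance = 1e-9)
  expect_equal(st2$species$conc / (lam * 5e-4),
               st1$species$conc / 5e-4, tolerance = 1e-9)
})

test_that("fixed-pH solves report the implied proton total", {
  st <- solve_at_ph(example_model("Ni_L3"), 5.1e-4, 1.01e-3, 7.4)
  expect_true(st$converged)
  # re-solving with the implied T_H reproduces the pH
  st2 <- solve_state(example_model("Ni_L3"), 5.1e-4, 1.01e-3, st$implied_T_H)
  expect_equal(st2$pH, 7.4, tolerance = 1e-8)
  # empty cell: only water equilibrium
  st0 <- solve_at_ph(water_model, 0, 0, 5)
  expect_equal(unname(st0$free[3]), 1e-5)
  expect_error(solve_at_ph(water_model, 0, 0, 15), "0-14")
})

test_that("LH2 and LH3 are equal at the pKa3 half-point", {
  st <- solve_at_ph(example_model("L1_protonation"), 0, 1e-3, 2.03)
  lh2 <- st$species$conc[st$species$r == 2 & st$species$q == 1]
  lh3 <- st$species$conc[st$species$r == 3 & st$species$q == 1]
  expect_equal(lh2 / lh3, 1, tolerance = 1e-3)
})

test_that("distribution fractions are normalised and match n-bar", {
  d <- speciation_vs_ph(example_model("L1_protonation"), 0, 1e-3,
                        pH = seq(2, 11, by = 0.5))
  sums <- tapply(d$fraction, d$pH, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # fraction-weighted mean proton number equals the protonation function
  mean_r <- tapply(d$fraction * d$r, d$pH, sum)
  nb <- nbar(example_model("L1_protonation"), as.numeric(names(mean_r)))
  expect_equal(as.numeric(mean_r), nb, tolerance = 1e-8)
})

test_that("predominant species selection and tie-breaking behave", {
  d3 <- speciation_vs_ph(example_model("Ni_L3"), 5.1e-4, 1.01e-3,
                         pH = seq(2, 11, by = 0.2))
  top <- predominant_species(d3, 7.4)
  expect_equal(c(top$p, top$q, top$r), c(1, 1, -2))
  # metal-free strongly acidic point: fully protonated ligand
  dl <- speciation_vs_ph(example_model("L1_protonation"), 0, 1e-3,
                         pH = seq(1.2, 4, by = 0.1))
  expect_equal(predominant_species(dl, 1.5)$r, 3)
  # single-species model
  dm <- speciation_vs_ph(monoprotic_model, 0, 1e-3, pH = c(4, 5))
  expect_equal(predominant_species(dm, 4)$species, "LH")
  expect_error(predominant_species(dm[0, ], 4), "Empty")
  expect_error(predominant_species(dm, 9), "outside")
})
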