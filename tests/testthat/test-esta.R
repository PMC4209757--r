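test_that("n-bar has the right limits, half-points and monotonicity", {
  lb <- c(9.20, 17.88, 19.91)
  expect_lt(nbar(lb, 12.5), 0.01)       # far above pKa1: no protons bound
  expect_gt(nbar(lb, 0), 2.99)          # far below pKa3: fully protonated
  expect_equal(nbar(lb, 2.03), 2.5, tolerance = 0.01)
  # closed-form three-term partition at pH 9.20
  h <- 10^-9.2
  t1 <- 10^9.20 * h; t2 <- 10^17.88 * h^2; t3 <- 10^19.91 * h^3
  expect_equal(nbar(lb, 9.20), (t1 + 2 * t2 + 3 * t3) / (1 + t1 + t2 + t3))
  expect_equal(nbar(lb, 9.20), 0.6968, tolerance = 1e-3)
  # monotone non-increasing, bounded by the number of steps
  grid <- seq(0, 14, by = 0.05)
  nb <- nbar(example_model("L1_protonation"), grid)
  expect_true(all(diff(nb) <= 1e-12))
  expect_true(all(nb >= 0 & nb <= 3))
})

test_that("Z-bar and Q-bar vanish without complexation", {
  m <- eq_model(eq_species(0, 1, 1:3, c(9.20, 17.88, 19.91)))
  pr <- titration_protocol(n_M = 5e-4 * 0.025, n_L = 1e-3 * 0.025,
                           n_acid = (0.01 + 3e-3) * 0.025, increment = 0.1)
  cv <- simulate_titration(m, pr)
  zq <- zbar_curve(cv, m)
  ok <- !zq$masked
  expect_true(any(ok))
  expect_lt(max(abs(zq$zbar[ok])), 1e-6)
  expect_lt(max(abs(zq$qbar[ok])), 1e-6)
})

test_that("a single strong ML complex plateaus at Z-bar = 1", {
  pr <- titration_protocol(n_M = 5e-4 * 0.025, n_L = 5e-4 * 0.025,
                           n_acid = (0.01 + 1.5e-3) * 0.025, increment = 0.05,
                           pH_stop = 10)
  cv <- simulate_titration(ml_model, pr)
  zq <- zbar_curve(cv, ml_model)
  ok <- !zq$masked
  low_pl <- zq[ok & zq$pL < quantile(zq$pL[ok], 0.1), ]
  expect_equal(median(low_pl$zbar), 1, tolerance = 0.02)
  # cross-check against the true speciation state: Z-bar equals
  # sum q [complexes] / T_M for complexes carrying no protons
  i <- which(ok)[sum(ok) %/% 2]
  st <- solve_state(ml_model, cv$T_M[i], cv$T_L[i], cv$T_H[i])
  z_true <- sum(st$species$q[st$species$p > 0] *
                  st$species$conc[st$species$p > 0]) / cv$T_M[i]
  expect_equal(zq$zbar[i], z_true, tolerance = 1e-6)
})

test_that("Q-bar counts protons released by MLH-2 formation", {
  m <- eq_model(rbind(eq_species(0, 1, 1:3, c(9.20, 17.88, 19.91)),
                      eq_species(1, 1, -2, 2)))  # very strong MLH-2
  st <- solve_at_ph(m, 1e-3, 1e-3, 8)
  frac <- st$species$conc[st$species$p == 1] / 1e-3
  expect_gt(frac, 0.999)  # fully complexed
  cv <- tibble::tibble(point = 1, v_cm3 = 0, pH = 8,
                       T_M = 1e-3, T_L = 1e-3, T_H = st$implied_T_H)
  zq <- qbar_curve(cv, m)
  expect_equal(zq$qbar, nbar(m, 8) + 2, tolerance = 1e-3)
})

test_that("Ni(II)-L1 synthetic data shows the diagnostic curve features", {
  zq <- lapply(l1_curves_clean, zbar_curve, model = l1_model)
  d <- diagnose(zq)
  expect_true(d$raised[d$flag == "ratio_splitting"])
  expect_true(d$raised[d$flag == "plateau_deviation"])  # does not level at 1
  expect_true(d$raised[d$flag == "fan_back"])
  # Q-bar is ~0 before complexation starts and rises thereafter
  z1 <- zq[[1]]
  early <- z1$qbar[z1$pH < 4.2 & !z1$masked]
  expect_lt(max(abs(early)), 0.05)
  expect_gt(max(z1$qbar[!z1$masked]), 1)
})

test_that("an ML-only system raises no diagnostic flags", {
  mk <- function(ratio) {
    pr <- titration_protocol(n_M = 5e-4 * 0.025, n_L = ratio * 5e-4 * 0.025,
                             n_acid = (0.01 + ratio * 1.5e-3) * 0.025,
                             increment = 0.05, pH_stop = 9.5)
    cv <- simulate_titration(ml_model, pr)
    attr(cv, "ratio") <- paste0("1:", ratio)
    zbar_curve(cv, ml_model)
  }
  d <- diagnose(list(mk(1), mk(2)))
  expect_false(any(d$raised))
  # adding an MLH species splits the curves at low pH
  mlh <- eq_model(rbind(eq_species(0, 1, 1, 9.0),
                        eq_species(1, 1, 0, 12.0),
                        eq_species(1, 1, 1, 16.5)))
  mk2 <- function(ratio) {
    pr <- titration_protocol(n_M = 5e-4 * 0.025, n_L = ratio * 5e-4 * 0.025,
                             n_acid = (0.01 + ratio * 1.5e-3) * 0.025,
                             increment = 0.05, pH_stop = 9.5)
    cv <- simulate_titration(mlh, pr)
    attr(cv, "ratio") <- paste0("1:", ratio)
    zbar_curve(cv, mlh)
  }
  d2 <- diagnose(list(mk2(1), mk2(2)))
  expect_true(d2$raised[d2$flag == "ratio_splitting"])
})

test_that("diagnose requires at least two ratios", {
  zq <- zbar_curve(l1_curves_clean[[1]], l1_model)
  expect_error(diagnose(list(zq)), "2 ratios")
})
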