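test_that("strong-acid limit and buffer midpoint are reproduced", {
  pr <- titration_protocol(n_acid = 1e-3 * 25 / 1000, v_max = 0.1,
                           increment = 0.05)
  sa <- simulate_titration(water_model, pr)
  expect_equal(sa$pH[1], 3.000, tolerance = 1e-3)
  # monoprotic ligand half-neutralised: buffer midpoint at pKa
  nl <- 1e-3 * 25 / 1000
  prb <- titration_protocol(n_L = nl, n_acid = nl, v_max = 0.25,
                            increment = 0.025)
  tc <- simulate_titration(monoprotic_model, prb)
  mid <- tc[abs(tc$v_cm3 - 0.125) < 1e-9, ]  # half the protons removed
  expect_equal(mid$pH, 9.20, tolerance = 0.01)
})

test_that("pH increases strictly along base titrations of every bundled model", {
  for (nm in c("Ni_L1_model1", "Ni_L2_model1", "Ni_L3")) {
    lig <- sub("Ni_(L[0-9]).*", "\\1", nm)
    cs <- generate_study_dataset(lig, ratios = 2, noise = FALSE)
    expect_true(all(diff(cs[[1]]$pH) > 0), label = nm)
    expect_lte(min(cs[[1]]$pH), 2.05)
    expect_gte(max(cs[[1]]$pH), 10.95)
  }
})

test_that("dilution bookkeeping is exact", {
  cv <- l1_curves_clean[[2]]
  pr <- attr(cv, "protocol")
  for (col in c("T_M", "T_L")) {
    n_run <- cv[[col]] * (pr$v0 + cv$v_cm3) / 1000
    n_expect <- if (col == "T_M") pr$n_M else pr$n_L
    expect_true(all(abs(n_run - n_expect) < 1e-12))
  }
  n_H <- cv$T_H * (pr$v0 + cv$v_cm3) / 1000
  expect_true(all(abs(n_H - (pr$n_acid - pr$titrant_conc * cv$v_cm3 / 1000))
                  < 1e-12))
})

test_that("noise model is reproducible, unbiased in scale, and plausibly normal", {
  cv <- strong_acid_curve
  expect_identical(add_noise(cv, 0, 0)$emf_mV, cv$emf_mV)
  n1 <- add_noise(cv, seed = 11)
  n2 <- add_noise(cv, seed = 11)
  expect_identical(n1$emf_mV, n2$emf_mV)
  # Monte-Carlo: sd of emf noise close to sigma_E (volume noise off)
  res <- unlist(lapply(1:8, function(s) {
    add_noise(cv, sigma_E = 0.1, sigma_v = 0, seed = 100 + s)$emf_mV -
      cv$emf_mV
  }))
  expect_gt(length(res), 500)
  expect_equal(sd(res), 0.1, tolerance = 0.15)
  # residuals about the clean curve pass a normality sanity check
  expect_gt(stats::shapiro.test(res[seq_len(1000)])$p.value, 0.001)
})

test_that("electrode calibration recovers the generating parameters", {
  cal <- calibrate_electrode(strong_acid_curve)
  expect_equal(cal$E0, 400, tolerance = 0.1)
  expect_equal(cal$slope, 59.16, tolerance = 0.05)
  # noisy: recovered values scatter within a few bootstrap sigmas
  cals <- sapply(1:20, function(s) {
    cc <- add_noise(strong_acid_curve, sigma_E = 0.1, sigma_v = 0, seed = s)
    unlist(calibrate_electrode(cc)[c("E0", "slope")])
  })
  expect_lt(abs(mean(cals["E0", ]) - 400), 3 * sd(cals["E0", ]))
  expect_lt(abs(mean(cals["slope", ]) - 59.16), 3 * sd(cals["slope", ]))
  # flat emf series is degenerate
  flat <- strong_acid_curve
  flat$emf_mV <- rep(250, nrow(flat))
  expect_error(calibrate_electrode(flat), "Flat|Degenerate|slope")
})

test_that("Gran endpoints match stoichiometry and flag carbonate", {
  g <- gran_check(strong_acid_curve)
  v_true <- 2.5e-4 / 0.1 * 1000
  expect_equal(g$v_eq_acid, v_true, tolerance = 0.002)
  expect_false(g$carbonate_flag)
  # 2 % carbonate in the titrant shifts the base-side endpoint
  prc <- titration_protocol(n_acid = 2.5e-4, increment = 0.02,
                            carbonate_frac = 0.02)
  gc <- gran_check(simulate_titration(water_model, prc))
  expect_true(gc$carbonate_flag)
  expect_error(gran_check(strong_acid_curve[0, ]), "Empty")
})

test_that("study datasets are seeded deterministically with ground truth sidecar", {
  dir <- withr::local_tempdir()
  a <- generate_study_dataset("L3", ratios = c(1, 2), seed = 5, dir = dir)
  b <- generate_study_dataset("L3", ratios = c(1, 2), seed = 5)
  expect_identical(a[[1]]$emf_mV, b[[1]]$emf_mV)
  expect_identical(a[[2]]$pH, b[[2]]$pH)
  truth <- jsonlite::fromJSON(file.path(dir, "L3_truth.json"))
  expect_equal(truth$truth$logbeta[truth$truth$p == 1 & truth$truth$r == 1],
               7.70)
  expect_true(file.exists(file.path(dir, "L3_curve1.csv")))
  # byte-identical CSV under the same seed
  f2 <- file.path(dir, "again")
  generate_study_dataset("L3", ratios = c(1, 2), seed = 5, dir = f2)
  expect_identical(readLines(file.path(dir, "L3_curve1.csv")),
                   readLines(file.path(f2, "L3_curve1.csv")))
  expect_error(generate_study_dataset("L9"), "arg")
})
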