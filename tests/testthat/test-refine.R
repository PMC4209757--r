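test_that("residuals vanish at the generating model and grow when perturbed", {
  r0 <- refinement_residuals(l1_curves_clean, l1_model)
  expect_lt(max(abs(r0)), 1e-9)
  m2 <- l1_model
  m2$species$log_beta[m2$species$p == 1 & m2$species$r == 1] <-
    m2$species$log_beta[m2$species$p == 1 & m2$species$r == 1] + 0.5
  r1 <- refinement_residuals(l1_curves_clean, m2)
  expect_gt(sum(r1^2), sum(r0^2) + 1)
  # propagated weights rescale residuals point-wise by sqrt(w)
  ru <- refinement_residuals(l1_curves_clean, m2, weights = "unit")
  rp <- refinement_residuals(l1_curves_clean, m2, weights = "propagated")
  w <- eqspec:::point_weights(l1_curves_clean, "propagated", 0.1, 0.005,
                              list(E0 = 400, slope = 59.16), "emf")
  expect_equal(rp, sqrt(w) * ru, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the Hamilton R-factor matches hand arithmetic and its edge cases", {
  expect_equal(hamilton_r(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(hamilton_r(c(1, 2, 3), c(0, 0, 0)), 1)
  expect_equal(hamilton_r(c(1, 2, 3), c(1.1, 1.9, 3.0)), sqrt(0.02 / 14))
  expect_error(hamilton_r(c(0, 0), c(1, 1)), "All-zero")
})

test_that("the limiting R-factor scales with the error model", {
  expect_equal(r_limit(l1_curves_clean, sigma_E = 0, sigma_v = 0), 0)
  a <- r_limit(l1_curves_clean, sigma_E = 0.1, sigma_v = 0)
  b <- r_limit(l1_curves_clean, sigma_E = 0.2, sigma_v = 0)
  expect_equal(b / a, 2, tolerance = 1e-9)
  # defaults land in the decade typical of glass-electrode work
  rl <- r_limit(l1_curves_clean)
  expect_gt(rl, 0.005)
  expect_lt(rl, 0.05)
})

test_that("the analytic parameter Jacobian matches finite differences", {
  cv <- l1_curves_clean[[1]][seq(1, nrow(l1_curves_clean[[1]]), by = 6), ]
  m <- l1_model
  ridx <- which(m$species$refine)
  par <- m$species$log_beta[ridx] + c(0.2, -0.1, 0.15)
  cc <- eqspec:::calc_observable(list(cv), m, par, ridx, derivs = TRUE)
  eps <- 1e-6
  for (j in seq_along(par)) {
    pp <- par; pp[j] <- pp[j] + eps
    pm <- par; pm[j] <- pm[j] - eps
    num <- (eqspec:::calc_observable(list(cv), m, pp, ridx)$pH[[1]] -
              eqspec:::calc_observable(list(cv), m, pm, ridx)$pH[[1]]) / (2 * eps)
    expect_equal(-cc$dxh[[1]][, j], num, tolerance = 1e-4)
  }
})

test_that("zero-noise protonation refinement is the identity from perturbed starts", {
  cs <- generate_study_dataset("L1", metal = FALSE, noise = FALSE)
  m <- example_model("L1_protonation")
  truth <- m$species$log_beta[m$species$refine]
  fit <- refine_constants(cs, m, start = truth + c(0.5, -0.5, 0.5))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$estimates$log_beta - truth)), 1e-6)
  expect_true(all(fit$estimates$detectable))
  expect_lt(fit$R_H, 1e-8)
  # accepted Levenberg-Marquardt steps reduce the objective monotonically
  expect_true(all(diff(fit$rss_trace) <= 1e-10))
  # broom accessors
  td <- tidy(fit)
  expect_equal(td$term, c("LH", "LH2", "LH3"))
  expect_equal(nrow(glance(fit)), 1)
})

test_that("a species absent from the truth is flagged as unsupported", {
  pr <- titration_protocol(n_M = 5e-4 * 0.025, n_L = 1e-3 * 0.025,
                           n_acid = (0.01 + 3e-3) * 0.025, increment = 0.08)
  cv <- simulate_titration(ml_model, pr)
  over <- eq_model(rbind(eq_species(0, 1, 1, 9.0),
                         eq_species(1, 1, 0, 12.0, refine = TRUE),
                         eq_species(1, 2, 0, 14.0, refine = TRUE)))
  fit <- suppressWarnings(refine_constants(cv, over))
  est <- fit$estimates
  ml2 <- est[est$q == 2, ]
  expect_true(!ml2$detectable || ml2$sigma > 10 * est$sigma[est$q == 1])
  ml <- est[est$q == 1, ]
  expect_equal(ml$log_beta, 12.0, tolerance = 1e-3)
})

test_that("model comparison surfaces the statistical model-choice signals", {
  cs <- generate_study_dataset("L2", noise = FALSE)
  m1 <- example_model("Ni_L2_model1")
  m2 <- example_model("Ni_L2_model2")
  f1 <- refine_constants(cs, m1,
                         start = m1$species$log_beta[m1$species$refine])
  f2 <- refine_constants(cs, m2,
                         start = m2$species$log_beta[m2$species$refine])
  cmp <- compare_models(list(f1, f2), labels = c("model1", "model2"))
  expect_equal(nrow(cmp), 2)
  # data generated from model 1: model 1 fits essentially exactly, the
  # competing ML formulation misfits and its ML constant is the shakiest
  expect_lt(cmp$R_H[1], 1e-8)
  expect_gt(cmp$R_H[2], cmp$R_H[1])
  expect_gt(cmp$max_sigma[2], cmp$max_sigma[1])
  worst <- f2$estimates[which.max(f2$estimates$sigma), ]
  expect_equal(c(worst$p, worst$q, worst$r), c(1, 1, 0))
  # identical fits tie; mismatched data error
  tie <- compare_models(list(f1, f1))
  expect_equal(tie$R_H[1], tie$R_H[2])
  half <- lapply(cs[1:2], identity)
  f3 <- refine_constants(half, m1,
                         start = m1$species$log_beta[m1$species$refine])
  expect_error(compare_models(list(f1, f3)), "different datasets")
})
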