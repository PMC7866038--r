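test_that("blood volume follows the BSA relation and rejects invalid BSA", {
  expect_equal(blood_volume(1.8), 4693)
  expect_equal(blood_volume(2.0), 5351)
  expect_lt(blood_volume(1.229 / 3.29 + 1e-9), 1e-4)
  expect_error(blood_volume(0.3), "invalid BSA")
})

test_that("constructors enforce their invariants", {
  expect_error(pk_params(k12 = -1, v_ml = 4693), "strictly positive")
  expect_error(regimen(bolus = 0, infusion = 0, bsa = 1.8), "both")
  expect_error(regimen(bsa = 1.8, delta_t = 400), "cycle_interval")
  expect_warning(regimen(bsa = 1.8, n_cycles = 4, t_span = 100),
                 "exceeds t_span")
})

test_that("bolus initial condition is D*BSA/V", {
  p <- default_pk()
  r <- regimen(bolus = 400, infusion = 0, bsa = 1.8)
  prof <- simulate_cycle(p, r)
  expect_equal(prof$sigma_B[1], 400 * 1.8 / 4.693)
  expect_equal(prof$sigma_P[1], 0)
})

test_that("with negligible inter-compartment exchange the one-compartment closed form is recovered", {
  p <- pk_params(k12 = 1e-10, k21 = 1e-10, cl = 65.3,
                 v_ml = blood_volume(1.8))
  r <- regimen(bolus = 0, infusion = 2400, bsa = 1.8)
  prof <- simulate_cycle(p, r)
  expected <- (2400 * 1.8 / (46 * 65.3)) *
    (1 - exp(-65.3 * prof$time_h / 4.693))
  expect_equal(prof$sigma_B, expected, tolerance = 1e-6)
})

test_that("numerical solution matches the closed-form oracle at study parameters", {
  p <- default_pk()
  r <- folfox_regimen()
  num <- simulate_cycle(p, r)
  ana <- analytic_cycle(p, r)
  expect_equal(num$time_h, ana$time_h)
  expect_lt(max(abs(num$sigma_B - ana$sigma_B)) / max(ana$sigma_B), 1e-6)
  expect_lt(max(abs(num$sigma_P - ana$sigma_P)) / max(ana$sigma_P), 1e-6)
})

test_that("infusion-only profile plateaus at R*BSA/(delta_t*Cl)", {
  p <- default_pk()
  r <- regimen(bolus = 0, infusion = 2400, bsa = 1.8)
  prof <- analytic_cycle(p, r)
  expect_equal(tail(prof$sigma_B, 1), 2400 * 1.8 / (46 * 65.3),
               tolerance = 1e-3)
  expect_equal(tail(prof$sigma_B, 1), 1.438, tolerance = 1e-3)
})

test_that("closed form agrees with numerical quadrature of the ODE at tight tolerance", {
  p <- default_pk()
  r <- folfox_regimen()
  num <- simulate_cycle(p, r, atol = 1e-12)
  ana <- analytic_cycle(p, r)
  expect_lt(max(abs(num$sigma_B - ana$sigma_B) /
                  pmax(abs(ana$sigma_B), 1e-9)), 1e-8)
})

test_that("trapezoidal AUC handles simple and analytic cases", {
  expect_equal(auc_trapezoid(tibble::tibble(time_h = c(0, 1),
                                            sigma_B = c(0, 2))), 1)
  const <- tibble::tibble(time_h = seq(0, 5, 0.5), sigma_B = 3)
  expect_equal(auc_trapezoid(const), 15)
  tt <- seq(0, 10, 0.01)
  dec <- tibble::tibble(time_h = tt, sigma_B = exp(-0.7 * tt))
  expect_equal(auc_trapezoid(dec), (1 - exp(-7)) / 0.7, tolerance = 1e-4)
  expect_equal(auc_trapezoid(dec, window = c(1, 4)),
               (exp(-0.7) - exp(-2.8)) / 0.7, tolerance = 1e-4)
  expect_error(auc_trapezoid(dec, window = c(4, 4)), "increasing")
  expect_error(auc_trapezoid(dec, window = c(0, 99)), "within")
})

test_that("exposure summary satisfies the averaging identities", {
  p <- default_pk()
  r <- folfox_regimen(n_cycles = 4, t_span = 4 * 336)
  es <- exposure_summary(simulate_regimen(p, r), r)
  # identical cycles: regimen average equals the per-cycle average
  expect_equal(es$sigma_dbar, es$sigma_bar_i[1])
  # the two averaging routes are algebraically identical
  expect_equal(es$sigma_dbar, mean(es$sigma_bar_i))
  expect_equal(es$sigma_dbar,
               sum(es$auc_per_cycle) / (es$n_cycles * es$delta_t))
  # fast terminal elimination: average within 2% of total dose / (Cl dt)
  expect_equal(es$sigma_dbar, (400 + 2400) * 1.8 / (65.3 * 46),
               tolerance = 0.02)
  expect_equal(nrow(tidy(es)), 4)
  expect_equal(glance(es)$sigma_dbar, es$sigma_dbar)
})

test_that("total exposure is conserved: AUC to washout equals dose/clearance", {
  p <- default_pk()
  r <- folfox_regimen()
  prof <- analytic_cycle(p, r, t_max = 100)
  expect_equal(auc_trapezoid(prof), (400 + 2400) * 1.8 / 65.3,
               tolerance = 0.01)
})

test_that("average exposure scales linearly with simultaneous dose scaling", {
  p <- default_pk()
  base <- folfox_regimen()
  scaled <- regimen(bolus = 800, infusion = 4800, bsa = 1.8)
  es1 <- exposure_summary(list(analytic_cycle(p, base)), base)
  es2 <- exposure_summary(list(analytic_cycle(p, scaled)), scaled)
  expect_equal(es2$sigma_dbar, 2 * es1$sigma_dbar, tolerance = 1e-10)
})
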