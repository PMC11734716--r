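# Growth law, rate factors and the closed-form fold-change laws.

test_that("rate factor is 1 at the reference point and matches direct arithmetic", {
  expect_identical(rate_factor(0, 0.822, mode = "linearized"), 1)
  expect_identical(rate_factor(0, 0.822, mode = "exact"), 1)
  # independent evaluation of the linearised exponent at 25 C
  slope <- 0.822 / (8.617e-5 * 273^2)
  expect_equal(rate_factor(25, 0.822, mode = "linearized"),
               exp(slope * 25), tolerance = 1e-12)
})

test_that("exact and linearised exponents differ by the curvature factor T/Ta", {
  ct <- thermal_constants()
  for (e_act in c(0.3, 0.822)) {
    lin <- log(rate_factor(32, e_act, ct, mode = "linearized"))
    exa <- log(rate_factor(32, e_act, ct, mode = "exact"))
    # algebraic identity: 1 - exact/lin = 1 - 1/(1 + T/Ta) for any E
    expect_equal((lin - exa) / lin, 1 - 1 / (1 + 32 / 273),
                 tolerance = 1e-12)
  }
  # linearised dominates the exact form above 0 C, and both increase in T
  temps <- seq(1, 32, by = 1)
  lin <- rate_factor(temps, 0.822, ct, mode = "linearized")
  exa <- rate_factor(temps, 0.822, ct, mode = "exact")
  expect_true(all(lin >= exa))
  expect_true(all(diff(lin) > 0) && all(diff(exa) > 0))
  # bound on the relative exponent error over the experimental range
  expect_true(all((log(lin) - log(exa)) / log(exa) <= 32 / 273 + 1e-12))
})

test_that("rate factor rejects invalid input", {
  expect_error(rate_factor(NaN, 0.8), "finite")
  expect_error(rate_factor(Inf, 0.8), "finite")
  expect_error(rate_factor(25, -0.1), "positive")
})

test_that("growth ODE matches the closed-form solution from a zero start", {
  gp <- growth_params(base_rate = 1, activation_energy = 0.822,
                      asymptotic_mass = 2.5)
  for (temp in c(12, 18, 25, 31)) {
    t_end <- 3 / rate_factor(temp, 0.822)
    sol <- solve_growth(gp, temp, t_end = t_end, n_steps = 150)
    expected <- growth_closed_form(gp, temp, sol$time)
    rel <- abs(sol$mass[-1] - expected[-1]) / expected[-1]
    expect_lt(max(rel), 1e-6)
    expect_true(all(diff(sol$mass) >= 0))
    expect_true(all(sol$mass < gp$asymptotic_mass))
  }
})

test_that("growth in the small-mass regime follows the quartic law m = (a t / 4)^4", {
  # huge asymptotic mass puts the whole trajectory in the m << M regime,
  # where integrating dm/dt = a m^(3/4) by hand gives m(t) = (a t / 4)^4
  gp <- growth_params(base_rate = 2, activation_energy = 0.822,
                      asymptotic_mass = 1e24)
  sol <- solve_growth(gp, 0, t_end = 1, n_steps = 50)
  expect_equal(sol$mass[-1], (2 * sol$time[-1] / 4)^4, tolerance = 1e-5)
})

test_that("growth saturates at the asymptotic mass and is grid-converged", {
  gp <- growth_params(base_rate = 1, activation_energy = 0.822,
                      asymptotic_mass = 3)
  late <- solve_growth(gp, 25, t_end = 500 / rate_factor(25, 0.822),
                       n_steps = 50)
  expect_equal(utils::tail(late$mass, 1), 3, tolerance = 1e-6)
  a <- solve_growth(gp, 25, t_end = 0.1, n_steps = 200)
  b <- solve_growth(gp, 25, t_end = 0.1, n_steps = 100)
  expect_lt(abs(utils::tail(a$mass, 1) - utils::tail(b$mass, 1)) /
              utils::tail(a$mass, 1), 1e-6)
})

test_that("growth parameters validate and accept metabolic provenance", {
  expect_error(growth_params(base_rate = 1, activation_energy = 0.8,
                             asymptotic_mass = -1))
  expect_error(growth_params(base_rate = 1, activation_energy = 0.8,
                             asymptotic_mass = 1, initial_mass = 2))
  gp <- growth_params(activation_energy = 0.8, asymptotic_mass = 1,
                      cell_mass = 3e-9, cell_energy = 2e-5,
                      metabolic_norm = 10)
  expect_equal(gp$base_rate, 10 * 3e-9 / 2e-5)
  expect_error(growth_params(base_rate = 1, activation_energy = 0.8,
                             asymptotic_mass = 1, cell_mass = 1,
                             cell_energy = 1, metabolic_norm = 1),
               "not both")
})

test_that("developmental-time fold change follows the exponential law", {
  sc <- ref_scaling()
  expect_identical(devtime_fold_change(25, sc), 1)
  # hand evaluation: exp(0.128 * 7) at 18 C
  expect_equal(devtime_fold_change(18, sc), exp(0.896), tolerance = 1e-12)
  expect_equal(devtime_fold_change(18, sc), 2.450, tolerance = 1e-3)
  temps <- seq(12, 31, by = 0.5)
  expect_true(all(diff(devtime_fold_change(temps, sc)) < 0))
  # exponential composition: fold(T2) = fold(T1) * relative fold T1 -> T2
  expect_equal(devtime_fold_change(29, sc),
               devtime_fold_change(16, sc) * exp(-sc$alpha * (29 - 16)),
               tolerance = 1e-12)
})

test_that("connectivity fold change is exponential and null at beta = 0", {
  sc <- ref_scaling()
  expect_identical(connectivity_fold_change(25, sc), 1)
  expect_equal(connectivity_fold_change(18, sc), exp(0.931),
               tolerance = 1e-12)
  expect_equal(connectivity_fold_change(18, sc), 2.537, tolerance = 1e-3)
  temps <- seq(12, 31, by = 0.5)
  expect_true(all(diff(connectivity_fold_change(temps, sc)) < 0))
  # equal activation energies: no change in partner number anywhere
  null <- scaling_params(alpha = 0.128, beta = 0)
  expect_equal(connectivity_fold_change(temps, null), rep(1, length(temps)))
})

test_that("fold-change laws are invariant to the mass unit", {
  # developmental time from the growth model in two mass units
  ct <- thermal_constants()
  # scaling factor implied by the activation energy used in the growth model
  sc <- scaling_params(alpha = 0.822 / (8.617e-5 * 273^2), beta = 0.133)
  for (unit in c(1, 1e3)) {
    gp <- growth_params(base_rate = unit^(1 / 4), activation_energy = 0.822,
                        asymptotic_mass = unit)
    t18 <- time_to_mass(gp, 18, constants = ct)
    t25 <- time_to_mass(gp, 25, constants = ct)
    expect_equal(t18 / t25, devtime_fold_change(18, sc), tolerance = 1e-9)
  }
})

test_that("scaling factors convert to the printed activation energies", {
  sc <- ref_scaling()
  en <- activation_energies(sc)
  # independent arithmetic: E = alpha K Ta^2
  expect_equal(en$e, 0.128 * 8.617e-5 * 273^2, tolerance = 1e-12)
  expect_equal(en$e, 0.822, tolerance = 1e-3)
  expect_equal(en$delta_e, 0.133 * 8.617e-5 * 273^2 / 4, tolerance = 1e-12)
  expect_lt(en$e_prime, en$e)
  # beta = 0 collapses the two energies
  en0 <- activation_energies(scaling_params(0.128, 0))
  expect_equal(en0$e_prime, en0$e)
  # beta >= 4 alpha would imply negative brain activation energy
  expect_warning(activation_energies(scaling_params(0.1, 0.5)), "negative")
})

test_that("devtime implied by the growth model reproduces the exponential law", {
  gp <- growth_params(base_rate = 1, activation_energy = 0.822,
                      asymptotic_mass = 1)
  sc <- scaling_params(alpha = 0.822 / (8.617e-5 * 273^2), beta = 0.133)
  temps <- seq(12, 31, by = 1)
  t_ref <- time_to_mass(gp, sc$ref_temp)
  implied <- vapply(temps, function(T) time_to_mass(gp, T), numeric(1)) / t_ref
  expect_equal(implied, devtime_fold_change(temps, sc), tolerance = 1e-4)
})

test_that("brain-stage advancement matches an ODE oracle and is fraction-free", {
  sc <- ref_scaling()
  en <- activation_energies(sc)
  body <- growth_params(base_rate = 1, activation_energy = en$e,
                        asymptotic_mass = 1)
  # small base rate keeps the brain deep in the m << M regime, where the
  # advancement is exactly fraction-independent
  brain <- growth_params(base_rate = 1e-3, activation_energy = en$e_prime,
                         asymptotic_mass = 1e12)
  stage <- function(temp, frac) {
    t_dev <- time_to_mass(body, temp)
    sol <- solve_growth(brain, temp, t_end = frac * t_dev, n_steps = 60)
    utils::tail(sol$mass, 1)
  }
  for (frac in c(0.25, 0.5, 0.75)) {
    ratio <- stage(18, frac) / stage(25, frac)
    expect_equal(ratio, relative_brain_stage(18, sc, frac),
                 tolerance = 1e-6)
  }
  expect_identical(relative_brain_stage(25, sc), 1)
  expect_equal(relative_brain_stage(18, sc), 2.537, tolerance = 1e-3)
  expect_gt(relative_brain_stage(20, sc), 1)
})

test_that("scaling params enforce the gamma identity and config round-trips", {
  sc <- scaling_params(0.2, 0.05, ref_temp = 20)
  expect_equal(sc$gamma, 0.2 - 0.05 / 4, tolerance = 1e-12)
  expect_error(scaling_params(0.1, 0.1, ref_temp = 50))
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("alpha: 0.128", "beta: 0.133", "ref_temp: 25"), cfg)
  sc2 <- read_scaling_config(cfg)
  expect_equal(sc2$alpha, 0.128)
  expect_equal(sc2$gamma, 0.128 - 0.133 / 4)
  out <- tempfile(fileext = ".json")
  write_result_json(list(e_prime = activation_energies(sc2)$e_prime), sc2, out)
  back <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(back$params$alpha, 0.128)
  expect_equal(back$result$e_prime, activation_energies(sc2)$e_prime,
               tolerance = 1e-12)
})
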