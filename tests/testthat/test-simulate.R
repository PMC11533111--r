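# Simulation engine: conservation, convergence, steady state, depuration.

ref_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- pbpk_simulate(reference_model("man"), default_scenario())
    cache
  }
})

test_that("zero infusion from a zero state yields identically zero trajectories", {
  sc <- pbpk_scenario(dose = 0)
  sim <- pbpk_simulate(reference_model("man"), sc)
  expect_equal(max(abs(sim$amounts)), 0)
  expect_equal(max(abs(sim$concentrations)), 0)
  expect_equal(mass_balance_report(sim), 0)
})

test_that("the reference run conserves mass to 1e-6 relative at every grid point", {
  sim <- ref_sim()
  expect_length(sim$times, 401L)           # 0..400 at 1-min steps
  expect_true(all(abs(residuals(sim)) <= 1e-6))
  expect_true(all(diff(sim$cumulative_dosed) >= 0))
  expect_true(all(diff(sim$cumulative_eliminated) >= 0))
  expect_true(all(sim$amounts >= 0))
  expect_equal(utils::tail(sim$cumulative_dosed, 1), 100 * 200)
})

test_that("a long infusion converges to the closed-form steady state", {
  m <- reference_model("man")
  sc <- pbpk_scenario(dose = 100, t_end = 10000, expos_end = 10000)
  sim <- pbpk_simulate(m, sc, output_step = 25)
  ss <- steady_state_infusion(m, 100)
  end <- nrow(sim$concentrations)
  for (j in 1:3)
    expect_lt(abs(sim$concentrations[end, j] - ss$concentrations[j]) /
                ss$concentrations[j], 1e-3)
})

test_that("steady-state linear solve agrees with the closed-form oracle", {
  m <- reference_model("man")
  ss <- steady_state_infusion(m, 100)
  oracle <- closed_form_steady_state(m, 100)
  expect_equal(unname(ss$concentrations), unname(oracle), tolerance = 1e-12)
  expect_equal(unname(ss$concentrations[["blood"]]), 100 / (1.6575 * 0.7))
  expect_equal(unname(ss$concentrations[["others"]]),
               3 * 100 / (1.6575 * 0.7))

  set.seed(41)
  for (i in 1:5) {
    mr <- random_valid_model(n_tissues = sample(1:4, 1))
    dose <- runif(1, 1, 500)
    expect_equal(unname(steady_state_infusion(mr, dose)$concentrations),
                 unname(closed_form_steady_state(mr, dose)),
                 tolerance = 1e-10)
  }

  expect_error(steady_state_infusion(reference_model("man", er_liver = 0), 100),
               "no bounded steady state")
})

test_that("body burden is strictly non-increasing during depuration", {
  sim <- ref_sim()
  burden <- rowSums(sim$amounts)
  post <- burden[sim$times > 200]
  expect_true(all(diff(post) < 0))
})

test_that("halving the solver tolerances barely moves the endpoint", {
  m <- reference_model("man")
  a <- pbpk_simulate(m, rtol = 1e-8, atol = 1e-10)
  b <- pbpk_simulate(m, rtol = 5e-9, atol = 5e-11)
  end <- length(a$times)
  expect_lt(abs(a$concentrations[end, "blood"] - b$concentrations[end, "blood"]) /
              b$concentrations[end, "blood"], 1e-4)
})

test_that("stiff and explicit high-order solvers agree on the reference run", {
  m <- reference_model("man")
  stiff <- pbpk_simulate(m, rtol = 1e-10, atol = 1e-12, method = "lsoda")
  explicit <- pbpk_simulate(m, rtol = 1e-10, atol = 1e-12, method = "ode45")
  expect_lt(max(abs(stiff$concentrations - explicit$concentrations)) /
              max(stiff$concentrations), 1e-6)
})

test_that("mass-balance residual degrades when tolerances are loosened", {
  m <- reference_model("man")
  tight <- mass_balance_report(pbpk_simulate(m, rtol = 1e-8, atol = 1e-10))
  loose <- mass_balance_report(pbpk_simulate(m, rtol = 1e-2, atol = 1e-4))
  expect_gte(loose, tight)
  expect_lte(tight, 1e-6)
})

test_that("event times always appear in the output grid", {
  sc <- pbpk_scenario(dose = 50, t_start = 0, t_end = 300,
                      expos_start = 12.5, expos_end = 137.5)
  sim <- pbpk_simulate(reference_model("man"), sc, output_step = 10)
  expect_true(all(c(12.5, 137.5) %in% sim$times))
  expect_false(is.unsorted(sim$times, strictly = TRUE))
  # no chemical enters before the exposure starts
  expect_equal(max(abs(sim$amounts[sim$times <= 12.5, ])), 0)
})

test_that("simulate() works as a method on the model object", {
  sim <- simulate(reference_model("man"), scenario = default_scenario(),
                  output_step = 50)
  expect_s3_class(sim, "pbpk_sim")
  expect_equal(sim$diagnostics$rtol, 1e-8)
})
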