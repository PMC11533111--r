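# Domain types, the ODE right-hand side, and physiological validation.

test_that("dosing rate is the infusion inside the closed exposure window and zero outside", {
  sc <- default_scenario()
  expect_equal(dosing_rate(100, sc), 100)
  expect_equal(dosing_rate(300, sc), 0)
  # both endpoints belong to the dosing interval
  expect_equal(dosing_rate(0, sc), 100)
  expect_equal(dosing_rate(200, sc), 100)
  expect_equal(dosing_rate(200 + 1e-9, sc), 0)
  expect_equal(dosing_rate(c(-5, 50, 199, 201, 400), sc),
               c(0, 100, 100, 0, 0))
})

test_that("concentrations divide amounts by blood volume and tissue weights", {
  m <- reference_model("man")
  conc <- concentrations(c(5.3, 3.796, 0), m)
  expect_equal(unname(conc[["blood"]]), 1)        # 5.3 mg / 5.3 L
  expect_equal(unname(conc[["liver"]]), 2)        # 3.796 mg / 1.898 kg
  expect_equal(unname(concentrations(c(0, 0, 0), m)), c(0, 0, 0))
})

test_that("amounts and concentrations are mutually inverse", {
  set.seed(11)
  for (i in 1:10) {
    m <- random_valid_model(n_tissues = sample(1:4, 1))
    s <- runif(length(m$tissues) + 1L, 0, 50)
    expect_equal(unname(compartment_amounts(concentrations(s, m), m)), s)
  }
})

test_that("rhs of a zero state during infusion is pure dosing input", {
  m <- reference_model("man")
  d <- pbpk_rhs(50, c(0, 0, 0), m, default_scenario())
  expect_equal(unname(d), c(100, 0, 0))
  expect_error(pbpk_rhs(50, c(0, 0), m, default_scenario()), "length")
})

test_that("rhs components sum to dosing minus clearance for arbitrary states", {
  set.seed(23)
  for (i in 1:20) {
    m <- random_valid_model(n_tissues = sample(1:4, 1))
    sc <- random_scenario()
    s <- runif(length(m$tissues) + 1L, 0, 100)
    t <- runif(1, sc$t_start, sc$t_end)
    expect_equal(sum(pbpk_rhs(t, s, m, sc)),
                 dosing_rate(t, sc) - clearance_rate(s, m))
  }
})

test_that("rhs is linear in the state once the dosing offset is removed", {
  set.seed(31)
  m <- random_valid_model(3)
  sc <- default_scenario()
  f <- function(s) pbpk_rhs(10, s, m, sc) - pbpk_rhs(10, numeric(4), m, sc)
  for (i in 1:10) {
    s1 <- runif(4, 0, 10); s2 <- runif(4, 0, 10)
    a <- runif(1, 0, 3); b <- runif(1, 0, 3)
    expect_equal(f(a * s1 + b * s2), a * f(s1) + b * f(s2))
  }
})

test_that("rhs vanishes at the analytic infusion steady state", {
  m <- reference_model("man")
  ss <- steady_state_infusion(m, 100)
  sc <- pbpk_scenario(dose = 100, t_end = 1e6, expos_end = 1e6)
  expect_lt(max(abs(pbpk_rhs(100, ss$amounts, m, sc))), 1e-9)
})

test_that("clearance is the extraction-weighted flow times blood concentration", {
  m <- reference_model("man")
  expect_equal(clearance_rate(c(0, 5, 5), m), 0)
  # at the steady-state blood concentration, clearance balances the infusion
  c_blood_ss <- 100 / (1.6575 * 0.7)
  expect_equal(clearance_rate(c(c_blood_ss * 5.3, 0, 0), m), 100)
  m0 <- reference_model("man", er_liver = 0)
  expect_equal(clearance_rate(c(50, 10, 10), m0), 0)
})

test_that("validation reports closure and range violations as data", {
  m <- reference_model("man")
  expect_identical(nrow(validate_model(m)), 0L)

  tampered <- unclass(m)
  tampered$blood$cardiac_output <- 7.0
  f <- validate_model(tampered)
  expect_true("flow_closure" %in% f$check)
  expect_match(f$message[f$check == "flow_closure"], "6.5")

  bad_er <- unclass(m)
  bad_er$tissues$liver$extraction <- 1.5
  f <- validate_model(bad_er)
  expect_true(any(f$check == "range" & f$quantity == "ER_liver"))
})

test_that("constructors reject unphysiological inputs", {
  expect_error(pbpk_tissue("liver", weight = -1, flow = 1, partition = 1),
               "weight")
  expect_error(pbpk_tissue("liver", 1, 1, 1, extraction = 1.2), "extraction")
  expect_error(pbpk_tissue("blood", 1, 1, 1), "reserved")
  expect_error(pbpk_blood(volume = 0, cardiac_output = 5), "positive")
  b <- pbpk_blood(5, 2)
  t1 <- pbpk_tissue("liver", 2, 1, 1.5)
  t2 <- pbpk_tissue("liver", 3, 1, 2)
  expect_error(pbpk_model(b, list(t1, t2)), "unique")
  expect_error(pbpk_model(b, list(t1), initial_amounts = c(-1, 0)),
               "non-negative")
  # closure enforced at construction
  expect_error(pbpk_model(b, list(t1), body_weight = 100), "validation")
  expect_error(pbpk_scenario(dose = 100, expos_end = 500, t_end = 400),
               "t_start")
})

test_that("models round-trip through JSON and YAML configuration files", {
  set.seed(7)
  m <- random_valid_model(3)
  sc <- random_scenario()
  for (ext in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_model_config(m, sc, path)
    got <- read_model_config(path)
    expect_equal(coef(got$model), coef(m))
    expect_equal(got$model$initial_amounts, m$initial_amounts)
    expect_equal(unclass(got$scenario), unclass(sc))
  }
})

test_that("configuration keys follow the published abbreviations, with rounded values admitted", {
  path <- withr::local_tempfile(fileext = ".json")
  # rounded published values: weight closure only holds to ~1e-3
  writeLines('{
    "BW": 73, "V_blood": 5.3, "QC": 6.5,
    "W_liver": 1.898, "Q_liver_total": 1.66, "PC_liver": 1.5, "ER_liver": 0.7,
    "W_others": 65.8, "Q_others": 4.84, "PC_others": 3,
    "Dose": 100, "Time_end_expos": 200
  }', path)
  got <- read_model_config(path)
  expect_equal(names(got$model$tissues), c("liver", "others"))
  expect_equal(got$model$tissues$liver$flow, 1.66)
  expect_equal(got$scenario$dose, 100)
  # at formula-construction tolerance the rounded weights no longer close
  expect_error(read_model_config(path, tolerance = 1e-9), "validation")
})
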