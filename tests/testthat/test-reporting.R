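# Reporting checklist, naming linter, and the results-table writer.

test_that("a fully annotated model with attached results scores 1.0 on applicable items", {
  m <- reference_model("man")
  sim <- pbpk_simulate(m, default_scenario(), output_step = 50)
  report <- checklist_evaluate(complete_metadata(), m, sim)
  expect_equal(checklist_score(report), 1.0)
  expect_true(all(report$status[report$status != "not-applicable"] == "pass"))
  # human-judgement items are surfaced but never scored
  expect_true("model_purpose" %in% report$id[report$status == "not-applicable"])
})

test_that("removing the license or the results flips the corresponding items to fail", {
  m <- reference_model("man")
  sim <- pbpk_simulate(m, default_scenario(), output_step = 50)

  md <- complete_metadata()
  md$license <- NULL
  report <- checklist_evaluate(md, m, sim)
  expect_equal(report$status[report$id == "license"], "fail")
  expect_lt(checklist_score(report), 1.0)

  no_results <- checklist_evaluate(complete_metadata(), m, NULL)
  expect_equal(no_results$status[no_results$id == "simulation_results"], "fail")
  expect_equal(no_results$status[no_results$id == "solver_recorded"], "fail")
})

test_that("checklist score is monotone in metadata completeness", {
  m <- reference_model("man")
  sim <- pbpk_simulate(m, default_scenario(), output_step = 100)
  full <- checklist_score(checklist_evaluate(complete_metadata(), m, sim))
  for (field in c("code_version", "article_citation", "code_citation",
                  "license", "ai_tools_disclosure")) {
    md <- complete_metadata()
    md[[field]] <- NULL
    expect_lte(checklist_score(checklist_evaluate(md, m, sim)), full)
  }
  md <- complete_metadata(); md$authors <- list()
  expect_lte(checklist_score(checklist_evaluate(md, m, sim)), full)
  md <- complete_metadata(); md$sources <- character()
  expect_lte(checklist_score(checklist_evaluate(md, m, sim)), full)
})

test_that("metadata manifests load from JSON and YAML", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(model_name = "demo", license = "CC-BY-4.0",
                            authors = list(list(name = "A. Modeller")),
                            sources = list("compendium")),
                       path, auto_unbox = TRUE)
  md <- read_metadata(path)
  expect_s3_class(md, "pbpk_metadata")
  expect_equal(md$license, "CC-BY-4.0")
  expect_equal(md$authors[[1]]$name, "A. Modeller")
})

test_that("naming linter accepts conventional abbreviations and repairs glued prefixes", {
  res <- naming_check(c("Q_liver_total", "PC_others", "A_blood", "BW",
                        "Time_end_expos", "Qliver", "liverQ", "ERliver"))
  conforming <- res$conforming
  names(conforming) <- res$name
  expect_true(all(conforming[c("Q_liver_total", "PC_others", "A_blood",
                               "BW", "Time_end_expos")]))
  expect_false(conforming[["Qliver"]])
  expect_equal(res$suggestion[res$name == "Qliver"], "Q_liver")
  expect_equal(res$suggestion[res$name == "ERliver"], "ER_liver")
  expect_false(conforming[["liverQ"]])
  expect_true(is.na(res$suggestion[res$name == "liverQ"]))
})

test_that("naming linter is idempotent on its own suggestions", {
  res <- naming_check(c("Qliver", "PCothers", "Wblood", "Aliver", "ERliver"))
  again <- naming_check(res$suggestion)
  expect_true(all(again$conforming))
})

test_that("all reference-model component names pass the linter", {
  res <- naming_check(names(coef(reference_model("woman"))))
  expect_true(all(res$conforming))
})

test_that("results tables round-trip at full double precision", {
  sim <- pbpk_simulate(reference_model("man"), default_scenario())
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_table(sim, path)
  back <- read_results_table(path)
  expect_equal(nrow(back), 401L)
  expect_equal(ncol(back), 9L)
  expect_equal(names(back),
               c("time_min", "A_blood_mg", "A_liver_mg", "A_others_mg",
                 "C_blood_mg_per_L", "C_liver_mg_per_kg", "C_others_mg_per_kg",
                 "cumulative_dosed_mg", "cumulative_eliminated_mg"))
  expect_identical(back$C_blood_mg_per_L, unname(sim$concentrations[, "blood"]))
  expect_identical(back$A_others_mg, unname(sim$amounts[, "others"]))

  empty <- sim
  empty$times <- numeric(0)
  expect_error(write_results_table(empty, path), "empty")
  expect_error(write_results_table(sim, file.path(tempdir(), "no", "such",
                                                  "dir", "x.csv")))
})
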