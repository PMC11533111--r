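# SBML Level 3 export, consistency checking, and lossless re-import.

man_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- to_sbml(reference_model("man"), default_scenario())
    cache
  }
})

test_that("the exported reference document has the expected structure and is consistent", {
  b <- man_bundle()
  doc <- b$doc
  count <- function(name)
    length(xml2::xml_find_all(doc, sprintf(".//*[local-name() = '%s']", name)))
  expect_equal(count("compartment"), 3L)
  expect_equal(count("species"), 3L)
  expect_equal(count("event"), 2L)
  expect_equal(count("rateRule"), 3L)
  expect_equal(count("assignmentRule"), 3L)
  expect_identical(sbml_check(b), character(0))
})

test_that("every exported parameter and compartment carries resolvable units", {
  doc <- man_bundle()$doc
  for (name in c("parameter", "compartment")) {
    nodes <- xml2::xml_find_all(doc, sprintf(".//*[local-name() = '%s']", name))
    units <- xml2::xml_attr(nodes, "units")
    expect_false(any(is.na(units)))
    expect_true(all(nzchar(units)))
  }
})

test_that("the dosing parameter's initial value respects the event semantics at t = 0", {
  dosing_value <- function(scenario) {
    doc <- to_sbml(reference_model("man"), scenario)$doc
    node <- xml2::xml_find_first(
      doc, ".//*[local-name() = 'parameter' and @id = 'Dosing']")
    as.numeric(xml2::xml_attr(node, "value"))
  }
  # exposure starts with the simulation: infusion already on
  expect_equal(dosing_value(default_scenario()), 100)
  # delayed exposure: infusion off until the start event fires
  expect_equal(dosing_value(pbpk_scenario(dose = 100, expos_start = 50)), 0)
})

test_that("export followed by import reproduces every numeric field exactly", {
  m <- reference_model("man")
  sc <- default_scenario()
  rt <- from_sbml(to_sbml(m, sc))
  expect_identical(coef(rt$model), coef(m))
  expect_identical(rt$model$initial_amounts, m$initial_amounts)
  expect_identical(unclass(rt$scenario), unclass(sc))
  expect_identical(names(rt$model$tissues), names(m$tissues))

  set.seed(53)
  for (i in 1:8) {
    mr <- random_valid_model(n_tissues = sample(1:4, 1))
    scr <- random_scenario()
    rtr <- from_sbml(to_sbml(mr, scr))
    expect_identical(coef(rtr$model), coef(mr))
    expect_identical(rtr$model$initial_amounts, mr$initial_amounts)
    expect_identical(unclass(rtr$scenario), unclass(scr))
  }
})

test_that("model annotations survive the SBML round trip", {
  md <- complete_metadata()
  m <- reference_model("man")
  m$metadata <- md
  rt <- from_sbml(to_sbml(m, default_scenario()))
  got <- rt$model$metadata
  expect_equal(got$model_name, md$model_name)
  expect_equal(got$license, md$license)
  expect_equal(got$authors[[1]]$orcid, md$authors[[1]]$orcid)
  expect_equal(got$sources, md$sources)
})

test_that("simulating the round-tripped model reproduces the native trajectories", {
  m <- reference_model("man")
  sc <- default_scenario()
  rt <- from_sbml(to_sbml(m, sc))
  a <- pbpk_simulate(m, sc)
  b <- pbpk_simulate(rt$model, rt$scenario)
  expect_lt(max(abs(a$concentrations - b$concentrations)) /
              max(a$concentrations), 1e-6)
})

test_that("documents round-trip through disk and invalid ones are rejected", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(man_bundle(), path)
  back <- read_sbml(path)
  expect_identical(sbml_check(back), character(0))
  rt <- from_sbml(back)
  expect_identical(coef(rt$model), coef(reference_model("man")))
  expect_equal(back$provenance$writer, "pbpksim")

  expect_error(read_sbml(withr::local_tempfile(fileext = ".xml")),
               "not found")
})

test_that("documents with constructs outside the rate-rule dialect are rejected by name", {
  doc <- xml2::read_xml(as.character(man_bundle()$doc))
  model_node <- xml2::xml_find_first(doc, ".//*[local-name() = 'model']")
  xml2::xml_add_child(model_node, "reaction", id = "r1")
  expect_error(from_sbml(structure(list(doc = doc, provenance = list()),
                                   class = "sbml_bundle")),
               "reaction")
})

test_that("the consistency checker catches broken references and missing units", {
  doc <- xml2::read_xml(as.character(man_bundle()$doc))
  par <- xml2::xml_find_first(
    doc, ".//*[local-name() = 'parameter' and @id = 'PC_liver']")
  xml2::xml_set_attr(par, "units", "furlong")
  problems <- sbml_check(doc)
  expect_true(any(grepl("furlong", problems)))

  doc2 <- xml2::read_xml(as.character(man_bundle()$doc))
  sp <- xml2::xml_find_first(doc2, ".//*[local-name() = 'species']")
  xml2::xml_set_attr(sp, "compartment", "nowhere")
  expect_true(any(grepl("nowhere", sbml_check(doc2))))
})
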