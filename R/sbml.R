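# SBML Level 3 Version 2 export and re-import of PBPK models.
#
# The ODEs are encoded as rate rules on amount species (not as reactions, so
# no stoichiometry has to be invented), concentrations as assignment-rule
# parameters, and the infusion as a non-constant "Dosing" parameter toggled
# by two events at the exposure boundaries.  Every parameter and compartment
# carries an explicit unit definition (min, L, kg, mg and derived units).
# Identifiers follow the conventional abbreviations (A_blood, C_liver,
# Q_liver_total-style names are the user's tissue names verbatim).

SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
PBPKSIM_ANNOT_NS <- "https://pbpksim.invalid/annotations"

fmt_num <- function(x) sprintf("%.17g", x)
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# -- tiny MathML builders (strings) -----------------------------------------
m_ci <- function(x) sprintf("<ci> %s </ci>", x)
m_cn <- function(x) sprintf('<cn sbml:units="dimensionless" xmlns:sbml="%s"> %s </cn>',
                            SBML_NS, fmt_num(x))
m_apply <- function(op, ...) sprintf("<apply><%s/>%s</apply>", op,
                                     paste0(c(...), collapse = ""))
m_time <- function()
  sprintf('<csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time"> t </csymbol>')
m_math <- function(body) sprintf('<math xmlns="%s">%s</math>', MATHML_NS, body)

# -- export -----------------------------------------------------------------

#' Export a PBPK model and exposure scenario to SBML Level 3
#'
#' Produces a self-contained SBML Level 3 Version 2 document: one compartment
#' per physiological compartment (sizes are the blood volume and tissue
#' weights), amount species with the model's initial values, the ODEs as rate
#' rules, concentrations as assignment rules, and the infusion as a `Dosing`
#' parameter switched by two events at the exposure boundaries.  All
#' parameters carry explicit units; model annotations are embedded both as
#' human-readable notes and as a machine-readable annotation element.
#'
#' @param model A validated [pbpk_model] with named compartments.
#' @param scenario A [pbpk_scenario].
#' @return An object of class `sbml_bundle`: list with `doc` (an
#'   [xml2::xml_document]) and `provenance` (writer, version, source model
#'   name).
#' @seealso [from_sbml()], [write_sbml()], [sbml_check()]
#' @export
to_sbml <- function(model, scenario = default_scenario()) {
  stopifnot(inherits(model, "pbpk_model"), inherits(scenario, "pbpk_scenario"))
  if (nrow(validate_model(model)) > 0L)
    stop("model fails validation; refusing to export", call. = FALSE)
  nm <- names(model$tissues)
  if (any(!nzchar(nm)))
    stop("cannot export: model has unnamed compartments", call. = FALSE)

  unit_defs <- paste0(
    '<unitDefinition id="min"><listOfUnits>',
    '<unit kind="second" exponent="1" scale="0" multiplier="60"/>',
    '</listOfUnits></unitDefinition>',
    '<unitDefinition id="L"><listOfUnits>',
    '<unit kind="litre" exponent="1" scale="0" multiplier="1"/>',
    '</listOfUnits></unitDefinition>',
    '<unitDefinition id="kg"><listOfUnits>',
    '<unit kind="kilogram" exponent="1" scale="0" multiplier="1"/>',
    '</listOfUnits></unitDefinition>',
    '<unitDefinition id="mg"><listOfUnits>',
    '<unit kind="gram" exponent="1" scale="-3" multiplier="1"/>',
    '</listOfUnits></unitDefinition>',
    '<unitDefinition id="mg_per_min"><listOfUnits>',
    '<unit kind="gram" exponent="1" scale="-3" multiplier="1"/>',
    '<unit kind="second" exponent="-1" scale="0" multiplier="60"/>',
    '</listOfUnits></unitDefinition>',
    '<unitDefinition id="L_per_min"><listOfUnits>',
    '<unit kind="litre" exponent="1" scale="0" multiplier="1"/>',
    '<unit kind="second" exponent="-1" scale="0" multiplier="60"/>',
    '</listOfUnits></unitDefinition>',
    '<unitDefinition id="mg_per_L"><listOfUnits>',
    '<unit kind="gram" exponent="1" scale="-3" multiplier="1"/>',
    '<unit kind="litre" exponent="-1" scale="0" multiplier="1"/>',
    '</listOfUnits></unitDefinition>',
    '<unitDefinition id="mg_per_kg"><listOfUnits>',
    '<unit kind="gram" exponent="1" scale="-3" multiplier="1"/>',
    '<unit kind="kilogram" exponent="-1" scale="0" multiplier="1"/>',
    '</listOfUnits></unitDefinition>',
    '<unitDefinition id="L_per_kg"><listOfUnits>',
    '<unit kind="litre" exponent="1" scale="0" multiplier="1"/>',
    '<unit kind="kilogram" exponent="-1" scale="0" multiplier="1"/>',
    '</listOfUnits></unitDefinition>')

  compartments <- paste0(
    sprintf('<compartment id="blood" name="blood" size="%s" units="L" constant="true"/>',
            fmt_num(model$blood$volume)),
    paste0(vapply(model$tissues, function(tis) sprintf(
      '<compartment id="%s" name="%s" size="%s" units="kg" constant="true"/>',
      tis$name, tis$name, fmt_num(tis$weight)), character(1)), collapse = ""))

  species <- paste0(
    sprintf('<species id="A_blood" name="amount of chemical in blood" compartment="blood" initialAmount="%s" substanceUnits="mg" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>',
            fmt_num(model$initial_amounts[["blood"]])),
    paste0(vapply(model$tissues, function(tis) sprintf(
      '<species id="A_%s" name="amount of chemical in %s" compartment="%s" initialAmount="%s" substanceUnits="mg" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>',
      tis$name, tis$name, tis$name,
      fmt_num(model$initial_amounts[[tis$name]])), character(1)), collapse = ""))

  par <- function(id, value, units, constant = "true")
    sprintf('<parameter id="%s" value="%s" units="%s" constant="%s"/>',
            id, fmt_num(value), units, constant)
  dosing0 <- if (scenario$expos_start <= scenario$t_start) scenario$dose else 0
  parameters <- paste0(
    par("BW", model$body_weight, "kg"),
    par("V_blood", model$blood$volume, "L"),
    par("W_blood", model$blood$weight, "kg"),
    par("QC", model$blood$cardiac_output, "L_per_min"),
    paste0(vapply(model$tissues, function(tis) paste0(
      par(paste0("W_", tis$name), tis$weight, "kg"),
      par(paste0("Q_", tis$name), tis$flow, "L_per_min"),
      par(paste0("PC_", tis$name), tis$partition, "L_per_kg"),
      par(paste0("ER_", tis$name), tis$extraction, "dimensionless")),
      character(1)), collapse = ""),
    par("Dose", scenario$dose, "mg_per_min"),
    par("Time_start_simul", scenario$t_start, "min"),
    par("Time_end_simul", scenario$t_end, "min"),
    par("Time_start_expos", scenario$expos_start, "min"),
    par("Time_end_expos", scenario$expos_end, "min"),
    par("Dosing", dosing0, "mg_per_min", constant = "false"),
    par("C_blood", model$initial_amounts[["blood"]] / model$blood$volume,
        "mg_per_L", constant = "false"),
    paste0(vapply(model$tissues, function(tis)
      par(paste0("C_", tis$name),
          model$initial_amounts[[tis$name]] / tis$weight,
          "mg_per_kg", constant = "false"), character(1)), collapse = ""))

  # assignment rules: concentrations from amounts
  assign_rules <- paste0(
    sprintf('<assignmentRule variable="C_blood">%s</assignmentRule>',
            m_math(m_apply("divide", m_ci("A_blood"), m_ci("V_blood")))),
    paste0(vapply(model$tissues, function(tis) sprintf(
      '<assignmentRule variable="C_%s">%s</assignmentRule>', tis$name,
      m_math(m_apply("divide", m_ci(paste0("A_", tis$name)),
                     m_ci(paste0("W_", tis$name))))), character(1)),
      collapse = ""))

  # rate rules: flow-limited exchange, hepatic-style extraction, infusion
  venous <- function(tn) m_apply("divide", m_ci(paste0("C_", tn)),
                                 m_ci(paste0("PC_", tn)))
  blood_terms <- vapply(nm, function(tn) m_apply(
    "times", m_ci(paste0("Q_", tn)),
    m_apply("minus", venous(tn), m_ci("C_blood"))), character(1))
  rate_rules <- paste0(
    sprintf('<rateRule variable="A_blood">%s</rateRule>',
            m_math(m_apply("plus", paste0(blood_terms, collapse = ""),
                           m_ci("Dosing")))),
    paste0(vapply(nm, function(tn) sprintf(
      '<rateRule variable="A_%s">%s</rateRule>', tn,
      m_math(m_apply("minus",
        m_apply("times", m_ci(paste0("Q_", tn)),
                m_apply("minus", m_ci("C_blood"), venous(tn))),
        m_apply("times", m_ci(paste0("Q_", tn)),
                m_ci(paste0("ER_", tn)), m_ci("C_blood"))))),
      character(1)), collapse = ""))

  trigger <- function(boundary_param) sprintf(
    '<trigger initialValue="false" persistent="true">%s</trigger>',
    m_math(m_apply("geq", m_time(), m_ci(boundary_param))))
  events <- paste0(
    '<event id="exposure_start" useValuesFromTriggerTime="true">',
    trigger("Time_start_expos"),
    '<listOfEventAssignments><eventAssignment variable="Dosing">',
    m_math(m_ci("Dose")),
    '</eventAssignment></listOfEventAssignments></event>',
    '<event id="exposure_end" useValuesFromTriggerTime="true">',
    trigger("Time_end_expos"),
    '<listOfEventAssignments><eventAssignment variable="Dosing">',
    m_math(m_cn(0)),
    '</eventAssignment></listOfEventAssignments></event>')

  md <- model$metadata
  provenance <- list(writer = "pbpksim",
                     version = as.character(utils::packageVersion("pbpksim")),
                     source_model = if (!is.null(md)) md$model_name else "pbpk_model")
  notes <- sbml_notes(md, provenance)
  annotation <- sbml_annotation(md, provenance)

  model_id <- gsub("[^A-Za-z0-9_]", "_",
                   if (!is.null(md) && nzchar(md$model_name %||% ""))
                     md$model_name else "flow_limited_pbpk_model")
  if (!grepl("^[A-Za-z_]", model_id)) model_id <- paste0("m_", model_id)

  doc_str <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="2">', SBML_NS),
    sprintf('<model id="%s" name="%s" substanceUnits="mg" timeUnits="min" extentUnits="mg">',
            model_id, xml_escape(provenance$source_model)),
    notes, annotation,
    "<listOfUnitDefinitions>", unit_defs, "</listOfUnitDefinitions>",
    "<listOfCompartments>", compartments, "</listOfCompartments>",
    "<listOfSpecies>", species, "</listOfSpecies>",
    "<listOfParameters>", parameters, "</listOfParameters>",
    "<listOfRules>", assign_rules, rate_rules, "</listOfRules>",
    "<listOfEvents>", events, "</listOfEvents>",
    "</model></sbml>")
  structure(list(doc = xml2::read_xml(doc_str), provenance = provenance),
            class = "sbml_bundle")
}

sbml_notes <- function(md, provenance) {
  lines <- c(sprintf("Exported by %s %s", provenance$writer, provenance$version))
  if (!is.null(md)) {
    field <- function(label, value)
      if (!is.null(value) && any(nzchar(value)))
        sprintf("%s: %s", label, paste(value, collapse = " | ")) else NULL
    lines <- c(lines,
               field("Model name", md$model_name),
               field("Code version", md$code_version),
               field("Article citation", md$article_citation),
               field("Code citation", md$code_citation),
               if (length(md$authors))
                 sprintf("Authors: %s", paste(vapply(md$authors, function(a)
                   paste0(a$name,
                          if (!is.null(a$orcid)) paste0(" (", a$orcid, ")") else ""),
                   character(1)), collapse = "; ")),
               field("License", md$license),
               field("Sources", md$sources),
               field("AI tools disclosure", md$ai_tools_disclosure))
  }
  paste0('<notes><body xmlns="http://www.w3.org/1999/xhtml">',
         paste0("<p>", xml_escape(lines), "</p>", collapse = ""),
         "</body></notes>")
}

sbml_annotation <- function(md, provenance) {
  esc <- xml_escape
  inner <- sprintf('<ps:provenance writer="%s" version="%s"/>',
                   esc(provenance$writer), esc(provenance$version))
  if (!is.null(md)) {
    fields <- c(model_name = md$model_name %||% "",
                code_version = md$code_version %||% "",
                article_citation = md$article_citation %||% "",
                code_citation = md$code_citation %||% "",
                license = md$license %||% "",
                ai_tools_disclosure = md$ai_tools_disclosure %||% "")
    inner <- paste0(inner, paste0(
      sprintf('<ps:field name="%s">%s</ps:field>', names(fields), esc(fields)),
      collapse = ""))
    if (length(md$authors))
      inner <- paste0(inner, paste0(vapply(md$authors, function(a) sprintf(
        '<ps:author name="%s" orcid="%s" contact="%s"/>', esc(a$name),
        esc(a$orcid %||% ""), esc(a$contact %||% "")), character(1)),
        collapse = ""))
    if (length(md$sources))
      inner <- paste0(inner, paste0(
        sprintf("<ps:source>%s</ps:source>", esc(md$sources)), collapse = ""))
  }
  sprintf('<annotation><ps:metadata xmlns:ps="%s">%s</ps:metadata></annotation>',
          PBPKSIM_ANNOT_NS, inner)
}

#' Write an SBML document to disk
#'
#' @param x An `sbml_bundle` from [to_sbml()], or a [pbpk_model] (exported
#'   with `scenario` first).
#' @param path Destination `.xml`/`.sbml` path.
#' @param scenario Scenario used when `x` is a model.
#' @param pretty Indent the output for human readers (default `TRUE`).
#' @return The path, invisibly.
#' @export
write_sbml <- function(x, path, scenario = default_scenario(), pretty = TRUE) {
  if (inherits(x, "pbpk_model")) x <- to_sbml(x, scenario)
  stopifnot(inherits(x, "sbml_bundle"))
  xml2::write_xml(x$doc, path,
                  options = if (pretty) c("format", "as_xml") else "as_xml")
  invisible(path)
}

#' Read an SBML document from disk
#'
#' @param path Path to an SBML `.xml`/`.sbml` file.
#' @return An `sbml_bundle` (provenance recovered from the document's
#'   annotation when present).
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  prov <- list(writer = NA_character_, version = NA_character_,
               source_model = NA_character_)
  pnode <- xml2::xml_find_first(doc, ".//*[local-name() = 'provenance']")
  if (!inherits(pnode, "xml_missing")) {
    prov$writer <- xml2::xml_attr(pnode, "writer")
    prov$version <- xml2::xml_attr(pnode, "version")
  }
  mnode <- xml2::xml_find_first(doc, ".//*[local-name() = 'model']")
  if (!inherits(mnode, "xml_missing"))
    prov$source_model <- xml2::xml_attr(mnode, "name")
  structure(list(doc = doc, provenance = prov), class = "sbml_bundle")
}

#' @export
print.sbml_bundle <- function(x, ...) {
  cat("<sbml_bundle>", x$provenance$source_model %||% "", "\n")
  cat(sprintf("  writer: %s %s\n", x$provenance$writer, x$provenance$version))
  problems <- sbml_check(x)
  cat(sprintf("  consistency: %s\n",
              if (length(problems) == 0L) "OK" else
                paste(length(problems), "problem(s)")))
  invisible(x)
}

# nodes of the core SBML namespace by local name, searched under `node`
sbml_nodes <- function(node, name)
  xml2::xml_find_all(node, sprintf(".//*[local-name() = '%s']", name))

# attribute value with NA mapped to ""
attr_or <- function(node, attribute) {
  v <- xml2::xml_attr(node, attribute)
  if (is.na(v)) "" else v
}

#' Structural consistency check of an SBML document
#'
#' Verifies the internal consistency of a document of the dialect written by
#' [to_sbml()]: well-formed Level 3 root, unique identifiers, resolvable
#' references (species to compartments, rules and event assignments to
#' declared identifiers, `ci` symbols in math to declared identifiers), units
#' declared on every parameter and compartment and resolvable to a unit
#' definition or SBML base unit, at most one rule per variable, and events
#' carrying both trigger math and assignments.
#'
#' @param bundle An `sbml_bundle` (or an [xml2::xml_document]).
#' @return Character vector of problems; `character(0)` when the document is
#'   consistent.
#' @export
sbml_check <- function(bundle) {
  doc <- if (inherits(bundle, "sbml_bundle")) bundle$doc else bundle
  problems <- character()
  say <- function(...) problems <<- c(problems, sprintf(...))

  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml") say("root element is not <sbml>")
  if (!identical(xml2::xml_attr(root, "level"), "3"))
    say("document is not SBML Level 3")
  model <- xml2::xml_find_first(doc, ".//*[local-name() = 'model']")
  if (inherits(model, "xml_missing")) {
    say("no <model> element")
    return(problems)
  }

  base_units <- c("second", "litre", "kilogram", "gram", "metre", "mole",
                  "dimensionless", "item")
  unit_ids <- xml2::xml_attr(sbml_nodes(model, "unitDefinition"), "id")
  known_units <- c(unit_ids, base_units)

  comp <- sbml_nodes(model, "compartment")
  spec <- sbml_nodes(model, "species")
  pars <- sbml_nodes(model, "parameter")
  ids <- c(xml2::xml_attr(comp, "id"), xml2::xml_attr(spec, "id"),
           xml2::xml_attr(pars, "id"))
  if (anyNA(ids)) say("element without an id")
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) say("duplicate identifier '%s'", d)

  comp_ids <- xml2::xml_attr(comp, "id")
  for (i in seq_along(spec)) {
    cref <- xml2::xml_attr(spec[[i]], "compartment")
    if (is.na(cref) || !cref %in% comp_ids)
      say("species '%s' references unknown compartment '%s'",
          xml2::xml_attr(spec[[i]], "id"), cref %||% "")
    su <- xml2::xml_attr(spec[[i]], "substanceUnits")
    if (is.na(su) || !su %in% known_units)
      say("species '%s' lacks resolvable substance units",
          xml2::xml_attr(spec[[i]], "id"))
  }
  for (nodes in list(comp, pars))
    for (i in seq_along(nodes)) {
      u <- xml2::xml_attr(nodes[[i]], "units")
      if (is.na(u) || !nzchar(u))
        say("'%s' has no units attribute", xml2::xml_attr(nodes[[i]], "id"))
      else if (!u %in% known_units)
        say("'%s' uses undefined unit '%s'", xml2::xml_attr(nodes[[i]], "id"), u)
    }

  rules <- c(sbml_nodes(model, "assignmentRule"), sbml_nodes(model, "rateRule"))
  rule_vars <- vapply(rules, function(r) xml2::xml_attr(r, "variable"),
                      character(1))
  for (v in rule_vars[!rule_vars %in% ids])
    say("rule targets undeclared variable '%s'", v)
  for (v in unique(rule_vars[duplicated(rule_vars)]))
    say("variable '%s' is targeted by more than one rule", v)
  for (r in rules)
    if (length(sbml_nodes(r, "math")) == 0L)
      say("rule for '%s' has no math", xml2::xml_attr(r, "variable"))

  # every symbol used in math must be declared (the time csymbol is implicit)
  ci <- trimws(xml2::xml_text(sbml_nodes(model, "ci")))
  for (s in unique(ci[!ci %in% ids]))
    say("math references undeclared symbol '%s'", s)

  for (ev in sbml_nodes(model, "event")) {
    if (length(sbml_nodes(ev, "trigger")) == 0L ||
        length(sbml_nodes(ev, "math")) == 0L)
      say("event '%s' lacks trigger math", xml2::xml_attr(ev, "id") %||% "?")
    ea <- sbml_nodes(ev, "eventAssignment")
    if (length(ea) == 0L)
      say("event '%s' has no assignments", xml2::xml_attr(ev, "id") %||% "?")
    for (a in ea) {
      v <- xml2::xml_attr(a, "variable")
      if (is.na(v) || !v %in% ids)
        say("event assignment targets undeclared variable '%s'", v %||% "")
    }
  }
  problems
}

#' Reconstruct a PBPK model and scenario from SBML
#'
#' Inverse of [to_sbml()] for documents in the dialect it writes (amount
#' species governed by rate rules, assignment-rule concentrations, an
#' event-switched `Dosing` parameter).  All numeric fields round-trip
#' exactly, and compartment order follows the species order of the document.
#' Documents containing constructs outside this dialect (reactions, function
#' definitions, algebraic rules) are rejected with an error naming the first
#' unsupported construct.
#'
#' @param bundle An `sbml_bundle` from [to_sbml()] or [read_sbml()].
#' @return A list with elements `model` and `scenario`.
#' @export
from_sbml <- function(bundle) {
  doc <- if (inherits(bundle, "sbml_bundle")) bundle$doc else bundle
  model_node <- xml2::xml_find_first(doc, ".//*[local-name() = 'model']")
  if (inherits(model_node, "xml_missing"))
    stop("not an SBML document: no <model> element", call. = FALSE)
  for (construct in c("reaction", "functionDefinition", "algebraicRule",
                      "initialAssignment", "constraint"))
    if (length(sbml_nodes(model_node, construct)) > 0L)
      stop(sprintf("unsupported model: contains <%s> elements, which this flow-limited dialect does not use",
                   construct), call. = FALSE)

  pars <- sbml_nodes(model_node, "parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                           xml2::xml_attr(pars, "id"))
  need <- function(id) {
    if (!id %in% names(pvals))
      stop(sprintf("unsupported model: required parameter '%s' not found", id),
           call. = FALSE)
    pvals[[id]]
  }

  spec <- sbml_nodes(model_node, "species")
  sp_ids <- xml2::xml_attr(spec, "id")
  sp_amounts <- as.numeric(xml2::xml_attr(spec, "initialAmount"))
  if (!"A_blood" %in% sp_ids)
    stop("unsupported model: no 'A_blood' species", call. = FALSE)
  tissue_names <- sub("^A_", "", sp_ids[sp_ids != "A_blood"])
  if (length(tissue_names) == 0L || any(!grepl("^A_", sp_ids)))
    stop("unsupported model: species identifiers must be 'A_<compartment>'",
         call. = FALSE)

  rate_vars <- vapply(sbml_nodes(model_node, "rateRule"),
                      function(r) xml2::xml_attr(r, "variable"), character(1))
  missing_rr <- setdiff(sp_ids, rate_vars)
  if (length(missing_rr) > 0L)
    stop(sprintf("unsupported model: species '%s' has no rate rule",
                 missing_rr[1L]), call. = FALSE)

  tissues <- lapply(tissue_names, function(tn)
    pbpk_tissue(tn, weight = need(paste0("W_", tn)),
                flow = need(paste0("Q_", tn)),
                partition = need(paste0("PC_", tn)),
                extraction = need(paste0("ER_", tn))))
  init <- sp_amounts[match(c("A_blood", paste0("A_", tissue_names)), sp_ids)]

  metadata <- annotation_metadata(model_node)
  model <- pbpk_model(
    blood = pbpk_blood(volume = need("V_blood"),
                       cardiac_output = need("QC"),
                       weight = if ("W_blood" %in% names(pvals))
                         pvals[["W_blood"]] else need("V_blood")),
    tissues = tissues,
    body_weight = need("BW"),
    initial_amounts = init,
    metadata = metadata,
    tolerance = 1e-3)
  scenario <- pbpk_scenario(dose = need("Dose"),
                            t_start = need("Time_start_simul"),
                            t_end = need("Time_end_simul"),
                            expos_start = need("Time_start_expos"),
                            expos_end = need("Time_end_expos"))
  list(model = model, scenario = scenario)
}

annotation_metadata <- function(model_node) {
  meta <- xml2::xml_find_first(model_node, ".//*[local-name() = 'metadata']")
  if (inherits(meta, "xml_missing")) return(NULL)
  fields <- sbml_nodes(meta, "field")
  vals <- stats::setNames(xml2::xml_text(fields),
                          xml2::xml_attr(fields, "name"))
  vals <- vals[nzchar(vals)]
  if (!"model_name" %in% names(vals)) return(NULL)
  authors <- lapply(sbml_nodes(meta, "author"), function(a) {
    out <- list(name = attr_or(a, "name"))
    if (nzchar(attr_or(a, "orcid"))) out$orcid <- attr_or(a, "orcid")
    if (nzchar(attr_or(a, "contact"))) out$contact <- attr_or(a, "contact")
    out
  })
  getval <- function(k) if (k %in% names(vals)) vals[[k]] else NULL
  pbpk_metadata(model_name = vals[["model_name"]],
                code_version = getval("code_version"),
                article_citation = getval("article_citation"),
                code_citation = getval("code_citation"),
                authors = authors,
                license = getval("license"),
                sources = xml2::xml_text(sbml_nodes(meta, "source")),
                ai_tools_disclosure = getval("ai_tools_disclosure"))
}
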