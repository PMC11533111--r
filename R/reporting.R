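# Model annotations, the machine-checkable reporting checklist, the
# naming-convention linter, and the results-table writer.

#' Descriptive model annotations
#'
#' The minimum descriptive information that should accompany a published
#' model: name, version, mutually citing article and code, authors with
#' ORCIDs and contact details, license, sources, and an explicit disclosure
#' of any AI tools used on the code.
#'
#' @param model_name Model name (required, non-empty).
#' @param code_version Code version: date and/or identifier.
#' @param article_citation Citation/DOI of the article describing the model.
#' @param code_citation Citation/DOI of the deposited code.
#' @param authors List of author entries, each a list with `name` (required)
#'   and optional `orcid` and `contact`.
#' @param license SPDX-style license identifier, e.g. `"CC-BY-4.0"`.
#' @param sources Character vector of literature sources for parameters and
#'   structure.
#' @param ai_tools_disclosure Statement on AI-tool use; supply `"none"` when
#'   none were used.  `NULL` means undisclosed.
#' @return An object of class `pbpk_metadata`.
#' @export
pbpk_metadata <- function(model_name, code_version = NULL,
                          article_citation = NULL, code_citation = NULL,
                          authors = list(), license = NULL,
                          sources = character(), ai_tools_disclosure = NULL) {
  if (!is.character(model_name) || length(model_name) != 1L || !nzchar(model_name))
    stop("model_name must be a non-empty string", call. = FALSE)
  if (length(authors) > 0L)
    for (a in authors)
      if (!is.list(a) || is.null(a$name))
        stop("each author entry must be a list with at least a 'name'",
             call. = FALSE)
  structure(list(model_name = model_name, code_version = code_version,
                 article_citation = article_citation,
                 code_citation = code_citation, authors = authors,
                 license = license, sources = as.character(sources),
                 ai_tools_disclosure = ai_tools_disclosure),
            class = "pbpk_metadata")
}

#' @export
print.pbpk_metadata <- function(x, ...) {
  cat("<pbpk_metadata>", x$model_name, "\n")
  if (!is.null(x$code_version)) cat("  version: ", x$code_version, "\n")
  if (!is.null(x$license)) cat("  license: ", x$license, "\n")
  if (length(x$authors))
    cat("  authors: ", paste(vapply(x$authors, `[[`, character(1), "name"),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Read model annotations from a manifest file
#'
#' @param path JSON or YAML manifest whose keys match the arguments of
#'   [pbpk_metadata()].
#' @return A `pbpk_metadata` object.
#' @export
read_metadata <- function(path) {
  man <- read_structured(path)
  do.call(pbpk_metadata, man[intersect(names(man), names(formals(pbpk_metadata)))])
}

# parse a JSON or YAML file into a plain list
read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
}

.checklist_items <- function() list(
  list(id = "model_name", description = "Model is named",
       check = function(md, model, result) nzchar(md$model_name %||% "")),
  list(id = "code_version", description = "Code version (date/identifier) recorded",
       check = function(md, model, result) nzchar(md$code_version %||% "")),
  list(id = "article_citation", description = "Article describing the model is cited",
       check = function(md, model, result) nzchar(md$article_citation %||% "")),
  list(id = "code_citation", description = "Deposited model code is cited",
       check = function(md, model, result) nzchar(md$code_citation %||% "")),
  list(id = "authors", description = "Code authors with contact details listed",
       check = function(md, model, result)
         length(md$authors) > 0L &&
           all(vapply(md$authors, function(a) nzchar(a$name %||% ""), logical(1)))),
  list(id = "license", description = "License declared",
       check = function(md, model, result) nzchar(md$license %||% "")),
  list(id = "sources", description = "Parameter/structure sources cited",
       check = function(md, model, result) length(md$sources) > 0L),
  list(id = "ai_tools_disclosure",
       description = "AI-tool use explicitly disclosed (possibly 'none')",
       check = function(md, model, result) !is.null(md$ai_tools_disclosure)),
  list(id = "parameter_units", description = "All parameters carry units",
       check = function(md, model, result) inherits(model, "pbpk_model")),
  list(id = "initial_values", description = "Initial state values recorded with units",
       check = function(md, model, result)
         inherits(model, "pbpk_model") && !is.null(model$initial_amounts)),
  list(id = "simulation_results",
       description = "Quantitative simulation results provided",
       check = function(md, model, result) inherits(result, "pbpk_sim")),
  list(id = "solver_recorded",
       description = "Solver and tolerances recorded with the results",
       check = function(md, model, result)
         inherits(result, "pbpk_sim") &&
           all(c("method", "rtol", "atol") %in% names(result$diagnostics))))

.checklist_informational <- function() data.frame(
  id = c("model_purpose", "conceptual_diagram", "applicability_domain"),
  description = c("Model purpose stated clearly (prose quality)",
                  "Conceptual model diagram provided and consistent",
                  "Applicability domain (species, sex, chemical group) described"),
  status = "not-applicable",
  evidence = "requires human judgement; not machine-checkable",
  stringsAsFactors = FALSE)

#' Evaluate the machine-checkable reporting checklist
#'
#' Scores a model, its annotations and (optionally) attached simulation
#' results against the objectively checkable subset of community reporting
#' recommendations (MIRIAM/MIASE-style): metadata completeness, units on all
#' parameters, recorded initial values, attached quantitative results, and a
#' recorded solver configuration.  Recommendations that require human
#' judgement are reported as `not-applicable` and excluded from the score.
#'
#' @param metadata A [pbpk_metadata] object (or `NULL`).
#' @param model A [pbpk_model] (or `NULL`).
#' @param result A `pbpk_sim` from [pbpk_simulate()], or `NULL` when no
#'   simulation results are attached.
#' @return An object of class `pbpk_checklist`: a data frame with columns
#'   `id`, `description`, `status` (`pass`/`fail`/`not-applicable`) and
#'   `evidence`, with attribute `score` = passes / applicable items.
#' @export
checklist_evaluate <- function(metadata = NULL, model = NULL, result = NULL) {
  if (is.null(metadata))
    metadata <- structure(list(model_name = ""), class = "pbpk_metadata")
  rows <- lapply(.checklist_items(), function(item) {
    ok <- isTRUE(item$check(metadata, model, result))
    data.frame(id = item$id, description = item$description,
               status = if (ok) "pass" else "fail",
               evidence = if (ok) "present" else "missing or incomplete",
               stringsAsFactors = FALSE)
  })
  report <- rbind(do.call(rbind, rows), .checklist_informational())
  applicable <- report$status != "not-applicable"
  score <- sum(report$status == "pass") / sum(applicable)
  structure(report, score = score, class = c("pbpk_checklist", "data.frame"))
}

#' @export
print.pbpk_checklist <- function(x, ...) {
  cat(sprintf("Reporting checklist: score %.2f (%d/%d applicable items pass)\n",
              attr(x, "score"), sum(x$status == "pass"),
              sum(x$status != "not-applicable")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%-14s] %-22s %s\n", x$status[i], x$id[i], x$description[i]))
  invisible(x)
}

#' Checklist score
#'
#' @param report A `pbpk_checklist`.
#' @return Fraction of applicable items passed, in `[0, 1]`.
#' @export
checklist_score <- function(report) {
  stopifnot(inherits(report, "pbpk_checklist"))
  attr(report, "score")
}

.naming_prefixes <- c(A = "amount", C = "concentration", Q = "blood flow",
                      W = "weight", V = "volume", PC = "partition coefficient",
                      ER = "extraction ratio")
.naming_whole_words <- c("BW", "QC", "CL", "Dose", "Dosing",
                         "Time_start_simul", "Time_end_simul",
                         "Time_start_expos", "Time_end_expos")

#' Lint model-component names against the standard abbreviation conventions
#'
#' PBPK component names conventionally start with a quantity prefix
#' (`A_`, `C_`, `Q_`, `W_`, `V_`, `PC_`, `ER_`) followed by the full tissue
#' name in lower case (e.g. `Q_liver_total`, `PC_others`); a small set of
#' whole-word abbreviations (`BW`, `QC`, `Dose`, `Time_*`) is also accepted.
#' Non-conforming names are reported with a suggested rename: a missing
#' underscore after a recognised prefix is inserted, and the suggestion
#' itself always conforms.
#'
#' @param names Character vector of component identifiers.
#' @return A data frame with columns `name`, `conforming` (logical),
#'   `suggestion` (`NA` when conforming or no mechanical fix exists) and
#'   `note`.
#' @export
naming_check <- function(names) {
  stopifnot(is.character(names))
  prefix_re <- paste0("^(", paste(names(.naming_prefixes), collapse = "|"),
                      ")_[a-z][a-z0-9_]*$")
  glued_re <- paste0("^(", paste(names(.naming_prefixes), collapse = "|"),
                     ")([a-z][A-Za-z0-9_]*)$")
  out <- lapply(names, function(nm) {
    if (nm %in% .naming_whole_words || grepl(prefix_re, nm))
      return(data.frame(name = nm, conforming = TRUE,
                        suggestion = NA_character_, note = "conforming",
                        stringsAsFactors = FALSE))
    if (grepl(glued_re, nm)) {
      pre <- sub(glued_re, "\\1", nm)
      rest <- tolower(sub(glued_re, "\\2", nm))
      return(data.frame(
        name = nm, conforming = FALSE,
        suggestion = paste0(pre, "_", rest),
        note = sprintf("missing underscore after %s prefix (%s)",
                       pre, .naming_prefixes[[pre]]),
        stringsAsFactors = FALSE))
    }
    data.frame(name = nm, conforming = FALSE, suggestion = NA_character_,
               note = "does not start with a recognised quantity prefix (A_, C_, Q_, W_, V_, PC_, ER_)",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write the simulation results table
#'
#' Writes the full time-resolved results (amounts, concentrations, cumulative
#' dosed and eliminated mass) to a CSV that round-trips at full double
#' precision, so later reproducibility checks can compare numbers exactly.
#'
#' @param result A `pbpk_sim` object with a non-empty grid.
#' @param path Destination CSV path.
#' @return The path, invisibly.
#' @export
write_results_table <- function(result, path) {
  stopifnot(inherits(result, "pbpk_sim"))
  if (length(result$times) == 0L)
    stop("empty simulation result: nothing to write", call. = FALSE)
  df <- as.data.frame(result)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write results table to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path CSV path.
#' @return A data frame with numeric columns.
#' @export
read_results_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
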