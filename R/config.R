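# Model and scenario definition via structured configuration files.  Keys
# use the conventional code abbreviations (BW, V_blood, QC, W_liver,
# Q_liver_total, PC_liver, ER_liver, Dose, Time_start_expos, ...); tissues
# are discovered from the W_<tissue> keys, in order of appearance.

#' Read a model (and optional scenario) from a configuration file
#'
#' The configuration is a flat JSON or YAML mapping using the standard
#' abbreviations: `BW` (kg), `V_blood` (L), optional `W_blood` (kg, defaults
#' to `V_blood`), `QC` (L/min), then per tissue `W_<name>` (kg), `Q_<name>`
#' (L/min; `Q_<name>_total` is accepted as an alias), `PC_<name>` (L/kg),
#' optional `ER_<name>` (default 0) and optional initial amount `A_<name>`
#' (mg, default 0, `A_blood` for the blood pool).  Scenario keys `Dose`,
#' `Time_start_simul`, `Time_end_simul`, `Time_start_expos`,
#' `Time_end_expos` are all optional and default to the standard infusion
#' scenario.
#'
#' Published parameter sets are usually rounded, so user-supplied models are
#' validated at a relative closure tolerance of `1e-3`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @param tolerance Relative closure tolerance for validation (default
#'   `1e-3`).
#' @return A list with elements `model` ([pbpk_model]) and `scenario`
#'   ([pbpk_scenario]).
#' @export
read_model_config <- function(path, tolerance = 1e-3) {
  cfg <- read_structured(path)
  if (!is.list(cfg)) stop("configuration must be a key-value mapping", call. = FALSE)
  get_num <- function(key, default = NULL) {
    v <- cfg[[key]]
    if (is.null(v)) return(default)
    if (!is.numeric(v) || length(v) != 1L)
      stop(sprintf("configuration key '%s' must be a numeric scalar", key),
           call. = FALSE)
    v
  }
  for (key in c("BW", "V_blood", "QC"))
    if (is.null(cfg[[key]]))
      stop(sprintf("configuration is missing required key '%s'", key),
           call. = FALSE)

  keys <- names(cfg)
  tissue_names <- sub("^W_", "", keys[grepl("^W_", keys)])
  tissue_names <- setdiff(tissue_names, "blood")
  if (length(tissue_names) == 0L)
    stop("configuration defines no tissues (no W_<tissue> keys)", call. = FALSE)

  tissues <- lapply(tissue_names, function(nm) {
    q <- get_num(paste0("Q_", nm), get_num(paste0("Q_", nm, "_total")))
    if (is.null(q))
      stop(sprintf("no blood flow Q_%s (or Q_%s_total) for tissue '%s'",
                   nm, nm, nm), call. = FALSE)
    pc <- get_num(paste0("PC_", nm))
    if (is.null(pc))
      stop(sprintf("no partition coefficient PC_%s for tissue '%s'", nm, nm),
           call. = FALSE)
    pbpk_tissue(nm, weight = get_num(paste0("W_", nm)), flow = q,
                partition = pc, extraction = get_num(paste0("ER_", nm), 0))
  })

  init <- c(get_num("A_blood", 0),
            vapply(tissue_names, function(nm) get_num(paste0("A_", nm), 0),
                   numeric(1)))
  model <- pbpk_model(
    blood = pbpk_blood(volume = get_num("V_blood"),
                       cardiac_output = get_num("QC"),
                       weight = get_num("W_blood", get_num("V_blood"))),
    tissues = tissues,
    body_weight = get_num("BW"),
    initial_amounts = init,
    metadata = if (!is.null(cfg$model_name)) pbpk_metadata(cfg$model_name),
    tolerance = tolerance)

  scenario <- pbpk_scenario(
    dose = get_num("Dose", 100),
    t_start = get_num("Time_start_simul", 0),
    t_end = get_num("Time_end_simul", 400),
    expos_start = get_num("Time_start_expos", 0),
    expos_end = get_num("Time_end_expos", 200))

  list(model = model, scenario = scenario)
}

#' Write a model and scenario to a configuration file
#'
#' Inverse of [read_model_config()]; the format (JSON or YAML) follows the
#' file extension.
#'
#' @param model A [pbpk_model].
#' @param scenario A [pbpk_scenario].
#' @param path Destination `.json`, `.yaml` or `.yml` path.
#' @return The path, invisibly.
#' @export
write_model_config <- function(model, scenario, path) {
  stopifnot(inherits(model, "pbpk_model"), inherits(scenario, "pbpk_scenario"))
  nm <- names(model$tissues)
  cfg <- c(as.list(coef(model)),
           as.list(stats::setNames(as.numeric(model$initial_amounts),
                                   paste0("A_", names(model$initial_amounts)))),
           list(Dose = scenario$dose,
                Time_start_simul = scenario$t_start,
                Time_end_simul = scenario$t_end,
                Time_start_expos = scenario$expos_start,
                Time_end_expos = scenario$expos_end))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(cfg, path, precision = 17)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}
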