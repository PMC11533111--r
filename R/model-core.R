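# Core domain types for flow-limited PBPK models: tissues, the central blood
# pool, the assembled model, and the exposure scenario.  All state is carried
# as chemical amounts (mg); concentrations are derived quantities.

#' Define a perfusion-limited tissue compartment
#'
#' A tissue is characterised by its wet weight, the blood flow perfusing it,
#' the tissue:blood partition coefficient of the chemical, and the extraction
#' ratio (the fraction of chemical removed from blood in a single pass, used
#' to model hepatic or renal elimination).
#'
#' @param name Compartment identifier, e.g. `"liver"`.  Must be non-empty and
#'   distinct from `"blood"`.
#' @param weight Tissue wet weight in kg (> 0).
#' @param flow Blood flow to the tissue in L/min (> 0).
#' @param partition Tissue:blood partition coefficient in L/kg (> 0).
#' @param extraction Extraction ratio, unitless in `[0, 1]`.  Default 0
#'   (non-eliminating tissue).
#' @return An object of class `pbpk_tissue`.
#' @examples
#' liver <- pbpk_tissue("liver", weight = 1.898, flow = 1.6575,
#'                      partition = 1.5, extraction = 0.7)
#' @export
pbpk_tissue <- function(name, weight, flow, partition, extraction = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (identical(name, "blood"))
    stop("'blood' is reserved for the central blood pool", call. = FALSE)
  for (v in c(weight = weight, flow = flow, partition = partition,
              extraction = extraction))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("tissue parameters must be finite numeric scalars", call. = FALSE)
  if (weight <= 0) stop("tissue weight must be > 0 kg", call. = FALSE)
  if (flow <= 0) stop("tissue blood flow must be > 0 L/min", call. = FALSE)
  if (partition <= 0) stop("partition coefficient must be > 0 L/kg", call. = FALSE)
  if (extraction < 0 || extraction > 1)
    stop("extraction ratio must lie in [0, 1]", call. = FALSE)
  structure(list(name = name, weight = weight, flow = flow,
                 partition = partition, extraction = extraction),
            class = "pbpk_tissue")
}

#' Define the central blood pool
#'
#' The blood compartment is described by its volume (used for the
#' concentration in mg/L), its mass (used in the body-weight closure check),
#' and the cardiac output.  By the usual convention blood density is taken as
#' 1 kg/L so the mass defaults to the volume.
#'
#' @param volume Total blood volume in L (> 0).
#' @param cardiac_output Cardiac output in L/min (> 0); in a closed
#'   flow-limited model it must equal the sum of tissue blood flows.
#' @param weight Blood mass in kg; defaults to `volume` (density 1 kg/L).
#' @return An object of class `pbpk_blood`.
#' @export
pbpk_blood <- function(volume, cardiac_output, weight = volume) {
  for (v in c(volume = volume, cardiac_output = cardiac_output, weight = weight))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("blood-pool parameters must be positive finite scalars", call. = FALSE)
  structure(list(volume = volume, weight = weight,
                 cardiac_output = cardiac_output),
            class = "pbpk_blood")
}

#' Assemble a flow-limited PBPK model
#'
#' Combines the blood pool and an ordered list of tissues into a whole-body
#' model.  Compartment order is blood first, then tissues in the order given;
#' every amount or concentration vector produced by the package respects it.
#' Construction enforces the physiological closure constraints: tissue weights
#' plus blood weight must sum to the body weight, and tissue blood flows must
#' sum to the cardiac output.
#'
#' @param blood A [pbpk_blood] object.
#' @param tissues A list of [pbpk_tissue] objects with unique names.
#' @param body_weight Body weight in kg.  Defaults to the sum of blood and
#'   tissue weights, which closes exactly.
#' @param initial_amounts Named or unnamed numeric vector of initial chemical
#'   amounts (mg), blood first; defaults to all zero.
#' @param metadata Optional [pbpk_metadata] annotations.
#' @param tolerance Relative closure tolerance applied at construction.
#'   Models built from derivation formulas close to `1e-9`; published models
#'   with rounded parameter values should be admitted with `tolerance = 1e-3`.
#' @return An object of class `pbpk_model`.
#' @seealso [validate_model()], [reference_model()], [pbpk_simulate()]
#' @export
pbpk_model <- function(blood, tissues, body_weight = NULL,
                       initial_amounts = NULL, metadata = NULL,
                       tolerance = 1e-9) {
  stopifnot(inherits(blood, "pbpk_blood"), is.list(tissues), length(tissues) >= 1L)
  for (tis in tissues)
    if (!inherits(tis, "pbpk_tissue"))
      stop("all tissues must be 'pbpk_tissue' objects", call. = FALSE)
  nm <- vapply(tissues, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("compartment names must be unique", call. = FALSE)
  names(tissues) <- nm
  if (is.null(body_weight))
    body_weight <- blood$weight + sum(vapply(tissues, `[[`, numeric(1), "weight"))
  if (!is.numeric(body_weight) || body_weight <= 0)
    stop("body weight must be a positive scalar", call. = FALSE)
  n <- length(tissues) + 1L
  if (is.null(initial_amounts)) initial_amounts <- numeric(n)
  if (length(initial_amounts) != n)
    stop(sprintf("initial_amounts must have length %d (blood + %d tissues)",
                 n, n - 1L), call. = FALSE)
  if (any(!is.finite(initial_amounts)) || any(initial_amounts < 0))
    stop("initial amounts must be finite and non-negative", call. = FALSE)
  initial_amounts <- stats::setNames(as.numeric(initial_amounts),
                                     c("blood", nm))
  if (!is.null(metadata) && !inherits(metadata, "pbpk_metadata"))
    stop("metadata must be a 'pbpk_metadata' object", call. = FALSE)
  model <- structure(list(blood = blood, tissues = tissues,
                          body_weight = body_weight,
                          initial_amounts = initial_amounts,
                          metadata = metadata),
                     class = "pbpk_model")
  findings <- validate_model(model, tolerance = tolerance)
  if (nrow(findings) > 0L)
    stop("model fails physiological-consistency validation:\n  ",
         paste(findings$message, collapse = "\n  "), call. = FALSE)
  model
}

#' Define an intravenous-infusion exposure scenario
#'
#' A constant-rate infusion running over `[expos_start, expos_end]` within the
#' simulation window `[t_start, t_end]`.  Times are minutes; the dosing
#' interval is closed at both endpoints.
#'
#' @param dose Infusion rate in mg/min (>= 0).
#' @param t_start,t_end Simulation window in min.
#' @param expos_start,expos_end Exposure window in min; must be nested inside
#'   the simulation window.
#' @return An object of class `pbpk_scenario`.
#' @export
pbpk_scenario <- function(dose = 100, t_start = 0, t_end = 400,
                          expos_start = 0, expos_end = 200) {
  for (v in c(dose, t_start, t_end, expos_start, expos_end))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("scenario fields must be finite numeric scalars", call. = FALSE)
  if (dose < 0) stop("infusion rate must be >= 0 mg/min", call. = FALSE)
  if (!(t_start <= expos_start && expos_start <= expos_end && expos_end <= t_end))
    stop("times must satisfy t_start <= expos_start <= expos_end <= t_end",
         call. = FALSE)
  structure(list(dose = dose, t_start = t_start, t_end = t_end,
                 expos_start = expos_start, expos_end = expos_end),
            class = "pbpk_scenario")
}

# vector of tissue attribute values, in compartment order
tissue_vec <- function(model, field)
  vapply(model$tissues, `[[`, numeric(1), field)

compartment_names <- function(model) c("blood", names(model$tissues))

#' Instantaneous infusion rate
#'
#' Piecewise-constant dosing input: `dose` while `t` lies in the closed
#' exposure interval, 0 outside it.
#'
#' @param t Time in min (finite numeric, vectorised).
#' @param scenario A [pbpk_scenario].
#' @return Infusion rate(s) in mg/min.
#' @export
dosing_rate <- function(t, scenario) {
  stopifnot(inherits(scenario, "pbpk_scenario"), all(is.finite(t)))
  ifelse(t >= scenario$expos_start & t <= scenario$expos_end,
         scenario$dose, 0)
}

#' Compartment concentrations from amounts
#'
#' Blood concentration is amount over blood volume (mg/L); each tissue
#' concentration is amount over tissue weight (mg/kg).
#'
#' @param amounts Numeric vector of chemical amounts in mg, blood first.
#' @param model A [pbpk_model].
#' @return Named numeric vector of concentrations in compartment order.
#' @export
concentrations <- function(amounts, model) {
  stopifnot(inherits(model, "pbpk_model"))
  amounts <- check_state(amounts, model)
  stats::setNames(
    amounts / c(model$blood$volume, tissue_vec(model, "weight")),
    compartment_names(model))
}

#' Compartment amounts from concentrations
#'
#' Inverse of [concentrations()]: multiplies blood concentration by blood
#' volume and tissue concentrations by tissue weights.
#'
#' @param conc Numeric vector of concentrations, blood first (mg/L, mg/kg).
#' @param model A [pbpk_model].
#' @return Named numeric vector of amounts in mg.
#' @export
compartment_amounts <- function(conc, model) {
  stopifnot(inherits(model, "pbpk_model"))
  conc <- check_state(conc, model)
  stats::setNames(
    conc * c(model$blood$volume, tissue_vec(model, "weight")),
    compartment_names(model))
}

check_state <- function(state, model) {
  if (!is.numeric(state) || length(state) != length(model$tissues) + 1L)
    stop(sprintf("state must be numeric of length %d (blood + %d tissues)",
                 length(model$tissues) + 1L, length(model$tissues)),
         call. = FALSE)
  as.numeric(state)
}

#' Right-hand side of the PBPK ODE system
#'
#' Net flow of chemical (mg/min) into each compartment under flow-limited
#' distribution.  Venous blood leaving a tissue is in equilibrium with it at
#' `C_tissue / PC_tissue`, so for each tissue
#' `dA_tissue/dt = Q * (C_blood - C_tissue/PC) - Q * ER * C_blood`,
#' and the blood pool receives the mirrored exchange terms plus the infusion:
#' `dA_blood/dt = sum(Q * (C_tissue/PC - C_blood)) + dosing_rate(t)`.
#'
#' @param t Time in min.
#' @param amounts State vector of amounts in mg, blood first.
#' @param model A [pbpk_model].
#' @param scenario A [pbpk_scenario].
#' @return Named derivative vector in mg/min.
#' @export
pbpk_rhs <- function(t, amounts, model, scenario) {
  stopifnot(inherits(model, "pbpk_model"), inherits(scenario, "pbpk_scenario"))
  amounts <- check_state(amounts, model)
  conc <- amounts / c(model$blood$volume, tissue_vec(model, "weight"))
  rhs_core(conc, model, dosing_rate(t, scenario))
}

# derivatives from concentrations and a scalar infusion rate
rhs_core <- function(conc, model, dose_rate) {
  q  <- tissue_vec(model, "flow")
  pc <- tissue_vec(model, "partition")
  er <- tissue_vec(model, "extraction")
  c_blood <- conc[1L]
  c_tis   <- conc[-1L]
  venous  <- c_tis / pc                      # venous blood leaving each tissue
  d_tis   <- q * (c_blood - venous) - q * er * c_blood
  d_blood <- sum(q * (venous - c_blood)) + dose_rate
  stats::setNames(c(d_blood, d_tis), compartment_names(model))
}

#' Instantaneous clearance rate
#'
#' Total elimination rate summed over eliminating tissues:
#' `CL = sum(Q_tissue * ER_tissue) * C_blood` in mg/min.  With a single
#' eliminating liver this is the classical hepatic clearance
#' `Q_liver_total * ER_liver * C_blood`.
#'
#' @inheritParams concentrations
#' @return Clearance rate in mg/min.
#' @export
clearance_rate <- function(amounts, model) {
  stopifnot(inherits(model, "pbpk_model"))
  amounts <- check_state(amounts, model)
  c_blood <- amounts[1L] / model$blood$volume
  sum(tissue_vec(model, "flow") * tissue_vec(model, "extraction")) * c_blood
}

#' Physiological-consistency validation
#'
#' Checks the closure constraints and parameter ranges of a model and reports
#' every violation as data rather than raising an error: body weight must
#' equal blood weight plus tissue weights, cardiac output must equal the sum
#' of tissue flows, all sizes and flows must be positive, extraction ratios
#' must lie in `[0, 1]`, and initial amounts must be non-negative.
#'
#' @param model A `pbpk_model` (or a bare list with the same fields, so that
#'   deliberately inconsistent models can be examined).
#' @param tolerance Relative tolerance for the weight and flow closure
#'   checks.  Use `1e-3` for models assembled from rounded published values.
#' @return A data frame of findings with columns `check`, `quantity`,
#'   `value`, `target`, `tolerance`, `message`; zero rows when the model is
#'   consistent.
#' @export
validate_model <- function(model, tolerance = 1e-3) {
  stopifnot(is.list(model), !is.null(model$blood), !is.null(model$tissues))
  finding <- function(check, quantity, value, target, message)
    data.frame(check = check, quantity = quantity, value = value,
               target = target, tolerance = tolerance, message = message,
               stringsAsFactors = FALSE)
  out <- list()
  w <- tissue_vec(model, "weight")
  q <- tissue_vec(model, "flow")
  pc <- tissue_vec(model, "partition")
  er <- tissue_vec(model, "extraction")
  nm <- names(model$tissues)

  w_total <- model$blood$weight + sum(w)
  if (abs(w_total - model$body_weight) > tolerance * model$body_weight)
    out <- c(out, list(finding(
      "weight_closure", "body_weight", w_total, model$body_weight,
      sprintf("blood + tissue weights sum to %.6g kg but body weight is %.6g kg (rel. tol. %g)",
              w_total, model$body_weight, tolerance))))
  q_total <- sum(q)
  if (abs(q_total - model$blood$cardiac_output) >
      tolerance * model$blood$cardiac_output)
    out <- c(out, list(finding(
      "flow_closure", "cardiac_output", q_total, model$blood$cardiac_output,
      sprintf("tissue flows sum to %.6g L/min but cardiac output is %.6g L/min (rel. tol. %g)",
              q_total, model$blood$cardiac_output, tolerance))))
  for (v in c(volume = model$blood$volume, weight = model$blood$weight,
              cardiac_output = model$blood$cardiac_output))
    if (!is.finite(v) || v <= 0)
      out <- c(out, list(finding("range", paste0("blood_", names(v)), v, NA,
                                 "blood-pool parameters must be positive")))
  bad <- function(x) !is.finite(x) | x <= 0
  for (i in seq_along(nm)) {
    if (bad(w[i]) || bad(q[i]) || bad(pc[i]))
      out <- c(out, list(finding(
        "range", nm[i], NA, NA,
        sprintf("tissue '%s': weight, flow and partition coefficient must be positive", nm[i]))))
    if (!is.finite(er[i]) || er[i] < 0 || er[i] > 1)
      out <- c(out, list(finding(
        "range", paste0("ER_", nm[i]), er[i], NA,
        sprintf("extraction ratio of '%s' is %.4g, outside [0, 1]", nm[i], er[i]))))
  }
  if (!is.null(model$initial_amounts) && any(model$initial_amounts < 0))
    out <- c(out, list(finding(
      "range", "initial_amounts", min(model$initial_amounts), 0,
      "initial amounts must be non-negative")))
  if (anyDuplicated(nm))
    out <- c(out, list(finding("names", "tissues", NA, NA,
                               "compartment names must be unique")))
  if (length(out) == 0L)
    return(data.frame(check = character(), quantity = character(),
                      value = numeric(), target = numeric(),
                      tolerance = numeric(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' @export
print.pbpk_tissue <- function(x, ...) {
  cat(sprintf("<pbpk_tissue> %s: W = %g kg, Q = %g L/min, PC = %g L/kg, ER = %g\n",
              x$name, x$weight, x$flow, x$partition, x$extraction))
  invisible(x)
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("Flow-limited PBPK model: blood + %d tissue compartment(s)\n",
              length(x$tissues)))
  cat(sprintf("  body weight %g kg, blood volume %g L, cardiac output %g L/min\n",
              x$body_weight, x$blood$volume, x$blood$cardiac_output))
  for (tis in x$tissues)
    cat(sprintf("  %-10s W = %-8g kg  Q = %-8g L/min  PC = %-5g L/kg  ER = %g\n",
                tis$name, tis$weight, tis$flow, tis$partition, tis$extraction))
  if (!is.null(x$metadata) && nzchar(x$metadata$model_name %||% ""))
    cat("  metadata:", x$metadata$model_name, "\n")
  invisible(x)
}

#' @export
print.pbpk_scenario <- function(x, ...) {
  cat(sprintf("IV infusion %g mg/min over [%g, %g] min; simulated [%g, %g] min\n",
              x$dose, x$expos_start, x$expos_end, x$t_start, x$t_end))
  invisible(x)
}

#' Extract model parameters as a named vector
#'
#' Returns the full parameter set using the field's conventional
#' abbreviations (`BW`, `V_blood`, `QC`, `Q_<tissue>`, `W_<tissue>`,
#' `PC_<tissue>`, `ER_<tissue>`).
#'
#' @param object A [pbpk_model].
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
coef.pbpk_model <- function(object, ...) {
  nm <- names(object$tissues)
  c(stats::setNames(c(object$body_weight, object$blood$volume,
                      object$blood$weight, object$blood$cardiac_output),
                    c("BW", "V_blood", "W_blood", "QC")),
    stats::setNames(tissue_vec(object, "weight"), paste0("W_", nm)),
    stats::setNames(tissue_vec(object, "flow"), paste0("Q_", nm)),
    stats::setNames(tissue_vec(object, "partition"), paste0("PC_", nm)),
    stats::setNames(tissue_vec(object, "extraction"), paste0("ER_", nm)))
}

#' @export
summary.pbpk_model <- function(object, ...) {
  print(object)
  findings <- validate_model(object)
  if (nrow(findings) == 0L) cat("  consistency: OK\n")
  else cat("  consistency findings:", nrow(findings), "\n")
  invisible(list(coefficients = coef.pbpk_model(object), findings = findings))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
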