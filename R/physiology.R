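# Reference physiology for European adults and the default exposure
# scenario.  Derived quantities (liver weight, residual tissue weight, liver
# and residual blood flows) are computed from primitive reference inputs and
# stored unrounded; rounding to the published precision happens only in the
# display formatter.

.reference_inputs <- list(
  man = list(sex = "man", body_weight = 73, liver_weight_fraction = 0.026,
             blood_volume = 5.3, cardiac_output = 6.5,
             liver_flow_fraction = 0.255),
  woman = list(sex = "woman", body_weight = 60, liver_weight_fraction = 0.026,
               blood_volume = 3.9, cardiac_output = 5.9,
               liver_flow_fraction = 0.270))

#' Primitive reference inputs for an adult physiology
#'
#' Reference body weight, liver weight fraction, blood volume, cardiac output
#' and hepatic flow fraction for European adult men and women (ICRP-style
#' reference values).
#'
#' @param sex `"man"` or `"woman"`.
#' @return A list with fields `sex`, `body_weight` (kg),
#'   `liver_weight_fraction`, `blood_volume` (L), `cardiac_output` (L/min)
#'   and `liver_flow_fraction`.
#' @export
reference_inputs <- function(sex = c("man", "woman")) {
  sex <- match.arg(sex)
  .reference_inputs[[sex]]
}

#' Derive tissue weights and flows from primitive reference inputs
#'
#' Applies the closure formulas: liver weight is the liver fraction of body
#' weight; blood weight equals blood volume (density 1 kg/L); the residual
#' "others" compartment takes the remaining weight; hepatic flow is the flow
#' fraction of cardiac output and "others" receives the remainder.  All
#' results are exact (unrounded).
#'
#' @param inputs A list as returned by [reference_inputs()].
#' @return A list with a `blood` [pbpk_blood] and numeric fields `W_liver`,
#'   `W_others` (kg), `Q_liver_total`, `Q_others` (L/min).
#' @export
derive_physiology <- function(inputs) {
  stopifnot(is.list(inputs))
  for (f in c("body_weight", "liver_weight_fraction", "blood_volume",
              "cardiac_output", "liver_flow_fraction"))
    if (!is.numeric(inputs[[f]]) || inputs[[f]] < 0)
      stop(sprintf("reference input '%s' missing or negative", f), call. = FALSE)
  w_liver <- inputs$liver_weight_fraction * inputs$body_weight
  w_others <- inputs$body_weight - w_liver - inputs$blood_volume
  q_liver <- inputs$liver_flow_fraction * inputs$cardiac_output
  q_others <- inputs$cardiac_output - q_liver
  if (w_others <= 0)
    stop("derived residual tissue weight is non-positive", call. = FALSE)
  if (q_others <= 0)
    stop("derived residual blood flow is non-positive", call. = FALSE)
  list(blood = pbpk_blood(volume = inputs$blood_volume,
                          cardiac_output = inputs$cardiac_output),
       W_liver = w_liver, W_others = w_others,
       Q_liver_total = q_liver, Q_others = q_others)
}

#' Reference three-compartment PBPK model
#'
#' Builds the packaged adult-man or adult-woman model: blood, liver and a
#' lumped "others" compartment, with the exemplar pharmacokinetic parameters
#' for a hypothetical hydrophobic chemical (`PC_liver` = 1.5 L/kg,
#' `PC_others` = 3 L/kg, hepatic extraction ratio 0.70) and all initial
#' amounts zero.  The partition coefficients and extraction ratio can be
#' overridden per chemical.
#'
#' @param sex `"man"` or `"woman"`.
#' @param pc_liver,pc_others Tissue:blood partition coefficients (L/kg).
#' @param er_liver Hepatic extraction ratio in `[0, 1]`.
#' @return A validated [pbpk_model].
#' @examples
#' m <- reference_model("man")
#' coef(m)
#' @export
reference_model <- function(sex = c("man", "woman"),
                            pc_liver = 1.5, pc_others = 3, er_liver = 0.70) {
  if (is.character(sex) && length(sex) == 1L && !sex %in% names(.reference_inputs))
    stop(sprintf("unknown sex '%s'; accepted labels: %s", sex,
                 paste(names(.reference_inputs), collapse = ", ")),
         call. = FALSE)
  sex <- match.arg(sex)
  inp <- reference_inputs(sex)
  phys <- derive_physiology(inp)
  pbpk_model(
    blood = phys$blood,
    tissues = list(
      pbpk_tissue("liver", weight = phys$W_liver, flow = phys$Q_liver_total,
                  partition = pc_liver, extraction = er_liver),
      pbpk_tissue("others", weight = phys$W_others, flow = phys$Q_others,
                  partition = pc_others, extraction = 0)),
    body_weight = inp$body_weight,
    metadata = pbpk_metadata(
      model_name = sprintf("Three-compartment flow-limited PBPK reference model (adult %s)", sex),
      code_version = paste0("pbpksim ", as.character(utils::packageVersion("pbpksim"))),
      license = "CC-BY-4.0",
      sources = c("ICRP reference anatomical and physiological values for adults",
                  "Exemplar partition coefficients and hepatic extraction ratio for a hypothetical hydrophobic chemical")),
    tolerance = 1e-9)
}

#' Default intravenous-infusion exposure scenario
#'
#' Constant infusion of 100 mg/min from 0 to 200 min, followed by 200 min of
#' depuration (simulation window 0 to 400 min).
#'
#' @return A [pbpk_scenario].
#' @export
default_scenario <- function() {
  pbpk_scenario(dose = 100, t_start = 0, t_end = 400,
                expos_start = 0, expos_end = 200)
}

# Display rounding that mirrors the published reference table cell by cell:
# product-derived weights and all flows print at 3 significant figures
# (keeping trailing zeros, e.g. 1.90); difference-derived weights print at 4
# significant figures with trailing zeros trimmed (65.8, 54.54).
printed_value <- function(x, rule = c("sf3", "sf4trim")) {
  rule <- match.arg(rule)
  if (rule == "sf3")
    return(formatC(signif(x, 3), digits = 3, format = "fg", flag = "#"))
  s <- formatC(signif(x, 4), digits = 4, format = "fg", flag = "#")
  s <- sub("\\.?0+$", "", s)
  sub("\\.$", "", s)
}

#' Reference physiology at published precision
#'
#' Returns the derived physiological parameters for one sex, both as exact
#' (unrounded) values and formatted at the precision conventionally printed
#' in reference tables.
#'
#' @param sex `"man"` or `"woman"`.
#' @return A data frame with columns `parameter`, `value` (exact numeric),
#'   `printed` (character) and `units`.
#' @export
printed_physiology <- function(sex = c("man", "woman")) {
  sex <- match.arg(sex)
  phys <- derive_physiology(reference_inputs(sex))
  data.frame(
    parameter = c("W_liver", "W_others", "Q_liver_total", "Q_others"),
    value = c(phys$W_liver, phys$W_others, phys$Q_liver_total, phys$Q_others),
    printed = c(printed_value(phys$W_liver, "sf3"),
                printed_value(phys$W_others, "sf4trim"),
                printed_value(phys$Q_liver_total, "sf3"),
                printed_value(phys$Q_others, "sf3")),
    units = c("kg", "kg", "L/min", "L/min"),
    stringsAsFactors = FALSE)
}

#' Reference physiology table
#'
#' The full reference parameter table for adult men and women (primitive and
#' derived quantities), as shipped with the package in
#' `inst/extdata/reference_physiology.csv`.
#'
#' @return A data frame with columns `parameter`, `man`, `woman`, `units`,
#'   `source`.
#' @export
reference_physiology_table <- function() {
  path <- system.file("extdata", "reference_physiology.csv",
                      package = "pbpksim", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
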