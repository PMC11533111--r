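---
title: "Flow-limited PBPK simulation: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow-limited PBPK simulation: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbpksim)
```

## The model and its assumptions

`pbpksim` simulates whole-body pharmacokinetics with a central blood pool
and `N` peripheral tissue compartments, each connected to blood by
perfusion. The state is the chemical amount per compartment, `A` (mg);
concentrations are derived algebraically (`C_blood = A_blood / V_blood` in
mg/L, `C_t = A_t / W_t` in mg/kg). The model is *flow-limited*: tissue
uptake is limited by blood perfusion, so venous blood leaving a tissue is
assumed to be at equilibrium with it, at concentration `C_t / PC_t` where
`PC_t` is the tissue:blood partition coefficient (L/kg). Each tissue may
also eliminate the chemical with a single-pass extraction ratio
`ER_t` in `[0, 1]`, giving the net flows

$$\frac{dA_t}{dt} = Q_t\left(C_{blood} - \frac{C_t}{PC_t}\right) - Q_t\,ER_t\,C_{blood},
\qquad
\frac{dA_{blood}}{dt} = \sum_t Q_t\left(\frac{C_t}{PC_t} - C_{blood}\right) + \mathrm{Dosing}(t).$$

Exposure is an intravenous infusion at constant rate `Dose` (mg/min) over a
closed interval `[Time_start_expos, Time_end_expos]` inside the simulation
window. The instantaneous clearance is
$CL = \sum_t Q_t\,ER_t\,C_{blood}$ (mg/min).

Assumptions worth keeping in mind: distribution is perfusion-limited (no
membrane-permeability limitation), elimination is linear in blood
concentration (no saturable Michaelis–Menten kinetics), the only exposure
route is intravenous, and physiology is static (no growth, pregnancy or
age scaling). These match the scope of the packaged reference model; the
types generalise the compartment list so user models may have any number of
tissues, but not beyond these structural assumptions.

A model is *physiologically consistent* when it closes: blood weight plus
tissue weights equal body weight, and tissue flows sum to the cardiac
output. `validate_model()` reports violations as data (a findings data
frame), never as exceptions, so inconsistent candidate models can be
examined. Two closure tolerances are used deliberately: models built from
derivation formulas must close to relative `1e-9` (they close to `1e-12` in
practice), while user-supplied models read from configuration files are
admitted at relative `1e-3`, because published parameter tables print
rounded values whose sums close only approximately.

## Reference physiology and the exemplar chemical

`reference_model("man")` / `"woman"` build the packaged three-compartment
exemplar (blood, liver, lumped "others") from primitive reference inputs:
body weight 73 / 60 kg, blood volume 5.3 / 3.9 L, cardiac output 6.5 /
5.9 L/min, liver weight fraction 0.026, hepatic flow fraction 0.255 /
0.270. Derived values are stored unrounded (e.g. liver weight
`0.026 * 73 = 1.898` kg, hepatic flow `0.255 * 6.5 = 1.6575` L/min);
`printed_physiology()` renders them at the precision conventionally printed
in reference tables, mirroring each cell's rounding rule (3 significant
figures with kept trailing zeros for product-derived weights and flows,
e.g. `1.90`; 4 significant figures with trimmed trailing zeros for the
difference-derived residual weight, e.g. `65.8`, `54.54`). Storing exact
values and rounding only at display time keeps closure exact and display
faithful at the same time.

The exemplar pharmacokinetic parameters describe a hypothetical hydrophobic
chemical with higher affinity for fatty tissues than for blood:
`PC_liver = 1.5` L/kg, `PC_others = 3` L/kg, hepatic `ER = 0.70` (a
high-clearance scenario). They are illustrative defaults, overridable per
chemical; blood density is taken as 1 kg/L so blood weight equals blood
volume numerically (measured densities span roughly 0.99–1.06 g/mL; the
fields are kept separate so other conventions remain expressible). Initial
amounts default to zero (clean body at exposure start).

The default scenario infuses 100 mg/min over 0–200 min and follows with
200 min of depuration (simulation window 0–400 min).

## Numerics

**Integration.** The system is linear with piecewise-constant forcing.
`pbpk_simulate()` integrates with `deSolve` (default `lsoda`, a
stiff-capable method in the tradition of MATLAB's `ode23s`-style solvers;
this system is only mildly stiff, and an explicit `ode45` run at tight
tolerance agrees to better than `1e-6` relative — a cross-check in the test
suite). Default tolerances are relative `1e-8` and absolute `1e-10` mg,
exposed as arguments. The output grid is 1 min by default over the
simulation window.

**Events.** Rather than letting the solver detect the dosing
discontinuity, integration is restarted at `Time_start_expos` and
`Time_end_expos`, so every solver step sees a smooth right-hand side. This
is deterministic and solver-agnostic. The dosing interval is closed at both
endpoints — the point value at the boundary is measure-zero for the
integral, but fixing the convention makes `dosing_rate()` and the SBML
event encoding (both triggers fire on `time >= boundary`) exactly
consistent.

**Mass balance.** The cumulative eliminated mass is integrated as an extra
state (the integral of the clearance rate) alongside the amounts, while the
cumulative infused mass has the closed form
`Dose * (clamp(t) - Time_start_expos)`. The audit
`|sum(A) + eliminated - dosed| / max(dosed, 1)` therefore compares the
solver against an exact quantity; on the reference run the maximum residual
is at round-off level (~`7e-16`), far inside the `1e-6` requirement.
`residuals()` on a simulation returns the pointwise residuals.

**Degenerate inputs.** Amounts more negative than `-1e-9` mg abort the run
as a solver failure; tiny negative round-off is clipped to zero. A model
whose total extraction `sum(Q_t * ER_t)` is zero has no bounded steady
state under constant infusion, and `steady_state_infusion()` says so
explicitly.

**Steady state.** `steady_state_infusion()` assembles the system's
coefficient matrix column by column from the (linear) right-hand side and
solves the linear system — no hard-coded formulas — so it works for any
tissue count. The closed form
`C_blood_ss = Dose / sum(Q_t ER_t)`, `C_t_ss = PC_t (1 - ER_t) C_blood_ss`
serves as the independent oracle in the tests; for the reference man at
100 mg/min, `C_blood_ss = 100 / 1.16025 = 86.18832` mg/L,
`C_liver_ss = 38.785` mg/kg, `C_others_ss = 258.565` mg/kg. A 10,000-min
infusion simulated on a 25-min output grid lands within `1e-13` relative of
the solve (the coarse output grid does not affect solver accuracy, only
reporting density).

## SBML dialect

`to_sbml()` writes SBML Level 3 Version 2 with the ODEs as **rate rules**
on amount species and the concentrations as assignment-rule parameters.
Rate rules (not reactions) were chosen because the model is posed as ODEs
on amounts — encoding it as reactions would invent stoichiometry the model
does not have. The infusion is a non-constant `Dosing` parameter toggled by
two events at the exposure boundaries; its initial value honours the event
semantics at `t = 0` (equal to `Dose` when the exposure starts with the
simulation, else 0). Every parameter and compartment carries a unit
(`min`, `L`, `kg`, `mg` and the derived `mg_per_min`, `L_per_min`,
`mg_per_L`, `mg_per_kg`, `L_per_kg` are declared as unit definitions).
Identifiers use the field's conventional abbreviations (`A_blood`,
`C_liver`, `Q_<tissue>`, `PC_<tissue>`, ...), so the document is readable
without a legend. Model annotations are embedded twice: human-readable
notes and a machine-readable annotation element from which `from_sbml()`
recovers them.

Numbers are serialised with 17 significant digits, so export followed by
import reproduces every numeric field bit-exactly and re-simulation of the
round-tripped model is identical. `from_sbml()` accepts only this dialect:
documents containing reactions, function definitions, algebraic rules,
initial assignments or constraints are rejected with an error naming the
first unsupported construct, which is honest about scope rather than
silently misreading third-party models. `sbml_check()` performs the
structural consistency checking (unique and resolvable identifiers, units
on everything, one rule per variable, complete events); it is a property of
this dialect, not a full implementation of the SBML validation
specification.

## Reporting checklist and naming linter

`checklist_evaluate()` scores only objectively checkable reporting items:
metadata completeness (name, version, mutually citing article and code,
authors, license, sources, explicit AI-tools disclosure), units on all
parameters, recorded initial values, attached quantitative simulation
results, and a recorded solver configuration. Items that require human
judgement (prose quality of the model purpose, the conceptual diagram, the
applicability domain) are surfaced as `not-applicable` and excluded from
the score — scoring them would be fake precision. The score is passes over
applicable items, and removing a satisfied field can only lower it.

`naming_check()` implements the demonstrably used conventions: a quantity
prefix (`A_`, `C_`, `Q_`, `W_`, `V_`, `PC_`, `ER_`) followed by the full
tissue name in lower case, plus a short whole-word list (`BW`, `QC`,
`Dose`, `Time_*`). A glued prefix (`Qliver`) gets a mechanical rename
suggestion that itself conforms (idempotence is property-tested); names
with no recognisable prefix are flagged without a guess.

## What the tests do and do not show

The randomized model generator used in the property tests samples 1–4
tissues with positive weights, flows, partition coefficients in
`[0.3, 5]` and at least one eliminating tissue, then derives body weight
and cardiac output from the sampled tissues so closure holds by
construction. This exercises the generic N-tissue code paths — mass-balance
identities, linearity of the right-hand side, steady-state solve versus
closed form, SBML round-trip — under a fixed seed. It does not emulate real
biological variability (no parameter correlations, no measurement error, no
saturable kinetics), so green tests certify the mathematics and the
plumbing, not predictive validity for any real chemical: validation against
experimental concentration data and sensitivity analysis are out of scope.

Problem sizes were chosen to keep the whole suite in seconds: the reference
run uses the 1-min grid (401 points), the steady-state run 10,000 min at a
25-min output grid, and the property loops 5–20 replicates each.

## Known limitations

Single exposure route (intravenous infusion), linear elimination only,
flow-limited distribution only, no age/species scaling, SBML import limited
to the package's own rate-rule dialect, and no spreadsheet output (the
results table is full-precision CSV).
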