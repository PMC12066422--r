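#' @include asipbpk-package.R
NULL

## The 14 perfusion-limited compartments of the whole-body model. Order is the
## canonical state ordering used throughout the ODE system.
.TISSUES <- c("lung", "heart", "brain", "muscle", "adipose", "skin",
              "spleen", "pancreas", "liver", "stomach", "gut", "bone",
              "kidney", "rest_of_body")

## Tissues whose tissue:plasma partition coefficients are carried explicitly on
## a CompoundRecord; the remaining three (stomach, pancreas, rest_of_body) are
## filled by surrogate rules in effectiveKp().
.KP_TISSUES <- c("bone", "brain", "adipose", "heart", "kidney", "gut",
                 "liver", "lung", "muscle", "skin", "spleen")

#' Tissue compartment names of the whole-body model
#'
#' @return Character vector of the 14 tissue compartment names, in the
#'   canonical state ordering.
#' @export
#' @examples
#' pbpkTissues()
pbpkTissues <- function() .TISSUES

#' Tissues with explicit partition coefficients
#'
#' @return Character vector of the 11 tissues whose tissue:plasma Kp values a
#'   [CompoundRecord] carries explicitly.
#' @export
kpTissues <- function() .KP_TISSUES

.is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# ---------------------------------------------------------------------------
# VirtualSubject
# ---------------------------------------------------------------------------

#' VirtualSubject: the reference human physiology
#'
#' Holds the tissue volumes (L) and regional blood flows (L/h) of the 14
#' perfusion-limited compartments plus the venous and arterial blood volumes.
#' Lung blood flow equals cardiac output; the non-lung flows sum to cardiac
#' output (flow balance), which the validity method enforces.
#'
#' @slot bodyWeight body weight in kg.
#' @slot tissues data.frame with columns `name`, `volume` (L), `blood_flow`
#'   (L/h); one row per tissue in [pbpkTissues()] order.
#' @slot venousVolume mixed venous blood volume, L.
#' @slot arterialVolume arterial blood volume, L.
#' @seealso [referenceSubject()]
#' @export
setClass("VirtualSubject",
         representation(bodyWeight = "numeric",
                        tissues = "data.frame",
                        venousVolume = "numeric",
                        arterialVolume = "numeric"))

setValidity("VirtualSubject", function(object) {
  msg <- character()
  tt <- object@tissues
  if (!.is_scalar_num(object@bodyWeight) || object@bodyWeight <= 0)
    msg <- c(msg, "bodyWeight must be a positive number")
  if (!all(c("name", "volume", "blood_flow") %in% names(tt)))
    msg <- c(msg, "tissues must have columns name, volume, blood_flow")
  else {
    if (!identical(sort(tt$name), sort(.TISSUES)))
      msg <- c(msg, sprintf("tissue names must be exactly {%s}",
                            paste(.TISSUES, collapse = ", ")))
    if (any(!is.finite(tt$volume)) || any(tt$volume <= 0))
      msg <- c(msg, "all tissue volumes must be positive")
    if (any(!is.finite(tt$blood_flow)) || any(tt$blood_flow <= 0))
      msg <- c(msg, "all tissue blood flows must be positive")
    if (identical(sort(tt$name), sort(.TISSUES))) {
      q_lung <- tt$blood_flow[tt$name == "lung"]
      q_rest <- sum(tt$blood_flow[tt$name != "lung"])
      if (abs(q_lung - q_rest) > 1e-6 * q_lung)
        msg <- c(msg, sprintf(
          "flow imbalance: lung flow (cardiac output) %.4f L/h != sum of non-lung flows %.4f L/h",
          q_lung, q_rest))
    }
  }
  for (sl in c("venousVolume", "arterialVolume"))
    if (!.is_scalar_num(slot(object, sl)) || slot(object, sl) <= 0)
      msg <- c(msg, paste(sl, "must be a positive number"))
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# CompoundRecord
# ---------------------------------------------------------------------------

#' CompoundRecord: drug-specific PBPK/PD parameters
#'
#' One record carries every compound-specific quantity the simulator needs:
#' ADME parameters, per-tissue tissue:plasma partition coefficients with their
#' global scaler, and the CYP11B1/CYP11B2 inhibition constants for the PD
#' layer.
#'
#' @slot name compound name.
#' @slot smiles SMILES string (whitespace-free).
#' @slot mw molecular weight, g/mol.
#' @slot fup fraction unbound in plasma (0, 1].
#' @slot bpr blood-to-plasma concentration ratio.
#' @slot giKa first-order gastrointestinal absorption rate constant, 1/h.
#' @slot clApp apparent (whole-body) clearance, L/h.
#' @slot vssPerKg steady-state volume of distribution, L/kg (metadata used in
#'   clearance derivation; the simulated distribution volume emerges from the
#'   Kp values).
#' @slot kp named numeric vector of tissue:plasma partition coefficients over
#'   the 11 tissues in [kpTissues()].
#' @slot kpScaler global multiplier applied to every Kp before use.
#' @slot ic50Cyp11b1 IC50 toward 11beta-hydroxylase, nmol/L.
#' @slot ic50Cyp11b2 IC50 toward aldosterone synthase, nmol/L.
#' @slot provenance free-text note on parameter origin (e.g. literature vs
#'   model-predicted); does not affect behaviour.
#' @seealso [compoundRecord()], [asiLibrary()], [applyCalibration()]
#' @export
setClass("CompoundRecord",
         representation(name = "character", smiles = "character",
                        mw = "numeric", fup = "numeric", bpr = "numeric",
                        giKa = "numeric", clApp = "numeric",
                        vssPerKg = "numeric", kp = "numeric",
                        kpScaler = "numeric",
                        ic50Cyp11b1 = "numeric", ic50Cyp11b2 = "numeric",
                        provenance = "character"),
         prototype(provenance = ""))

setValidity("CompoundRecord", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  chk <- function(val, nm, lo = 0, hi = Inf, lo_open = TRUE, hi_closed = FALSE) {
    if (!.is_scalar_num(val)) return(paste(nm, "must be a finite number"))
    ok_lo <- if (lo_open) val > lo else val >= lo
    ok_hi <- if (hi_closed) val <= hi else val < hi
    if (!ok_lo || !ok_hi) paste0(nm, " = ", val, " outside its valid range")
    else NULL
  }
  msg <- c(msg,
           chk(object@mw, "mw"),
           chk(object@fup, "fup", 0, 1, hi_closed = TRUE),
           chk(object@bpr, "bpr"),
           chk(object@giKa, "giKa"),
           chk(object@clApp, "clApp"),
           chk(object@vssPerKg, "vssPerKg"),
           chk(object@kpScaler, "kpScaler"),
           chk(object@ic50Cyp11b1, "ic50Cyp11b1"),
           chk(object@ic50Cyp11b2, "ic50Cyp11b2"))
  if (!all(.KP_TISSUES %in% names(object@kp)))
    msg <- c(msg, sprintf("kp must be named over {%s}; missing: %s",
                          paste(.KP_TISSUES, collapse = ", "),
                          paste(setdiff(.KP_TISSUES, names(object@kp)),
                                collapse = ", ")))
  else if (any(!is.finite(object@kp[.KP_TISSUES])) ||
           any(object@kp[.KP_TISSUES] <= 0))
    msg <- c(msg, "all kp values must be positive and finite")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# CalibrationFactors
# ---------------------------------------------------------------------------

#' CalibrationFactors: the two-parameter calibration transform
#'
#' The distribution/elimination calibration multiplies the Kp scaler by
#' `kpFactor` and divides the apparent clearance by `clDivisor`.
#'
#' @slot kpFactor multiplier on the Kp scaler (unitless, > 0).
#' @slot clDivisor divisor on apparent clearance (unitless, > 0).
#' @seealso [calibrationFactors()], [applyCalibration()]
#' @export
setClass("CalibrationFactors",
         representation(kpFactor = "numeric", clDivisor = "numeric"))

setValidity("CalibrationFactors", function(object) {
  msg <- character()
  if (!.is_scalar_num(object@kpFactor) || object@kpFactor <= 0)
    msg <- c(msg, "kpFactor must be a positive number")
  if (!.is_scalar_num(object@clDivisor) || object@clDivisor <= 0)
    msg <- c(msg, "clDivisor must be a positive number")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# DoseRegimen
# ---------------------------------------------------------------------------

#' DoseRegimen: oral dosing schedule
#'
#' @slot dose dose amount per administration, mg.
#' @slot nDoses number of administrations (>= 1).
#' @slot interval dosing interval, h (required > 0 when nDoses > 1).
#' @slot route administration route; only "oral" is supported.
#' @seealso [doseRegimen()], [simulatePbpk()]
#' @export
setClass("DoseRegimen",
         representation(dose = "numeric", nDoses = "integer",
                        interval = "numeric", route = "character"),
         prototype(route = "oral"))

setValidity("DoseRegimen", function(object) {
  msg <- character()
  if (!.is_scalar_num(object@dose) || object@dose < 0)
    msg <- c(msg, "dose must be a non-negative number (mg)")
  if (length(object@nDoses) != 1L || is.na(object@nDoses) || object@nDoses < 1L)
    msg <- c(msg, "nDoses must be an integer >= 1")
  if (object@nDoses > 1L &&
      (!.is_scalar_num(object@interval) || object@interval <= 0))
    msg <- c(msg, "interval must be > 0 h when nDoses > 1")
  if (!identical(object@route, "oral"))
    msg <- c(msg, "route must be 'oral'")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ConcentrationTimeSeries
# ---------------------------------------------------------------------------

#' ConcentrationTimeSeries: simulated drug disposition over time
#'
#' @slot times output time grid, h; strictly increasing, starting at 0.
#' @slot plasmaConc venous plasma concentration, ng/mL, one value per time.
#' @slot amounts matrix (times x compartments) of drug amounts in mg; columns
#'   are `depot`, the 14 tissues, `venous`, `arterial`, `eliminated`.
#' @seealso [simulatePbpk()], [ncaSummary()], [inhibitionTimecourse()]
#' @export
setClass("ConcentrationTimeSeries",
         representation(times = "numeric", plasmaConc = "numeric",
                        amounts = "matrix"))

setValidity("ConcentrationTimeSeries", function(object) {
  msg <- character()
  n <- length(object@times)
  if (n < 1L || object@times[1L] != 0)
    msg <- c(msg, "times must start at 0")
  if (n > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@plasmaConc) != n)
    msg <- c(msg, "plasmaConc must have one value per time point")
  if (nrow(object@amounts) != n)
    msg <- c(msg, "amounts must have one row per time point")
  want <- c("depot", .TISSUES, "venous", "arterial", "eliminated")
  if (!identical(colnames(object@amounts), want))
    msg <- c(msg, "amounts columns must be depot, the 14 tissues, venous, arterial, eliminated")
  if (any(object@amounts < 0))
    msg <- c(msg, "all compartment amounts must be non-negative")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# PDProfile
# ---------------------------------------------------------------------------

#' PDProfile: enzyme-inhibition time course
#'
#' Percent inhibition of aldosterone synthase (CYP11B2) and 11beta-hydroxylase
#' (CYP11B1) over time, derived from free plasma drug concentration through the
#' Emax model.
#'
#' @slot times h.
#' @slot inhibitionCyp11b2 percent inhibition of aldosterone synthase.
#' @slot inhibitionCyp11b1 percent inhibition of 11beta-hydroxylase.
#' @slot e0 baseline effect, percent (default 0).
#' @slot imax maximal inhibition, percent (default 100).
#' @seealso [inhibitionTimecourse()], [emaxInhibition()]
#' @export
setClass("PDProfile",
         representation(times = "numeric",
                        inhibitionCyp11b2 = "numeric",
                        inhibitionCyp11b1 = "numeric",
                        e0 = "numeric", imax = "numeric"),
         prototype(e0 = 0, imax = 100))

setValidity("PDProfile", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@inhibitionCyp11b2) != n ||
      length(object@inhibitionCyp11b1) != n)
    msg <- c(msg, "inhibition vectors must match the time grid length")
  tol <- 1e-9
  for (sl in c("inhibitionCyp11b2", "inhibitionCyp11b1")) {
    v <- slot(object, sl)
    if (length(v) == n && n > 0 &&
        (any(v < -tol) || any(v > object@imax + tol)))
      msg <- c(msg, paste(sl, "must lie in [0, imax]"))
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# StudyDesign
# ---------------------------------------------------------------------------

#' StudyDesign: a SAD or MAD simulation design
#'
#' @slot compound compound name (must exist in the library passed to
#'   [runStudy()]).
#' @slot design "SAD" (single ascending dose) or "MAD" (multiple ascending
#'   dose).
#' @slot doses dose grid, mg.
#' @slot interval dosing interval, h (MAD; default 24).
#' @slot nDoses doses per subject (1 for SAD).
#' @slot duration simulated horizon, h.
#' @seealso [defaultDesigns()], [runStudy()]
#' @export
setClass("StudyDesign",
         representation(compound = "character", design = "character",
                        doses = "numeric", interval = "numeric",
                        nDoses = "integer", duration = "numeric"))

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (!object@design %in% c("SAD", "MAD"))
    msg <- c(msg, "design must be 'SAD' or 'MAD'")
  if (length(object@doses) == 0L || any(!is.finite(object@doses)) ||
      any(object@doses <= 0))
    msg <- c(msg, "doses must be a non-empty vector of positive amounts (mg)")
  if (identical(object@design, "SAD") && object@nDoses != 1L)
    msg <- c(msg, "SAD designs administer a single dose")
  if (identical(object@design, "MAD")) {
    if (object@nDoses < 2L)
      msg <- c(msg, "MAD designs need nDoses >= 2")
    ## horizon must cover at least 5 dosing intervals plus a washout window
    if (object@duration < 5 * object@interval + object@interval)
      msg <- c(msg, "MAD duration must cover >= 5 dosing intervals plus washout")
  }
  if (object@duration < (object@nDoses - 1L) * object@interval + 24)
    msg <- c(msg, "duration must cover the last dosing interval")
  if (length(msg)) msg else TRUE
})
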