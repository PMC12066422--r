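#' @include AllClasses.R
NULL

#' Construct a CompoundRecord
#'
#' Constructor validating every compound-specific parameter the simulator
#' consumes. Embedded whitespace in the SMILES string (as found in published
#' tables) is stripped.
#'
#' @param name compound name.
#' @param smiles SMILES string.
#' @param mw molecular weight, g/mol.
#' @param fup fraction unbound in plasma, (0, 1].
#' @param bpr blood-to-plasma concentration ratio, > 0.
#' @param giKa first-order GI absorption rate constant, 1/h.
#' @param clApp apparent clearance, L/h.
#' @param vssPerKg steady-state volume of distribution, L/kg.
#' @param kp named numeric vector of tissue:plasma partition coefficients over
#'   [kpTissues()].
#' @param kpScaler global Kp multiplier, > 0.
#' @param ic50Cyp11b1 IC50 toward 11beta-hydroxylase, nmol/L.
#' @param ic50Cyp11b2 IC50 toward aldosterone synthase, nmol/L.
#' @param provenance free-text note on parameter origin.
#' @return A validated [CompoundRecord-class].
#' @export
#' @examples
#' rec <- compoundRecord("toy", "C", mw = 16.04, fup = 0.5, bpr = 1,
#'                       giKa = 1, clApp = 5, vssPerKg = 1,
#'                       kp = setNames(rep(1, 11), kpTissues()),
#'                       kpScaler = 1, ic50Cyp11b1 = 100, ic50Cyp11b2 = 10)
compoundRecord <- function(name, smiles, mw, fup, bpr, giKa, clApp, vssPerKg,
                           kp, kpScaler, ic50Cyp11b1, ic50Cyp11b2,
                           provenance = "") {
  new("CompoundRecord", name = as.character(name),
      smiles = gsub("[[:space:]]+", "", as.character(smiles)),
      mw = as.numeric(mw), fup = as.numeric(fup), bpr = as.numeric(bpr),
      giKa = as.numeric(giKa), clApp = as.numeric(clApp),
      vssPerKg = as.numeric(vssPerKg), kp = kp,
      kpScaler = as.numeric(kpScaler),
      ic50Cyp11b1 = as.numeric(ic50Cyp11b1),
      ic50Cyp11b2 = as.numeric(ic50Cyp11b2),
      provenance = as.character(provenance))
}

#' Construct CalibrationFactors
#'
#' @param kpFactor multiplier applied to the Kp scaler (default 0.85, the
#'   value obtained by calibrating the model compound against clinical data).
#' @param clDivisor divisor applied to apparent clearance (default 4.7).
#' @return A [CalibrationFactors-class].
#' @export
calibrationFactors <- function(kpFactor = 0.85, clDivisor = 4.7) {
  new("CalibrationFactors", kpFactor = as.numeric(kpFactor),
      clDivisor = as.numeric(clDivisor))
}

# ---------------------------------------------------------------------------
# ADME parameter-derivation formulas
# ---------------------------------------------------------------------------

#' Fraction unbound from plasma protein binding ratio
#'
#' `f_up = 1 - ppbr`, where ppbr is the fraction of drug bound to plasma
#' proteins.
#'
#' @param ppbr plasma protein binding ratio, in `[0, 1)`.
#' @return Fraction unbound, unitless.
#' @export
#' @examples
#' fupFromPpbr(0.74)  # 0.26
fupFromPpbr <- function(ppbr) {
  if (!is.numeric(ppbr) || any(!is.finite(ppbr)) ||
      any(ppbr < 0) || any(ppbr >= 1))
    stop("ppbr must lie in [0, 1)")
  1 - ppbr
}

#' Apparent clearance from Vss and half-life
#'
#' `CL_app = Vss * 0.693 / half_life` (one-compartment elimination identity).
#'
#' @param vss steady-state volume of distribution, L.
#' @param halfLife elimination half-life, h.
#' @return Apparent clearance, L/h.
#' @export
#' @examples
#' clappFromVssHalflife(100, 6.93)  # 10
clappFromVssHalflife <- function(vss, halfLife) {
  if (!is.numeric(vss) || any(!is.finite(vss)) || any(vss <= 0))
    stop("vss must be positive (L)")
  if (!is.numeric(halfLife) || any(!is.finite(halfLife)) || any(halfLife <= 0))
    stop("halfLife must be positive (h)")
  vss * 0.693 / halfLife
}

#' Effective intestinal permeability from apparent permeability
#'
#' Log-linear regression `log10(Peff) = 0.6795 * log10(Papp) - 0.3355`.
#' Operand units follow the source regression's as-published convention.
#'
#' @param papp apparent (cell-monolayer) permeability, > 0.
#' @return Effective intestinal permeability on the regression's scale.
#' @export
peffFromPapp <- function(papp) {
  if (!is.numeric(papp) || any(!is.finite(papp)) || any(papp <= 0))
    stop("papp must be positive")
  10^(0.6795 * log10(papp) - 0.3355)
}

#' GI absorption rate constant from effective permeability
#'
#' `gi_ka = 2 * Peff / radius`, with the small-intestinal radius defaulting to
#' 1.25 cm (2.5 cm diameter).
#'
#' @param peff effective intestinal permeability, cm/h.
#' @param radius small-intestinal radius, cm.
#' @return First-order absorption rate constant, 1/h.
#' @export
#' @examples
#' gikaFromPeff(0.625)  # 1
gikaFromPeff <- function(peff, radius = 1.25) {
  if (!is.numeric(peff) || any(!is.finite(peff)) || any(peff <= 0))
    stop("peff must be positive")
  if (!is.numeric(radius) || any(!is.finite(radius)) || any(radius <= 0))
    stop("radius must be positive (cm)")
  2 * peff / radius
}

#' Molecular weight from a SMILES string
#'
#' Parses the SMILES (whitespace stripped first; published tables often embed
#' spaces), adds implicit hydrogens, and returns the average molecular weight
#' from a standard atomic-weight table, rounded to 2 decimals.
#'
#' @param smiles a single SMILES string.
#' @return Molecular weight, g/mol, rounded to 2 decimals.
#' @export
#' @examples
#' \dontrun{
#' mwFromSmiles("C")  # 16.04 (methane)
#' }
mwFromSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("smiles must be a single non-empty string")
  clean <- gsub("[[:space:]]+", "", smiles)
  props <- tryCatch(
    suppressWarnings(
      ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", clean, identity))),
    error = function(e)
      stop(sprintf("could not parse SMILES '%s': %s", clean,
                   conditionMessage(e)), call. = FALSE))
  mw <- suppressWarnings(as.numeric(props$MW))
  if (length(mw) != 1L || !is.finite(mw) || mw <= 0)
    stop(sprintf("could not parse SMILES '%s': no valid molecule produced",
                 clean))
  round(mw, 2)
}

# ---------------------------------------------------------------------------
# Calibration transform
# ---------------------------------------------------------------------------

#' Apply the two-parameter calibration to a compound record
#'
#' Returns a copy of `record` with `kpScaler <- kpScaler * kpFactor` and
#' `clApp <- clApp / clDivisor`; every other field is unchanged. The defaults
#' (0.85, 4.7) are the factors obtained by calibrating the model compound
#' against clinical plasma data and are applied unchanged to all compounds.
#' Computation keeps full precision; round reported values to 2 decimals for
#' table comparison.
#'
#' @param record a [CompoundRecord-class].
#' @param factors a [CalibrationFactors-class] (default `{0.85, 4.7}`).
#' @return A calibrated [CompoundRecord-class].
#' @export
#' @examples
#' lib <- asiLibrary()
#' cal <- applyCalibration(lib[["Baxdrostat"]])
#' round(c(kpScaler(cal), apparentClearance(cal)), 2)
applyCalibration <- function(record, factors = calibrationFactors()) {
  stopifnot(is(record, "CompoundRecord"), is(factors, "CalibrationFactors"))
  validObject(record); validObject(factors)
  record@kpScaler <- record@kpScaler * factors@kpFactor
  record@clApp <- record@clApp / factors@clDivisor
  validObject(record)
  record
}

# ---------------------------------------------------------------------------
# Compound sheet I/O (YAML)
# ---------------------------------------------------------------------------

#' Write a compound record to a compound-sheet file
#'
#' The sheet is a YAML key-value file with a `kp` sub-table; reading it back
#' with [readCompoundSheet()] reproduces the record exactly.
#'
#' @param record a [CompoundRecord-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCompoundSheet <- function(record, path) {
  stopifnot(is(record, "CompoundRecord"))
  validObject(record)
  x <- list(name = record@name, smiles = record@smiles, mw = record@mw,
            f_up = record@fup, bpr = record@bpr, gi_ka = record@giKa,
            cl_app = record@clApp, vss_per_kg = record@vssPerKg,
            kp = as.list(record@kp[.KP_TISSUES]),
            kp_scaler = record@kpScaler,
            ic50_cyp11b1 = record@ic50Cyp11b1,
            ic50_cyp11b2 = record@ic50Cyp11b2,
            provenance = record@provenance)
  writeLines(yaml::as.yaml(x, precision = 15), path)
  invisible(path)
}

#' Read a compound record from a compound-sheet file
#'
#' @param path path of a YAML compound sheet as written by
#'   [writeCompoundSheet()].
#' @return A validated [CompoundRecord-class].
#' @export
readCompoundSheet <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("name", "smiles", "mw", "f_up", "bpr", "gi_ka", "cl_app",
            "vss_per_kg", "kp", "kp_scaler", "ic50_cyp11b1", "ic50_cyp11b2")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("compound sheet is missing fields: ", paste(missing, collapse = ", "))
  compoundRecord(name = x$name, smiles = x$smiles, mw = x$mw, fup = x$f_up,
                 bpr = x$bpr, giKa = x$gi_ka, clApp = x$cl_app,
                 vssPerKg = x$vss_per_kg, kp = unlist(x$kp),
                 kpScaler = x$kp_scaler, ic50Cyp11b1 = x$ic50_cyp11b1,
                 ic50Cyp11b2 = x$ic50_cyp11b2,
                 provenance = if (is.null(x$provenance)) "" else x$provenance)
}
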