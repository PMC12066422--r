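#' @include AllClasses.R
NULL

#' Accessors for asipbpk S4 objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an asipbpk S4 object.
#' @name accessors
#' @return The corresponding field (see each method's class documentation for
#'   units).
NULL

#' @rdname accessors
#' @export
setGeneric("bodyWeight", function(object) standardGeneric("bodyWeight"))
#' @rdname accessors
#' @export
setGeneric("tissueTable", function(object) standardGeneric("tissueTable"))
#' @rdname accessors
#' @export
setGeneric("cardiacOutput", function(object) standardGeneric("cardiacOutput"))
#' @rdname accessors
#' @export
setGeneric("venousVolume", function(object) standardGeneric("venousVolume"))
#' @rdname accessors
#' @export
setGeneric("arterialVolume", function(object) standardGeneric("arterialVolume"))

#' @rdname accessors
#' @export
setGeneric("compoundName", function(object) standardGeneric("compoundName"))
#' @rdname accessors
#' @export
setGeneric("smilesString", function(object) standardGeneric("smilesString"))
#' @rdname accessors
#' @export
setGeneric("molecularWeight", function(object) standardGeneric("molecularWeight"))
#' @rdname accessors
#' @export
setGeneric("fractionUnbound", function(object) standardGeneric("fractionUnbound"))
#' @rdname accessors
#' @export
setGeneric("bloodPlasmaRatio", function(object) standardGeneric("bloodPlasmaRatio"))
#' @rdname accessors
#' @export
setGeneric("absorptionRate", function(object) standardGeneric("absorptionRate"))
#' @rdname accessors
#' @export
setGeneric("apparentClearance", function(object) standardGeneric("apparentClearance"))
#' @rdname accessors
#' @export
setGeneric("vssPerKg", function(object) standardGeneric("vssPerKg"))
#' @rdname accessors
#' @export
setGeneric("kpValues", function(object) standardGeneric("kpValues"))
#' @rdname accessors
#' @export
setGeneric("kpScaler", function(object) standardGeneric("kpScaler"))
#' @rdname accessors
#' @export
setGeneric("ic50", function(object, enzyme = c("cyp11b2", "cyp11b1"))
  standardGeneric("ic50"))

#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setGeneric("plasmaConc", function(object) standardGeneric("plasmaConc"))
#' @rdname accessors
#' @export
setGeneric("compartmentAmounts", function(object)
  standardGeneric("compartmentAmounts"))

#' @rdname accessors
#' @export
setGeneric("doseAmount", function(object) standardGeneric("doseAmount"))
#' @rdname accessors
#' @export
setGeneric("nDoses", function(object) standardGeneric("nDoses"))
#' @rdname accessors
#' @export
setGeneric("doseInterval", function(object) standardGeneric("doseInterval"))

#' @rdname accessors
#' @export
setGeneric("inhibition", function(object, enzyme = c("cyp11b2", "cyp11b1"))
  standardGeneric("inhibition"))

# --- VirtualSubject ---------------------------------------------------------

#' @rdname accessors
setMethod("bodyWeight", "VirtualSubject", function(object) object@bodyWeight)
#' @rdname accessors
setMethod("tissueTable", "VirtualSubject", function(object) object@tissues)
#' @rdname accessors
setMethod("cardiacOutput", "VirtualSubject", function(object)
  object@tissues$blood_flow[object@tissues$name == "lung"])
#' @rdname accessors
setMethod("venousVolume", "VirtualSubject", function(object) object@venousVolume)
#' @rdname accessors
setMethod("arterialVolume", "VirtualSubject", function(object) object@arterialVolume)

setMethod("show", "VirtualSubject", function(object) {
  cat(sprintf("VirtualSubject: %.1f kg reference human\n", object@bodyWeight))
  cat(sprintf("  cardiac output: %.1f L/h; blood: %.2f L venous + %.2f L arterial\n",
              cardiacOutput(object), object@venousVolume, object@arterialVolume))
  cat(sprintf("  14 tissues, total volume %.2f L\n", sum(object@tissues$volume)))
  invisible(object)
})

# --- CompoundRecord ---------------------------------------------------------

#' @rdname accessors
setMethod("compoundName", "CompoundRecord", function(object) object@name)
#' @rdname accessors
setMethod("smilesString", "CompoundRecord", function(object) object@smiles)
#' @rdname accessors
setMethod("molecularWeight", "CompoundRecord", function(object) object@mw)
#' @rdname accessors
setMethod("fractionUnbound", "CompoundRecord", function(object) object@fup)
#' @rdname accessors
setMethod("bloodPlasmaRatio", "CompoundRecord", function(object) object@bpr)
#' @rdname accessors
setMethod("absorptionRate", "CompoundRecord", function(object) object@giKa)
#' @rdname accessors
setMethod("apparentClearance", "CompoundRecord", function(object) object@clApp)
#' @rdname accessors
setMethod("vssPerKg", "CompoundRecord", function(object) object@vssPerKg)
#' @rdname accessors
setMethod("kpValues", "CompoundRecord", function(object) object@kp[.KP_TISSUES])
#' @rdname accessors
setMethod("kpScaler", "CompoundRecord", function(object) object@kpScaler)
#' @rdname accessors
setMethod("ic50", "CompoundRecord", function(object, enzyme = c("cyp11b2", "cyp11b1")) {
  enzyme <- match.arg(enzyme)
  if (enzyme == "cyp11b2") object@ic50Cyp11b2 else object@ic50Cyp11b1
})

setMethod("show", "CompoundRecord", function(object) {
  cat(sprintf("CompoundRecord: %s (MW %.2f g/mol)\n", object@name, object@mw))
  cat(sprintf("  fup %.2f | bpr %.2f | gi_ka %.2f 1/h | CL_app %.2f L/h | Vss %.2f L/kg\n",
              object@fup, object@bpr, object@giKa, object@clApp, object@vssPerKg))
  cat(sprintf("  Kp scaler %.2f over %d tissues; IC50 CYP11B2 %.4g, CYP11B1 %.4g nmol/L\n",
              object@kpScaler, length(.KP_TISSUES),
              object@ic50Cyp11b2, object@ic50Cyp11b1))
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
  invisible(object)
})

setMethod("show", "CalibrationFactors", function(object) {
  cat(sprintf("CalibrationFactors: Kp_scaler x %.4g, CL_app / %.4g\n",
              object@kpFactor, object@clDivisor))
  invisible(object)
})

# --- DoseRegimen ------------------------------------------------------------

#' @rdname accessors
setMethod("doseAmount", "DoseRegimen", function(object) object@dose)
#' @rdname accessors
setMethod("nDoses", "DoseRegimen", function(object) object@nDoses)
#' @rdname accessors
setMethod("doseInterval", "DoseRegimen", function(object) object@interval)

setMethod("show", "DoseRegimen", function(object) {
  if (object@nDoses == 1L)
    cat(sprintf("DoseRegimen: single oral dose of %g mg\n", object@dose))
  else
    cat(sprintf("DoseRegimen: %g mg oral q%gh x %d doses\n",
                object@dose, object@interval, object@nDoses))
  invisible(object)
})

# --- ConcentrationTimeSeries ------------------------------------------------

#' @rdname accessors
setMethod("timePoints", "ConcentrationTimeSeries", function(object) object@times)
#' @rdname accessors
setMethod("plasmaConc", "ConcentrationTimeSeries", function(object) object@plasmaConc)
#' @rdname accessors
setMethod("compartmentAmounts", "ConcentrationTimeSeries", function(object)
  object@amounts)

setMethod("show", "ConcentrationTimeSeries", function(object) {
  n <- length(object@times)
  cat(sprintf("ConcentrationTimeSeries: %d samples over [0, %g] h\n",
              n, object@times[n]))
  cat(sprintf("  Cmax %.4g ng/mL at t = %g h; eliminated %.4g mg\n",
              max(object@plasmaConc),
              object@times[which.max(object@plasmaConc)],
              object@amounts[n, "eliminated"]))
  invisible(object)
})

# --- PDProfile --------------------------------------------------------------

#' @rdname accessors
setMethod("timePoints", "PDProfile", function(object) object@times)
#' @rdname accessors
setMethod("inhibition", "PDProfile", function(object, enzyme = c("cyp11b2", "cyp11b1")) {
  enzyme <- match.arg(enzyme)
  if (enzyme == "cyp11b2") object@inhibitionCyp11b2 else object@inhibitionCyp11b1
})

setMethod("show", "PDProfile", function(object) {
  n <- length(object@times)
  cat(sprintf("PDProfile: %d samples over [%g, %g] h (E0 %g%%, Imax %g%%)\n",
              n, object@times[1L], object@times[n], object@e0, object@imax))
  cat(sprintf("  peak inhibition: CYP11B2 %.1f%%, CYP11B1 %.1f%%\n",
              max(object@inhibitionCyp11b2), max(object@inhibitionCyp11b1)))
  invisible(object)
})

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign: %s %s, doses {%s} mg", object@compound,
              object@design, paste(object@doses, collapse = ", ")))
  if (object@design == "MAD")
    cat(sprintf(", q%gh x %d", object@interval, object@nDoses))
  cat(sprintf(", horizon %g h\n", object@duration))
  invisible(object)
})
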