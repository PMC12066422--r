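#' @include compound.R
NULL

## Built-in five-compound parameter library. Values are the published ADME
## parameters, tissue:plasma partition coefficients and CYP11B1/CYP11B2 IC50s
## of the five aldosterone synthase inhibitors (LCI699 is the 11beta-
## hydroxylase-selective comparator). f_up of Baxdrostat is literature-
## measured; the remaining parameters are model-predicted.
.ASI_LIBRARY <- list(
  Baxdrostat = list(
    smiles = "CCC(=O)NC1CCCC2=C1C=NC=C2C3=CC4=C(C=C3)N(C(=O)CC4)C",
    mw = 363.50, fup = 0.26, bpr = 0.96, giKa = 0.96, clApp = 14.83,
    vssPerKg = 1.37,
    kp = c(bone = 2.55, brain = 45.07, adipose = 18.05, heart = 7.31,
           kidney = 7.12, gut = 9.81, liver = 4.75, lung = 9.41,
           muscle = 8.02, skin = 37.69, spleen = 5.39),
    kpScaler = 0.16, ic50Cyp11b1 = 1310, ic50Cyp11b2 = 13,
    provenance = "f_up literature-measured; other parameters model-predicted; IC50 from clinical data"),
  BI689648 = list(
    smiles = "COCC1=CC(=CN=C1)C2=CC3=C(N=C2)N(CCC3)C(=O)N",
    mw = 298.36, fup = 0.18, bpr = 1.04, giKa = 0.73, clApp = 14.32,
    vssPerKg = 1.29,
    kp = c(bone = 0.24, brain = 0.22, adipose = 1.29, heart = 0.37,
           kidney = 0.28, gut = 0.30, liver = 0.23, lung = 0.26,
           muscle = 0.13, skin = 0.39, spleen = 0.19),
    kpScaler = 3.75, ic50Cyp11b1 = 310, ic50Cyp11b2 = 2.1,
    provenance = "parameters model-predicted; IC50 from monkey adrenal homogenate"),
  Lorundrostat = list(
    smiles = "CC1=CC=C(C=C1)C2=CN=NC(=N2)N3CCN(CC3)CC(=O)NC4CCC(CC4)NC(=O)C",
    mw = 451.6, fup = 0.11, bpr = 0.66, giKa = 0.36, clApp = 39.36,
    vssPerKg = 1.54,
    kp = c(bone = 0.33, brain = 0.29, adipose = 2.20, heart = 0.46,
           kidney = 0.30, gut = 0.36, liver = 0.26, lung = 0.30,
           muscle = 0.19, skin = 0.46, spleen = 0.22),
    kpScaler = 3.33, ic50Cyp11b1 = 475, ic50Cyp11b2 = 1.27,
    provenance = "parameters model-predicted; IC50 from monkey adrenal homogenate"),
  Dexfadrostat = list(
    smiles = "C1CC(N2C=NC=C2C1)C3=CC=C(C=C3)C#N",
    mw = 223.27, fup = 0.18, bpr = 0.74, giKa = 0.86, clApp = 71.11,
    vssPerKg = 1.67,
    kp = c(bone = 1.21, brain = 1.03, adipose = 11.88, heart = 1.55,
           kidney = 0.81, gut = 0.98, liver = 0.76, lung = 0.31,
           muscle = 0.34, skin = 1.05, spleen = 0.41),
    kpScaler = 0.91, ic50Cyp11b1 = 94, ic50Cyp11b2 = 2.5,
    provenance = "parameters model-predicted; IC50 from monkey adrenal homogenate"),
  LCI699 = list(
    smiles = "C1CC2=CN=CN2C1C3=C(C=C(C=C3)C#N)F",
    mw = 227.24, fup = 0.20, bpr = 0.77, giKa = 1.63, clApp = 95.05,
    vssPerKg = 1.58,
    kp = c(bone = 0.73, brain = 0.63, adipose = 6.58, heart = 0.97,
           kidney = 0.55, gut = 0.64, liver = 0.50, lung = 0.29,
           muscle = 0.25, skin = 0.73, spleen = 0.31),
    kpScaler = 1.46, ic50Cyp11b1 = 77, ic50Cyp11b2 = 10,
    provenance = "parameters model-predicted; IC50 from monkey adrenal homogenate; 11beta-hydroxylase-selective comparator"))

#' Built-in ASI compound library
#'
#' Returns the five built-in aldosterone synthase inhibitor records
#' (Baxdrostat, BI689648, Lorundrostat, Dexfadrostat, LCI699) with their
#' published, uncalibrated parameters. Every record passes a full integrity
#' check on construction; apply [applyCalibration()] for the calibrated
#' parameter set.
#'
#' @return Named list of five [CompoundRecord-class] objects.
#' @export
#' @examples
#' lib <- asiLibrary()
#' names(lib)
#' lib[["Baxdrostat"]]
asiLibrary <- function() {
  out <- lapply(names(.ASI_LIBRARY), function(nm) {
    p <- .ASI_LIBRARY[[nm]]
    tryCatch(
      compoundRecord(name = nm, smiles = p$smiles, mw = p$mw, fup = p$fup,
                     bpr = p$bpr, giKa = p$giKa, clApp = p$clApp,
                     vssPerKg = p$vssPerKg, kp = p$kp, kpScaler = p$kpScaler,
                     ic50Cyp11b1 = p$ic50Cyp11b1, ic50Cyp11b2 = p$ic50Cyp11b2,
                     provenance = p$provenance),
      error = function(e)
        stop(sprintf("library integrity check failed for %s: %s", nm,
                     conditionMessage(e)), call. = FALSE))
  })
  names(out) <- names(.ASI_LIBRARY)
  out
}
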