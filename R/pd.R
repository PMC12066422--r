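#' @include pbpk.R
NULL

#' Free molar concentration from total plasma concentration
#'
#' Only unbound drug is assumed pharmacologically active: the free plasma
#' concentration is `cp * f_up`, converted from ng/mL to nmol/L at molar mass
#' `mw` (`cp * f_up * 1000 / mw`).
#'
#' @param cp total plasma concentration, ng/mL (vectorised).
#' @param fup fraction unbound.
#' @param mw molecular weight, g/mol.
#' @return Free concentration, nmol/L.
#' @export
#' @examples
#' freeMolarConc(363.5, 1, 363.5)  # 1000 nmol/L
freeMolarConc <- function(cp, fup, mw) {
  if (!is.numeric(cp) || any(!is.finite(cp)) || any(cp < 0))
    stop("cp must be non-negative (ng/mL)")
  if (!.is_scalar_num(mw) || mw <= 0)
    stop("mw must be positive (g/mol)")
  if (!.is_scalar_num(fup) || fup <= 0 || fup > 1)
    stop("fup must lie in (0, 1]")
  cp * fup * 1000 / mw
}

#' Emax enzyme inhibition
#'
#' Saturable exposure-response model. The underlying effect equation is
#' `E = E0 - Imax * C / (C + IC50)`; this function reports the positive
#' inhibition magnitude `e0 + imax * c / (c + ic50)` in percent (the
#' convention in which 0% is no inhibition and `imax` complete inhibition).
#'
#' @param cFree free drug concentration, nmol/L (vectorised).
#' @param ic50 half-maximal inhibitory concentration, nmol/L.
#' @param imax maximal inhibition, percent (default 100).
#' @param e0 baseline, percent (default 0).
#' @return Percent inhibition, bounded by `imax`.
#' @export
#' @examples
#' emaxInhibition(10, 10)  # 50 (half-maximal at C = IC50)
emaxInhibition <- function(cFree, ic50, imax = 100, e0 = 0) {
  if (!is.numeric(cFree) || any(!is.finite(cFree)) || any(cFree < 0))
    stop("cFree must be non-negative (nmol/L)")
  if (!.is_scalar_num(ic50) || ic50 <= 0)
    stop("ic50 must be positive (nmol/L)")
  e0 + imax * cFree / (cFree + ic50)
}

#' Selectivity index
#'
#' Ratio of the IC50 toward 11beta-hydroxylase (CYP11B1) to the IC50 toward
#' aldosterone synthase (CYP11B2). Values above 1 indicate preferential
#' aldosterone synthase inhibition.
#'
#' @param ic50Cyp11b1 IC50 toward 11beta-hydroxylase, nmol/L.
#' @param ic50Cyp11b2 IC50 toward aldosterone synthase, nmol/L.
#' @return Unitless selectivity index (unrounded).
#' @export
#' @examples
#' selectivityIndex(77, 10)  # 7.7
selectivityIndex <- function(ic50Cyp11b1, ic50Cyp11b2) {
  if (!is.numeric(ic50Cyp11b1) || any(!is.finite(ic50Cyp11b1)) ||
      any(ic50Cyp11b1 <= 0))
    stop("ic50Cyp11b1 must be positive (nmol/L)")
  if (!is.numeric(ic50Cyp11b2) || any(!is.finite(ic50Cyp11b2)) ||
      any(ic50Cyp11b2 <= 0))
    stop("ic50Cyp11b2 must be positive (nmol/L)")
  ic50Cyp11b1 / ic50Cyp11b2
}

#' Enzyme-inhibition time course from a PK simulation
#'
#' Converts the plasma concentration of a simulated series to free molar
#' concentration and evaluates the Emax model pointwise for each enzyme using
#' the record's CYP11B1 and CYP11B2 IC50s.
#'
#' @param ts a [ConcentrationTimeSeries-class].
#' @param record a [CompoundRecord-class].
#' @param imax maximal inhibition, percent.
#' @param e0 baseline, percent.
#' @return A [PDProfile-class].
#' @export
#' @examples
#' bax <- applyCalibration(asiLibrary()[["Baxdrostat"]])
#' ts <- simulatePbpk(bax, referenceSubject(), doseRegimen(10), tEnd = 48)
#' inhibitionTimecourse(ts, bax)
inhibitionTimecourse <- function(ts, record, imax = 100, e0 = 0) {
  stopifnot(is(ts, "ConcentrationTimeSeries"), is(record, "CompoundRecord"))
  cf <- freeMolarConc(plasmaConc(ts), record@fup, record@mw)
  new("PDProfile", times = timePoints(ts),
      inhibitionCyp11b2 = emaxInhibition(cf, record@ic50Cyp11b2, imax, e0),
      inhibitionCyp11b1 = emaxInhibition(cf, record@ic50Cyp11b1, imax, e0),
      e0 = e0, imax = imax)
}

#' Inhibition summary over a dosing interval
#'
#' Evaluates inhibition of both enzymes at three free-concentration summaries
#' of the interval: the peak, the trough (minimum), and the time-average. All
#' three are reported because a single summary convention is not canonical.
#'
#' @param ts a [ConcentrationTimeSeries-class] covering the interval.
#' @param record a [CompoundRecord-class].
#' @param from,to interval bounds, h (default the full series).
#' @param imax,e0 Emax model constants, percent.
#' @return data.frame with rows `peak`, `trough`, `average` and columns
#'   `free_conc_nM`, `inhib_cyp11b2_pct`, `inhib_cyp11b1_pct`.
#' @export
inhibitionSummary <- function(ts, record, from = NULL, to = NULL,
                              imax = 100, e0 = 0) {
  stopifnot(is(ts, "ConcentrationTimeSeries"), is(record, "CompoundRecord"))
  tv <- timePoints(ts)
  if (is.null(from)) from <- tv[1L]
  if (is.null(to)) to <- tv[length(tv)]
  w <- windowSeries(ts, from, to, rebase = TRUE)
  cf <- freeMolarConc(plasmaConc(w), record@fup, record@mw)
  tw <- timePoints(w)
  cf_avg <- pracma::trapz(tw, cf) / (tw[length(tw)] - tw[1L])
  summaries <- c(peak = max(cf), trough = min(cf), average = cf_avg)
  data.frame(
    row.names = names(summaries),
    free_conc_nM = unname(summaries),
    inhib_cyp11b2_pct = emaxInhibition(unname(summaries), record@ic50Cyp11b2,
                                       imax, e0),
    inhib_cyp11b1_pct = emaxInhibition(unname(summaries), record@ic50Cyp11b1,
                                       imax, e0))
}

#' Write a PD profile to CSV
#'
#' Columns: `time_h`, `inhib_cyp11b2_pct`, `inhib_cyp11b1_pct`.
#'
#' @param profile a [PDProfile-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePdProfile <- function(profile, path) {
  stopifnot(is(profile, "PDProfile"))
  df <- data.frame(time_h = profile@times,
                   inhib_cyp11b2_pct = profile@inhibitionCyp11b2,
                   inhib_cyp11b1_pct = profile@inhibitionCyp11b1)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
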