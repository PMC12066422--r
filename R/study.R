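#' @include pbpk.R nca.R pd.R library.R
NULL

#' Construct a StudyDesign
#'
#' @param compound compound name.
#' @param design "SAD" or "MAD".
#' @param doses dose grid, mg.
#' @param interval dosing interval, h (MAD; default 24).
#' @param nDoses doses per subject; defaults to 1 for SAD and 10 for MAD
#'   (ten 24-h intervals exceed five terminal half-lives for every calibrated
#'   library compound, so the last interval is at steady state).
#' @param duration simulated horizon, h; defaults to 96 h for SAD and to the
#'   full dosing span plus a one-interval washout for MAD.
#' @return A [StudyDesign-class].
#' @export
#' @examples
#' studyDesign("Baxdrostat", "MAD", c(0.5, 1, 3, 10, 30))
studyDesign <- function(compound, design = c("SAD", "MAD"), doses,
                        interval = 24, nDoses = NULL, duration = NULL) {
  design <- match.arg(design)
  if (is.null(nDoses)) nDoses <- if (design == "SAD") 1L else 10L
  if (is.null(duration))
    duration <- if (design == "SAD") 96 else (nDoses - 1L) * interval +
      2 * interval
  new("StudyDesign", compound = as.character(compound), design = design,
      doses = as.numeric(doses), interval = as.numeric(interval),
      nDoses = as.integer(nDoses), duration = as.numeric(duration))
}

#' Default SAD/MAD simulation designs
#'
#' The standard dose-ranging grids: SAD and MAD at {0.5, 1, 3, 10, 30} mg for
#' Baxdrostat, BI689648, Dexfadrostat and LCI699; Lorundrostat (dosed higher
#' clinically) at SAD {5, 10, 20, 50, 100} mg and MAD {3, 12.5, 50, 100} mg.
#' All multiple-dose designs use a 24 h interval.
#'
#' @return List of 10 [StudyDesign-class] objects (5 compounds x SAD/MAD).
#' @export
#' @examples
#' length(defaultDesigns())
defaultDesigns <- function() {
  std <- c(0.5, 1, 3, 10, 30)
  out <- list()
  for (cmp in c("Baxdrostat", "BI689648", "Dexfadrostat", "LCI699")) {
    out[[paste0(cmp, "_SAD")]] <- studyDesign(cmp, "SAD", std)
    out[[paste0(cmp, "_MAD")]] <- studyDesign(cmp, "MAD", std)
  }
  out[["Lorundrostat_SAD"]] <- studyDesign("Lorundrostat", "SAD",
                                           c(5, 10, 20, 50, 100))
  out[["Lorundrostat_MAD"]] <- studyDesign("Lorundrostat", "MAD",
                                           c(3, 12.5, 50, 100))
  out
}

#' Run a SAD/MAD study design
#'
#' Simulates every dose of the design on the given subject, computing per dose
#' the concentration-time series, NCA summaries of the first and last dosing
#' interval, the enzyme-inhibition time course, and the steady-state
#' inhibition summary (peak/trough/average of the last interval). Fully
#' deterministic given its inputs.
#'
#' @param design a [StudyDesign-class].
#' @param library named list of [CompoundRecord-class] objects (default
#'   [asiLibrary()]).
#' @param calibrated apply the default [calibrationFactors()] before
#'   simulating (default TRUE); FALSE simulates the raw parameters.
#' @param subject a [VirtualSubject-class] (default [referenceSubject()]).
#' @param dtOut output sampling step, h.
#' @return List with `design`, `compound` (the record actually simulated) and
#'   `results`: one entry per dose holding `dose`, `series`, `pkFirst`,
#'   `pkLast` (one-row NCA data.frames), `pd` (a [PDProfile-class]) and
#'   `pdSummary`.
#' @export
#' @examples
#' res <- runStudy(studyDesign("Baxdrostat", "SAD", 2.5), dtOut = 0.25)
#' res$results[[1]]$pkFirst
runStudy <- function(design, library = asiLibrary(), calibrated = TRUE,
                     subject = referenceSubject(), dtOut = 0.1) {
  stopifnot(is(design, "StudyDesign"))
  validObject(design)
  if (!design@compound %in% names(library))
    stop(sprintf("unknown compound '%s'; library contains: %s",
                 design@compound, paste(names(library), collapse = ", ")))
  record <- library[[design@compound]]
  if (calibrated) record <- applyCalibration(record)

  n <- design@nDoses
  iv <- design@interval
  results <- lapply(design@doses, function(d) {
    regimen <- doseRegimen(d, nDoses = n, interval = iv)
    ts <- simulatePbpk(record, subject, regimen, tEnd = design@duration,
                       dtOut = dtOut)
    if (n == 1L) {
      pk_first <- pk_last <- ncaSummary(ts)
      ss_from <- 0; ss_to <- min(iv, design@duration)
    } else {
      pk_first <- ncaSummary(windowSeries(ts, 0, iv))
      ss_from <- (n - 1L) * iv; ss_to <- n * iv
      pk_last <- ncaSummary(windowSeries(ts, ss_from, ss_to))
    }
    pd <- inhibitionTimecourse(ts, record)
    list(dose = d, series = ts, pkFirst = pk_first, pkLast = pk_last,
         pd = pd,
         pdSummary = inhibitionSummary(ts, record, from = ss_from, to = ss_to))
  })
  names(results) <- paste0(design@doses, "mg")
  list(design = design, compound = record, results = results)
}

#' Assemble the PK summary table of a study run
#'
#' @param run the return value of [runStudy()].
#' @return data.frame with one row per dose x interval (first/last) and the
#'   four NCA endpoints, suitable for [writeNcaSummary()].
#' @export
studySummaryTable <- function(run) {
  design <- run$design
  do.call(rbind, lapply(run$results, function(r) {
    data.frame(compound = design@compound, design = design@design,
               dose = r$dose,
               interval = c("first", "last"),
               rbind(r$pkFirst, r$pkLast), row.names = NULL)
  }))
}

#' Two-fold deviation check
#'
#' A prediction is acceptable when its ratio to the observation lies within
#' `[0.5, 2]` (boundaries inclusive); outside that band the deviation is
#' considered significant.
#'
#' @param predicted predicted value (> 0 expected for a meaningful ratio).
#' @param observed observed value (> 0).
#' @return List with `ratio` and logical `pass`.
#' @export
#' @examples
#' twoFoldCheck(396.55, 365.79)
twoFoldCheck <- function(predicted, observed) {
  if (!is.numeric(observed) || any(!is.finite(observed)) || any(observed <= 0))
    stop("observed must be positive")
  if (!is.numeric(predicted) || any(!is.finite(predicted)))
    stop("predicted must be a finite number")
  ratio <- predicted / observed
  list(ratio = ratio, pass = ratio >= 0.5 & ratio <= 2)
}
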