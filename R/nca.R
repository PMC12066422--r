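#' @include pbpk.R
NULL

#' Area under the concentration-time curve over an interval
#'
#' Linear trapezoidal integral of plasma concentration over `[lower, upper]`.
#' If either bound is not a grid point a boundary sample is linearly
#' interpolated.
#'
#' @param ts a [ConcentrationTimeSeries-class].
#' @param lower,upper integration bounds, h.
#' @return AUC, ng*h/mL.
#' @export
aucInterval <- function(ts, lower = 0, upper = 24) {
  stopifnot(is(ts, "ConcentrationTimeSeries"))
  tv <- ts@times
  if (lower < tv[1L] || upper > tv[length(tv)] || lower >= upper)
    stop(sprintf("series spans [%g, %g] h; cannot integrate over [%g, %g] h",
                 tv[1L], tv[length(tv)], lower, upper))
  keep <- tv >= lower & tv <= upper
  t_sub <- tv[keep]
  c_sub <- ts@plasmaConc[keep]
  if (!length(t_sub) || t_sub[1L] > lower) {
    t_sub <- c(lower, t_sub)
    c_sub <- c(approx(tv, ts@plasmaConc, xout = lower)$y, c_sub)
  }
  if (t_sub[length(t_sub)] < upper) {
    t_sub <- c(t_sub, upper)
    c_sub <- c(c_sub, approx(tv, ts@plasmaConc, xout = upper)$y)
  }
  pracma::trapz(t_sub, c_sub)
}

#' AUC from 0 to 24 hours
#'
#' @param ts a [ConcentrationTimeSeries-class] spanning at least 24 h.
#' @return AUC0-24, ng*h/mL.
#' @export
#' @examples
#' ts <- simulatePbpk(applyCalibration(asiLibrary()[["Baxdrostat"]]),
#'                    referenceSubject(), doseRegimen(2.5), tEnd = 48)
#' auc024(ts)
auc024 <- function(ts) {
  stopifnot(is(ts, "ConcentrationTimeSeries"))
  if (ts@times[length(ts@times)] < 24)
    stop("series must span at least 24 h for AUC0-24")
  aucInterval(ts, 0, 24)
}

#' Maximum concentration and its time
#'
#' @param ts a [ConcentrationTimeSeries-class].
#' @return Named numeric `c(cmax = ng/mL, tmax = h)`; ties resolve to the
#'   earliest attaining time.
#' @export
cmaxTmax <- function(ts) {
  stopifnot(is(ts, "ConcentrationTimeSeries"))
  i <- which.max(ts@plasmaConc)  # earliest index at the maximum
  c(cmax = ts@plasmaConc[i], tmax = ts@times[i])
}

#' Terminal elimination half-life
#'
#' `ln(2)/k`, where `k` is minus the slope of an ordinary least-squares fit of
#' `log(conc)` on time over the last `nTail` positive-concentration samples
#' after Tmax.
#'
#' @param ts a [ConcentrationTimeSeries-class].
#' @param nTail number of terminal samples in the regression (default 5).
#' @return Terminal half-life, h.
#' @export
terminalHalfLife <- function(ts, nTail = 5L) {
  stopifnot(is(ts, "ConcentrationTimeSeries"))
  nTail <- as.integer(nTail)
  if (nTail < 2L) stop("nTail must be at least 2")
  i_max <- which.max(ts@plasmaConc)
  post <- seq_along(ts@times) > i_max & ts@plasmaConc > 0
  idx <- which(post)
  if (length(idx) < nTail)
    stop(sprintf("need at least %d positive post-peak samples, found %d",
                 nTail, length(idx)))
  idx <- utils::tail(idx, nTail)
  fit <- lm(log(ts@plasmaConc[idx]) ~ ts@times[idx])
  k <- -unname(coef(fit)[2L])
  if (!is.finite(k) || k <= 0)
    stop("no terminal phase: tail log-concentration slope is non-negative")
  log(2) / k
}

#' Prediction-vs-observation fit metrics
#'
#' MAE, MSE, RMSE and R-square between a predicted and an observed series on
#' the same grid. R-square is `1 - SSres/SStot` with SStot about the observed
#' mean; for a constant observed series it is undefined and reported as NaN
#' with a warning.
#'
#' @param pred,obs numeric vectors of equal length (>= 2).
#' @return Named list with `mae`, `mse`, `rmse`, `r2`.
#' @export
#' @examples
#' fitMetrics(c(2, 2), c(1, 3))  # MAE 1, MSE 1, RMSE 1, R2 0
fitMetrics <- function(pred, obs) {
  if (!is.numeric(pred) || !is.numeric(obs) || length(pred) != length(obs))
    stop("pred and obs must be numeric vectors of equal length")
  if (length(pred) < 2L) stop("need at least 2 paired values")
  err <- pred - obs
  mse <- mean(err^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    warning("constant observed series: R-square is undefined")
    r2 <- NaN
  } else {
    r2 <- 1 - sum(err^2) / ss_tot
  }
  list(mae = mean(abs(err)), mse = mse, rmse = sqrt(mse), r2 = r2)
}

#' Non-compartmental PK summary of a series
#'
#' Computes the four standard endpoints of a dosing interval: AUC over
#' `[aucFrom, aucTo]`, Cmax and Tmax (earliest), and the terminal half-life
#' from the series tail. For per-interval summaries of a multiple-dose
#' simulation, pass a [windowSeries()]-rebased interval.
#'
#' @param ts a [ConcentrationTimeSeries-class].
#' @param aucFrom,aucTo AUC bounds, h (default 0-24).
#' @param nTail terminal samples for the half-life fit.
#' @return One-row data.frame with `auc_0_24`, `cmax`, `tmax`, `t_half`.
#' @export
ncaSummary <- function(ts, aucFrom = 0, aucTo = 24, nTail = 5L) {
  ct <- cmaxTmax(ts)
  t_half <- tryCatch(terminalHalfLife(ts, nTail), error = function(e) NA_real_)
  data.frame(auc_0_24 = aucInterval(ts, aucFrom, aucTo),
             cmax = unname(ct["cmax"]), tmax = unname(ct["tmax"]),
             t_half = t_half)
}

#' Write a PK summary table to CSV
#'
#' One row per compound x dose x design with the four NCA endpoints; header
#' mandatory.
#'
#' @param summary data.frame as assembled by [runStudy()] post-processing
#'   (columns compound, design, dose, auc_0_24, cmax, tmax, t_half).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeNcaSummary <- function(summary, path) {
  stopifnot(is.data.frame(summary))
  write.csv(summary, path, row.names = FALSE)
  invisible(path)
}
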