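#' @include AllClasses.R physiology.R compound.R
NULL

#' Construct a DoseRegimen
#'
#' @param dose dose per administration, mg.
#' @param nDoses number of administrations (default 1; multiple doses are
#'   given every `interval` hours).
#' @param interval dosing interval, h (default 24).
#' @return A [DoseRegimen-class].
#' @export
#' @examples
#' doseRegimen(2.5)                    # single oral dose
#' doseRegimen(10, nDoses = 10)        # 10 mg q24h x 10
doseRegimen <- function(dose, nDoses = 1L, interval = 24) {
  new("DoseRegimen", dose = as.numeric(dose), nDoses = as.integer(nDoses),
      interval = as.numeric(interval), route = "oral")
}

## canonical state ordering of the ODE system
.STATE_NAMES <- c("depot", .TISSUES, "venous", "arterial", "eliminated")

#' Effective (scaled) tissue:plasma partition coefficient
#'
#' Returns `kp[tissue] * kpScaler` for the 11 tissues the record carries
#' explicitly. The three tissues without published values use surrogates:
#' stomach takes gut's Kp, pancreas takes spleen's, and rest_of_body the mean
#' of the 11 explicit values — each then scaled by the Kp scaler.
#'
#' @param record a [CompoundRecord-class].
#' @param tissue tissue name(s) among [pbpkTissues()]; default all 14.
#' @return Named numeric vector of effective tissue:plasma partition
#'   coefficients.
#' @export
#' @examples
#' bax <- applyCalibration(asiLibrary()[["Baxdrostat"]])
#' effectiveKp(bax, "liver")
effectiveKp <- function(record, tissue = pbpkTissues()) {
  stopifnot(is(record, "CompoundRecord"))
  validObject(record)
  unknown <- setdiff(tissue, .TISSUES)
  if (length(unknown))
    stop(sprintf("unknown tissue(s): %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(.TISSUES, collapse = ", ")))
  base <- record@kp[.KP_TISSUES]
  full <- c(base, stomach = unname(base["gut"]),
            pancreas = unname(base["spleen"]),
            rest_of_body = mean(base))
  out <- full[tissue] * record@kpScaler
  names(out) <- tissue
  out
}

#' Build the whole-body ODE right-hand side
#'
#' Assembles the linear rate equations of the whole-body model over the state
#' `(depot, 14 tissue amounts, venous, arterial, eliminated)`, all in mg.
#' Each non-lung tissue T obeys
#' `dA_T/dt = Q_T * A_ART/V_ART - Q_T * A_T / (V_T * KpB_T)`; the lung is fed
#' from the mixed venous pool with the same form. The gut additionally gains
#' `gi_ka * A_depot` (oral absorption), the arterial pool collects the lung
#' outflow and feeds all non-lung tissues, and the venous pool collects the
#' non-lung tissue outflows, feeds the lung, and loses `CL * C_plasma` to
#' elimination. `KpB_T = effectiveKp/bpr` converts the tissue:plasma
#' coefficient to tissue:blood; `C_plasma = (A_VEN/V_VEN)/bpr`.
#'
#' @param record a [CompoundRecord-class].
#' @param subject a [VirtualSubject-class]; a flow-imbalanced subject is
#'   rejected at build time.
#' @return A list with `rates(t, state, parms)` (deSolve-compatible rate
#'   function), the constant system `matrix`, and `stateNames`.
#' @export
#' @examples
#' sys <- buildOdes(asiLibrary()[["Baxdrostat"]], referenceSubject())
#' y0 <- setNames(numeric(18), sys$stateNames)
#' sys$rates(0, y0, NULL)[[1]]  # zero state -> zero derivative
buildOdes <- function(record, subject) {
  stopifnot(is(record, "CompoundRecord"), is(subject, "VirtualSubject"))
  validObject(record)
  validObject(subject)  # rejects flow-imbalanced subjects

  tt <- tissueTable(subject)
  vol <- setNames(tt$volume, tt$name)[.TISSUES]
  q <- setNames(tt$blood_flow, tt$name)[.TISSUES]
  v_ven <- venousVolume(subject)
  v_art <- arterialVolume(subject)
  bpr <- record@bpr
  kpb <- effectiveKp(record) / bpr  # tissue:blood
  cl <- record@clApp
  ka <- record@giKa

  n <- length(.STATE_NAMES)
  A <- matrix(0, n, n, dimnames = list(.STATE_NAMES, .STATE_NAMES))
  nonlung <- setdiff(.TISSUES, "lung")

  ## depot -> gut (first-order oral absorption)
  A["depot", "depot"] <- -ka
  A["gut", "depot"] <- ka

  ## tissue exchange with blood
  for (ts in nonlung) {
    kout <- q[ts] / (vol[ts] * kpb[ts])
    A[ts, "arterial"] <- A[ts, "arterial"] + q[ts] / v_art
    A[ts, ts] <- A[ts, ts] - kout
    A["venous", ts] <- A["venous", ts] + kout
  }
  k_lung_out <- q["lung"] / (vol["lung"] * kpb["lung"])
  A["lung", "venous"] <- A["lung", "venous"] + q["lung"] / v_ven
  A["lung", "lung"] <- A["lung", "lung"] - k_lung_out
  A["arterial", "lung"] <- A["arterial", "lung"] + k_lung_out
  A["arterial", "arterial"] <- A["arterial", "arterial"] - sum(q[nonlung]) / v_art
  A["venous", "venous"] <- A["venous", "venous"] - q["lung"] / v_ven

  ## systemic clearance acts on venous plasma concentration
  k_el <- cl / (v_ven * bpr)
  A["venous", "venous"] <- A["venous", "venous"] - k_el
  A["eliminated", "venous"] <- k_el

  rates <- function(t, state, parms) list(as.vector(A %*% state))
  list(rates = rates, matrix = A, stateNames = .STATE_NAMES)
}

#' Simulate a dosing regimen on the whole-body model
#'
#' Integrates the ODE system of [buildOdes()] with each dose added to the oral
#' depot at `k * interval` (k = 0, ..., nDoses-1). The integrator (lsoda)
#' restarts at every dose event so the impulses are exact. Plasma
#' concentration is reported as `(A_VEN/V_VEN)/bpr` in ng/mL. Tolerances are
#' fixed at `rtol = 1e-8`, `atol = 1e-10` for reproducibility.
#'
#' @param record a [CompoundRecord-class].
#' @param subject a [VirtualSubject-class].
#' @param regimen a [DoseRegimen-class].
#' @param tEnd simulation horizon, h; must cover the last dose.
#' @param dtOut output sampling step, h (default 0.1).
#' @param infusionRate test-harness constant venous infusion, mg/h
#'   (default 0; not a user-facing dosing route).
#' @param rtol,atol solver tolerances.
#' @return A [ConcentrationTimeSeries-class].
#' @export
#' @examples
#' ts <- simulatePbpk(applyCalibration(asiLibrary()[["Baxdrostat"]]),
#'                    referenceSubject(), doseRegimen(2.5), tEnd = 48)
#' ts
simulatePbpk <- function(record, subject, regimen, tEnd, dtOut = 0.1,
                         infusionRate = 0, rtol = 1e-8, atol = 1e-10) {
  stopifnot(is(regimen, "DoseRegimen"))
  validObject(regimen)
  if (!.is_scalar_num(tEnd) || tEnd <= 0) stop("tEnd must be positive (h)")
  if (!.is_scalar_num(dtOut) || dtOut <= 0) stop("dtOut must be positive (h)")
  if (regimen@nDoses > 1L && tEnd < (regimen@nDoses - 1L) * regimen@interval)
    stop("tEnd must cover the last dose: need >= (nDoses-1)*interval")

  sys <- buildOdes(record, subject)
  A <- sys$matrix
  forc <- numeric(length(.STATE_NAMES))
  names(forc) <- .STATE_NAMES
  forc["venous"] <- infusionRate
  rates <- function(t, state, parms) list(as.vector(A %*% state) + forc)

  dose_times <- if (regimen@nDoses > 1L)
    regimen@interval * seq_len(regimen@nDoses - 1L) else numeric()
  times <- sort(unique(c(seq(0, tEnd, by = dtOut), tEnd, dose_times)))

  y0 <- setNames(numeric(length(.STATE_NAMES)), .STATE_NAMES)
  y0["depot"] <- regimen@dose

  events <- NULL
  if (length(dose_times))
    events <- list(data = data.frame(var = "depot", time = dose_times,
                                     value = regimen@dose, method = "add"))

  sol <- deSolve::lsoda(y = y0, times = times, func = rates, parms = NULL,
                        events = events, rtol = rtol, atol = atol,
                        maxsteps = 50000)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1L] < 0)
    stop(sprintf(
      "ODE solver failed (istate %d) for %s; last time reached %.4g h",
      diagn[1L], record@name, max(sol[, "time"])))

  amounts <- unclass(sol)[, .STATE_NAMES, drop = FALSE]
  total_dosed <- regimen@dose * regimen@nDoses
  neg_tol <- max(1e-9 * max(total_dosed, 1), atol * 100)
  if (any(amounts < -neg_tol)) {
    worst <- which(amounts == min(amounts), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "negative state beyond tolerance: compartment '%s' reached %.3g mg at t = %.4g h",
      colnames(amounts)[worst["col"]], min(amounts),
      sol[worst["row"], "time"]))
  }
  amounts[amounts < 0] <- 0  # clamp solver noise within tolerance

  ## ng/mL = (mg/L) * 1000, plasma = venous blood / bpr
  conc <- (amounts[, "venous"] / venousVolume(subject)) / record@bpr * 1000

  new("ConcentrationTimeSeries", times = as.numeric(sol[, "time"]),
      plasmaConc = as.numeric(conc), amounts = amounts)
}

#' Window a concentration-time series
#'
#' Extracts the samples in `[from, to]` (interpolating boundary samples if the
#' endpoints are not grid points) and, by default, rebases time so the window
#' starts at 0 — the form the per-interval NCA expects.
#'
#' @param ts a [ConcentrationTimeSeries-class].
#' @param from,to window bounds, h.
#' @param rebase shift times so the window starts at 0 (default TRUE).
#' @return A [ConcentrationTimeSeries-class] covering the window.
#' @export
windowSeries <- function(ts, from, to, rebase = TRUE) {
  stopifnot(is(ts, "ConcentrationTimeSeries"))
  tv <- ts@times
  if (from < tv[1L] || to > tv[length(tv)] || from >= to)
    stop(sprintf("window [%g, %g] h outside the series span [%g, %g] h",
                 from, to, tv[1L], tv[length(tv)]))
  keep <- tv >= from & tv <= to
  t_new <- tv[keep]
  conc <- ts@plasmaConc[keep]
  amt <- ts@amounts[keep, , drop = FALSE]
  interp_row <- function(at) {
    vapply(seq_len(ncol(ts@amounts)), function(j)
      approx(tv, ts@amounts[, j], xout = at)$y, numeric(1L))
  }
  if (!length(t_new) || t_new[1L] > from) {
    t_new <- c(from, t_new)
    conc <- c(approx(tv, ts@plasmaConc, xout = from)$y, conc)
    amt <- rbind(interp_row(from), amt)
  }
  if (t_new[length(t_new)] < to) {
    t_new <- c(t_new, to)
    conc <- c(conc, approx(tv, ts@plasmaConc, xout = to)$y)
    amt <- rbind(amt, interp_row(to))
  }
  if (rebase) t_new <- t_new - from
  colnames(amt) <- colnames(ts@amounts)
  new("ConcentrationTimeSeries", times = t_new, plasmaConc = conc,
      amounts = amt)
}

#' Calibrate Kp scaler and clearance against observed concentrations
#'
#' Exhaustive grid search over `(kpFactor, clDivisor)` pairs: for each pair
#' the record is calibrated with [applyCalibration()], the regimen simulated,
#' the simulation interpolated at the observed sampling times, and the RMSE
#' against the observed concentrations computed. Returns the factor pair with
#' minimal RMSE; ties break deterministically toward the smallest `kpFactor`,
#' then the smallest `clDivisor`.
#'
#' @param record an uncalibrated [CompoundRecord-class].
#' @param subject a [VirtualSubject-class].
#' @param regimen a [DoseRegimen-class].
#' @param observed data.frame with columns `time_h`, `conc_ng_per_mL`; at
#'   least 3 points inside the simulated window.
#' @param kpFactors,clDivisors candidate factor grids (positive numerics).
#' @param dtOut output step for the candidate simulations, h.
#' @return The best-fitting [CalibrationFactors-class], with attributes
#'   `rmse` (the achieved RMSE) and `grid` (the full RMSE table).
#' @export
calibrateToObserved <- function(record, subject, regimen, observed,
                                kpFactors, clDivisors, dtOut = 0.25) {
  stopifnot(is(record, "CompoundRecord"), is(subject, "VirtualSubject"),
            is(regimen, "DoseRegimen"))
  if (!is.data.frame(observed) ||
      !all(c("time_h", "conc_ng_per_mL") %in% names(observed)))
    stop("observed must be a data.frame with columns time_h, conc_ng_per_mL")
  if (!length(kpFactors) || !length(clDivisors) ||
      any(kpFactors <= 0) || any(clDivisors <= 0))
    stop("kpFactors and clDivisors must be non-empty positive grids")
  t_end <- max(observed$time_h)
  if (sum(observed$time_h >= 0 & observed$time_h <= t_end) < 3L)
    stop("observed must contain at least 3 points within the simulated window")

  grid <- expand.grid(kpFactor = sort(unique(kpFactors)),
                      clDivisor = sort(unique(clDivisors)),
                      KEEP.OUT.ATTRS = FALSE)
  grid$rmse <- vapply(seq_len(nrow(grid)), function(i) {
    cal <- applyCalibration(record, calibrationFactors(grid$kpFactor[i],
                                                       grid$clDivisor[i]))
    ts <- simulatePbpk(cal, subject, regimen, tEnd = t_end, dtOut = dtOut)
    pred <- approx(timePoints(ts), plasmaConc(ts),
                   xout = observed$time_h, rule = 2)$y
    sqrt(mean((pred - observed$conc_ng_per_mL)^2))
  }, numeric(1L))

  ## grid is sorted by (clDivisor, kpFactor) blocks; re-rank for the stated
  ## tie-break: smallest kpFactor first, then smallest clDivisor
  ord <- order(grid$rmse, grid$kpFactor, grid$clDivisor)
  best <- grid[ord[1L], ]
  out <- calibrationFactors(best$kpFactor, best$clDivisor)
  attr(out, "rmse") <- best$rmse
  attr(out, "grid") <- grid
  out
}

# ---------------------------------------------------------------------------
# Time-series I/O
# ---------------------------------------------------------------------------

#' Write a concentration-time series to CSV
#'
#' Columns: `time_h`, `plasma_ng_per_mL`, then one column per compartment
#' amount in mg; header row mandatory.
#'
#' @param ts a [ConcentrationTimeSeries-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTimeSeries <- function(ts, path) {
  stopifnot(is(ts, "ConcentrationTimeSeries"))
  df <- data.frame(time_h = ts@times, plasma_ng_per_mL = ts@plasmaConc,
                   ts@amounts, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an observed concentration table
#'
#' @param path CSV with columns `time_h`, `conc_ng_per_mL`.
#' @return data.frame with those two columns, sorted by time.
#' @export
readObservedConc <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_h", "conc_ng_per_mL") %in% names(df)))
    stop("observed-concentration CSV must have columns time_h, conc_ng_per_mL")
  df <- df[order(df$time_h), c("time_h", "conc_ng_per_mL")]
  rownames(df) <- NULL
  df
}
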