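lib <- asiLibrary()
subj <- referenceSubject()

test_that("effective Kp scales printed values and fills surrogate tissues", {
  bax14 <- compoundRecord("bax14", "C", mw = 363.5, fup = 0.26, bpr = 0.96,
                          giKa = 0.96, clApp = 3.15, vssPerKg = 1.37,
                          kp = kpValues(lib[["Baxdrostat"]]), kpScaler = 0.14,
                          ic50Cyp11b1 = 1310, ic50Cyp11b2 = 13)
  expect_equal(unname(effectiveKp(bax14, "liver")), 4.75 * 0.14)
  for (rec in lib) {
    ek <- effectiveKp(rec)
    expect_named(ek, pbpkTissues())
    expect_equal(unname(ek["stomach"]), unname(ek["gut"]))
    expect_equal(unname(ek["pancreas"]), unname(ek["spleen"]))
    expect_equal(unname(ek["rest_of_body"]),
                 mean(kpValues(rec)) * kpScaler(rec))
    # identity scaler returns the printed values unchanged
    raw <- rec; raw@kpScaler <- 1
    expect_equal(effectiveKp(raw, kpTissues()), kpValues(rec))
  }
  expect_error(effectiveKp(lib[["LCI699"]], "gizzard"), "unknown tissue")
})

test_that("the ODE system is linear, mass-closed, and rejects bad subjects", {
  sys <- buildOdes(lib[["Baxdrostat"]], subj)
  y0 <- setNames(numeric(18), sys$stateNames)
  expect_equal(sys$rates(0, y0, NULL)[[1]], rep(0, 18))
  # total mass (incl. eliminated) is conserved at arbitrary states
  set.seed(11)
  for (i in 1:20) {
    y <- setNames(runif(18, 0, 5), sys$stateNames)
    expect_equal(sum(sys$rates(0, y, NULL)[[1]]), 0, tolerance = 1e-10)
  }

  # with CL = 0 and unit partitioning the equilibrium is uniform concentration
  sys0 <- buildOdes(toyRecord(clApp = 1e-12), subj)
  tt <- tissueTable(subj)
  vols <- c(depot = 0, setNames(tt$volume, tt$name)[pbpkTissues()],
            venous = venousVolume(subj), arterial = arterialVolume(subj),
            eliminated = 0)
  y_eq <- vols * 2  # 2 mg/L everywhere, nothing in depot
  dy <- sys0$rates(0, y_eq, NULL)[[1]]
  expect_equal(max(abs(dy[2:17])), 0, tolerance = 1e-9)

  bad <- subj
  bad@tissues$blood_flow[bad@tissues$name == "kidney"] <- 999
  expect_error(buildOdes(lib[["Baxdrostat"]], bad), "flow imbalance")
})

test_that("zero dose yields an identically zero series", {
  ts <- simulatePbpk(toyRecord(), subj, doseRegimen(0), tEnd = 24, dtOut = 1)
  expect_equal(max(plasmaConc(ts)), 0)
  expect_equal(max(compartmentAmounts(ts)), 0)
})

test_that("mass balance holds over single and multiple dosing", {
  bax <- applyCalibration(lib[["Baxdrostat"]])
  for (reg in list(doseRegimen(2.5),
                   doseRegimen(10, nDoses = 4, interval = 24))) {
    ts <- simulatePbpk(bax, subj, reg, tEnd = 96, dtOut = 0.5)
    amt <- compartmentAmounts(ts)
    # doses at exactly t = k*interval are reported pre-dose by the solver
    given <- doseAmount(reg) *
      pmin(floor(timePoints(ts) / doseInterval(reg) - 1e-12) + 1, nDoses(reg))
    given[1] <- doseAmount(reg)
    expect_equal(rowSums(amt), given, tolerance = 1e-6)
  }
  # no elimination: everything administered stays in the body
  ts0 <- simulatePbpk(toyRecord(clApp = 1e-10), subj,
                      doseRegimen(5, nDoses = 3, interval = 12),
                      tEnd = 48, dtOut = 0.5)
  body <- rowSums(compartmentAmounts(ts0)[, setdiff(colnames(compartmentAmounts(ts0)),
                                                    "eliminated")])
  expect_equal(body[length(body)], 15, tolerance = 1e-6)
})

test_that("plasma exposure is dose-proportional", {
  bax <- applyCalibration(lib[["Baxdrostat"]])
  ts1 <- simulatePbpk(bax, subj, doseRegimen(1), tEnd = 48, dtOut = 0.25)
  ts10 <- simulatePbpk(bax, subj, doseRegimen(10), tEnd = 48, dtOut = 0.25)
  expect_equal(auc024(ts10) / auc024(ts1), 10, tolerance = 1e-3)
  expect_equal(unname(cmaxTmax(ts10)["cmax"] / cmaxTmax(ts1)["cmax"]), 10,
               tolerance = 1e-3)
  expect_equal(unname(cmaxTmax(ts10)["tmax"]), unname(cmaxTmax(ts1)["tmax"]))
})

test_that("a multiple-dose profile is the superposition of shifted single doses", {
  bax <- applyCalibration(lib[["Baxdrostat"]])
  n <- 4L; iv <- 24
  mad <- simulatePbpk(bax, subj, doseRegimen(10, nDoses = n, interval = iv),
                      tEnd = 120, dtOut = 0.5)
  sad <- simulatePbpk(bax, subj, doseRegimen(10), tEnd = 120, dtOut = 0.5)
  t <- timePoints(sad)
  super <- numeric(length(t))
  for (k in seq_len(n) - 1L) {
    sh <- t - iv * k
    ok <- sh >= 0
    super[ok] <- super[ok] + approx(t, plasmaConc(sad), xout = sh[ok])$y
  }
  expect_equal(plasmaConc(mad), super, tolerance = 1e-3)
})

test_that("the collapsed subject reproduces the analytic Bateman solution", {
  rec <- toyRecord(clApp = 5, giKa = 0.8)
  csub <- collapsedSubject()
  ts <- simulatePbpk(rec, csub, doseRegimen(10), tEnd = 48, dtOut = 0.25)
  vol <- totalVolume(csub)
  expected <- batemanConc(timePoints(ts), 10, ka = 0.8, ke = 5 / vol, vol = vol)
  expect_lt(max(abs(plasmaConc(ts) - expected)) / max(expected), 1e-3)
})

test_that("constant venous infusion reaches Css = R/CL", {
  rec <- toyRecord(clApp = 5)
  ts <- simulatePbpk(rec, subj, doseRegimen(0), tEnd = 1500, dtOut = 10,
                     infusionRate = 2)
  css <- plasmaConc(ts)[length(timePoints(ts))]
  expect_equal(css, 2 / 5 * 1000, tolerance = 1e-3)
})

test_that("slower clearance never decreases AUC", {
  bax <- lib[["Baxdrostat"]]
  aucs <- vapply(c(1, 2, 4.7, 8), function(cd) {
    cal <- applyCalibration(bax, calibrationFactors(0.85, cd))
    auc024(simulatePbpk(cal, subj, doseRegimen(2.5), tEnd = 24, dtOut = 0.5))
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
})

test_that("regimen preconditions are enforced", {
  expect_error(doseRegimen(-1), "non-negative")
  expect_error(doseRegimen(1, nDoses = 3, interval = 0), "interval")
  expect_error(simulatePbpk(toyRecord(), subj,
                            doseRegimen(1, nDoses = 5, interval = 24),
                            tEnd = 48), "cover the last dose")
})

test_that("grid-search calibration recovers known factors", {
  bax <- lib[["Baxdrostat"]]
  reg <- doseRegimen(2.5)
  truth <- applyCalibration(bax, calibrationFactors(0.85, 4.7))
  sim <- simulatePbpk(truth, subj, reg, tEnd = 96, dtOut = 0.25)
  obs_t <- c(0.5, 1, 2, 3, 4, 6, 8, 12, 16, 24, 36, 48, 60, 72, 96)
  base <- approx(timePoints(sim), plasmaConc(sim), xout = obs_t)$y
  kf <- seq(0.75, 0.95, by = 0.05)
  cd <- seq(4.3, 5.1, by = 0.2)

  # noiseless self-recovery is exact
  fit <- calibrateToObserved(bax, subj, reg,
                             data.frame(time_h = obs_t, conc_ng_per_mL = base),
                             kpFactors = kf, clDivisors = cd)
  expect_equal(fit@kpFactor, 0.85)
  expect_equal(fit@clDivisor, 4.7)
  expect_lt(attr(fit, "rmse"), 1e-8)

  # a one-point grid returns that point
  one <- calibrateToObserved(bax, subj, reg,
                             data.frame(time_h = obs_t, conc_ng_per_mL = base),
                             kpFactors = 0.9, clDivisors = 5)
  expect_equal(c(one@kpFactor, one@clDivisor), c(0.9, 5))

  # 5% multiplicative noise moves the optimum at most one grid step
  set.seed(1)
  noisy <- data.frame(time_h = obs_t,
                      conc_ng_per_mL = base * (1 + rnorm(length(base), 0, 0.05)))
  fitn <- calibrateToObserved(bax, subj, reg, noisy,
                              kpFactors = kf, clDivisors = cd)
  expect_lte(abs(fitn@kpFactor - 0.85), 0.05 + 1e-12)
  expect_lte(abs(fitn@clDivisor - 4.7), 0.2 + 1e-12)

  expect_error(calibrateToObserved(bax, subj, reg, noisy,
                                   kpFactors = numeric(), clDivisors = cd),
               "non-empty")
  expect_error(calibrateToObserved(bax, subj, reg, noisy[1:2, ],
                                   kpFactors = kf, clDivisors = cd),
               "at least 3 points")
})

test_that("time-series and observed-data files round-trip", {
  bax <- applyCalibration(lib[["Baxdrostat"]])
  ts <- simulatePbpk(bax, subj, doseRegimen(2.5), tEnd = 24, dtOut = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  writeTimeSeries(ts, f)
  df <- read.csv(f, check.names = FALSE)
  expect_equal(names(df)[1:2], c("time_h", "plasma_ng_per_mL"))
  expect_equal(df$plasma_ng_per_mL, plasmaConc(ts))
  expect_true(all(c("depot", "venous", "eliminated") %in% names(df)))

  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_h = c(4, 1, 2), conc_ng_per_mL = c(3, 1, 2)), f2,
            row.names = FALSE)
  obs <- readObservedConc(f2)
  expect_equal(obs$time_h, c(1, 2, 4))  # sorted on read
  expect_error(readObservedConc(f), "columns")  # wrong layout rejected
})

test_that("windowing extracts and rebases an interval exactly", {
  bax <- applyCalibration(lib[["Baxdrostat"]])
  ts <- simulatePbpk(bax, subj, doseRegimen(10, nDoses = 3, interval = 24),
                     tEnd = 72, dtOut = 0.5)
  w <- windowSeries(ts, 48, 72)
  expect_equal(timePoints(w)[1], 0)
  expect_equal(max(timePoints(w)), 24)
  expect_equal(plasmaConc(w)[1],
               plasmaConc(ts)[timePoints(ts) == 48])
  expect_error(windowSeries(ts, -1, 24), "outside")
})
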