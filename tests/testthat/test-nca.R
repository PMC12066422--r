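test_that("trapezoidal AUC handles flat, ramp, and split intervals", {
  t48 <- seq(0, 48, by = 0.5)
  expect_equal(auc024(syntheticSeries(t48, rep(1, length(t48)))), 24)
  t24 <- seq(0, 24, by = 0.1)
  expect_equal(auc024(syntheticSeries(t24, t24)), 288)  # triangle 24*24/2
  # interpolated boundary when 24 h is off-grid
  toff <- c(seq(0, 23.7, by = 0.3), 25)
  expect_equal(auc024(syntheticSeries(toff, rep(2, length(toff)))), 48)
  # additivity over subintervals
  bax <- applyCalibration(asiLibrary()[["Baxdrostat"]])
  ts <- simulatePbpk(bax, referenceSubject(), doseRegimen(2.5),
                     tEnd = 48, dtOut = 0.25)
  expect_equal(aucInterval(ts, 0, 12) + aucInterval(ts, 12, 24), auc024(ts))
  expect_error(auc024(syntheticSeries(seq(0, 12, 1), rep(1, 13))), "24 h")
})

test_that("Cmax/Tmax take the earliest maximum", {
  tv <- seq(0, 48, by = 0.5)
  expect_equal(cmaxTmax(syntheticSeries(tv, rep(3, length(tv)))),
               c(cmax = 3, tmax = 0))
  # single-peak Bateman curve peaks at ln(ka/ke)/(ka - ke)
  ka <- 1.2; ke <- 0.1
  conc <- batemanConc(tv, 10, ka, ke, vol = 50)
  ct <- cmaxTmax(syntheticSeries(tv, conc))
  expect_lte(abs(ct[["tmax"]] - log(ka / ke) / (ka - ke)), 0.5)
})

test_that("terminal half-life comes from the log-linear tail", {
  tv <- seq(0, 48, by = 2)
  expect_equal(terminalHalfLife(syntheticSeries(tv, 10 * exp(-0.1 * tv))),
               log(2) / 0.1)
  expect_equal(terminalHalfLife(syntheticSeries(tv, 10 * exp(-0.693 * tv))),
               log(2) / 0.693)
  # invariant under multiplicative rescaling of concentrations
  expect_equal(terminalHalfLife(syntheticSeries(tv, 7.3 * 10 * exp(-0.1 * tv))),
               terminalHalfLife(syntheticSeries(tv, 10 * exp(-0.1 * tv))))
  # a non-decaying tail has no terminal phase
  flat_tail <- c(1, 10, 8, 6, rep(5, 7))
  expect_error(terminalHalfLife(syntheticSeries(0:10, flat_tail)),
               "no terminal phase")
  expect_error(terminalHalfLife(syntheticSeries(seq(0, 3, 1),
                                                c(1, 2, 1.5, 1.2)), nTail = 5),
               "post-peak")
})

test_that("fit metrics match hand-computed values and Jensen ordering", {
  m <- fitMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m), c(mae = 0, mse = 0, rmse = 0, r2 = 1))
  m2 <- fitMetrics(c(2, 2), c(1, 3))
  expect_equal(unlist(m2), c(mae = 1, mse = 1, rmse = 1, r2 = 0))
  set.seed(7)
  for (i in 1:10) {
    p <- rnorm(20); o <- rnorm(20)
    m3 <- fitMetrics(p, o)
    expect_gte(m3$rmse, m3$mae)
    expect_equal(m3$rmse, sqrt(m3$mse))
    expect_lte(m3$r2, 1)
  }
  expect_warning(mc <- fitMetrics(c(1, 2), c(5, 5)), "undefined")
  expect_true(is.nan(mc$r2))
  expect_error(fitMetrics(1, c(1, 2)), "equal length")
})

test_that("NCA summaries inherit dose linearity", {
  bax <- applyCalibration(asiLibrary()[["Baxdrostat"]])
  subj <- referenceSubject()
  s1 <- ncaSummary(simulatePbpk(bax, subj, doseRegimen(1), tEnd = 72,
                                dtOut = 0.25))
  s10 <- ncaSummary(simulatePbpk(bax, subj, doseRegimen(10), tEnd = 72,
                                 dtOut = 0.25))
  expect_equal(s10$auc_0_24 / s1$auc_0_24, 10, tolerance = 1e-3)
  expect_equal(s10$cmax / s1$cmax, 10, tolerance = 1e-3)
  expect_equal(s10$tmax, s1$tmax)
  expect_equal(s10$t_half, s1$t_half, tolerance = 1e-6)
})
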